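#' Pipeline configuration
#'
#' A single validated configuration object binding all stage parameters:
#' paradigm and ground-truth settings, QC thresholds (0.5 voxel motion /
#' 5% global signal / 6 mm max displacement / 15% repaired volumes /
#' 7 runs), GLM settings, cluster-correction settings, and MVPA settings.
#' Configurations round-trip losslessly through JSON
#' ([write_config_json()] / [read_config_json()]).
#'
#' @param n_td,n_asd cohort group sizes.
#' @param paradigm a [paradigm_spec()].
#' @param seed master seed; all stage seeds are derived from it.
#' @param qc list: `voxel_mm`, `global_pct`, `max_disp_mm`,
#'   `max_pct_repaired`, `min_runs`.
#' @param glm list: `hp_cutoff_s`, `baseline`.
#' @param correction list: `voxel_p`, `fwe_p`, `n_iter`, `fwhm_mm`.
#' @param mvpa list: `C`, `k`, `repeats`, `n_perm`, `alpha`, `epsilon`.
#' @param spike_prob per-volume artifact probability injected before QC.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(n_td = 21, n_asd = 21,
                            paradigm = paradigm_spec(), seed = 1L,
                            qc = list(voxel_mm = 3.125,
                                      global_pct = 0.05,
                                      max_disp_mm = 6,
                                      max_pct_repaired = 0.15,
                                      min_runs = 7),
                            glm = list(hp_cutoff_s = 120,
                                       baseline = "environmental"),
                            correction = list(voxel_p = 0.005,
                                              fwe_p = 0.05,
                                              n_iter = 1000,
                                              fwhm_mm = 6),
                            mvpa = list(C = 1, k = 4, repeats = 100,
                                        n_perm = 1000, alpha = 0.05,
                                        epsilon = 0.1),
                            spike_prob = 0.02) {
  cfg <- structure(list(n_td = n_td, n_asd = n_asd, paradigm = paradigm,
                        seed = seed, qc = qc, glm = glm,
                        correction = correction, mvpa = mvpa,
                        spike_prob = spike_prob),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config object to validate; errors name the offending field.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid config field `%s`: %s", field, msg))
  chk(config$n_td >= 1 && config$n_asd >= 1, "n_td/n_asd",
      "group sizes must be >= 1")
  chk(inherits(config$paradigm, "paradigm_spec"), "paradigm",
      "must be a paradigm_spec")
  q <- config$qc
  chk(q$voxel_mm > 0, "qc$voxel_mm", "must be positive")
  chk(q$global_pct > 0 && q$global_pct < 1, "qc$global_pct",
      "must be in (0, 1)")
  chk(q$max_disp_mm > 0, "qc$max_disp_mm", "must be positive")
  chk(q$max_pct_repaired >= 0 && q$max_pct_repaired <= 1,
      "qc$max_pct_repaired", "must be in [0, 1]")
  chk(q$min_runs >= 1, "qc$min_runs", "must be >= 1")
  co <- config$correction
  chk(co$voxel_p > 0 && co$voxel_p < 1, "correction$voxel_p",
      "must be in (0, 1)")
  chk(co$fwe_p > 0 && co$fwe_p < 1, "correction$fwe_p",
      "must be in (0, 1)")
  chk(co$n_iter >= 1, "correction$n_iter", "must be >= 1")
  chk(co$fwhm_mm >= 0, "correction$fwhm_mm", "must be non-negative")
  m <- config$mvpa
  chk(m$C > 0, "mvpa$C", "must be positive")
  chk(m$k >= 2, "mvpa$k", "must be >= 2")
  chk(m$repeats >= 1, "mvpa$repeats", "must be >= 1")
  chk(m$n_perm >= 1, "mvpa$n_perm", "must be >= 1")
  chk(m$alpha > 0 && m$alpha < 1, "mvpa$alpha", "must be in (0, 1)")
  chk(config$spike_prob >= 0 && config$spike_prob <= 1, "spike_prob",
      "must be in [0, 1]")
  invisible(config)
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config_json <- function(config, path) {
  lst <- unclass(config)
  lst$paradigm <- unclass(lst$paradigm)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lst$paradigm
  paradigm <- paradigm_spec(
    n_runs = p$n_runs, stim_ms = p$stim_ms,
    pre_buffer_ms = p$pre_buffer_ms, post_buffer_ms = p$post_buffer_ms,
    acq_ms = p$acq_ms, pad_ms = p$pad_ms, conditions = p$conditions,
    exemplars_per_condition = p$exemplars_per_condition,
    catch_label = p$catch_label, catch_per_run = p$catch_per_run,
    run_volumes = p$run_volumes, order_seed = p$order_seed)
  pipeline_config(n_td = lst$n_td, n_asd = lst$n_asd,
                  paradigm = paradigm, seed = lst$seed, qc = lst$qc,
                  glm = lst$glm, correction = lst$correction,
                  mvpa = lst$mvpa, spike_prob = lst$spike_prob)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in order: cohort simulation, artifact injection plus
#' despiking and motion QC, subject inclusion, single-subject GLMs with
#' AR(1) prewhitening and contrast estimation, group comparison and
#' behavior-covariate tests on ROI contrast values, gPPI network
#' connectivity with univariate link tests, and MVPA (SVC group
#' classification on the mother-voice connectivity contrast, SVR
#' prediction of behavior scores from both connectivity contrasts in the
#' ASD group), each with permutation inference. Randomness is funneled
#' through the master seed via derived per-stage streams.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written (CSV/JSON) and hashed into the manifest.
#' @param truth a [ground_truth()] (defaults to the planted-effect
#'   [default_ground_truth()]).
#' @return A `pipeline_result`: list with per-stage results and a
#'   `manifest` recording seeds, parameters, and (when `out_dir` is
#'   given) output file hashes.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         truth = default_ground_truth()) {
  validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  hrf <- hrf_model()

  cohort <- stage("simulate",
    simulate_cohort(config$n_td, config$n_asd, truth = truth,
                    spec = config$paradigm,
                    seed = derive_seed(config$seed, 1), hrf = hrf))
  schedule <- cohort$schedule
  network <- cohort$network

  # despiking + QC per run, subject inclusion
  qc <- config$qc
  cohort <- stage("qc", {
    for (i in seq_along(cohort$subjects)) {
      sub <- cohort$subjects[[i]]
      run_qcs <- vector("list", length(sub$bold))
      for (ri in seq_along(sub$bold)) {
        art <- inject_artifacts(sub$bold[[ri]], config$spike_prob,
                                seed = derive_seed(sub$seed, 100 + ri))
        g <- rowMeans(art$data$series)
        flagged <- detect_spike_volumes(art$motion, g,
                                        voxel_mm = qc$voxel_mm,
                                        global_pct = qc$global_pct)
        sub$bold[[ri]] <- interpolate_volumes(art$data, flagged)
        run_qcs[[ri]] <- qc_run(art$motion, flagged,
                                max_disp_mm = qc$max_disp_mm,
                                max_pct_repaired = qc$max_pct_repaired)
      }
      sub$run_qc <- run_qcs
      sub$included <- qc_subject(run_qcs, min_runs = qc$min_runs)
      sub$bold <- sub$bold[vapply(run_qcs, `[[`, logical(1), "included")]
      cohort$subjects[[i]] <- sub
    }
    cohort$subjects <- Filter(function(s) s$included, cohort$subjects)
    cohort
  })
  manifest_df <- cohort_manifest(cohort)

  # single-subject GLMs on ROI series; activation contrasts
  glm_res <- stage("glm", {
    lapply(cohort$subjects, function(sub) {
      design <- build_design(schedule, hrf,
                             hp_cutoff_s = config$glm$hp_cutoff_s,
                             baseline = config$glm$baseline)
      keep <- vapply(sub$bold, `[[`, numeric(1), "run")
      rows <- design$runs %in% keep
      design$X <- design$X[rows, , drop = FALSE]
      design$runs <- design$runs[rows]
      # drop empty run-offset columns when runs were excluded
      nz <- apply(design$X, 2, function(c) any(c != 0))
      design$X <- design$X[, nz, drop = FALSE]
      design$labels <- design$labels[nz]
      fit <- fit_glm_ar1(sub$bold, design)
      list(
        mother_gt_unfamiliar =
          compute_contrast(fit, c(mother = 1, unfamiliar = -1))$value,
        unfamiliar_gt_environmental =
          compute_contrast(fit, c(unfamiliar = 1))$value)
    })
  })
  act <- lapply(c("mother_gt_unfamiliar", "unfamiliar_gt_environmental"),
                function(ct) t(sapply(glm_res, `[[`, ct)))
  names(act) <- c("mother_gt_unfamiliar", "unfamiliar_gt_environmental")

  groups <- manifest_df$group
  scores <- manifest_df$score
  group_maps <- stage("group_stats",
    lapply(act, second_level_ttest, groups = groups))
  asd <- groups == "ASD"
  behavior_maps <- stage("group_stats",
    lapply(act, function(v)
      covariate_regression(v[asd, , drop = FALSE], scores[asd])))

  # gPPI connectivity matrices and univariate link tests
  conn <- stage("gppi",
    lapply(cohort$subjects, function(sub)
      network_gppi(sub$bold, network, schedule, hrf)))
  links_group <- stage("gppi", lapply(
    c("mother_gt_unfamiliar", "unfamiliar_gt_environmental"),
    function(ct) univariate_link_tests(lapply(conn, `[[`, ct),
                                       groups = groups)))
  names(links_group) <- names(act)

  # MVPA
  m <- config$mvpa
  mvpa_res <- stage("mvpa", {
    Xm <- assemble_features(conn, "mother_gt_unfamiliar")
    svc <- svc_cross_validate(Xm, groups, C = m$C, k = m$k,
                              repeats = m$repeats,
                              seed = derive_seed(config$seed, 2))
    svc <- permutation_test_classification(
      Xm, groups, svc, n_perm = m$n_perm,
      seed = derive_seed(config$seed, 3))
    Xb <- assemble_features(conn, c("mother_gt_unfamiliar",
                                    "unfamiliar_gt_environmental"))
    Xb <- Xb[asd, , drop = FALSE]
    folds <- balanced_fold_assignment(scores[asd], k = m$k,
                                      alpha = m$alpha,
                                      seed = derive_seed(config$seed, 4))
    svr <- cv_regression_predict(Xb, scores[asd], folds, model = "svr",
                                 C = m$C, epsilon = m$epsilon)
    svr <- permutation_test_regression(
      Xb, scores[asd], folds, svr, n_surrogates = m$n_perm,
      seed = derive_seed(config$seed, 5))
    list(svc_group = svc, svr_behavior = svr)
  })

  result <- structure(
    list(cohort_manifest = manifest_df, activation = act,
         group_maps = group_maps, behavior_maps = behavior_maps,
         connectivity = conn, link_tests = links_group,
         mvpa = mvpa_res,
         manifest = list(seed = config$seed,
                         config = unclass(config),
                         n_subjects = nrow(manifest_df),
                         stages = c("simulate", "qc", "glm",
                                    "group_stats", "gppi", "mvpa"),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- character(0)
    f <- file.path(out_dir, "cohort_manifest.csv")
    write.csv(manifest_df, f, row.names = FALSE); files <- c(files, f)
    for (ct in names(act)) {
      f <- file.path(out_dir, sprintf("activation_%s.csv", ct))
      write.csv(as.data.frame(act[[ct]]), f, row.names = FALSE)
      files <- c(files, f)
    }
    for (ct in names(links_group)) {
      f <- file.path(out_dir, sprintf("links_%s.csv", ct))
      write.csv(links_group[[ct]], f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "mvpa.json")
    jsonlite::write_json(
      list(svc_group = list(accuracy = mvpa_res$svc_group$accuracy,
                            p = mvpa_res$svc_group$p,
                            settings = mvpa_res$svc_group$settings),
           svr_behavior = list(r = mvpa_res$svr_behavior$r,
                               p = mvpa_res$svr_behavior$p)),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    result$manifest$files <-
      data.frame(path = files, md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
  }
  result
}

#' Write a human-readable pipeline report
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param path optional output file; when `NULL` the report is returned
#'   as a character vector.
#' @return The report lines, invisibly when written to a file.
#' @export
write_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Task-evoked activation and connectivity pipeline report")
  add("=======================================================")
  md <- result$cohort_manifest
  if (!is.null(md) && nrow(md)) {
    add("Included subjects: %d (%d TD, %d ASD)", nrow(md),
        sum(md$group == "TD"), sum(md$group == "ASD"))
  } else add("Included subjects: none recorded")
  for (ct in names(result$group_maps %||% list())) {
    gm <- result$group_maps[[ct]]
    add("Group map [%s]: max |t| = %.2f (df = %d)", ct,
        max(abs(gm$t)), gm$df)
  }
  for (ct in names(result$link_tests %||% list())) {
    lt <- result$link_tests[[ct]]
    add("Link tests [%s]: %d of %d significant at q < 0.05", ct,
        sum(lt$significant), nrow(lt))
  }
  mv <- result$mvpa
  if (!is.null(mv)) {
    add("SVC group classification: accuracy = %.1f%%, p = %.4g",
        100 * mv$svc_group$accuracy, mv$svc_group$p %||% NA)
    add("SVR behavior prediction: r(pred, obs) = %.3f, p = %.4g",
        mv$svr_behavior$r, mv$svr_behavior$p %||% NA)
  } else add("MVPA stage missing: no results to report")
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}

#' Write ROI-level BOLD series or connectivity matrices as CSV
#'
#' @param x a `bold_run` (rows = volumes, columns = ROI names) or a
#'   square connectivity matrix with node dimnames.
#' @param path file path.
#' @export
write_series_csv <- function(x, path) {
  if (inherits(x, "bold_run")) x <- x$series
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a volumetric image as NIfTI-1
#'
#' @param vol a 3D/4D array or `bold_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_mm isotropic voxel size recorded in the header.
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = 2) {
  if (inherits(vol, "bold_volume")) {
    voxel_mm <- vol$mask$voxel_mm
    vol <- vol$data
  }
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}
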