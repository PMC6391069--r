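#' Ground truth for synthetic BOLD generation
#'
#' Collects every planted effect the simulator uses, so downstream
#' analyses can be validated against known answers: condition-dependent
#' ROI activation amplitudes, condition-specific seed-to-target coupling
#' modulations (the generative analog of gPPI betas), an additive
#' TD-minus-ASD group difference on planted features, a linear coupling
#' from a brain feature to an integer behavior score (lower = better
#' social function), and the noise model.
#'
#' The noise model has five components: `phi`, the AR(1) coefficient of
#' the observation noise; `sd`, its marginal standard deviation;
#' `drift_amp`, the amplitude of a linear-plus-sinusoidal low-frequency
#' drift; `neural_sd`, the standard deviation of slow intrinsic neural
#' fluctuations (these give the seed regions stochastic activity, without
#' which condition-specific coupling would be indistinguishable from task
#' activation); `spike_prob`, used only by [inject_artifacts()]; and
#' `offset`, the constant baseline of the BOLD signal.
#'
#' @param network a `network_spec` defining the ROIs.
#' @param conditions stimulus conditions carrying planted activation.
#' @param activation_beta ROI x condition matrix of activation amplitudes
#'   (arbitrary units).
#' @param modulation condition x seed x target array of coupling
#'   modulation strengths.
#' @param group_effect list with elements `activation` and `modulation`:
#'   the additive TD-ASD difference, subtracted (toward zero) from planted
#'   entries for ASD subjects.
#' @param behavior_coupling list with slope `b`, intercept `a`, residual
#'   standard deviation `score_sd`, and the integer score range; the
#'   behavior score of subject i is
#'   `round(a + b * feature_i + e_i)` clamped to the range, where
#'   `feature_i` is the subject's mean absolute planted coupling.
#' @param noise list as described above.
#' @param subject_sd standard deviation of the subject-level scaling of
#'   planted effects (between-subject heterogeneity).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(network = default_voice_network(),
                         conditions = c("mother", "unfamiliar",
                                        "environmental"),
                         activation_beta = NULL,
                         modulation = NULL,
                         group_effect = list(activation = 0.3,
                                             modulation = 0.4),
                         behavior_coupling = list(a = 18, b = -20,
                                                  score_sd = 1.2,
                                                  range = c(2L, 20L)),
                         noise = list(phi = 0.3, sd = 0.5,
                                      drift_amp = 0.5, neural_sd = 0.35,
                                      spike_prob = 0, offset = 100),
                         subject_sd = 0.2) {
  nodes <- network$name
  n_roi <- length(nodes)
  n_cond <- length(conditions)
  if (is.null(activation_beta)) {
    activation_beta <- matrix(0, n_roi, n_cond,
                              dimnames = list(nodes, conditions))
  }
  if (is.null(modulation)) {
    modulation <- array(0, c(n_cond, n_roi, n_roi),
                        dimnames = list(conditions, nodes, nodes))
  }
  stopifnot(identical(dim(activation_beta), c(n_roi, n_cond)),
            identical(dim(modulation), c(n_cond, n_roi, n_roi)))
  if (abs(noise$phi) >= 1) stop("AR(1) coefficient `phi` must satisfy |phi| < 1")
  stopifnot_prob(noise$spike_prob %||% 0, "spike_prob")
  structure(list(network = network, conditions = conditions,
                 activation_beta = activation_beta,
                 modulation = modulation,
                 group_effect = group_effect,
                 behavior_coupling = behavior_coupling,
                 noise = noise, subject_sd = subject_sd),
            class = "ground_truth")
}

#' Default planted effects emulating a voice-processing study
#'
#' Auditory regions respond to all sounds, voice-selective regions
#' respond preferentially to voices, and reward/salience regions carry a
#' mother-voice-specific response. Condition-specific coupling is planted
#' from superior temporal (voice-selective) seeds to reward and salience
#' targets, strongest for the biologically salient voice condition. The
#' group effect reduces planted coupling and activation in the ASD group,
#' and the behavior coupling maps stronger coupling to lower (better)
#' social-communication scores.
#'
#' @inheritParams ground_truth
#' @param ... overrides passed on to [ground_truth()].
#' @return A `ground_truth` with non-zero planted effects.
#' @export
default_ground_truth <- function(network = default_voice_network(), ...) {
  conditions <- c("mother", "unfamiliar", "environmental")
  nodes <- network$name
  beta <- matrix(0, length(nodes), 3, dimnames = list(nodes, conditions))
  auditory <- intersect(c("HG_L", "PP_R"), nodes)
  voice <- intersect(c("pSTS_L", "pSTS_R", "aSTS_L", "aSTS_R"), nodes)
  reward <- intersect(c("NAc_L", "NAc_R", "vmPFC", "OFC_R"), nodes)
  salience <- intersect(c("AI_L", "AI_R", "rACC_R"), nodes)
  beta[auditory, ] <- 1.0
  beta[voice, ] <- rep(c(0.9, 0.9, 0.3), each = length(voice))
  beta[reward, ] <- rep(c(0.6, 0.2, 0.0), each = length(reward))
  beta[salience, ] <- rep(c(0.5, 0.3, 0.1), each = length(salience))

  mod <- array(0, c(3, length(nodes), length(nodes)),
               dimnames = list(conditions, nodes, nodes))
  plant <- function(cond, seed, target, m) {
    if (seed %in% nodes && target %in% nodes)
      mod[cond, seed, target] <<- m
  }
  for (tg in c(reward, salience)) {
    plant("mother", "pSTS_L", tg, 0.8)
    plant("mother", "pSTS_R", tg, 0.7)
  }
  for (tg in reward) plant("unfamiliar", "pSTS_L", tg, 0.25)
  plant("unfamiliar", "pSTS_R", "AI_R", 0.25)
  ground_truth(network = network, conditions = conditions,
               activation_beta = beta, modulation = mod, ...)
}

#' Strong-effect ground truth for recovery validation
#'
#' A validation preset with planted effects large relative to the
#' single-subject estimation noise of the connectivity pipeline, used to
#' verify that planted group differences and brain-behavior couplings
#' are recovered by classification and prediction (a power check, not a
#' portrait of realistic effect sizes; [default_ground_truth()] is the
#' realistic-regime default).
#'
#' @inheritParams default_ground_truth
#' @export
strong_effect_ground_truth <- function(network = default_voice_network(),
                                       subject_sd = 0.3,
                                       behavior_coupling =
                                         list(a = 20, b = -14,
                                              score_sd = 0.6,
                                              range = c(2L, 20L)),
                                       ...) {
  conditions <- c("mother", "unfamiliar", "environmental")
  nodes <- network$name
  beta <- matrix(0, length(nodes), 3, dimnames = list(nodes, conditions))
  voice <- intersect(c("pSTS_L", "pSTS_R", "aSTS_L", "aSTS_R"), nodes)
  targets <- intersect(c("NAc_L", "NAc_R", "vmPFC", "OFC_R",
                         "AI_L", "AI_R", "rACC_R"), nodes)
  beta[intersect(c("HG_L", "PP_R"), nodes), ] <- 1.0
  beta[voice, ] <- rep(c(0.9, 0.9, 0.3), each = length(voice))
  beta[targets, ] <- rep(c(2.0, 0.4, 0.0), each = length(targets))
  mod <- array(0, c(3, length(nodes), length(nodes)),
               dimnames = list(conditions, nodes, nodes))
  # single planted seed keeps each pairwise fit free of unmodeled input
  # from other coupled seeds
  mod["mother", "pSTS_L", targets] <- 4.0
  mod["unfamiliar", "pSTS_L",
      intersect(c("NAc_L", "NAc_R", "vmPFC", "OFC_R"), nodes)] <- 0.4
  # quiet non-seed nodes: the planted seed's intrinsic fluctuations carry
  # the coupling signal, and quieter targets make it identifiable
  nsd <- stats::setNames(rep(0.12, length(nodes)), nodes)
  nsd[intersect(c("pSTS_L", "pSTS_R"), nodes)] <- 0.35
  ground_truth(network = network, conditions = conditions,
               noise = list(phi = 0.3, sd = 0.5, drift_amp = 0.5,
                            neural_sd = nsd, spike_prob = 0,
                            offset = 100),
               activation_beta = beta, modulation = mod,
               group_effect = list(activation = 0.6, modulation = 3.4),
               behavior_coupling = behavior_coupling,
               subject_sd = subject_sd, ...)
}

# Planted-feature summary used as the brain feature coupled to behavior:
# mean absolute value of the subject's non-zero coupling modulations.
planted_feature <- function(modulation) {
  nz <- modulation[modulation != 0]
  if (length(nz) == 0) 0 else mean(abs(nz))
}

# Apply the additive TD-ASD group effect and subject-level scaling to a
# ground truth, returning the subject-specific truth.
subject_truth <- function(truth, group, scale) {
  shrink <- function(x, amount) {
    planted <- x != 0
    x[planted] <- x[planted] -
      pmin(abs(x[planted]), amount) * sign(x[planted])
    x
  }
  tr <- truth
  if (identical(group, "ASD")) {
    tr$activation_beta <- shrink(tr$activation_beta,
                                 truth$group_effect$activation %||% 0)
    tr$modulation <- shrink(tr$modulation,
                            truth$group_effect$modulation %||% 0)
  }
  tr$activation_beta <- tr$activation_beta * scale
  tr$modulation <- tr$modulation * scale
  tr
}

# Intrinsic neural fluctuation at the acquisition timescale: AR(1)
# sampled per TR (constant within each TR at microtime), correlation
# time `tau_s`, marginal sd `neural_sd`. Intrinsic activity is
# band-limited to what TR sampling can resolve; faster fluctuations
# would be unidentifiable from the sampled BOLD signal.
intrinsic_neural <- function(n_vols, microtime, tr_s, neural_sd,
                             tau_s = 2) {
  if (neural_sd <= 0) return(numeric(n_vols * microtime))
  a <- exp(-tr_s / tau_s)
  w <- rnorm(n_vols, sd = neural_sd * sqrt(1 - a^2))
  z <- as.numeric(filter(w, a, method = "recursive"))
  rep(z, each = microtime)
}

ar1_noise <- function(n, phi, sd) {
  if (sd <= 0) return(numeric(n))
  if (phi == 0) return(rnorm(n, sd = sd))
  w <- rnorm(n, sd = sd * sqrt(1 - phi^2))
  as.numeric(filter(w, phi, method = "recursive"))
}

drift_series <- function(n, tr_s, amp) {
  if (amp <= 0) return(numeric(n))
  t <- seq_len(n)
  phase <- runif(1, 0, 2 * pi)
  amp * (seq(-1, 1, length.out = n) +
           0.5 * sin(2 * pi * t * tr_s / 100 + phase))
}

# Condition boxcars at microtime for all conditions of a truth object.
truth_boxcars <- function(schedule, run, truth, hrf, tr_s, n_vols) {
  sapply(truth$conditions, function(cond)
    condition_boxcar(schedule, run, cond, tr_s, n_vols, hrf$microtime))
}

#' Simulate ROI-level BOLD runs with planted activation and coupling
#'
#' For each ROI the latent neural series is the sum of (i) planted
#' condition activations times the condition boxcars, (ii) slow intrinsic
#' neural fluctuations, and (iii) condition-modulated input from every
#' seed ROI: `sum_c sum_s m_c[s, r] * psi_c(t) * z_s(t)`, where `z_s` is
#' the seed's first-order (task + intrinsic) neural activity. The BOLD
#' signal is the HRF-convolved neural series sampled at the TR, plus a
#' constant offset, low-frequency drift, and AR(1) observation noise.
#'
#' @param schedule an `event_schedule` (from [generate_paradigm()] or
#'   [read_events_tsv()]).
#' @param truth a [ground_truth()]; its network must match `network`.
#' @param network a `network_spec`.
#' @param subject_seed integer seed; identical seeds give bit-identical
#'   data.
#' @param hrf an [hrf_model()].
#' @param tr_s,n_vols sampling interval (s) and volumes per run; defaults
#'   are taken from attributes attached by [generate_paradigm()].
#' @param runs which runs of the schedule to simulate.
#' @return A list of `bold_run` objects, one per run: each has `series`
#'   (volumes x ROI matrix with node-name columns), `tr_s`, and `run`.
#' @export
simulate_roi_bold <- function(schedule, truth, network = truth$network,
                              subject_seed = 1L, hrf = hrf_model(),
                              tr_s = attr(schedule, "tr_s") %||% 3.576,
                              n_vols = attr(schedule, "n_vols") %||% 67L,
                              runs = sort(unique(schedule$run))) {
  stopifnot(inherits(truth, "ground_truth"))
  nodes <- network$name
  if (!identical(nodes, truth$network$name))
    stop("network nodes do not match the ground truth network")
  sched_conds <- setdiff(unique(schedule$condition), "catch")
  if (!all(truth$conditions %in% c(sched_conds, "catch")) &&
      !all(sched_conds %in% truth$conditions))
    stop("condition sets of schedule and ground truth do not match")
  n_roi <- length(nodes)
  n_cond <- length(truth$conditions)
  mt <- hrf$microtime
  dt <- tr_s / mt
  noise <- truth$noise

  lapply(runs, function(r) {
    with_seed(derive_seed(subject_seed, r), {
      psi <- truth_boxcars(schedule, r, truth, hrf, tr_s, n_vols)
      n_micro <- nrow(psi)
      # first-order neural activity per ROI (task + intrinsic);
      # neural_sd may be scalar or per-ROI
      nsd0 <- noise$neural_sd %||% 0
      if (!is.null(names(nsd0))) {
        nsd <- rep(0, n_roi)
        hit <- match(names(nsd0), nodes)
        nsd[hit[!is.na(hit)]] <- nsd0[!is.na(hit)]
      } else nsd <- rep_len(nsd0, n_roi)
      z <- psi %*% t(truth$activation_beta)
      for (j in seq_len(n_roi))
        z[, j] <- z[, j] + intrinsic_neural(n_vols, mt, tr_s, nsd[j],
                                            tau_s = noise$tau_s %||% 2)
      # condition-modulated coupling input
      neural <- z
      for (ci in seq_len(n_cond)) {
        m <- truth$modulation[ci, , ]          # seed x target
        if (any(m != 0))
          neural <- neural + (psi[, ci] * z) %*% m
      }
      series <- apply(neural, 2, microtime_to_tr, hrf = hrf, tr_s = tr_s,
                      n_vols = n_vols)
      for (j in seq_len(n_roi)) {
        series[, j] <- series[, j] + (noise$offset %||% 0) +
          drift_series(n_vols, tr_s, noise$drift_amp %||% 0) +
          ar1_noise(n_vols, noise$phi %||% 0, noise$sd %||% 0)
      }
      colnames(series) <- nodes
      structure(list(series = series, tr_s = tr_s, run = r),
                class = "bold_run")
    })
  })
}

#' Volumetric mask geometry
#'
#' A 3D brain mask on an isotropic grid with the coordinate origin at the
#' grid center, so voxel (i, j, k) has mm coordinates
#' `(c(i, j, k) - (dim + 1) / 2) * voxel_mm`.
#'
#' @param dim integer triple of grid dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @param shape `"box"` (all voxels in-mask) or `"ellipsoid"` (inscribed
#'   ellipsoid with the given semi-axes).
#' @param semiaxes_mm semi-axes of the ellipsoid in mm (defaults to half
#'   the field of view).
#' @return A `mask_spec`: list with logical array `mask`, `dim`,
#'   `voxel_mm`.
#' @export
mask_spec <- function(dim, voxel_mm = 2,
                      shape = c("box", "ellipsoid"),
                      semiaxes_mm = dim * voxel_mm / 2) {
  shape <- match.arg(shape)
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim > 0), voxel_mm > 0)
  if (shape == "box") {
    m <- array(TRUE, dim)
  } else {
    ctr <- (dim + 1) / 2
    xs <- ((seq_len(dim[1]) - ctr[1]) * voxel_mm / semiaxes_mm[1])^2
    ys <- ((seq_len(dim[2]) - ctr[2]) * voxel_mm / semiaxes_mm[2])^2
    zs <- ((seq_len(dim[3]) - ctr[3]) * voxel_mm / semiaxes_mm[3])^2
    m <- outer(outer(xs, ys, `+`), zs, `+`) <= 1
  }
  structure(list(mask = m, dim = dim, voxel_mm = voxel_mm),
            class = "mask_spec")
}

#' MNI-shaped whole-brain mask at 2 mm resolution
#'
#' An ellipsoidal stand-in for a normalized whole-brain mask on the
#' standard 91 x 109 x 91 grid of 2 mm MNI space, with semi-axes sized so
#' the mask holds approximately 200,000 voxels (about 1.6 L), the search
#' volume of a whole-brain cluster-extent correction.
#'
#' @return A `mask_spec`.
#' @export
mni_like_mask <- function() {
  mask_spec(c(91L, 109L, 91L), voxel_mm = 2, shape = "ellipsoid",
            semiaxes_mm = c(64, 84, 71))
}

# mm coordinates of all voxels (n x 3), grid origin at center.
voxel_coords_mm <- function(mask) {
  ctr <- (mask$dim + 1) / 2
  idx <- which(array(TRUE, mask$dim), arr.ind = TRUE)
  sweep(idx, 2, ctr) * mask$voxel_mm
}

# linear indices of in-mask voxels within `radius` mm of `center` mm
sphere_voxels <- function(mask, center, radius) {
  ctr <- (mask$dim + 1) / 2
  # bounding box in voxel indices
  lo <- pmax(1, floor(ctr + (center - radius) / mask$voxel_mm))
  hi <- pmin(mask$dim, ceiling(ctr + (center + radius) / mask$voxel_mm))
  if (any(lo > hi)) return(integer(0))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  grid <- expand.grid(i = gx, j = gy, k = gz)
  mm <- sweep(as.matrix(grid), 2, ctr) * mask$voxel_mm
  d2 <- rowSums(sweep(mm, 2, center)^2)
  keep <- d2 <= radius^2
  lin <- (grid$k - 1) * mask$dim[1] * mask$dim[2] +
    (grid$j - 1) * mask$dim[1] + grid$i
  lin <- lin[keep]
  lin[mask$mask[lin]]
}

#' Simulate a volumetric BOLD run with Gaussian activation blobs
#'
#' Each ROI's noiseless BOLD series (HRF-convolved planted neural signal)
#' is spread spatially as a Gaussian blob centered on the ROI's MNI
#' coordinates (blob standard deviation = ROI radius), and spatially
#' independent Gaussian noise is added to every in-mask voxel.
#'
#' @inheritParams simulate_roi_bold
#' @param mask a [mask_spec()]; every ROI center must be in-mask.
#' @param run which run to simulate.
#' @return A `bold_volume`: list with `data` (4D array x,y,z,t; zero
#'   outside the mask), `mask`, `tr_s`, `run`.
#' @export
simulate_volume_bold <- function(schedule, truth,
                                 network = truth$network, mask,
                                 subject_seed = 1L, hrf = hrf_model(),
                                 tr_s = attr(schedule, "tr_s") %||% 3.576,
                                 n_vols = attr(schedule, "n_vols") %||% 67L,
                                 run = 1L) {
  stopifnot(inherits(mask, "mask_spec"))
  if (sum(mask$mask) == 0) stop("mask is empty")
  ctr <- (mask$dim + 1) / 2
  for (i in seq_len(nrow(network))) {
    v <- round(ctr + c(network$x[i], network$y[i], network$z[i]) /
                 mask$voxel_mm)
    if (any(v < 1) || any(v > mask$dim) ||
        !mask$mask[v[1], v[2], v[3]])
      stop(sprintf("ROI center outside mask: %s", network$name[i]))
  }
  clean_truth <- truth
  clean_truth$noise <- list(phi = 0, sd = 0, drift_amp = 0,
                            neural_sd = truth$noise$neural_sd %||% 0,
                            offset = 0)
  roi <- simulate_roi_bold(schedule, clean_truth, network,
                           subject_seed = subject_seed, hrf = hrf,
                           tr_s = tr_s, n_vols = n_vols, runs = run)[[1]]
  n_roi <- nrow(network)
  nvox <- prod(mask$dim)
  with_seed(derive_seed(subject_seed, 10000 + run), {
    dat <- array(0, c(mask$dim, n_vols))
    flat <- matrix(0, nvox, n_vols)
    coords <- voxel_coords_mm(mask)
    for (i in seq_len(n_roi)) {
      cen <- c(network$x[i], network$y[i], network$z[i])
      s <- network$radius[i]
      near <- sphere_voxels(mask, cen, 4 * s)
      if (length(near) == 0) next
      d2 <- rowSums(sweep(coords[near, , drop = FALSE], 2, cen)^2)
      w <- exp(-d2 / (2 * s^2))
      flat[near, ] <- flat[near, ] + outer(w, roi$series[, i])
    }
    inmask <- which(mask$mask)
    sdn <- truth$noise$sd %||% 0
    if (sdn > 0)
      flat[inmask, ] <- flat[inmask, ] +
        matrix(rnorm(length(inmask) * n_vols, sd = sdn),
               length(inmask), n_vols)
    flat[-inmask, ] <- 0
    dat[] <- flat
    structure(list(data = dat, mask = mask, tr_s = tr_s, run = run),
              class = "bold_volume")
  })
}

#' Simulate a cohort of subjects with known group and behavior structure
#'
#' Generates `n_td` typically developing and `n_asd` ASD-group subjects.
#' Each subject gets a deterministic seed derived from the master seed, a
#' subject-level scaling of the planted effects (heterogeneity), the
#' group effect applied to planted features of the ASD group, ROI-level
#' BOLD for every run of the schedule, and an integer behavior score
#' `round(a + b * feature + e)` clamped to the configured range, where
#' `feature` is the subject's mean absolute planted coupling (lower
#' scores = better social function).
#'
#' @param n_td,n_asd group sizes (each >= 1).
#' @param truth a [ground_truth()].
#' @param spec a [paradigm_spec()] used to generate the shared schedule.
#' @param seed master seed; regenerating with the same seed reproduces
#'   identical data.
#' @param hrf an [hrf_model()].
#' @return A `synthetic_cohort`: list with `subjects` (each: `id`,
#'   `group`, `score`, `feature`, `seed`, `scale`, `bold` list of
#'   `bold_run`s), `schedule`, `network`, `truth`, `seed`.
#' @export
simulate_cohort <- function(n_td = 21, n_asd = 21,
                            truth = default_ground_truth(),
                            spec = paradigm_spec(), seed = 1L,
                            hrf = hrf_model()) {
  stopifnot(n_td >= 1, n_asd >= 1)
  schedule <- generate_paradigm(spec)
  attr(schedule, "tr_s") <- spec$tr_ms / 1000
  attr(schedule, "n_vols") <- spec$run_volumes
  groups <- c(rep("TD", n_td), rep("ASD", n_asd))
  bc <- truth$behavior_coupling
  subjects <- lapply(seq_along(groups), function(i) {
    sseed <- derive_seed(seed, i)
    with_seed(derive_seed(sseed, 0), {
      scale <- 1 + rnorm(1, sd = truth$subject_sd)
      st <- subject_truth(truth, groups[i], scale)
      feature <- planted_feature(st$modulation)
      eps <- rnorm(1, sd = bc$score_sd %||% 0)
      score <- round(bc$a + bc$b * feature + eps)
      score <- min(max(score, bc$range[1]), bc$range[2])
      bold <- simulate_roi_bold(schedule, st, truth$network,
                                subject_seed = sseed, hrf = hrf)
      list(id = sprintf("sub-%02d", i), group = groups[i],
           score = as.integer(score), feature = feature,
           seed = sseed, scale = scale, bold = bold)
    })
  })
  structure(list(subjects = subjects, schedule = schedule,
                 network = truth$network, truth = truth, seed = seed,
                 hrf = hrf),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("Synthetic cohort: %d subjects (%d TD, %d ASD), %d runs each\n",
              length(g), sum(g == "TD"), sum(g == "ASD"),
              length(x$subjects[[1]]$bold)))
  invisible(x)
}

#' Cohort manifest as a data frame
#'
#' @param cohort a `synthetic_cohort`.
#' @return Data frame with one row per subject: id, group, score, seed.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    id = vapply(cohort$subjects, `[[`, character(1), "id"),
    group = vapply(cohort$subjects, `[[`, character(1), "group"),
    score = vapply(cohort$subjects, `[[`, integer(1), "score"),
    seed = vapply(cohort$subjects, `[[`, numeric(1), "seed"),
    stringsAsFactors = FALSE)
}

#' Inject motion and global-signal artifacts into a BOLD run
#'
#' Corrupts a run at randomly chosen volumes and returns a motion trace
#' whose scan-to-scan displacement exceeds the despiking threshold
#' exactly at the injected volumes; a global-signal spike (+8% of the
#' run median) is co-injected at the same volumes.
#'
#' @param data a `bold_run`.
#' @param spike_prob per-volume probability of injecting a spike.
#' @param spike_mm size of the translation step at spiked volumes (mm).
#' @param seed integer seed.
#' @return List with `data` (corrupted `bold_run`), `motion` (a
#'   `motion_trace` data frame), and `spike_volumes` (injected indices).
#' @export
inject_artifacts <- function(data, spike_prob, spike_mm = 2.0, seed = 1L) {
  stopifnot(inherits(data, "bold_run"))
  stopifnot_prob(spike_prob, "spike_prob")
  n <- nrow(data$series)
  with_seed(seed, {
    spikes <- which(runif(n) < spike_prob)
    spikes <- spikes[spikes > 1]       # first volume has no displacement
    x <- numeric(n)
    if (length(spikes)) {
      for (v in spikes) x[v:n] <- x[v:n] + spike_mm
      g <- apply(data$series, 1, mean)
      delta <- 0.08 * median(g)
      data$series[spikes, ] <- data$series[spikes, ] + delta
    }
    motion <- motion_trace(x = x, y = numeric(n), z = numeric(n))
    list(data = data, motion = motion, spike_volumes = spikes)
  })
}
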