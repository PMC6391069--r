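#' Extract per-node BOLD time series for a network
#'
#' For volumetric input, each node's series is the mean over in-sphere
#' voxels per volume; ROI-level input is passed through (columns
#' reordered to the network's node order).
#'
#' @param data a `bold_run` (ROI-level) or `bold_volume`.
#' @param network a `network_spec`.
#' @return Volumes x nodes matrix with node-name columns.
#' @export
extract_roi_timeseries <- function(data, network) {
  if (inherits(data, "bold_run")) {
    missing <- setdiff(network$name, colnames(data$series))
    if (length(missing))
      stop(sprintf("node(s) not present in ROI data: %s",
                   paste(missing, collapse = ", ")))
    return(data$series[, network$name, drop = FALSE])
  }
  stopifnot(inherits(data, "bold_volume"))
  n_vols <- dim(data$data)[4]
  flat <- matrix(data$data, ncol = n_vols)
  out <- sapply(seq_len(nrow(network)), function(i) {
    vox <- sphere_voxels(data$mask,
                         c(network$x[i], network$y[i], network$z[i]),
                         network$radius[i])
    if (length(vox) == 0)
      stop(sprintf("node not resolvable in the data: %s",
                   network$name[i]))
    colMeans(flat[vox, , drop = FALSE])
  })
  colnames(out) <- network$name
  out
}

# HRF convolution operator mapping microtime neural activity to BOLD
# sampled at the TR: H[i, j] = k[(i-1)*mt + 1 - j + 1].
hrf_operator <- function(hrf, tr_s, n_vols) {
  dt <- tr_s / hrf$microtime
  k <- hrf_kernel(hrf, dt)
  n_micro <- n_vols * hrf$microtime
  H <- matrix(0, n_vols, n_micro)
  for (i in seq_len(n_vols)) {
    s <- (i - 1) * hrf$microtime + 1       # microtime sample index
    j <- seq_len(min(s, length(k)))
    H[i, s - j + 1] <- k[j]
  }
  H
}

# Precompute the ridge deconvolution operator. The neural estimate is
# parameterized at the acquisition timescale (one value per TR, constant
# across the TR's microtime bins): temporal detail above the sampling
# bandwidth is unidentifiable from TR-sampled BOLD, and an unrestricted
# microtime inverse spreads energy into it. The operator is row-centered
# (implicit intercept) so the BOLD baseline is not attributed to neural
# activity. `M` maps the centered series to the TR-resolution estimate.
deconv_operator <- function(hrf, tr_s, n_vols, reg = 1) {
  if (reg < 0) stop("`reg` must be non-negative")
  H <- hrf_operator(hrf, tr_s, n_vols)
  mt <- hrf$microtime
  # collapse microtime columns into per-TR boxes
  Hb <- H %*% (diag(n_vols) %x% rep(1, mt))
  Hc <- sweep(Hb, 2, colMeans(Hb))
  G <- crossprod(Hc)
  lambda <- reg * mean(diag(G))
  list(Hb = Hb, Hc = Hc, microtime = mt,
       M = solve(G + diag(lambda, nrow(G)), t(Hc)))
}

#' Deconvolve quasi-neuronal activity from a BOLD series
#'
#' Recovers the latent neural time series by ridge-regularized
#' least-squares inversion of the HRF convolution operator,
#' `z = (H'H + lambda I)^{-1} H' y`, with the estimate parameterized at
#' the acquisition timescale (one value per TR, constant within the TR's
#' microtime bins) because faster structure is unidentifiable from
#' TR-sampled data. `lambda` is `reg` times the mean diagonal of `H'H`;
#' the series is mean-centered and the operator carries an implicit
#' intercept.
#'
#' @param seed_bold numeric BOLD series (one run).
#' @param hrf an [hrf_model()].
#' @param tr_s sampling interval (s).
#' @param reg relative ridge regularization weight (>= 0).
#' @param op optional precomputed [deconv_operator] (internal reuse).
#' @return A `neural_series`: list with `z` (microtime neural estimate),
#'   `fitted` (reconvolved BOLD), `resid`, `reg`.
#' @export
deconvolve_neural <- function(seed_bold, hrf = hrf_model(),
                              tr_s = 3.576, reg = 0.01, op = NULL) {
  y <- as.numeric(seed_bold) - mean(seed_bold)
  if (is.null(op)) op <- deconv_operator(hrf, tr_s, length(y), reg)
  z_tr <- drop(op$M %*% y)
  fitted <- drop(op$Hc %*% z_tr)
  structure(list(z = rep(z_tr, each = op$microtime), z_tr = z_tr,
                 fitted = fitted, resid = y - fitted, reg = reg),
            class = "neural_series")
}

#' Build gPPI interaction regressors for one seed
#'
#' The deconvolved seed activity is multiplied by each condition's task
#' boxcar at microtime resolution (`psi_c(t) * z(t)`), convolved with the
#' HRF, and downsampled to the TR, yielding one interaction column per
#' modeled condition. The interaction regressor is identically zero
#' wherever the condition is off. Task main-effect columns
#' (HRF-convolved boxcars) and the raw seed series are also returned.
#'
#' @param neural a [deconvolve_neural()] result for the seed.
#' @param schedule an `event_schedule`.
#' @param run run index within the schedule.
#' @param seed_bold the seed's observed BOLD series for this run.
#' @param hrf an [hrf_model()].
#' @param tr_s,n_vols timing of the run.
#' @param conditions conditions modeled in the gPPI GLM (all three task
#'   conditions by default, including the activation-baseline condition,
#'   which is needed to form connectivity contrasts against it).
#' @return A `ppi_regressors`: list with `interaction` (volumes x
#'   conditions), `task` (volumes x conditions), `seed` (BOLD series),
#'   `conditions`.
#' @export
build_ppi_regressors <- function(neural, schedule, run, seed_bold,
                                 hrf = hrf_model(), tr_s = 3.576,
                                 n_vols = length(seed_bold),
                                 conditions = c("mother", "unfamiliar",
                                                "environmental")) {
  stopifnot(inherits(neural, "neural_series"))
  dt <- tr_s / hrf$microtime
  k <- hrf_kernel(hrf, dt)
  at <- seq(1, n_vols * hrf$microtime, by = hrf$microtime)
  inter <- task <- matrix(0, n_vols, length(conditions),
                          dimnames = list(NULL, conditions))
  for (ci in seq_along(conditions)) {
    psi <- condition_boxcar(schedule, run, conditions[ci], tr_s, n_vols,
                            hrf$microtime)
    inter[, ci] <- conv_causal(psi * neural$z, k)[at]
    task[, ci] <- conv_causal(psi, k)[at]
  }
  structure(list(interaction = inter, task = task,
                 seed = as.numeric(seed_bold), conditions = conditions),
            class = "ppi_regressors")
}

#' Fit the gPPI model for one seed-target pair
#'
#' Least-squares regression of the target BOLD series on the
#' condition-specific interaction regressors, the seed series (direct
#' effect), optionally the task main-effect columns, and a constant:
#' `target ~ conv(HRF, psi_c * deconv(seed)) + task + seed + constant`.
#' Including the task main effects (the default) prevents task
#' activation from leaking into the interaction coefficients; setting
#' `include_task_main_effects = FALSE` gives the strict
#' interaction+seed+constant model for comparison.
#'
#' @param target_bold the target ROI's BOLD series (one or more runs,
#'   concatenated; pass matching stacked regressors).
#' @param regs a `ppi_regressors` (or list of them, one per run, which
#'   are stacked with per-run intercepts).
#' @param include_task_main_effects logical.
#' @return A `gppi_fit`: list with `ppi_beta` (named per condition),
#'   `seed_beta`, `beta` (all coefficients), `conditions`.
#' @export
fit_gppi <- function(target_bold, regs, include_task_main_effects = TRUE) {
  if (inherits(regs, "ppi_regressors")) regs <- list(regs)
  target_bold <- as.numeric(target_bold)
  if (var(target_bold) == 0) stop("degenerate fit: zero-variance target")
  inter <- do.call(rbind, lapply(regs, `[[`, "interaction"))
  task <- do.call(rbind, lapply(regs, `[[`, "task"))
  seed <- unlist(lapply(regs, `[[`, "seed"))
  if (identical(seed, target_bold))
    stop("seed and target series are identical")
  if (length(target_bold) != length(seed))
    stop("target length does not match regressors")
  conds <- regs[[1]]$conditions
  X <- inter
  colnames(X) <- paste0("ppi_", conds)
  if (include_task_main_effects) {
    colnames(task) <- paste0("task_", conds)
    X <- cbind(X, task)
  }
  X <- cbind(X, seed = seed)
  if (length(regs) > 1) {
    nv <- vapply(regs, function(r) nrow(r$interaction), integer(1))
    for (ri in 2:length(regs)) {
      col <- numeric(sum(nv))
      col[sum(nv[seq_len(ri - 1)]) + seq_len(nv[ri])] <- 1
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- sprintf("run%d", ri)
    }
  }
  X <- cbind(X, constant = 1)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient gPPI design")
  beta <- qr.coef(qx, target_bold)
  ppi <- beta[paste0("ppi_", conds)]
  names(ppi) <- conds
  structure(list(ppi_beta = ppi, seed_beta = unname(beta["seed"]),
                 beta = beta, conditions = conds),
            class = "gppi_fit")
}

#' Seed-by-target gPPI connectivity matrices over a network
#'
#' Runs the full gPPI model for every ordered (seed, target) pair of the
#' network: the seed series is deconvolved once per run, interaction
#' regressors are built per condition, and each target is regressed on
#' them (runs concatenated with run intercepts). Returns one matrix per
#' requested condition contrast, with cells `beta_c1 - beta_c2` and a
#' masked (NA) diagonal; matrices are directional and not symmetric.
#'
#' @param bold a `bold_run` or list of `bold_run`s for one subject.
#' @param network a `network_spec`.
#' @param schedule an `event_schedule`.
#' @param hrf an [hrf_model()].
#' @param conditions conditions modeled inside the gPPI GLM.
#' @param contrasts named list of condition pairs `c(c1, c2)`; a single
#'   condition name gives that condition's beta matrix.
#' @param reg deconvolution ridge weight.
#' @param include_task_main_effects passed to [fit_gppi()].
#' @return A `connectivity_set`: named list of seed x target matrices.
#' @export
network_gppi <- function(bold, network, schedule, hrf = hrf_model(),
                         conditions = c("mother", "unfamiliar",
                                        "environmental"),
                         contrasts = list(
                           mother_gt_unfamiliar = c("mother", "unfamiliar"),
                           unfamiliar_gt_environmental =
                             c("unfamiliar", "environmental")),
                         reg = 0.01,
                         include_task_main_effects = TRUE) {
  if (inherits(bold, "bold_run")) bold <- list(bold)
  nodes <- network$name
  if (length(nodes) < 2) stop("network needs at least 2 nodes")
  series <- lapply(bold, extract_roi_timeseries, network = network)
  tr_s <- bold[[1]]$tr_s
  n_vols <- nrow(series[[1]])
  op <- deconv_operator(hrf, tr_s, n_vols, reg)
  runs <- vapply(bold, `[[`, numeric(1), "run")

  betas <- array(NA_real_,
                 c(length(nodes), length(nodes), length(conditions)),
                 dimnames = list(nodes, nodes, conditions))
  for (si in seq_along(nodes)) {
    regs <- lapply(seq_along(bold), function(bi) {
      sb <- series[[bi]][, si]
      nz <- deconvolve_neural(sb, hrf, tr_s, reg, op = op)
      build_ppi_regressors(nz, schedule, runs[bi], sb, hrf, tr_s,
                           n_vols, conditions)
    })
    for (ti in seq_along(nodes)) {
      if (ti == si) next
      tb <- unlist(lapply(series, function(s) s[, ti]))
      fit <- fit_gppi(tb, regs, include_task_main_effects)
      betas[si, ti, ] <- fit$ppi_beta
    }
  }
  out <- lapply(contrasts, function(ct) {
    if (length(ct) == 1) betas[, , ct]
    else betas[, , ct[1]] - betas[, , ct[2]]
  })
  structure(c(out, list(.betas = betas)), class = "connectivity_set")
}

#' Univariate link tests over subjects' connectivity matrices
#'
#' Per off-diagonal (seed, target) cell, a two-sample t test (when
#' `groups` is given) or Pearson correlation (when `scores` is given)
#' across subjects, with Benjamini-Hochberg adjustment over all tested
#' links.
#'
#' @param matrices list of per-subject seed x target matrices (same
#'   node order, NA diagonal).
#' @param groups two-level group labels (one per subject), or `NULL`.
#' @param scores numeric behavior scores (one per subject), or `NULL`.
#' @param q_threshold FDR significance level.
#' @return A `link_tests` data frame: `seed`, `target`, `statistic`
#'   (t or r), `p`, `q` (BH-adjusted), `significant`.
#' @export
univariate_link_tests <- function(matrices, groups = NULL, scores = NULL,
                                  q_threshold = 0.05) {
  stopifnot(length(matrices) >= 3, xor(is.null(groups), is.null(scores)))
  nodes <- rownames(matrices[[1]])
  n <- length(nodes)
  cells <- which(row(matrices[[1]]) != col(matrices[[1]]))
  vals <- sapply(matrices, function(m) m[cells])    # links x subjects
  if (!is.null(groups)) {
    groups <- as.character(groups)
    lev <- unique(groups)
    if ("TD" %in% lev) lev <- c("TD", setdiff(lev, "TD"))
    stat <- numeric(nrow(vals)); p <- numeric(nrow(vals))
    for (i in seq_len(nrow(vals))) {
      tt <- t.test(vals[i, groups == lev[1]], vals[i, groups == lev[2]],
                   var.equal = TRUE)
      stat[i] <- unname(tt$statistic); p[i] <- tt$p.value
    }
  } else {
    stat <- apply(vals, 1, cor, y = scores)
    nsub <- length(scores)
    tst <- stat * sqrt((nsub - 2) / (1 - stat^2))
    p <- 2 * pt(-abs(tst), nsub - 2)
  }
  q <- p.adjust(p, method = "BH")
  idx <- arrayInd(cells, c(n, n))
  out <- data.frame(seed = nodes[idx[, 1]], target = nodes[idx[, 2]],
                    statistic = stat, p = p, q = q,
                    significant = q < q_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("link_tests", "data.frame")
  out
}
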