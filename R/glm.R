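#' Build an event-related design matrix
#'
#' Condition boxcars (stimulus duration) are convolved with the canonical
#' HRF and with its temporal derivative at microtime resolution and
#' downsampled to the TR. A discrete cosine drift basis implements the
#' high-pass filter (default cutoff period 120 s, i.e. 0.5 cycles/min),
#' per run, plus run intercepts and a single overall constant. The
#' baseline condition (environmental sounds by default) is not modeled
#' and serves as the implicit baseline; catch trials are modeled as a
#' nuisance condition when present.
#'
#' @param schedule an `event_schedule`.
#' @param hrf an [hrf_model()].
#' @param tr_s,n_vols sampling interval and volumes per run (defaults
#'   from schedule attributes).
#' @param hp_cutoff_s high-pass cutoff period in seconds.
#' @param baseline condition label left unmodeled.
#' @param nuisance condition labels modeled but excluded from contrasts.
#' @return A `design_matrix`: list with `X` (volumes x columns), column
#'   `labels`, `condition_cols` (named HRF-column indices for modeled,
#'   non-nuisance conditions), `runs` (row run index), `tr_s`, `n_vols`.
#' @export
build_design <- function(schedule, hrf = hrf_model(),
                         tr_s = attr(schedule, "tr_s") %||% 3.576,
                         n_vols = attr(schedule, "n_vols") %||% 67L,
                         hp_cutoff_s = 120,
                         baseline = "environmental",
                         nuisance = "catch") {
  validate_schedule(schedule)
  runs <- sort(unique(schedule$run))
  conds <- unique(schedule$condition)
  modeled <- setdiff(conds, baseline)
  if (length(modeled) == 0) stop("no modeled conditions in schedule")
  for (cond in modeled)
    if (sum(schedule$condition == cond) == 0)
      stop(sprintf("modeled condition has zero events: %s", cond))

  dt <- tr_s / hrf$microtime
  cond_blocks <- list()
  for (cond in modeled) {
    hcol <- numeric(0); dcol <- numeric(0)
    for (r in runs) {
      psi <- condition_boxcar(schedule, r, cond, tr_s, n_vols,
                              hrf$microtime)
      h <- conv_causal(psi, hrf_kernel(hrf, dt))
      d <- conv_causal(psi, hrf_derivative(hrf, dt) * dt)
      at <- seq(1, n_vols * hrf$microtime, by = hrf$microtime)
      hcol <- c(hcol, h[at]); dcol <- c(dcol, d[at])
    }
    cond_blocks[[cond]] <- cbind(hcol, dcol)
  }
  n_total <- n_vols * length(runs)
  X <- do.call(cbind, cond_blocks)
  labels <- as.vector(rbind(modeled, paste0(modeled, "_deriv")))
  colnames(X) <- labels

  # per-run discrete cosine drift basis up to the cutoff
  run_len_s <- n_vols * tr_s
  K <- max(0L, floor(2 * run_len_s / hp_cutoff_s))
  if (K > 0) {
    for (k in seq_len(K)) {
      col <- numeric(n_total)
      for (ri in seq_along(runs)) {
        t0 <- (seq_len(n_vols) - 0.5) / n_vols
        col[(ri - 1) * n_vols + seq_len(n_vols)] <- cos(pi * k * t0)
      }
      X <- cbind(X, col)
      labels <- c(labels, sprintf("drift%d", k))
    }
  }
  # run intercept offsets (runs 2..R) + single overall constant
  if (length(runs) > 1) {
    for (ri in 2:length(runs)) {
      col <- numeric(n_total)
      col[(ri - 1) * n_vols + seq_len(n_vols)] <- 1
      X <- cbind(X, col)
      labels <- c(labels, sprintf("run%d", runs[ri]))
    }
  }
  X <- cbind(X, 1)
  labels <- c(labels, "constant")
  colnames(X) <- labels
  cond_main <- setdiff(modeled, nuisance)
  structure(list(X = X, labels = labels,
                 condition_cols = stats::setNames(match(cond_main, labels),
                                                  cond_main),
                 runs = rep(runs, each = n_vols),
                 tr_s = tr_s, n_vols = n_vols),
            class = "design_matrix")
}

# Apply the AR(1) whitening filter within each run:
# first row scaled by sqrt(1 - phi^2), then y_t - phi * y_{t-1}.
whiten_ar1 <- function(M, runs, phi) {
  M <- as.matrix(M)
  out <- M
  for (r in unique(runs)) {
    i <- which(runs == r)
    out[i[1], ] <- sqrt(1 - phi^2) * M[i[1], ]
    if (length(i) > 1)
      out[i[-1], ] <- M[i[-1], ] - phi * M[i[-length(i)], ]
  }
  out
}

#' Fit a GLM with AR(1) prewhitening
#'
#' The AR(1) coefficient is estimated from pooled ordinary-least-squares
#' residuals (lag-1 autocorrelation within runs, pooled across series),
#' the data and design are whitened by the corresponding filter, and
#' coefficients are re-estimated by least squares on the whitened system.
#' Forcing `phi = 0` reproduces plain OLS exactly.
#'
#' @param data a `bold_run`, a list of `bold_run`s (runs are
#'   concatenated; the design must span them), or a numeric matrix
#'   (volumes x series).
#' @param design a [build_design()] result.
#' @param phi optional fixed AR(1) coefficient; `NULL` to estimate.
#' @return A `glm_fit`: list with `beta` (regressors x series), `phi`,
#'   `sigma2` (per series), `df`, `XtXinv` (whitened), `design`.
#' @export
fit_glm_ar1 <- function(data, design, phi = NULL) {
  Y <- glm_response_matrix(data)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop("data length does not match design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- design$labels[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(phi)) {
    res <- Y - X %*% qr.coef(qx, Y)
    num <- 0; den <- 0
    for (r in unique(design$runs)) {
      i <- which(design$runs == r)
      e <- res[i, , drop = FALSE]
      num <- num + sum(e[-1, , drop = FALSE] *
                         e[-nrow(e), , drop = FALSE])
      den <- den + sum(e^2)
    }
    phi <- if (den > 0) num / den else 0
    phi <- max(min(phi, 0.99), -0.99)
  }
  Xw <- whiten_ar1(X, design$runs, phi)
  Yw <- whiten_ar1(Y, design$runs, phi)
  qw <- qr(Xw)
  beta <- qr.coef(qw, Yw)
  resw <- Yw - Xw %*% beta
  df <- nrow(Y) - qw$rank
  sigma2 <- colSums(resw^2) / df
  XtXinv <- chol2inv(qr.R(qw))
  rownames(beta) <- design$labels
  structure(list(beta = beta, phi = phi, sigma2 = sigma2, df = df,
                 XtXinv = XtXinv, design = design),
            class = "glm_fit")
}

glm_response_matrix <- function(data) {
  if (inherits(data, "bold_run")) return(as.matrix(data$series))
  if (is.list(data) && all(vapply(data, inherits, logical(1), "bold_run")))
    return(do.call(rbind, lapply(data, function(b) as.matrix(b$series))))
  as.matrix(data)
}

#' Compute a contrast of GLM coefficients
#'
#' Contrast weights are given by condition name (e.g.
#' `c(mother = 1, unfamiliar = -1)`); derivative, drift, and constant
#' columns get zero weight. A single-condition weight against the
#' implicit baseline is simply that condition's coefficient.
#'
#' @param fit a [fit_glm_ar1()] result.
#' @param weights named numeric vector over condition columns, or a full
#'   numeric vector over all regressors.
#' @return A `contrast_result`: list with `value` and `t` (per series),
#'   `se`, `df`, `weights`.
#' @export
compute_contrast <- function(fit, weights) {
  labels <- fit$design$labels
  if (!is.null(names(weights))) {
    w <- numeric(length(labels))
    idx <- match(names(weights), labels)
    if (anyNA(idx))
      stop(sprintf("unknown regressor(s): %s",
                   paste(names(weights)[is.na(idx)], collapse = ", ")))
    w[idx] <- weights
  } else {
    if (length(weights) != length(labels))
      stop("unnamed weights must cover every regressor")
    w <- as.numeric(weights)
  }
  if (all(w == 0)) stop("contrast weights are all zero")
  value <- drop(crossprod(w, fit$beta))
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtXinv %*% w))
  tval <- ifelse(se > 0, value / se, ifelse(value == 0, 0, Inf * sign(value)))
  structure(list(value = value, t = tval, se = se, df = fit$df,
                 weights = w),
            class = "contrast_result")
}

#' Mean contrast value within spherical ROIs of a volumetric map
#'
#' @param map a 3D array of voxelwise values on the grid of `mask`.
#' @param network a `network_spec` (subset of nodes to extract).
#' @param mask a [mask_spec()] giving the geometry.
#' @return Named numeric vector of per-ROI means over voxels whose
#'   centers lie within the ROI radius.
#' @export
extract_roi_betas <- function(map, network, mask) {
  stopifnot(inherits(mask, "mask_spec"),
            identical(dim(map), as.integer(mask$dim)))
  out <- vapply(seq_len(nrow(network)), function(i) {
    vox <- sphere_voxels(mask,
                         c(network$x[i], network$y[i], network$z[i]),
                         network$radius[i])
    if (length(vox) == 0)
      stop(sprintf("ROI does not intersect the mask: %s",
                   network$name[i]))
    mean(map[vox])
  }, numeric(1))
  names(out) <- network$name
  out
}
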