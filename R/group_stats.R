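#' Voxelwise two-sample t map (group comparison)
#'
#' Pooled-variance two-sample t statistics per feature (voxel or ROI),
#' direction `levels[1] - levels[2]` of the group factor (TD - ASD when
#' groups are labeled "TD"/"ASD": TD is placed first).
#'
#' @param values subjects x features numeric matrix of contrast values.
#' @param groups group labels, one per subject (2 levels, >= 2 each).
#' @return A `stat_map`: list with `t` (per feature), `df`
#'   (`n1 + n2 - 2`), `type`, `direction`.
#' @export
second_level_ttest <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if ("TD" %in% lev) lev <- c("TD", setdiff(lev, "TD"))
  i1 <- groups == lev[1]; i2 <- groups == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  m1 <- colMeans(values[i1, , drop = FALSE])
  m2 <- colMeans(values[i2, , drop = FALSE])
  v1 <- apply(values[i1, , drop = FALSE], 2, var)
  v2 <- apply(values[i2, , drop = FALSE], 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- ifelse(se > 0, (m1 - m2) / se, 0)
  structure(list(t = tval, df = n1 + n2 - 2, type = "two-sample",
                 direction = paste(lev, collapse = " - ")),
            class = "stat_map")
}

#' Voxelwise simple-regression t map (behavior covariate)
#'
#' Per feature, the t statistic of the slope of activation on the
#' behavioral score (df = n - 2). A negative t means activity increases
#' as the score decreases, i.e. greater activity with better social
#' function when lower scores are better.
#'
#' @param values subjects x features numeric matrix.
#' @param scores behavioral scores, one per subject (non-constant).
#' @return A `stat_map` with `t`, `df = n - 2`, `type = "regression"`.
#' @export
covariate_regression <- function(values, scores) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) stop("at least 3 subjects required")
  if (var(scores) == 0) stop("degenerate predictor: scores are constant")
  x <- scores - mean(scores)
  sxx <- sum(x^2)
  b <- drop(crossprod(x, scale(values, scale = FALSE))) / sxx
  fitted <- outer(x, b)
  res <- scale(values, scale = FALSE) - fitted
  s2 <- colSums(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- ifelse(se > 0, b / se, ifelse(b == 0, 0, Inf * sign(b)))
  structure(list(t = tval, df = n - 2, type = "regression",
                 direction = "slope of activation on score"),
            class = "stat_map")
}

#' Monte Carlo cluster-extent threshold for family-wise error control
#'
#' Estimates the cluster-size threshold controlling the family-wise
#' error of suprathreshold clusters: each iteration fills the mask with
#' independent Gaussian noise, smooths at the given FWHM, re-standardizes
#' to zero mean and unit variance in-mask, thresholds one-tailed at
#' `voxel_p`, and records the largest face-connected (6-neighbor) cluster.
#' The returned extent is the smallest cluster size `s` with
#' `P(max cluster >= s) <= fwe_p` under the null.
#'
#' @param mask a [mask_spec()].
#' @param fwhm_mm smoothness of the simulated noise (applied smoothing).
#' @param voxel_p one-tailed voxelwise height threshold probability.
#' @param fwe_p target family-wise error rate.
#' @param n_iter number of Monte Carlo iterations (>= 1000 recommended).
#' @param seed integer seed.
#' @return A `cluster_threshold`: list with `extent` (voxels),
#'   `max_sizes` (per-iteration maxima), and the parameters.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm = 6,
                                          voxel_p = 0.005, fwe_p = 0.05,
                                          n_iter = 1000, seed = 1L) {
  stopifnot(inherits(mask, "mask_spec"), n_iter >= 1)
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative")
  stopifnot_prob(voxel_p, "voxel_p"); stopifnot_prob(fwe_p, "fwe_p")
  if (voxel_p <= 0 || voxel_p >= 1) stop("`voxel_p` must be in (0, 1)")
  inm <- which(mask$mask)
  if (length(inm) == 0) stop("mask is empty")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / mask$voxel_mm
  zc <- qnorm(1 - voxel_p)
  d <- mask$dim
  max_sizes <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      vol <- array(0, d)
      vol[inm] <- rnorm(length(inm))
      if (sigma_vox > 0)
        vol <- .smooth3d_cpp(vol, d, rep(sigma_vox, 3))
      v <- vol[inm]
      vol[inm] <- (v - mean(v)) / sd(v)
      supra <- array(FALSE, d)
      supra[inm] <- vol[inm] > zc
      .max_cluster_size_cpp(supra, d)
    }, integer(1))
  })
  # smallest extent s with P(max >= s) <= fwe_p
  s <- 1L
  while (mean(max_sizes >= s) > fwe_p) s <- s + 1L
  structure(list(extent = s, max_sizes = max_sizes, fwhm_mm = fwhm_mm,
                 voxel_p = voxel_p, fwe_p = fwe_p, n_iter = n_iter,
                 n_mask_voxels = length(inm), seed = seed),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "Cluster-extent threshold: %d voxels (FWE p<%g at voxel p<%g, %g mm FWHM,\n  %d in-mask voxels, %d iterations)\n",
    x$extent, x$fwe_p, x$voxel_p, x$fwhm_mm, x$n_mask_voxels, x$n_iter))
  invisible(x)
}

#' Threshold a statistical map and apply a cluster-extent correction
#'
#' Thresholds the t map at the one-tailed `voxel_p` height threshold
#' (Student t with the map's df), labels face-connected suprathreshold
#' clusters, and marks clusters at or above the extent threshold as
#' surviving the correction.
#'
#' @param map a `stat_map` whose `t` is a vector over in-mask voxels, or
#'   a 3D t array.
#' @param mask a [mask_spec()].
#' @param extent cluster-extent threshold in voxels (e.g. from
#'   [monte_carlo_cluster_threshold()]).
#' @param voxel_p one-tailed voxelwise height threshold.
#' @param direction `"pos"` tests t > threshold, `"neg"` tests
#'   t < -threshold.
#' @return A `cluster_table` data frame: one row per cluster with
#'   `size`, `peak_x`, `peak_y`, `peak_z` (mm), `peak_t`,
#'   `survives_correction`.
#' @export
apply_cluster_correction <- function(map, mask, extent,
                                     voxel_p = 0.005,
                                     direction = c("pos", "neg")) {
  direction <- match.arg(direction)
  stopifnot(inherits(mask, "mask_spec"))
  inm <- which(mask$mask)
  if (inherits(map, "stat_map")) {
    tarr <- array(0, mask$dim)
    if (length(map$t) == length(inm)) tarr[inm] <- map$t
    else if (identical(dim(map$t), as.integer(mask$dim))) tarr <- map$t
    else stop("stat map length matches neither mask voxels nor grid")
    df <- map$df
  } else {
    tarr <- map
    df <- attr(map, "df")
    if (is.null(df)) stop("3D t array must carry a `df` attribute")
  }
  tc <- qt(1 - voxel_p, df)
  supra <- array(FALSE, mask$dim)
  supra[inm] <- if (direction == "pos") tarr[inm] > tc else tarr[inm] < -tc
  lab <- .label_clusters_cpp(supra, mask$dim)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0) {
    out <- data.frame(size = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      peak_t = numeric(0),
                      survives_correction = logical(0))
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  ctr <- (mask$dim + 1) / 2
  rows <- lapply(ids, function(id) {
    vox <- which(lab == id)
    tv <- tarr[vox]
    if (direction == "neg") tv <- -tv
    peak <- vox[which.max(tv)]
    pk <- (arrayInd(peak, mask$dim)[1, ] - ctr) * mask$voxel_mm
    data.frame(size = length(vox), peak_x = pk[1], peak_y = pk[2],
               peak_z = pk[3], peak_t = tarr[peak],
               survives_correction = length(vox) >= extent)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), ]
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Small volume correction within an anatomical search region
#'
#' Re-runs the Monte Carlo cluster simulation restricted to `roi_mask`
#' (which must lie within the analysis mask) and applies the cluster
#' correction within that region only. Smaller search volumes yield
#' smaller extent thresholds, giving sensitivity for small structures.
#'
#' @inheritParams apply_cluster_correction
#' @param roi_mask a [mask_spec()] restricted to the search region.
#' @inheritParams monte_carlo_cluster_threshold
#' @return A `cluster_table` (with the extent used in attribute
#'   `extent`).
#' @export
small_volume_correct <- function(map, mask, roi_mask, fwhm_mm = 6,
                                 voxel_p = 0.005, fwe_p = 0.05,
                                 n_iter = 1000, seed = 1L,
                                 direction = "pos") {
  stopifnot(inherits(roi_mask, "mask_spec"))
  if (sum(roi_mask$mask) == 0) stop("roi_mask is empty")
  if (!identical(roi_mask$dim, mask$dim))
    stop("roi_mask must be contained in the analysis mask (same grid)")
  if (any(roi_mask$mask & !mask$mask))
    stop("roi_mask must be contained in the analysis mask")
  thr <- monte_carlo_cluster_threshold(roi_mask, fwhm_mm = fwhm_mm,
                                       voxel_p = voxel_p, fwe_p = fwe_p,
                                       n_iter = n_iter, seed = seed)
  # restrict the map to the search region
  restricted <- if (inherits(map, "stat_map")) {
    tarr <- array(0, mask$dim)
    inm <- which(mask$mask)
    if (length(map$t) == length(inm)) tarr[inm] <- map$t else tarr <- map$t
    structure(tarr, df = map$df)
  } else map
  out <- apply_cluster_correction(restricted, roi_mask,
                                  extent = thr$extent,
                                  voxel_p = voxel_p,
                                  direction = direction)
  attr(out, "extent") <- thr$extent
  out
}

#' Standardized effect sizes from mean cluster t scores
#'
#' For a two-sample comparison, `d = t / sqrt(N / 2)`; for a covariate
#' (regression) effect, `f = t / sqrt(N)`. `t` is the mean t score within
#' a cluster and `N` the total sample size. The two are consistent:
#' `f = d / sqrt(2)` at equal `N`.
#'
#' @param t mean t score within a cluster.
#' @param N sample size.
#' @return Effect size value.
#' @export
cohens_d_from_t <- function(t, N) {
  if (N < 2) stop("`N` must be at least 2")
  t / sqrt(N / 2)
}

#' @rdname cohens_d_from_t
#' @export
cohens_f_from_t <- function(t, N) {
  if (N < 1) stop("`N` must be at least 1")
  t / sqrt(N)
}
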