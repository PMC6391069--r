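#' Motion trace and scan-to-scan displacement
#'
#' A motion trace records per-volume translations in mm. Scan-to-scan
#' displacement is the Euclidean norm of the difference between
#' successive (x, y, z) translation vectors; the first volume's
#' displacement is defined as 0.
#'
#' @param x,y,z per-volume translations (mm).
#' @return A `motion_trace` data frame with columns `volume`, `x`, `y`,
#'   `z`, `displacement`.
#' @export
motion_trace <- function(x, y = numeric(length(x)),
                         z = numeric(length(x))) {
  stopifnot(length(y) == length(x), length(z) == length(x),
            all(is.finite(c(x, y, z))))
  disp <- c(0, sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
  out <- data.frame(volume = seq_along(x), x = x, y = y, z = z,
                    displacement = disp)
  class(out) <- c("motion_trace", "data.frame")
  out
}

#' Read or write motion traces as CSV
#'
#' Columns: `volume, x_mm, y_mm, z_mm`.
#' @param path file path.
#' @param motion a `motion_trace`.
#' @export
read_motion_csv <- function(path) {
  d <- read.csv(path)
  motion_trace(d$x_mm, d$y_mm, d$z_mm)
}

#' @rdname read_motion_csv
#' @export
write_motion_csv <- function(motion, path) {
  write.csv(data.frame(volume = motion$volume, x_mm = motion$x,
                       y_mm = motion$y, z_mm = motion$z),
            path, row.names = FALSE)
  invisible(path)
}

#' Detect volumes corrupted by motion or global-signal spikes
#'
#' A volume is flagged when its scan-to-scan displacement exceeds half a
#' voxel (`0.5 * voxel_mm`, 1.5625 mm at the 3.125 mm in-plane
#' acquisition resolution) or when its global signal deviates from the
#' run median by more than `global_pct` (5%) of the median.
#'
#' @param motion a [motion_trace()].
#' @param global_signal per-volume global mean signal (same length).
#' @param voxel_mm in-plane voxel size used for the motion threshold.
#' @param global_pct relative global-signal deviation threshold.
#' @return Sorted integer vector of flagged volume indices.
#' @export
detect_spike_volumes <- function(motion, global_signal = NULL,
                                 voxel_mm = 3.125, global_pct = 0.05) {
  stopifnot(inherits(motion, "motion_trace"))
  flagged <- which(motion$displacement > 0.5 * voxel_mm)
  if (!is.null(global_signal)) {
    if (length(global_signal) != nrow(motion))
      stop("motion trace and global signal have different lengths")
    med <- median(global_signal)
    flagged <- union(flagged,
                     which(abs(global_signal - med) > global_pct * abs(med)))
  }
  sort(flagged)
}

#' Replace flagged volumes by interpolation from adjacent scans
#'
#' Interior flagged volumes are replaced by linear interpolation between
#' the nearest unflagged neighbors; flagged volumes at a run boundary are
#' replaced by the nearest unflagged volume.
#'
#' @param data a `bold_run` or a volumes-by-series numeric matrix.
#' @param flagged integer indices of volumes to repair.
#' @return Object of the same type with flagged volumes replaced.
#' @export
interpolate_volumes <- function(data, flagged) {
  if (inherits(data, "bold_run")) {
    data$series <- interpolate_volumes(data$series, flagged)
    return(data)
  }
  m <- as.matrix(data)
  n <- nrow(m)
  flagged <- sort(unique(as.integer(flagged)))
  if (length(flagged) == 0) return(m)
  if (any(flagged < 1 | flagged > n)) stop("flagged indices out of range")
  good <- setdiff(seq_len(n), flagged)
  if (length(good) == 0) stop("unrecoverable run: all volumes flagged")
  for (v in flagged) {
    lo <- max(good[good < v], -Inf)
    hi <- min(good[good > v], Inf)
    if (is.infinite(lo)) {
      m[v, ] <- m[hi, ]
    } else if (is.infinite(hi)) {
      m[v, ] <- m[lo, ]
    } else {
      w <- (v - lo) / (hi - lo)
      m[v, ] <- (1 - w) * m[lo, ] + w * m[hi, ]
    }
  }
  m
}

#' Run- and subject-level inclusion criteria
#'
#' A run is included when its maximum scan-to-scan displacement is below
#' 6 mm and no more than 15% of its volumes were repaired. A subject is
#' included when at least `min_runs` (7) runs pass.
#'
#' @param motion a [motion_trace()].
#' @param flagged volume indices repaired by despiking.
#' @param max_disp_mm,max_pct_repaired run inclusion thresholds.
#' @return `qc_run`: a `run_qc` list with `max_displacement_mm`,
#'   `pct_repaired`, `included`.
#' @export
qc_run <- function(motion, flagged = integer(0), max_disp_mm = 6,
                   max_pct_repaired = 0.15) {
  stopifnot(inherits(motion, "motion_trace"))
  maxd <- max(motion$displacement)
  pct <- length(unique(flagged)) / nrow(motion)
  structure(list(max_displacement_mm = maxd, pct_repaired = pct,
                 included = (maxd < max_disp_mm) && (pct <= max_pct_repaired)),
            class = "run_qc")
}

#' @rdname qc_run
#' @param run_qcs list of `run_qc` objects for one subject.
#' @param min_runs minimum number of included runs.
#' @return `qc_subject`: `TRUE` when the subject passes.
#' @export
qc_subject <- function(run_qcs, min_runs = 7) {
  stopifnot(length(run_qcs) > 0)
  sum(vapply(run_qcs, `[[`, logical(1), "included")) >= min_runs
}

#' Gaussian spatial smoothing of a volume
#'
#' Convolves each 3D frame with an isotropic Gaussian of the given full
#' width at half maximum (`sigma = fwhm / (2 * sqrt(2 * log(2)))` mm,
#' converted to voxels via the mask geometry). Within a mask, kernels are
#' renormalized over in-mask voxels so that constant signal is preserved
#' at the mask boundary.
#'
#' @param vol a 3D array, a 4D array, or a `bold_volume`.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param voxel_mm isotropic voxel size (taken from the mask if given).
#' @param mask optional [mask_spec()]; smoothing is then restricted to
#'   and renormalized within the mask.
#' @return Smoothed object of the same type.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 6, voxel_mm = 2, mask = NULL) {
  if (fwhm_mm <= 0) stop("`fwhm_mm` must be positive")
  if (inherits(vol, "bold_volume")) {
    vol$data <- smooth_gaussian(vol$data, fwhm_mm,
                                vol$mask$voxel_mm, vol$mask)
    return(vol)
  }
  if (!is.null(mask)) voxel_mm <- mask$voxel_mm
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  d <- dim(vol)
  smooth_frame <- function(fr) {
    if (is.null(mask)) {
      .smooth3d_cpp(fr, dim(fr), rep(sigma_vox, 3))
    } else {
      num <- .smooth3d_cpp(fr * mask$mask, mask$dim, rep(sigma_vox, 3))
      den <- .smooth3d_cpp(array(as.double(mask$mask), mask$dim),
                           mask$dim, rep(sigma_vox, 3))
      out <- array(0, mask$dim)
      inm <- mask$mask
      out[inm] <- num[inm] / den[inm]
      out
    }
  }
  if (length(d) == 3) return(smooth_frame(vol))
  stopifnot(length(d) == 4)
  out <- vol
  for (t in seq_len(d[4])) out[, , , t] <- smooth_frame(vol[, , , t])
  out
}
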