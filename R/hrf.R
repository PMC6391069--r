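#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities: a positive
#' response peaking around 6 s and a later undershoot around 16 s scaled
#' by `undershoot_ratio`. Time is discretized at a microtime resolution of
#' `microtime` bins per TR, so event regressors can be built on a fine
#' grid and downsampled to the acquisition times.
#'
#' @param peak_delay_s delay of the response peak (s).
#' @param undershoot_delay_s delay of the undershoot (s).
#' @param peak_disp,undershoot_disp dispersions of the two gamma
#'   components.
#' @param undershoot_ratio ratio of undershoot to peak amplitude.
#' @param microtime microtime bins per TR.
#' @param length_s kernel support (s).
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                      peak_disp = 1, undershoot_disp = 1,
                      undershoot_ratio = 1 / 6,
                      microtime = 16L, length_s = 32) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_disp > 0, undershoot_disp > 0, length_s > 0,
            microtime >= 1)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_disp = peak_disp,
                 undershoot_disp = undershoot_disp,
                 undershoot_ratio = undershoot_ratio,
                 microtime = as.integer(microtime),
                 length_s = length_s),
            class = "hrf_model")
}

#' Sample the canonical HRF (and its temporal derivative) on a time grid
#'
#' @param hrf an [hrf_model()].
#' @param dt sampling interval (s), typically `tr_s / hrf$microtime`.
#' @return `hrf_kernel`: numeric vector of the HRF sampled at
#'   `seq(0, length_s, by = dt)`, scaled so that a 1 s block of unit
#'   neural activity evokes a response with unit peak (a planted
#'   activation amplitude of 1 then produces an event response of about
#'   1 signal unit for stimuli near 1 s); `hrf_derivative`: its
#'   finite-difference temporal derivative (sums to approximately
#'   zero).
#' @export
hrf_kernel <- function(hrf, dt) {
  stopifnot(inherits(hrf, "hrf_model"), dt > 0)
  t <- seq(0, hrf$length_s, by = dt)
  # gamma density parameterized by shape = delay/disp, scale = disp
  g <- function(delay, disp)
    dgamma(t, shape = delay / disp, scale = disp)
  h <- g(hrf$peak_delay_s, hrf$peak_disp) -
    hrf$undershoot_ratio * g(hrf$undershoot_delay_s, hrf$undershoot_disp)
  # normalize so a 1 s unit block evokes a unit-peak response
  nb <- max(1L, round(1 / dt))
  block <- convolve(c(rep(1, nb), numeric(length(h))), rev(h),
                    type = "open")
  h / max(block)
}

#' @rdname hrf_kernel
#' @export
hrf_derivative <- function(hrf, dt) {
  h <- hrf_kernel(hrf, dt)
  c(diff(h), 0) / dt
}

# Causal convolution of a microtime series with a kernel, truncated to
# the length of the input.
conv_causal <- function(x, kernel) {
  n <- length(x)
  y <- convolve(c(x, numeric(length(kernel))), rev(kernel),
                type = "open")[seq_len(n)]
  y
}

# Boxcar indicator of one condition at microtime resolution.
# Returns a vector of length n_vols * microtime for one run.
condition_boxcar <- function(schedule, run, condition, tr_s, n_vols,
                             microtime) {
  dt <- tr_s / microtime
  n <- n_vols * microtime
  psi <- numeric(n)
  ev <- schedule[schedule$run == run & schedule$condition == condition, ]
  if (nrow(ev) == 0) return(psi)
  for (i in seq_len(nrow(ev))) {
    a <- floor(ev$onset[i] / dt) + 1
    b <- min(n, a + max(1, round(ev$duration[i] / dt)) - 1)
    if (a <= n) psi[a:b] <- 1
  }
  psi
}

# Convolve a microtime neural series with the HRF and sample at TR
# (first microtime bin of each volume).
microtime_to_tr <- function(neural, hrf, tr_s, n_vols) {
  dt <- tr_s / hrf$microtime
  k <- hrf_kernel(hrf, dt)
  y <- conv_causal(neural, k)
  y[seq(1, n_vols * hrf$microtime, by = hrf$microtime)]
}
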