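# Shared fixtures: small schedules and ground truths built in code.

small_spec <- function(n_runs = 2, exemplars = 8, catch = 2) {
  paradigm_spec(n_runs = n_runs, exemplars_per_condition = exemplars,
                catch_per_run = catch)
}

small_schedule <- function(...) {
  spec <- small_spec(...)
  sch <- generate_paradigm(spec)
  attr(sch, "tr_s") <- spec$tr_ms / 1000
  attr(sch, "n_vols") <- spec$run_volumes
  sch
}

full_schedule <- function() {
  spec <- paradigm_spec()
  sch <- generate_paradigm(spec)
  attr(sch, "tr_s") <- spec$tr_ms / 1000
  attr(sch, "n_vols") <- spec$run_volumes
  sch
}

# quiet truth: no planted effects, all noise off, zero offset
silent_truth <- function(network = default_voice_network()) {
  tr <- ground_truth(network = network)
  tr$noise <- list(phi = 0, sd = 0, drift_amp = 0, neural_sd = 0,
                   spike_prob = 0, offset = 0)
  tr
}

# independent direct convolution oracle (naive double loop)
naive_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    jmax <- min(t, length(k))
    out[t] <- sum(k[seq_len(jmax)] * x[t - seq_len(jmax) + 1])
  }
  out
}

# independent 6-connected max cluster size (plain R flood fill)
naive_max_cluster <- function(supra) {
  d <- dim(supra)
  lab <- array(0L, d)
  best <- 0L
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  idx <- which(supra, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[idx[r, 1], idx[r, 2], idx[r, 3]] != 0L) next
    queue <- list(idx[r, ])
    lab[idx[r, 1], idx[r, 2], idx[r, 3]] <- 1L
    size <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (j in seq_len(6)) {
        w <- v + nb[j, ]
        if (any(w < 1) || any(w > d)) next
        if (supra[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- 1L
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
    best <- max(best, size)
  }
  best
}
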