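#' Sparse-sampling auditory paradigm specification
#'
#' Describes the timing of a sparse temporal sampling event-related design
#' in which each repetition time (TR) contains a stimulus presented in a
#' silent gap around a compressed volume acquisition. The TR is the exact
#' sum of its parts: a pre-stimulus silent buffer, the stimulus itself, a
#' post-stimulus buffer, the volume acquisition, and a short timing pad,
#' so auditory stimuli are never masked by scanner noise.
#'
#' The default values describe a 3576 ms TR (956 ms stimulus, 300 ms
#' buffers on either side, 2000 ms acquisition, 20 ms pad), 10 runs of
#' 4 minutes (67 volumes), three stimulus conditions with 48 exemplars
#' each across the session, and 3 catch trials per run.
#'
#' @param n_runs number of functional runs.
#' @param stim_ms stimulus duration in milliseconds.
#' @param pre_buffer_ms,post_buffer_ms silent buffers around the stimulus
#'   (ms).
#' @param acq_ms volume acquisition time (ms).
#' @param pad_ms additional timing pad (ms).
#' @param conditions character vector of stimulus condition labels
#'   (excluding catch trials).
#' @param exemplars_per_condition total exemplars of each condition across
#'   the whole session.
#' @param catch_label label used for catch trials.
#' @param catch_per_run number of catch trials in each run.
#' @param run_volumes volumes acquired per run.
#' @param order_seed integer seed controlling the pseudo-random stimulus
#'   order; the same seed always yields the same schedule.
#'
#' @return An object of class `paradigm_spec` with derived fields `tr_ms`
#'   (sum of the five components) and `silent_gap_ms` (`tr_ms - stim_ms`,
#'   the total silent period between successive stimulus presentations).
#' @export
#' @examples
#' spec <- paradigm_spec()
#' spec$tr_ms          # 3576
#' spec$silent_gap_ms  # 2620
paradigm_spec <- function(n_runs = 10,
                          stim_ms = 956,
                          pre_buffer_ms = 300,
                          post_buffer_ms = 300,
                          acq_ms = 2000,
                          pad_ms = 20,
                          conditions = c("mother", "unfamiliar",
                                         "environmental"),
                          exemplars_per_condition = 48,
                          catch_label = "catch",
                          catch_per_run = 3,
                          run_volumes = 67,
                          order_seed = 1L) {
  durs <- c(stim_ms, pre_buffer_ms, post_buffer_ms, acq_ms, pad_ms)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all paradigm durations must be positive")
  if (n_runs < 1 || run_volumes < 1)
    stop("`n_runs` and `run_volumes` must be positive")
  if (anyDuplicated(conditions))
    stop("condition labels must be unique")
  spec <- list(
    n_runs = as.integer(n_runs),
    stim_ms = stim_ms,
    pre_buffer_ms = pre_buffer_ms,
    post_buffer_ms = post_buffer_ms,
    acq_ms = acq_ms,
    pad_ms = pad_ms,
    tr_ms = stim_ms + pre_buffer_ms + post_buffer_ms + acq_ms + pad_ms,
    conditions = conditions,
    exemplars_per_condition = as.integer(exemplars_per_condition),
    catch_label = catch_label,
    catch_per_run = as.integer(catch_per_run),
    run_volumes = as.integer(run_volumes),
    order_seed = as.integer(order_seed)
  )
  # total inter-stimulus silent period: both buffers + acquisition + pad
  spec$silent_gap_ms <- spec$pre_buffer_ms + spec$acq_ms +
    spec$post_buffer_ms + spec$pad_ms
  class(spec) <- "paradigm_spec"
  spec
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf(
    "Sparse-sampling paradigm: %d runs x %d volumes, TR %g ms (silent gap %g ms)\n",
    x$n_runs, x$run_volumes, x$tr_ms, x$silent_gap_ms))
  cat(sprintf("  conditions: %s (+%d %s/run), %d exemplars/condition\n",
              paste(x$conditions, collapse = ", "), x$catch_per_run,
              x$catch_label, x$exemplars_per_condition))
  invisible(x)
}

# Split `total` events as evenly as possible over `n` runs
# (deterministic: the first `total %% n` runs get the extra event).
split_events_over_runs <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  counts <- rep(base, n)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

#' Generate a TR-locked event schedule for a sparse-sampling paradigm
#'
#' Events are locked to TR slots (one stimulus per TR, no jitter): every
#' onset is an integer multiple of the TR. Within each run the requested
#' exemplars of each condition plus the catch trials are placed in
#' pseudo-randomly chosen TR slots and pseudo-randomly ordered,
#' deterministically given `spec$order_seed`, so the presentation order is
#' identical for every subject.
#'
#' @param spec a [paradigm_spec()].
#' @return An `event_schedule`: a data frame with columns `run` (1-based),
#'   `onset` (seconds from run start), `duration` (seconds), and
#'   `condition`, sorted by run and onset.
#' @export
generate_paradigm <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  per_run <- lapply(spec$conditions, function(cond)
    split_events_over_runs(spec$exemplars_per_condition, spec$n_runs))
  names(per_run) <- spec$conditions
  n_events_run <- vapply(seq_len(spec$n_runs), function(r)
    sum(vapply(per_run, `[`, integer(1), r)) + spec$catch_per_run,
    integer(1))
  if (any(n_events_run > spec$run_volumes))
    stop(sprintf(
      "infeasible packing: run needs %d event slots but only %d TRs are available",
      max(n_events_run), spec$run_volumes))

  tr_s <- spec$tr_ms / 1000
  dur_s <- spec$stim_ms / 1000
  rows <- with_seed(spec$order_seed, {
    lapply(seq_len(spec$n_runs), function(r) {
      labels <- c(
        rep(spec$conditions, times = vapply(per_run, `[`, integer(1), r)),
        rep(spec$catch_label, spec$catch_per_run))
      labels <- sample(labels)
      slots <- sort(sample(seq_len(spec$run_volumes), length(labels)) - 1L)
      data.frame(run = r, onset = slots * tr_s, duration = dur_s,
                 condition = labels, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_schedule", "data.frame")
  out
}

validate_schedule <- function(schedule, tr_s = NULL) {
  stopifnot(is.data.frame(schedule))
  need <- c("run", "onset", "duration", "condition")
  if (!all(need %in% names(schedule)))
    stop("schedule must have columns run, onset, duration, condition")
  for (r in unique(schedule$run)) {
    on <- schedule$onset[schedule$run == r]
    if (is.unsorted(on, strictly = TRUE))
      stop("onsets within a run must be strictly increasing")
  }
  if (!is.null(tr_s)) {
    frac <- abs(schedule$onset / tr_s - round(schedule$onset / tr_s))
    if (any(frac > 1e-6)) stop("onsets must be integer multiples of the TR")
  }
  invisible(schedule)
}

#' Write or read per-run event tables
#'
#' Event tables use the tab-separated events dialect with columns
#' `onset` (s), `duration` (s), `trial_type`; one file per run named
#' `run-<k>_events.tsv`.
#'
#' @param schedule an `event_schedule`.
#' @param dir output directory (created if absent).
#' @return `write_events_tsv` returns the written file paths, invisibly;
#'   `read_events_tsv` returns an `event_schedule`.
#' @export
write_events_tsv <- function(schedule, dir) {
  validate_schedule(schedule)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sort(unique(schedule$run)), function(r) {
    f <- file.path(dir, sprintf("run-%02d_events.tsv", r))
    sub <- schedule[schedule$run == r,
                    c("onset", "duration", "condition")]
    names(sub)[3] <- "trial_type"
    write.table(sub, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1))
  invisible(paths)
}

#' @rdname write_events_tsv
#' @param files paths to `*_events.tsv` files, in run order.
#' @export
read_events_tsv <- function(files) {
  rows <- lapply(seq_along(files), function(i) {
    d <- read.delim(files[i], stringsAsFactors = FALSE)
    data.frame(run = i, onset = d$onset, duration = d$duration,
               condition = d$trial_type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_schedule", "data.frame")
  out
}
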