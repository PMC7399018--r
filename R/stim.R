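#' Randomized block-design stimulus schedule
#'
#' Generates onset times for a block design in which every stimulation
#' block of `stim_dur` seconds is followed by a rest period drawn
#' uniformly from `[rest_min, rest_max]` seconds.  The randomized rest
#' de-synchronizes the task from periodic physiological noise such as
#' Mayer waves.  Defaults reproduce a finger-tapping protocol of 30
#' blocks of 2 s stimulation with rest in [10, 20] s.
#'
#' @param n_blocks number of stimulation blocks.
#' @param stim_dur block duration (s).
#' @param rest_min,rest_max bounds of the uniform rest interval (s).
#' @param lead_in rest before the first block (s).
#' @param seed optional integer seed for reproducible schedules.
#' @return object of class `stim_schedule`: list with `onset`, `duration`
#'   (s) and `n_blocks`.
#' @export
make_stim_schedule <- function(n_blocks = 30, stim_dur = 2,
                               rest_min = 10, rest_max = 20,
                               lead_in = 15, seed = NULL) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (stim_dur <= 0 || rest_min < 0 || rest_max < 0 || lead_in < 0) {
    stop("durations must be non-negative (stim_dur positive)")
  }
  if (rest_min > rest_max) stop("rest_min must not exceed rest_max")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rests <- stats::runif(n_blocks - 1, rest_min, rest_max)
  onset <- lead_in + c(0, cumsum(stim_dur + rests))
  structure(list(onset = onset, duration = rep(stim_dur, n_blocks),
                 n_blocks = n_blocks,
                 rest_range = c(rest_min, rest_max)),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("Block design:", x$n_blocks, "blocks of", x$duration[1],
      "s, rest in [", x$rest_range[1], ",", x$rest_range[2], "] s\n")
  invisible(x)
}

#' Total recording duration implied by a schedule
#'
#' Last offset plus a trailing rest long enough for the hemodynamic
#' response to return to baseline.
#' @param schedule a `stim_schedule`.
#' @param tail trailing rest (s).
#' @return duration in seconds.
#' @export
schedule_duration <- function(schedule, tail = 20) {
  n <- schedule$n_blocks
  schedule$onset[n] + schedule$duration[n] + tail
}

#' Boxcar regressor of a stimulus schedule
#'
#' @param schedule a `stim_schedule`.
#' @param fs sampling frequency (Hz).
#' @param n_samples length of the output vector.
#' @return numeric vector, 1 during stimulation and 0 elsewhere.
#' @export
stim_boxcar <- function(schedule, fs, n_samples) {
  t <- (seq_len(n_samples) - 1) / fs
  box <- numeric(n_samples)
  for (b in seq_len(schedule$n_blocks)) {
    box[t >= schedule$onset[b] &
        t < schedule$onset[b] + schedule$duration[b]] <- 1
  }
  box
}
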