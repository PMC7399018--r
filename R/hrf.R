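#' Single-gamma hemodynamic response kernel
#'
#' Gamma-variate impulse response normalized to unit peak, the canonical
#' single-basis HRF for block-design fNIRS GLMs.  The shape and scale are
#' solved from the requested peak latency and full width at half maximum:
#' with mode \eqn{m = (k-1)\theta} and variance \eqn{k\theta^2}, the scale
#' is \eqn{\theta = (\sqrt{m^2 + 4\sigma^2} - m)/2} where
#' \eqn{\sigma = \mathrm{FWHM}/2.355}.
#'
#' @param time_grid time points (s) at which to evaluate the kernel; must
#'   be non-negative with a positive step.
#' @param peak_time latency of the kernel maximum (s).
#' @param fwhm full width at half maximum (s).
#' @return numeric vector of kernel values in [0, 1], zero at t = 0.
#' @export
gamma_hrf <- function(time_grid, peak_time = 6, fwhm = 5.2) {
  if (peak_time <= 0 || fwhm <= 0) stop("peak_time and fwhm must be positive")
  if (length(time_grid) > 1 && any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  theta <- (sqrt(peak_time^2 + 4 * sigma^2) - peak_time) / 2
  k <- peak_time / theta + 1
  h <- stats::dgamma(time_grid, shape = k, scale = theta)
  h / stats::dgamma(peak_time, shape = k, scale = theta)
}

#' Convolve a stimulus schedule with the gamma HRF
#'
#' @param schedule a `stim_schedule`.
#' @param fs sampling frequency (Hz).
#' @param n_samples output length.
#' @param peak_time,fwhm kernel parameters passed to [gamma_hrf()].
#' @return task regressor: boxcar convolved with the unit-peak kernel.
#' @export
task_regressor <- function(schedule, fs, n_samples, peak_time = 6,
                           fwhm = 5.2) {
  box <- stim_boxcar(schedule, fs, n_samples)
  tk <- seq(0, 30, by = 1 / fs)
  kern <- gamma_hrf(tk, peak_time, fwhm)
  ## normalize so that a block of the schedule's duration peaks at 1
  block <- rep(1, max(1L, round(schedule$duration[1] * fs)))
  ref <- max(stats::convolve(c(block, numeric(length(kern))),
                             rev(kern), type = "open"))
  y <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_samples)]
  y / ref
}
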