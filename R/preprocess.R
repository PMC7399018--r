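#' Per-channel signal-to-noise ratio
#'
#' SNR of the raw light intensity, defined as the mean of the full
#' recording divided by its standard deviation (population form),
#' computed separately at each wavelength.
#'
#' @param raw a `raw_recording`.
#' @return matrix (channel x wavelength) of SNR values; a constant
#'   channel has zero variance and reports `Inf`.
#' @export
compute_snr <- function(raw) {
  n <- dim(raw$intensity)[3]
  if (n < 2) stop("need at least 2 time points to compute SNR")
  m <- apply(raw$intensity, c(1, 2), mean)
  ## population SD (divide by n, not n - 1)
  s <- sqrt(apply(raw$intensity, c(1, 2), function(x) mean((x - mean(x))^2)))
  snr <- m / s
  snr[s == 0] <- Inf
  dimnames(snr) <- list(raw$channel_ids, raw$wavelengths)
  snr
}

#' Remove low-SNR channels
#'
#' A channel is removed when its SNR is strictly below `threshold` at
#' either wavelength (SNR exactly equal to the threshold is kept).
#' Removed channels are recorded with their SNR values so the decision
#' can be audited; they are excluded from all downstream stages.
#'
#' @param raw a `raw_recording`.
#' @param threshold SNR pruning threshold.
#' @return the recording with failing channels dropped; the `pruned`
#'   element lists channel id, wavelength SNRs and reason.
#' @export
prune_channels <- function(raw, threshold = 8) {
  snr <- compute_snr(raw)
  bad <- apply(snr < threshold, 1, any)
  pruned <- data.frame(channel = raw$channel_ids[bad],
                       snr_w1 = snr[bad, 1], snr_w2 = snr[bad, 2],
                       reason = rep(sprintf("SNR < %g", threshold), sum(bad)),
                       row.names = NULL)
  raw$intensity <- raw$intensity[!bad, , , drop = FALSE]
  raw$channel_ids <- raw$channel_ids[!bad]
  raw$pruned <- pruned
  if (length(raw$channel_ids) == 0) {
    stop("all channels pruned (SNR < ", threshold, ")")
  }
  raw
}

#' Convert light intensity to optical-density changes
#'
#' Decadic optical density relative to the channel mean:
#' \eqn{\Delta OD(t) = -\log_{10}(I(t)/\bar I)}.
#'
#' @param raw a `raw_recording` (possibly pruned).
#' @return object of class `od_recording` with a `channel x wavelength x
#'   time` array `od`.
#' @export
intensity_to_od <- function(raw) {
  bad <- which(raw$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive intensity in channel %s, wavelength %s, sample %d",
                 raw$channel_ids[bad[1, 1]], raw$wavelengths[bad[1, 2]],
                 bad[1, 3]))
  }
  m <- apply(raw$intensity, c(1, 2), mean)
  od <- -log10(raw$intensity / as.vector(m))
  structure(list(od = od, fs = raw$fs, probe = raw$probe,
                 schedule = raw$schedule, channel_ids = raw$channel_ids,
                 wavelengths = raw$wavelengths,
                 pruned = raw$pruned, meta = raw$meta, truth = raw$truth),
            class = "od_recording")
}

#' Modified Beer-Lambert inversion
#'
#' Solves, per channel and time point, the two-wavelength system
#' \deqn{\Delta OD_\lambda = (\varepsilon_{HbO}(\lambda)\,\Delta HbO +
#'   \varepsilon_{HbR}(\lambda)\,\Delta HbR)\, d \, DPF}
#' for the hemoglobin concentration changes, with source-detector
#' distance d in cm and concentrations in uM.
#'
#' @param od an `od_recording`.
#' @param dpf differential pathlength factor (same value for both
#'   wavelengths).
#' @param extinction 2 x 2 matrix (wavelength x chromophore) of decadic
#'   molar extinction coefficients; defaults to the shipped table at the
#'   recording's wavelengths.
#' @return object of class `hb_recording` with `hbo` and `hbr` matrices
#'   (channel x time, uM).
#' @export
od_to_hb <- function(od, dpf = 6, extinction = NULL) {
  if (length(od$wavelengths) != 2) {
    stop("modified Beer-Lambert inversion requires exactly two wavelengths")
  }
  if (is.null(extinction)) {
    extinction <- extinction_coefficients(od$wavelengths)
  }
  if (abs(det(extinction)) < 1e-8) stop("singular extinction matrix")
  einv <- solve(extinction)
  ch <- od$probe$channels
  sep <- ch$separation[match(od$channel_ids, ch$channel)]
  if (anyNA(sep)) stop("missing source-detector separation for a channel")
  n_ch <- length(od$channel_ids)
  n <- dim(od$od)[3]
  hbo <- matrix(NA_real_, n_ch, n)
  hbr <- matrix(NA_real_, n_ch, n)
  for (j in seq_len(n_ch)) {
    rhs <- rbind(od$od[j, 1, ], od$od[j, 2, ]) / (sep[j] * dpf)
    conc <- einv %*% rhs * 1e6   # M -> uM
    hbo[j, ] <- conc[1, ]
    hbr[j, ] <- conc[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, fs = od$fs, probe = od$probe,
                 schedule = od$schedule, channel_ids = od$channel_ids,
                 pruned = od$pruned, band = NULL, meta = od$meta,
                 truth = od$truth),
            class = "hb_recording")
}

#' Zero-phase bandpass filter of hemoglobin time series
#'
#' Third-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase, no group delay), removing slow drifts
#' below `low` and cardiac/high-frequency physiology above `high`.
#'
#' @param hb an `hb_recording` (or any object with `hbo`/`hbr` matrices
#'   and `fs`).
#' @param low,high band edges in Hz.
#' @param order Butterworth section order.
#' @return the recording with filtered `hbo`/`hbr` and `band` recorded.
#' @export
bandpass <- function(hb, low = 0.005, high = 0.5, order = 3) {
  fs <- hb$fs
  if (low <= 0 || high >= fs / 2 || low >= high) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  f <- function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }
  hb$hbo <- t(apply(hb$hbo, 1, f))
  hb$hbr <- t(apply(hb$hbr, 1, f))
  hb$band <- c(low = low, high = high)
  hb
}

#' Run the full preprocessing chain on a raw recording
#'
#' Stage order is fixed: SNR pruning, optical-density conversion, spline
#' motion correction, wavelet motion correction, modified Beer-Lambert
#' inversion, bandpass filtering.  Parameters of every stage are recorded
#' in the returned object's `log`.
#'
#' @param raw a `raw_recording`.
#' @param snr_threshold pruning threshold.
#' @param spline,wavelet parameter lists for [spline_correct()] and
#'   [wavelet_correct()]; `NULL` skips a stage.
#' @param dpf differential pathlength factor for [od_to_hb()].
#' @param band two-element band (Hz) for [bandpass()].
#' @return an `hb_recording` with a `log` element describing the stages.
#' @export
preprocess <- function(raw, snr_threshold = 8,
                       spline = list(), wavelet = list(),
                       dpf = 6, band = c(0.005, 0.5)) {
  stages <- list()
  raw <- prune_channels(raw, snr_threshold)
  stages$prune <- list(threshold = snr_threshold,
                       removed = raw$pruned$channel)
  od <- intensity_to_od(raw)
  stages$od <- list(reference = "mean intensity")
  if (!is.null(spline)) {
    od <- do.call(spline_correct, c(list(od), spline))
    stages$spline <- spline
  }
  if (!is.null(wavelet)) {
    od <- do.call(wavelet_correct, c(list(od), wavelet))
    stages$wavelet <- wavelet
  }
  hb <- od_to_hb(od, dpf = dpf)
  stages$mbll <- list(dpf = dpf)
  hb <- bandpass(hb, band[1], band[2])
  stages$bandpass <- list(band = band, order = 3, zero_phase = TRUE)
  hb$log <- stages
  hb
}
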