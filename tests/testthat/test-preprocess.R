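make_raw <- function(intensity, fs = 10, probe = NULL) {
  ## minimal raw_recording around a channel x wavelength x time array
  n_ch <- dim(intensity)[1]
  if (is.null(probe)) {
    probe <- make_probe(sources = cbind(0, seq_len(n_ch) * 10),
                        detectors = cbind(3, seq_len(n_ch) * 10))
  }
  structure(list(intensity = intensity, fs = fs, probe = probe,
                 schedule = make_stim_schedule(1, 2, 5, 5, seed = 1),
                 channel_ids = probe$channels$channel[seq_len(n_ch)],
                 wavelengths = c(760, 850), meta = list()),
            class = "raw_recording")
}

test_that("SNR follows the mean-over-population-SD definition", {
  x <- array(0, c(1, 2, 100))
  x[1, 1, ] <- 100                       # constant -> infinite SNR
  x[1, 2, ] <- rep(c(90, 110), 50)       # mean 100, population SD 10
  snr <- compute_snr(make_raw(x))
  expect_equal(snr[1, 1], Inf)
  expect_equal(snr[1, 2], 10)
  ## mean 80, SD 10 (exactly, population form)
  y <- array(0, c(1, 2, 100))
  y[1, 1, ] <- rep(c(70, 90), 50)
  y[1, 2, ] <- rep(c(70, 90), 50)
  expect_equal(compute_snr(make_raw(y))[1, 1], 8)
})

test_that("pruning removes a channel failing at either wavelength, keeps SNR == 8", {
  mk_series <- function(snr, n = 100) {
    ## mean 100, population SD = 100/snr
    100 + rep(c(-1, 1), n / 2) * 100 / snr
  }
  x <- array(0, c(3, 2, 100))
  x[1, 1, ] <- mk_series(7.9); x[1, 2, ] <- mk_series(20)  # fails at w1
  x[2, 1, ] <- mk_series(8);   x[2, 2, ] <- mk_series(8)   # boundary: kept
  x[3, 1, ] <- mk_series(50);  x[3, 2, ] <- mk_series(50)  # fine
  raw <- make_raw(x)
  pr <- prune_channels(raw, threshold = 8)
  expect_equal(pr$pruned$channel, raw$channel_ids[1])
  expect_equal(pr$channel_ids, raw$channel_ids[2:3])
  ## identity when everything passes
  pr2 <- prune_channels(make_raw(x[2:3, , , drop = FALSE]), 8)
  expect_equal(length(pr2$channel_ids), 2)
  expect_equal(nrow(pr2$pruned), 0)
})

test_that("optical density conversion follows the decadic definition", {
  x <- array(100, c(1, 2, 50))
  od <- intensity_to_od(make_raw(x))
  expect_equal(max(abs(od$od)), 0)
  ## one sample at I0/10 -> OD 1 there (relative to the perturbed mean)
  x2 <- array(100, c(1, 2, 1000))
  x2[1, 1, 500] <- 10
  od2 <- intensity_to_od(make_raw(x2))
  i0 <- mean(x2[1, 1, ])
  expect_equal(od2$od[1, 1, 500], -log10(10 / i0))
  expect_equal(od2$od[1, 1, 1], -log10(100 / i0))
  ## non-positive intensity is an informative error
  x3 <- array(100, c(1, 2, 10)); x3[1, 2, 3] <- 0
  expect_error(intensity_to_od(make_raw(x3)), "non-positive intensity")
})

test_that("MBLL solves the two-wavelength system exactly", {
  ext <- extinction_coefficients()
  d <- 3; dpf <- 6
  ## forward-construct OD from (1, -0.5) uM
  conc <- c(1, -0.5)
  od_vals <- as.numeric(ext %*% conc) * 1e-6 * d * dpf
  x <- array(0, c(1, 2, 20))
  x[1, 1, ] <- od_vals[1]; x[1, 2, ] <- od_vals[2]
  od <- structure(list(od = x, fs = 10,
                       probe = make_probe(sources = matrix(c(0, 0), 1),
                                          detectors = matrix(c(3, 0), 1)),
                       schedule = NULL, channel_ids = 1,
                       wavelengths = c(760, 850)),
                  class = "od_recording")
  hb <- od_to_hb(od, dpf = dpf)
  expect_equal(hb$hbo[1, 1], 1, tolerance = 1e-12)
  expect_equal(hb$hbr[1, 1], -0.5, tolerance = 1e-12)
  ## zero OD -> zero concentrations
  od$od[] <- 0
  hb0 <- od_to_hb(od)
  expect_equal(max(abs(hb0$hbo)), 0)
  expect_equal(max(abs(hb0$hbr)), 0)
  ## doubling the separation halves the recovered concentrations
  od$od[1, 1, ] <- od_vals[1]; od$od[1, 2, ] <- od_vals[2]
  od6 <- od
  od6$probe <- make_probe(sources = matrix(c(0, 0), 1),
                          detectors = matrix(c(6, 0), 1), long_sep = 6)
  hb6 <- od_to_hb(od6, dpf = dpf)
  expect_equal(hb6$hbo[1, 1], 0.5, tolerance = 1e-12)
  ## singular extinction matrix rejected
  expect_error(od_to_hb(od, extinction = matrix(1, 2, 2)), "singular")
})

test_that("bandpass is zero-phase with the specified response", {
  fs <- 8.9
  t <- seq(0, 400, 1 / fs)
  mk <- function(x) structure(list(hbo = matrix(x, 1), hbr = matrix(0 * x, 1),
                                   fs = fs), class = "hb_recording")
  rms <- function(x) sqrt(mean(x^2))
  ## cardiac-band attenuation: >= 20 dB at 1.1 Hz
  x1 <- sin(2 * pi * 1.1 * t)
  y1 <- bandpass(mk(x1))$hbo[1, ]
  expect_lt(rms(y1) / rms(x1), 0.10)
  ## mid-band preservation at 0.05 Hz, amplitude and phase
  x2 <- sin(2 * pi * 0.05 * t)
  y2 <- bandpass(mk(x2))$hbo[1, ]
  core <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_equal(rms(y2[core]) / rms(x2[core]), 1, tolerance = 0.1)
  expect_gt(stats::cor(x2[core], y2[core]), 0.999) # no phase shift
  ## linearity: zero in, zero out
  expect_equal(max(abs(bandpass(mk(0 * t))$hbo)), 0)
  ## invalid band edges
  expect_error(bandpass(mk(x1), low = 0.5, high = 0.005), "band edges")
  expect_error(bandpass(mk(x1), high = 10), "band edges")
})

test_that("full chain recovers injected amplitudes through block averaging", {
  p <- mini_probe()
  s <- make_stim_schedule(20, 2, 10, 20, seed = 12)
  gt <- make_ground_truth(p)
  rec <- simulate_session(p, s, gt, physio_off(), noise_off(), seed = 13)
  fc <- which.max(gt$nominal_attenuation)
  hb <- preprocess(rec)
  ba <- block_average(hb)
  ## reference: the true injected concentration trace, block-averaged the
  ## same way (the block design itself biases the peak via HRF overlap)
  task <- task_regressor(s, rec$fs, dim(rec$intensity)[3])
  mk_truth <- function(x) structure(
    list(hbo = matrix(x, 1), hbr = matrix(x, 1), fs = rec$fs,
         schedule = s, channel_ids = 1), class = "hb_recording")
  ref <- max(block_average(mk_truth(gt$amp_hbo * task))$hbo_mean)
  got <- max(ba$hbo_mean[match(fc, ba$channel_ids), ])
  expect_equal(got, ref, tolerance = 0.05)
  ## HbR side, same comparison
  ref_r <- min(block_average(mk_truth(gt$amp_hbr * task))$hbo_mean)
  got_r <- min(ba$hbr_mean[match(fc, ba$channel_ids), ])
  expect_equal(got_r, ref_r, tolerance = 0.05)
  ## stage order is logged
  expect_equal(names(hb$log),
               c("prune", "od", "spline", "wavelet", "mbll", "bandpass"))
})
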