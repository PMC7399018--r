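test_that("gamma kernel peaks at the requested latency with unit height", {
  tg <- seq(0, 30, by = 0.01)
  h <- gamma_hrf(tg)
  expect_equal(tg[which.max(h)], 6, tolerance = 0.011)
  expect_equal(max(h), 1)
  expect_equal(h[1], 0)
  expect_true(all(h >= 0))
  expect_gt(sum(h) * 0.01, 0)
  expect_lt(h[length(h)], 1e-3)            # decayed by 30 s
  h9 <- gamma_hrf(tg, peak_time = 9, fwhm = 4)
  expect_equal(tg[which.max(h9)], 9, tolerance = 0.011)
  expect_error(gamma_hrf(tg, peak_time = -1), "positive")
})

test_that("design matrix columns match the stated structure", {
  s <- make_stim_schedule(1, 2, 10, 10, seed = 1, lead_in = 10)
  fs <- 8.9; n <- 400
  short <- sin(2 * pi * 0.1 * (1:n) / fs)
  d <- build_design(s, fs, n, short_series = short, drift_order = 3)
  expect_equal(colnames(d$X),
               c("task", "short", "intercept", "drift1", "drift2", "drift3"))
  expect_equal(mean(d$X[, "short"]), 0, tolerance = 1e-12)
  expect_equal(qr(d$X)$rank, 6)
  ## direct convolution oracle for the single-block task column
  kern <- gamma_hrf(seq(0, 30, 1 / fs))
  box <- stim_boxcar(s, fs, n)
  conv <- numeric(n)
  for (i in seq_len(n)) {
    k <- seq_len(min(i, length(kern)))
    conv[i] <- sum(box[i - k + 1] * kern[k])
  }
  conv <- conv / max(conv) * max(d$X[, "task"])
  expect_equal(d$X[, "task"], conv, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## single HRF-shaped bump beginning at the onset
  expect_equal(max(abs(d$X[seq_len(10 * fs) - 1, "task"])), 0)
  ## drift_order 0 -> intercept + task + short only
  d0 <- build_design(s, fs, n, short_series = short, drift_order = 0)
  expect_equal(colnames(d0$X), c("task", "short", "intercept"))
  ## empty schedule flagged degenerate
  s0 <- make_stim_schedule(1, 2, 10, 10, seed = 1, lead_in = 200)
  dd <- build_design(s0, fs, n, drift_order = 0)
  expect_true(dd$degenerate)
})

test_that("AR-IRLS is exact on noiseless data and recovers AR(1) effects", {
  fs <- 8.9
  s <- make_stim_schedule(10, 2, 10, 15, seed = 2)
  n <- 1500
  des <- build_design(s, fs, n, drift_order = 1)
  b_true <- c(0.5, 0.2, 0.05)
  f0 <- ar_irls_fit(drop(des$X %*% b_true), des, fs = fs)
  expect_equal(f0$coefficients$beta, b_true, tolerance = 1e-8)
  expect_lt(max(abs(f0$residuals)), 1e-8)

  set.seed(5)
  hit <- 0; l1 <- numeric(0)
  for (r in 1:25) {
    y <- drop(des$X %*% c(0.5, 0, 0)) +
      0.3 * as.numeric(stats::arima.sim(list(ar = 0.8), n))
    f <- ar_irls_fit(y, des, fs = fs)
    cf <- f$coefficients[1, ]
    hit <- hit + (abs(cf$beta - 0.5) < 3 * cf$se)
    l1 <- c(l1, stats::acf(f$residuals, lag.max = 1, plot = FALSE)$acf[2])
    expect_gte(f$ar_order, 1)   # serial correlation detected
  }
  expect_gte(hit / 25, 0.9)
  expect_lt(mean(abs(l1)), 0.1) # whitening leaves white residuals
})

test_that("activation rule requires both chromophores with correct signs", {
  p <- make_probe(sources = matrix(c(0, 0), 1),
                  detectors = matrix(c(3, 0), 1))
  row <- function(chrom, beta, pval)
    data.frame(channel = 1, chromophore = chrom, beta = beta, se = 1,
               t = beta, p = pval, ar_order = 0, converged = TRUE)
  mk <- function(b_hbo, p_hbo, b_hbr, p_hbr)
    rbind(row("HbO", b_hbo, p_hbo), row("HbR", b_hbr, p_hbr))
  b <- classify_activation(mk(1, 0.01, -1, 0.01), p)
  expect_equal(as.integer(b), 1L)
  expect_equal(as.integer(classify_activation(mk(1, 0.01, 1, 0.01), p)), 0L)
  ## boundary: p exactly alpha is NOT significant
  expect_equal(as.integer(classify_activation(mk(1, 0.05, -1, 0.01), p)), 0L)
  expect_equal(as.integer(classify_activation(mk(-1, 0.01, -1, 0.01), p)), 0L)
  ## missing chromophore errors
  expect_error(classify_activation(row("HbO", 1, 0.01), p), "exactly one")
  ## channels absent from the table (pruned) default to 0
  p2 <- make_probe(sources = rbind(c(0, 0), c(0, 10)),
                   detectors = rbind(c(3, 0), c(3, 10)))
  b2 <- classify_activation(mk(1, 0.01, -1, 0.01), p2)
  expect_equal(as.integer(b2), c(1L, 0L))
})

test_that("block averaging is unbiased, baseline-corrected, and SE-scaled", {
  fs <- 8.9
  s <- make_stim_schedule(30, 2, 10, 20, seed = 6)
  n <- ceiling(schedule_duration(s) * fs)
  mk <- function(x) structure(list(hbo = matrix(x, 1), hbr = matrix(x, 1),
                                   fs = fs, schedule = s, channel_ids = 1),
                              class = "hb_recording")
  ## constant signal -> flat zero after baseline correction
  ba0 <- block_average(mk(rep(5, n)))
  expect_equal(max(abs(ba0$hbo_mean)), 0)
  ## noiseless HRF recovered
  task <- task_regressor(s, fs, n)
  ba1 <- block_average(mk(0.8 * task))
  expect_equal(max(ba1$hbo_mean), 0.8, tolerance = 0.08)
  ## SE scales like 1/sqrt(n_blocks)
  set.seed(7)
  noise_sd <- 0.5
  ba2 <- block_average(mk(stats::rnorm(n, 0, noise_sd)))
  mid <- round(ncol(ba2$hbo_se) / 2)
  ## epoch SD at a fixed time point is noise_sd * sqrt(1 + 1/pre) after
  ## baseline subtraction; just check the 1/sqrt(30) order of magnitude
  expect_equal(mean(ba2$hbo_se[, mid]), noise_sd * sqrt(1 + 1 / 18) / sqrt(30),
               tolerance = 0.35)
  expect_error(block_average(mk(rep(1, 10))), "no usable epochs")
})

test_that("short-channel regression improves fits under shared physiology", {
  p <- mini_probe()
  s <- make_stim_schedule(10, 2, 10, 15, seed = 8)
  gt <- make_ground_truth(p, amp_hbo = 0, amp_hbr = 0)   # null sessions
  strong <- physio_params(mayer_amp = 1, resp_amp = 0.5, drift_amp = 1.5,
                          gain_sd = 0.05)
  quiet <- noise_params(intensity_noise_sd = 0.002, background_sd = 0.05,
                        spike_rate = 0, shift_rate = 0)
  se_with <- c(); se_without <- c()
  for (k in 1:6) {
    rec <- simulate_session(p, s, gt, strong, quiet, seed = 140 + k)
    hb <- preprocess(rec)
    r1 <- fit_session_glm(hb, use_short = TRUE)
    r0 <- fit_session_glm(hb, use_short = FALSE)
    se_with <- c(se_with, r1$se[r1$chromophore == "HbO"])
    se_without <- c(se_without, r0$se[r0$chromophore == "HbO"])
  }
  ## paired comparison over channel-sessions: superficial regression
  ## yields systematically tighter task-coefficient estimates
  expect_lt(mean(se_with), 0.85 * mean(se_without))
  expect_gt(mean(se_with < se_without), 0.7)
})
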