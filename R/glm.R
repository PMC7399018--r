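#' Build a GLM design matrix for one channel
#'
#' Columns: the task regressor (stimulus boxcar convolved with the
#' unit-peak gamma HRF), the mean-centered nearest-short-channel series
#' (superficial nuisance regressor), and polynomial drift terms of order
#' 0..`drift_order` (order 0 is the intercept).
#'
#' @param schedule a `stim_schedule`.
#' @param fs sampling frequency (Hz).
#' @param n_samples number of rows.
#' @param short_series optional numeric vector (same length) with the
#'   short-channel measurement for the fitted chromophore.
#' @param drift_order polynomial drift order (0 = intercept only).
#' @param hrf_peak,hrf_fwhm gamma kernel parameters.
#' @return object of class `design_matrix`: list with `X` (matrix),
#'   `labels`, `degenerate` flag and the HRF parameters.
#' @export
build_design <- function(schedule, fs, n_samples, short_series = NULL,
                         drift_order = 3, hrf_peak = 6, hrf_fwhm = 5.2) {
  if (!is.null(short_series) && length(short_series) != n_samples) {
    stop("short-channel series length must equal n_samples")
  }
  task <- task_regressor(schedule, fs, n_samples, hrf_peak, hrf_fwhm)
  degenerate <- all(task == 0)
  tt <- seq_len(n_samples) / n_samples
  drift <- cbind(rep(1, n_samples),
                 if (drift_order >= 1) stats::poly(tt, drift_order))
  labels <- c("task",
              if (!is.null(short_series)) "short",
              "intercept",
              if (drift_order >= 1) paste0("drift", seq_len(drift_order)))
  X <- cbind(task,
             if (!is.null(short_series)) short_series - mean(short_series),
             drift)
  colnames(X) <- labels
  if (!degenerate && qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    dep <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(labels[dep], collapse = ", "))
  }
  structure(list(X = X, labels = labels, degenerate = degenerate,
                 hrf = c(peak = hrf_peak, fwhm = hrf_fwhm),
                 drift_order = drift_order),
            class = "design_matrix")
}

## Tukey bisquare weights
bisquare_w <- function(u, c = 4.685) {
  w <- (1 - (u / c)^2)^2
  w[abs(u) >= c] <- 0
  w
}

robust_wls <- function(X, y, tune = 4.685, max_iter = 30, tol = 1e-6) {
  beta <- qr.coef(qr(X), y)
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- stats::mad(r)
    if (s < 1e-12) {                       # (near-)exact fit
      return(list(beta = beta, r = r, w = rep(1, length(y)), s = 0))
    }
    w <- bisquare_w(r / s, tune)
    fit <- stats::lm.wfit(X, y, w)
    b_new <- fit$coefficients
    if (max(abs(b_new - beta)) < tol * max(1e-12, max(abs(beta)))) {
      beta <- b_new; break
    }
    beta <- b_new
  }
  r <- y - drop(X %*% beta)
  s <- stats::mad(r)
  list(beta = beta, r = r, w = bisquare_w(r / max(s, 1e-12), tune), s = s)
}

## robust standard errors with the standard psi-based correction
robust_se <- function(X, r, s, tune = 4.685) {
  n <- nrow(X); k <- ncol(X)
  if (s <= 0) return(rep(0, k))
  u <- r / s
  psi <- u * (1 - (u / tune)^2)^2
  psi[abs(u) >= tune] <- 0
  psip <- (1 - (u / tune)^2) * (1 - 5 * (u / tune)^2)
  psip[abs(u) >= tune] <- 0
  kappa <- 1 + k / n * stats::var(psip) / mean(psip)^2
  sigma2 <- s^2 * sum(psi^2) / (n - k) / mean(psip)^2 * kappa^2
  xtx_inv <- chol2inv(chol(crossprod(X)))
  sqrt(sigma2 * diag(xtx_inv))
}

ar_whiten <- function(x, a) {
  p <- length(a)
  if (p == 0) return(x)
  e <- as.numeric(stats::filter(x, c(1, -a), method = "convolution",
                                sides = 1))
  e[seq_len(p)] <- NA
  e
}

#' AR-prewhitened robust GLM fit for one chromophore series
#'
#' Iterates: (1) fit the regression; (2) estimate an autoregressive model
#' on the residuals, with the order chosen by AIC up to `p_max`; (3)
#' whiten the response and design with the AR filter; (4) re-fit with
#' iteratively reweighted least squares using Tukey bisquare weights.
#' The loop stops when the relative change in the coefficient vector
#' falls below `tol` or after `max_iter` outer iterations.  Standard
#' errors come from the robust whitened fit; p-values are two-sided t
#' with n - k degrees of freedom.  Prewhitening removes the serial
#' correlation of hemodynamic noise; the bisquare weights down-weight
#' residual motion transients.
#'
#' @param y numeric response (one chromophore of one channel).
#' @param design a `design_matrix` (or plain matrix).
#' @param fs sampling frequency; sets the default AR order cap
#'   `p_max = round(4 * fs)`.
#' @param p_max maximum AR order searched.
#' @param tune bisquare tuning constant.
#' @param max_iter maximum outer iterations.
#' @param tol relative coefficient-change convergence tolerance.
#' @return object of class `glm_fit`: coefficient table (`beta`, `se`,
#'   `t`, `p` per regressor), selected `ar_order`, `converged` flag,
#'   iteration count, whitened residuals and weight summary.
#' @export
ar_irls_fit <- function(y, design, fs = NULL, p_max = NULL,
                        tune = 4.685, max_iter = 10, tol = 1e-2) {
  X <- if (inherits(design, "design_matrix")) design$X else design
  labels <- colnames(X)
  n <- length(y); k <- ncol(X)
  if (is.null(p_max)) {
    p_max <- if (!is.null(fs)) round(4 * fs) else 20L
  }
  p_max <- min(p_max, floor(n / 4))
  if (n <= k + p_max) stop("series too short for the requested AR order")

  beta <- qr.coef(qr(X), y)
  ar_order <- 0L
  converged <- FALSE
  iter <- 0L
  res_w <- y - drop(X %*% beta)
  w <- rep(1, n)
  s <- stats::mad(res_w)
  Xw <- X; yw <- y
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    if (stats::sd(r) < 1e-12) {
      ## exact fit: nothing to whiten, keep OLS coefficients
      converged <- TRUE
      res_w <- r; s <- 0; w <- rep(1, n); Xw <- X; yw <- y
      break
    }
    a <- tryCatch({
      fit_ar <- stats::ar.burg(r, aic = TRUE, order.max = p_max,
                               demean = FALSE)
      fit_ar$ar
    }, error = function(e) numeric(0))
    ar_order <- length(a)
    yw_full <- ar_whiten(y, a)
    keep <- !is.na(yw_full)
    yw <- yw_full[keep]
    Xw <- apply(X, 2, ar_whiten, a = a)[keep, , drop = FALSE]
    rob <- robust_wls(Xw, yw, tune)
    b_new <- rob$beta
    delta <- max(abs(b_new - beta)) / max(abs(beta), 1e-12)
    beta <- b_new
    res_w <- rob$r; w <- rob$w; s <- rob$s
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- robust_se(Xw, res_w, s, tune)
  df <- nrow(Xw) - k
  tval <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(
    coefficients = data.frame(term = labels, beta = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), row.names = NULL),
    ar_order = ar_order, converged = converged, iterations = iter,
    df = df, residuals = res_w, weights = w, scale = s),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("AR-IRLS GLM fit (AR order", x$ar_order,
      if (x$converged) ", converged" else ", NOT converged", ")\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit the activation GLM for every long channel of a session
#'
#' For each surviving long channel, fits the AR-IRLS GLM separately to
#' the HbO and HbR series, using the nearest surviving short channel's
#' same-chromophore series as the superficial regressor.
#'
#' @param hb a preprocessed `hb_recording`.
#' @param use_short include the short-channel regressor (requires at
#'   least one surviving short channel).
#' @param drift_order,hrf_peak,hrf_fwhm design parameters.
#' @param ... passed to [ar_irls_fit()].
#' @return data frame with one row per (channel, chromophore): beta, se,
#'   t, p of the task regressor, AR order, convergence flag.
#' @export
fit_session_glm <- function(hb, use_short = TRUE, drift_order = 3,
                            hrf_peak = 6, hrf_fwhm = 5.2, ...) {
  ch <- hb$probe$channels
  kept <- hb$channel_ids
  long_ids <- kept[ch$type[match(kept, ch$channel)] == "long"]
  short_ids <- kept[ch$type[match(kept, ch$channel)] == "short"]
  if (use_short && length(short_ids) == 0) {
    stop("no short channels available; refit with use_short = FALSE")
  }
  n <- ncol(hb$hbo)
  out <- NULL
  for (j in long_ids) {
    row <- match(j, kept)
    short_row <- if (use_short) {
      match(nearest_short_channel(hb$probe, j, available = short_ids), kept)
    } else NA
    for (chrom in c("HbO", "HbR")) {
      y <- if (chrom == "HbO") hb$hbo[row, ] else hb$hbr[row, ]
      ss <- if (use_short) {
        if (chrom == "HbO") hb$hbo[short_row, ] else hb$hbr[short_row, ]
      } else NULL
      des <- build_design(hb$schedule, hb$fs, n, short_series = ss,
                          drift_order = drift_order,
                          hrf_peak = hrf_peak, hrf_fwhm = hrf_fwhm)
      fit <- ar_irls_fit(y, des, fs = hb$fs, ...)
      cf <- fit$coefficients[fit$coefficients$term == "task", ]
      out <- rbind(out, data.frame(
        channel = j, chromophore = chrom, beta = cf$beta, se = cf$se,
        t = cf$t, p = cf$p, ar_order = fit$ar_order,
        converged = fit$converged))
    }
  }
  out
}

#' Dual-chromophore activation classification
#'
#' A channel is activated when the task response is significant for both
#' chromophores (p < `alpha`) with a positive HbO and a negative HbR
#' coefficient.  Channels absent from the results table (e.g. pruned)
#' are classified 0.
#'
#' @param results data frame as returned by [fit_session_glm()].
#' @param probe the `probe_layout` defining the full ordered channel set.
#' @param alpha significance level (strict inequality).
#' @param session optional session identifier stored on the vector.
#' @return object of class `activation_vector`: named 0/1 integer vector
#'   over all long channels of the probe.
#' @export
classify_activation <- function(results, probe, alpha = 0.05,
                                session = NULL) {
  ch <- probe$channels
  long_ids <- ch$channel[ch$type == "long"]
  b <- stats::setNames(integer(length(long_ids)), long_ids)
  for (j in intersect(unique(results$channel), long_ids)) {
    r <- results[results$channel == j, ]
    hbo <- r[r$chromophore == "HbO", ]
    hbr <- r[r$chromophore == "HbR", ]
    if (nrow(hbo) != 1 || nrow(hbr) != 1) {
      stop("channel ", j, ": need exactly one HbO and one HbR result")
    }
    b[as.character(j)] <- as.integer(
      hbo$p < alpha && hbr$p < alpha && hbo$beta > 0 && hbr$beta < 0)
  }
  structure(b, class = "activation_vector", session = session,
            alpha = alpha)
}

#' Block-averaged hemodynamic response
#'
#' Epochs every channel around each stimulus onset, subtracts the
#' pre-onset baseline mean per epoch, and averages across blocks.
#'
#' @param hb an `hb_recording`.
#' @param schedule a `stim_schedule`; defaults to the recording's own.
#' @param window epoch window relative to onset (s), default [-2, 15].
#' @return object of class `block_average`: list with `time` and, per
#'   chromophore, `mean` and `se` matrices (channel x time).
#' @export
block_average <- function(hb, schedule = hb$schedule, window = c(-2, 15)) {
  fs <- hb$fs
  n <- ncol(hb$hbo)
  pre <- round(-window[1] * fs)
  post <- round(window[2] * fs)
  len <- pre + post + 1
  onsets <- round(schedule$onset * fs) + 1
  usable <- onsets[onsets - pre >= 1 & onsets + post <= n]
  if (length(usable) == 0) stop("no usable epochs inside the recording")
  avg_one <- function(x) {
    ep <- vapply(usable, function(o) {
      e <- x[(o - pre):(o + post)]
      e - mean(e[seq_len(pre)])
    }, numeric(len))
    list(mean = rowMeans(ep),
         se = apply(ep, 1, stats::sd) / sqrt(length(usable)))
  }
  n_ch <- nrow(hb$hbo)
  res <- list(time = seq(-pre, post) / fs, n_blocks = length(usable),
              channel_ids = hb$channel_ids)
  for (chrom in c("hbo", "hbr")) {
    m <- matrix(NA_real_, n_ch, len); s <- matrix(NA_real_, n_ch, len)
    for (j in seq_len(n_ch)) {
      a <- avg_one(hb[[chrom]][j, ])
      m[j, ] <- a$mean; s[j, ] <- a$se
    }
    res[[paste0(chrom, "_mean")]] <- m
    res[[paste0(chrom, "_se")]] <- s
  }
  structure(res, class = "block_average")
}
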