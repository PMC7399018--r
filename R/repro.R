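#' Size and overlap reproducibility of a session pair
#'
#' Given the binary activation vectors of two sessions of a subject,
#' computes the activated-channel counts \eqn{A_{s_i}}, \eqn{A_{s_j}},
#' their common count \eqn{A_{overlap}}, and the two indices
#' \deqn{R_q = 1 - \frac{|A_{s_i} - A_{s_j}|}{A_{s_i} + A_{s_j}}, \qquad
#'       R_o = \frac{2 A_{overlap}}{A_{s_i} + A_{s_j}},}
#' restricted to a region of interest.  When neither session has any
#' activated channel in the ROI both indices are defined as 0.
#'
#' @param b_i,b_j `activation_vector`s (or named 0/1 vectors) with
#'   identical channel ordering.
#' @param roi optional channel ids to restrict to; default all channels
#'   of the vectors.
#' @return list with `A_i`, `A_j`, `A_overlap`, `R_q`, `R_o`.
#' @export
pair_scores <- function(b_i, b_j, roi = NULL) {
  if (length(b_i) != length(b_j) ||
      !identical(names(b_i), names(b_j))) {
    stop("activation vectors must share an identical channel set/ordering")
  }
  if (!is.null(roi)) {
    keep <- names(b_i) %in% as.character(roi)
    if (sum(keep) < length(roi)) stop("ROI contains unknown channels")
    b_i <- b_i[keep]; b_j <- b_j[keep]
  }
  a_i <- sum(b_i == 1); a_j <- sum(b_j == 1)
  ov <- sum(b_i == 1 & b_j == 1)
  tot <- a_i + a_j
  list(A_i = a_i, A_j = a_j, A_overlap = ov,
       R_q = if (tot > 0) 1 - abs(a_i - a_j) / tot else 0,
       R_o = if (tot > 0) 2 * ov / tot else 0)
}

#' Subject-level reproducibility across sessions
#'
#' Mean and standard error of R_q and R_o over all session pairs of a
#' subject, the variability complement `v_q = 1 - mean(R_q)`, and the
#' relative heart-rate / mean-arterial-pressure changes across the
#' sessions (percent range over mean of the per-session values, each
#' session value being the mean of its pre/post readings).
#'
#' @param sessions list of >= 2 `activation_vector`s.
#' @param roi optional ROI channel ids.
#' @param physio optional data frame with per-session `hr_pre`,
#'   `hr_post`, `map_pre`, `map_post` (one row per session).
#' @return one-row data frame: mean/SE of R_q and R_o, v_q, n_pairs,
#'   delta_hr_pct, delta_map_pct.
#' @export
subject_repro <- function(sessions, roi = NULL, physio = NULL) {
  if (length(sessions) < 2) stop("need at least 2 sessions")
  pairs <- utils::combn(length(sessions), 2)
  rq <- numeric(ncol(pairs)); ro <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    sc <- pair_scores(sessions[[pairs[1, p]]], sessions[[pairs[2, p]]], roi)
    rq[p] <- sc$R_q; ro[p] <- sc$R_o
  }
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- data.frame(R_q = mean(rq), R_q_se = se(rq),
                    R_o = mean(ro), R_o_se = se(ro),
                    v_q = 1 - mean(rq), n_pairs = ncol(pairs))
  if (!is.null(physio)) {
    hr <- (physio$hr_pre + physio$hr_post) / 2
    map <- (physio$map_pre + physio$map_post) / 2
    out$delta_hr_pct <- 100 * (max(hr) - min(hr)) / mean(hr)
    out$delta_map_pct <- 100 * (max(map) - min(map)) / mean(map)
  }
  out
}

#' Channel activation frequency across sessions
#'
#' @param sessions list of `activation_vector`s (identical ordering).
#' @param roi optional ROI channel ids.
#' @return data frame: channel, count, frequency (count / n sessions).
#' @export
frequency_map <- function(sessions, roi = NULL) {
  if (length(sessions) < 1) stop("need at least 1 session")
  b <- sessions[[1]]
  for (s in sessions[-1]) {
    if (!identical(names(s), names(b))) stop("mismatched channel sets")
  }
  counts <- Reduce(`+`, lapply(sessions, as.integer))
  out <- data.frame(channel = as.integer(names(b)), count = counts,
                    frequency = counts / length(sessions))
  if (!is.null(roi)) out <- out[out$channel %in% roi, ]
  rownames(out) <- NULL
  out
}

#' Group medians of subject-level reproducibility
#'
#' Median across subjects of every numeric summary column, within each
#' combination of the grouping columns (e.g. condition and ROI).  For an
#' even number of subjects the median is the midpoint of the two central
#' order statistics.
#'
#' @param tab data frame with one row per subject (and grouping keys).
#' @param by character vector of grouping column names (may be empty).
#' @param columns numeric columns to summarize; default every numeric
#'   column not in `by`.
#' @return data frame of group medians.
#' @export
summarize_medians <- function(tab, by = character(),
                              columns = NULL) {
  if (is.null(columns)) {
    columns <- names(tab)[vapply(tab, is.numeric, logical(1))]
    columns <- setdiff(columns, c(by, "subject"))
  }
  if (length(by) == 0) {
    out <- as.data.frame(lapply(tab[columns], stats::median))
    return(out)
  }
  groups <- unique(tab[by])
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(tab))
    for (v in by) sel <- sel & tab[[v]] == groups[[v]][g]
    if (!any(sel)) { warning("empty group skipped"); next }
    med <- as.data.frame(lapply(tab[sel, columns, drop = FALSE],
                                stats::median))
    out <- rbind(out, cbind(groups[g, , drop = FALSE], med))
  }
  rownames(out) <- NULL
  out
}

#' Regression of fNIRS variability on systemic physiology
#'
#' Ordinary least squares of the variability complement
#' \eqn{v_q = 1 - \bar R_q} on the relative heart-rate and
#' mean-arterial-pressure changes:
#' \eqn{v_q = \alpha + \beta\,\Delta HR + \gamma\,\Delta MAP}.
#' Covariates enter as fractions (percent / 100) by default.
#'
#' @param tab data frame with columns `v_q`, `delta_hr_pct`,
#'   `delta_map_pct`.
#' @param covariates `"fraction"` (divide percents by 100) or
#'   `"percent"` (use the percent values as-is); the published estimates
#'   do not state the convention, so both are supported.
#' @return coefficient table: term, estimate, se, t, p.
#' @export
variability_regression <- function(tab, covariates = c("fraction", "percent")) {
  covariates <- match.arg(covariates)
  if (nrow(tab) < 4) stop("need more rows than parameters (>= 4)")
  sc <- if (covariates == "fraction") 100 else 1
  d <- data.frame(v_q = tab$v_q,
                  dhr = tab$delta_hr_pct / sc,
                  dmap = tab$delta_map_pct / sc)
  if (stats::sd(d$dhr) == 0 || stats::sd(d$dmap) == 0 ||
      abs(stats::cor(d$dhr, d$dmap)) > 1 - 1e-10) {
    stop("collinear covariates")
  }
  fit <- stats::lm(v_q ~ dhr + dmap, data = d)
  cf <- summary(fit)$coefficients
  data.frame(term = c("alpha", "beta_hr", "gamma_map"),
             estimate = cf[, 1], se = cf[, 2], t = cf[, 3], p = cf[, 4],
             row.names = NULL)
}

#' Inverse-variance weighted group-level coefficients
#'
#' Combines per-measurement GLM task coefficients per channel and
#' chromophore with weights \eqn{1/SE_i^2}:
#' \deqn{\beta_g = \frac{\sum \beta_i / SE_i^2}{\sum 1/SE_i^2}, \qquad
#'       SE_g = \Big(\sum 1/SE_i^2\Big)^{-1/2},}
#' and applies the same dual-chromophore rule to declare group-level
#' activation.
#'
#' @param tables list of per-session results from [fit_session_glm()]
#'   (rows: channel, chromophore, beta, se).
#' @param alpha significance level of the group activation rule.
#' @return list with `betas` (channel, chromophore, beta_g, se_g, t, p,
#'   n) and `activation` (channel, active).
#' @export
group_betas <- function(tables, alpha = 0.05) {
  all <- do.call(rbind, tables)
  if (any(all$se <= 0)) stop("zero or negative SE in input betas")
  keys <- unique(all[, c("channel", "chromophore")])
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    sel <- all$channel == keys$channel[i] &
      all$chromophore == keys$chromophore[i]
    b <- all$beta[sel]; se <- all$se[sel]
    w <- 1 / se^2
    bg <- sum(w * b) / sum(w)
    seg <- 1 / sqrt(sum(w))
    tg <- bg / seg
    out <- rbind(out, data.frame(
      channel = keys$channel[i], chromophore = keys$chromophore[i],
      beta_g = bg, se_g = seg, t = tg,
      p = 2 * stats::pnorm(-abs(tg)), n = sum(sel)))
  }
  act <- NULL
  for (j in unique(out$channel)) {
    hbo <- out[out$channel == j & out$chromophore == "HbO", ]
    hbr <- out[out$channel == j & out$chromophore == "HbR", ]
    ok <- nrow(hbo) == 1 && nrow(hbr) == 1 &&
      hbo$p < alpha && hbr$p < alpha && hbo$beta_g > 0 && hbr$beta_g < 0
    act <- rbind(act, data.frame(channel = j, active = as.integer(ok)))
  }
  list(betas = out, activation = act)
}
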