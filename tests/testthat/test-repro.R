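test_that("pair scores follow the size/overlap formulas", {
  b1 <- act_vec(c(1, 1, 1, 0, 0, 0))
  b2 <- act_vec(c(1, 0, 0, 0, 0, 0))
  sc <- pair_scores(b1, b2)
  expect_equal(sc$A_i, 3); expect_equal(sc$A_j, 1)
  expect_equal(sc$A_overlap, 1)
  expect_equal(sc$R_q, 0.5)    # 1 - |3-1|/4
  expect_equal(sc$R_o, 0.5)    # 2*1/4
  ## identical non-empty vectors
  sc2 <- pair_scores(b1, b1)
  expect_equal(sc2$R_q, 1); expect_equal(sc2$R_o, 1)
  ## degenerate all-zero pair is defined as 0/0 -> 0
  z <- act_vec(rep(0, 6))
  sc3 <- pair_scores(z, z)
  expect_equal(sc3$R_q, 0); expect_equal(sc3$R_o, 0)
  ## mismatched channel sets rejected
  expect_error(pair_scores(b1, act_vec(c(1, 0))), "identical channel")
})

test_that("indices match brute-force set recomputation on random pairs", {
  set.seed(10)
  for (r in 1:300) {
    b1 <- act_vec(stats::rbinom(64, 1, stats::runif(1, 0, 0.4)))
    b2 <- act_vec(stats::rbinom(64, 1, stats::runif(1, 0, 0.4)))
    sc <- pair_scores(b1, b2)
    bf <- brute_scores(b1, b2)
    expect_identical(sc$R_q, bf$R_q)
    expect_identical(sc$R_o, bf$R_o)
    ## bounds and reordering invariance
    expect_lte(sc$R_o, 1)
    if (sc$A_i + sc$A_j > 0) {
      expect_lte(sc$R_o, 2 * min(sc$A_i, sc$A_j) / (sc$A_i + sc$A_j))
    }
    perm <- sample(64)
    p1 <- act_vec(as.integer(b1)[perm]); p2 <- act_vec(as.integer(b2)[perm])
    pc <- pair_scores(p1, p2)
    expect_identical(pc$R_q, sc$R_q)
    expect_identical(pc$R_o, sc$R_o)
  }
})

test_that("adding a commonly activated channel never decreases overlap", {
  set.seed(11)
  for (r in 1:50) {
    b1 <- stats::rbinom(20, 1, 0.3); b2 <- stats::rbinom(20, 1, 0.3)
    off <- which(b1 == 0 & b2 == 0)
    if (length(off) == 0) next
    j <- off[1]
    a1 <- b1; a2 <- b2; a1[j] <- 1; a2[j] <- 1
    expect_gte(pair_scores(act_vec(a1), act_vec(a2))$R_o,
               pair_scores(act_vec(b1), act_vec(b2))$R_o)
  }
})

test_that("subject-level means equal the brute-force pair enumeration", {
  s1 <- act_vec(c(1, 1, 0, 0)); s2 <- act_vec(c(1, 0, 1, 0))
  s3 <- act_vec(c(0, 1, 1, 0))
  out <- subject_repro(list(s1, s2, s3))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  ses <- list(s1, s2, s3)
  rq <- vapply(pairs, function(p) pair_scores(ses[[p[1]]], ses[[p[2]]])$R_q,
               numeric(1))
  ro <- vapply(pairs, function(p) pair_scores(ses[[p[1]]], ses[[p[2]]])$R_o,
               numeric(1))
  expect_equal(out$R_q, mean(rq))
  expect_equal(out$R_o, mean(ro))
  expect_equal(out$v_q, 1 - mean(rq))
  expect_equal(out$n_pairs, 3)
  ## three identical sessions: perfect reproducibility, zero spread
  out2 <- subject_repro(list(s1, s1, s1))
  expect_equal(out2$R_q, 1); expect_equal(out2$R_o, 1)
  expect_equal(out2$R_q_se, 0)
  ## two sessions: single pair
  out3 <- subject_repro(list(s1, s2))
  expect_equal(out3$R_q, pair_scores(s1, s2)$R_q)
  expect_error(subject_repro(list(s1)), "at least 2")
})

test_that("frequency maps count activations and respect the union bound", {
  s1 <- act_vec(c(1, 0, 1, 0)); s2 <- act_vec(c(1, 1, 0, 0))
  s3 <- act_vec(c(0, 1, 1, 0))
  fm <- frequency_map(list(s1, s2, s3))
  expect_equal(fm$count, c(2, 2, 2, 0))
  expect_equal(fm$frequency, c(2, 2, 2, 0) / 3)
  un <- as.integer(s1) | as.integer(s2) | as.integer(s3)
  expect_equal(fm$count > 0, as.logical(un))
  z <- act_vec(rep(0, 4))
  expect_equal(frequency_map(list(z, z))$count, rep(0, 4))
})

test_that("group medians use the midpoint rule and honor grouping", {
  tab <- benchmark_table("sessions")
  med <- summarize_medians(tab, by = "condition")
  same <- med[med$condition == "same_day", ]
  expect_equal(same$R_q, 0.73)
  expect_equal(same$R_o, 0.36)
  ## single subject: median is that subject
  one <- summarize_medians(tab[1, ], by = "condition")
  expect_equal(one$R_q, 0)
  ## even group size: midpoint of central order statistics
  ev <- summarize_medians(data.frame(g = "a", x = c(1, 2, 3, 10)), by = "g")
  expect_equal(ev$x, 2.5)
})

test_that("variability regression recovers exact linear structure", {
  ## constant response: intercept only
  tab <- data.frame(v_q = rep(0.3, 6),
                    delta_hr_pct = c(5, 8, 12, 3, 9, 15),
                    delta_map_pct = c(4, 7, 2, 9, 12, 6))
  cf <- suppressWarnings(variability_regression(tab)) # perfect-fit warning
  expect_equal(cf$estimate, c(0.3, 0, 0), tolerance = 1e-10)
  ## exact recovery of a known slope (fractional covariates)
  tab2 <- tab
  tab2$v_q <- 0.2 + 1.0 * tab2$delta_hr_pct / 100
  cf2 <- suppressWarnings(variability_regression(tab2))
  expect_equal(cf2$estimate[cf2$term == "beta_hr"], 1, tolerance = 1e-10)
  expect_equal(cf2$estimate[cf2$term == "alpha"], 0.2, tolerance = 1e-10)
  ## percent convention scales the slope by 1/100
  cf3 <- suppressWarnings(variability_regression(tab2, covariates = "percent"))
  expect_equal(cf3$estimate[cf3$term == "beta_hr"], 0.01, tolerance = 1e-10)
  ## collinear covariates rejected
  bad <- tab; bad$delta_map_pct <- 2 * bad$delta_hr_pct
  expect_error(variability_regression(bad), "collinear")
  expect_error(variability_regression(tab[1:3, ]), ">= 4")
})

test_that("group betas are inverse-variance weighted with the dual rule", {
  mk <- function(beta, se, chrom = "HbO")
    data.frame(channel = 1, chromophore = chrom, beta = beta, se = se)
  ## hand-computed weighted mean: (1/0.01)/(1/0.01 + 1/1) = 100/101
  g <- group_betas(list(rbind(mk(1, 0.1), mk(-1, 0.1, "HbR")),
                        rbind(mk(0, 1), mk(0, 1, "HbR"))))
  hbo <- g$betas[g$betas$chromophore == "HbO", ]
  expect_equal(hbo$beta_g, 100 / 101, tolerance = 1e-12)
  expect_equal(hbo$se_g, 1 / sqrt(101), tolerance = 1e-12)
  ## equal SEs reduce to the plain mean
  g2 <- group_betas(list(rbind(mk(1, 0.5), mk(-1, 0.5, "HbR")),
                         rbind(mk(3, 0.5), mk(-3, 0.5, "HbR"))))
  expect_equal(g2$betas$beta_g[g2$betas$chromophore == "HbO"], 2)
  ## single measurement passes through
  g3 <- group_betas(list(rbind(mk(1.7, 0.2), mk(-0.5, 0.2, "HbR"))))
  expect_equal(g3$betas$beta_g[g3$betas$chromophore == "HbO"], 1.7)
  ## significant positive HbO + negative HbR -> active
  expect_equal(g3$activation$active, 1L)
  expect_error(group_betas(list(mk(1, 0))), "SE")
})
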