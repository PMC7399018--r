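## Shared fixtures, built in code at test time.

## Small bilateral probe (12 long + 2 short channels) used wherever the
## full 68-channel layout would make a test needlessly slow.
mini_probe <- function() {
  mk <- function(cx) {
    list(s = rbind(c(cx, 0), c(cx + 5, 0)),
         d = rbind(c(cx + 2.5, 1.658), c(cx + 2.5, -1.658),
                   c(cx - 3, 0), c(cx + 8, 0), c(cx, 0.8)))
  }
  L <- mk(-9); R <- mk(4)
  make_probe(sources = rbind(L$s, R$s), detectors = rbind(L$d, R$d))
}

## Quiet parameter sets: everything off, for deterministic forward checks.
physio_off <- function() {
  physio_params(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                drift_amp = 0, gain_sd = 0)
}
noise_off <- function() {
  noise_params(intensity_noise_sd = 0, background_sd = 0,
               spike_rate = 0, shift_rate = 0)
}

## A named binary activation vector over n channels.
act_vec <- function(x) {
  structure(as.integer(x), names = as.character(seq_along(x)),
            class = "activation_vector")
}

## Brute-force set-based recomputation of the reproducibility indices,
## independent of pair_scores(): builds the activated-channel *sets* and
## works from set cardinalities.
brute_scores <- function(b_i, b_j) {
  set_i <- which(b_i == 1)
  set_j <- which(b_j == 1)
  a_i <- length(set_i); a_j <- length(set_j)
  ov <- length(intersect(set_i, set_j))
  if (a_i + a_j == 0) return(list(R_q = 0, R_o = 0))
  list(R_q = 1 - abs(a_i - a_j) / (a_i + a_j),
       R_o = 2 * ov / (a_i + a_j))
}

## Random rigid transform for registration tests.
random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0.1, 2.5)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = stats::rnorm(3, 0, 20))
}

eight_landmarks <- function() {
  landmark_set(rbind(
    c(0, -95, 10), c(55, 70, -15), c(0, 95, -5), c(-75, 0, -20),
    c(75, 0, -20), c(0, 90, 25), c(-12, 88, -35), c(12, 88, -35)))
}
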