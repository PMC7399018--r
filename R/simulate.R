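#' Ground-truth activation model for the simulator
#'
#' Defines where and how strongly the simulated cortex responds: a focal
#' activation at `focus` (scalp-plane cm) whose effect on each long
#' channel is attenuated by a Gaussian kernel of the distance between the
#' channel midpoint and the focus.  A channel counts as truly activated
#' when its attenuation at the nominal (undisplaced) probe position is at
#' least `active_threshold`.
#'
#' @param probe a `probe_layout`.
#' @param focus activation focus (cm); `NULL` places it on the midpoint
#'   of the first left-hemisphere long channel, i.e. directly under the
#'   probe as a focal cortical response would be.
#' @param amp_hbo,amp_hbr evoked peak amplitudes (uM); HbO positive, HbR
#'   negative.
#' @param kernel_sd spatial scale of the sensitivity kernel (cm).
#' @param active_threshold attenuation above which a channel is labelled
#'   truly active.
#' @return object of class `ground_truth`.
#' @export
make_ground_truth <- function(probe, focus = NULL, amp_hbo = 0.8,
                              amp_hbr = -0.3, kernel_sd = 1,
                              active_threshold = 0.5) {
  if (amp_hbo < 0 || amp_hbr > 0) {
    stop("evoked HbO amplitude must be >= 0 and HbR amplitude <= 0")
  }
  ch <- probe$channels
  if (is.null(focus)) {
    left_long <- ch[ch$type == "long" & ch$hemisphere == "left", ]
    if (nrow(left_long) == 0) left_long <- ch[ch$type == "long", ]
    focus <- c(left_long$x[1], left_long$y[1])
  }
  d0 <- sqrt((ch$x - focus[1])^2 + (ch$y - focus[2])^2)
  att0 <- exp(-d0^2 / (2 * kernel_sd^2))
  att0[ch$type != "long"] <- 0
  structure(list(focus = focus, amp_hbo = amp_hbo, amp_hbr = amp_hbr,
                 kernel_sd = kernel_sd,
                 active = att0 >= active_threshold & amp_hbo > 0,
                 nominal_attenuation = att0,
                 active_threshold = active_threshold),
            class = "ground_truth")
}

#' Default systemic-physiology parameters for the simulator
#'
#' Superficial/systemic hemodynamics shared by all channels (including
#' short channels): cardiac pulsation, respiration, Mayer waves and a
#' slow drift, with small channel-to-channel gain variation.  Amplitudes
#' are HbO concentrations in uM; the HbR component is `hbr_ratio` times
#' the HbO component (anticorrelated by default).
#' @param cardiac_freq,cardiac_amp cardiac frequency (Hz) and amplitude (uM).
#' @param resp_freq,resp_amp respiration frequency and amplitude.
#' @param mayer_freq,mayer_amp Mayer-wave frequency and amplitude.
#' @param drift_amp amplitude of a very-low-frequency drift (uM).
#' @param hbr_ratio HbR/HbO scaling of the superficial component.
#' @param gain_sd channel gain standard deviation around 1.
#' @param short_gain relative strength of the superficial component in
#'   short channels (scalp is their only source of signal).
#' @return list of parameters.
#' @export
physio_params <- function(cardiac_freq = 1.1, cardiac_amp = 0.15,
                          resp_freq = 0.25, resp_amp = 0.1,
                          mayer_freq = 0.1, mayer_amp = 0.2,
                          drift_amp = 0.3, hbr_ratio = -0.3,
                          gain_sd = 0.1, short_gain = 1.5) {
  as.list(environment())
}

#' Default noise and artifact parameters for the simulator
#'
#' @param intensity_noise_sd multiplicative white measurement noise
#'   (fraction of the baseline intensity).
#' @param background_sd,background_ar sd (uM) and lag-1 coefficient of
#'   AR(1) background hemodynamic noise per channel (HbO; HbR scaled by
#'   0.4).
#' @param spike_rate motion spikes per minute; 0 disables them.
#' @param spike_amp spike amplitude in multiples of the channel OD sd.
#' @param spike_dur_range spike duration range (s).
#' @param shift_rate baseline shifts per minute (persist to the end).
#' @param shift_amp shift amplitude in multiples of the channel OD sd.
#' @return list of parameters.
#' @export
noise_params <- function(intensity_noise_sd = 0.005,
                         background_sd = 0.15, background_ar = 0.9,
                         spike_rate = 0.5, spike_amp = 10,
                         spike_dur_range = c(0.2, 0.5),
                         shift_rate = 0.1, shift_amp = 8) {
  as.list(environment())
}

shared_physio <- function(t, p, rng_phase) {
  if (p$cardiac_amp == 0 && p$resp_amp == 0 && p$mayer_amp == 0 &&
      p$drift_amp == 0) {
    return(numeric(length(t)))
  }
  ph <- rng_phase
  p$cardiac_amp * sin(2 * pi * p$cardiac_freq * t + ph[1]) +
    p$resp_amp * sin(2 * pi * p$resp_freq * t + ph[2]) +
    p$mayer_amp * sin(2 * pi * p$mayer_freq * t + ph[3]) +
    p$drift_amp * sin(2 * pi * 0.004 * t + ph[4])
}

ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

#' Simulate one fNIRS recording session
#'
#' Forward model: per-channel HbO/HbR time series (evoked response in
#' long channels, attenuated by the Gaussian sensitivity kernel of the
#' displaced channel-to-focus distance; shared superficial physiology in
#' all channels; AR(1) background noise) are mapped to optical density at
#' the two wavelengths through the same decadic extinction matrix the
#' analysis inverts, optionally corrupted by motion spikes and baseline
#' shifts, and converted to light intensity
#' \eqn{I(t) = I_0 \cdot 10^{-\Delta OD(t)}} with multiplicative
#' measurement noise.
#'
#' @param probe a `probe_layout`.
#' @param schedule a `stim_schedule`.
#' @param truth a `ground_truth` (see [make_ground_truth()]).
#' @param physio list from [physio_params()].
#' @param noise list from [noise_params()].
#' @param displacement 2-vector (cm): rigid scalp-plane displacement of
#'   the probe relative to the head (and therefore to the focus) for this
#'   session.
#' @param fs sampling frequency (Hz).
#' @param dpf differential pathlength factor used by the forward model.
#' @param baseline_intensity baseline detector intensity I0 (a.u.).
#' @param meta named list of session metadata (subject, session,
#'   condition, time_of_day, hr, map, ...).
#' @param seed optional integer seed.
#' @return object of class `raw_recording`: intensity array
#'   (channel x wavelength x time), fs, probe, schedule, metadata, and
#'   the applied ground truth (with the session's attenuations) in
#'   `$truth`.
#' @export
simulate_session <- function(probe, schedule, truth,
                             physio = physio_params(),
                             noise = noise_params(),
                             displacement = c(0, 0), fs = 8.9,
                             dpf = 6, baseline_intensity = 1000,
                             meta = list(), seed = NULL) {
  if (any(!is.finite(displacement))) stop("displacement must be finite")
  if (baseline_intensity <= 0) stop("baseline intensity must be positive")
  if (!is.null(seed)) set.seed(seed)

  ch <- probe$channels
  n_ch <- nrow(ch)
  n <- ceiling(schedule_duration(schedule) * fs)
  t <- (seq_len(n) - 1) / fs

  ## evoked response, attenuated by displaced channel-to-focus distance
  task <- task_regressor(schedule, fs, n)
  d <- sqrt((ch$x + displacement[1] - truth$focus[1])^2 +
            (ch$y + displacement[2] - truth$focus[2])^2)
  att <- exp(-d^2 / (2 * truth$kernel_sd^2))
  att[ch$type != "long"] <- 0

  phase <- stats::runif(4, 0, 2 * pi)
  sup <- shared_physio(t, physio, phase)
  gain <- 1 + stats::rnorm(n_ch, 0, physio$gain_sd)
  gain[ch$type == "short"] <- physio$short_gain *
    (1 + stats::rnorm(sum(ch$type == "short"), 0, physio$gain_sd))

  ext <- extinction_coefficients(probe$wavelengths) # per-wavelength rows
  intensity <- array(NA_real_, c(n_ch, length(probe$wavelengths), n))
  for (j in seq_len(n_ch)) {
    hbo <- truth$amp_hbo * att[j] * task + gain[j] * sup +
      ar1_noise(n, noise$background_sd, noise$background_ar)
    hbr <- truth$amp_hbr * att[j] * task + physio$hbr_ratio * gain[j] * sup +
      ar1_noise(n, 0.4 * noise$background_sd, noise$background_ar)
    for (w in seq_along(probe$wavelengths)) {
      od <- (ext[w, "HbO"] * hbo + ext[w, "HbR"] * hbr) * 1e-6 *
        ch$separation[j] * dpf
      od <- add_motion_artifacts(od, fs, noise)
      i0 <- baseline_intensity
      eps <- if (noise$intensity_noise_sd > 0) {
        stats::rnorm(n, 0, noise$intensity_noise_sd)
      } else 0
      intensity[j, w, ] <- i0 * 10^(-od) * (1 + eps)
    }
  }
  if (any(intensity <= 0)) {
    stop("forward model produced non-positive intensities; reduce noise")
  }
  truth$applied_attenuation <- att
  truth$displacement <- displacement
  structure(list(intensity = intensity, fs = fs, probe = probe,
                 schedule = schedule, channel_ids = ch$channel,
                 wavelengths = probe$wavelengths, meta = meta,
                 truth = truth),
            class = "raw_recording")
}

add_motion_artifacts <- function(od, fs, noise) {
  n <- length(od)
  dur_min <- n / fs / 60
  base_sd <- max(stats::sd(od), 1e-4)
  n_spike <- if (noise$spike_rate > 0) stats::rpois(1, noise$spike_rate * dur_min) else 0L
  if (n_spike > 0) {
    for (k in seq_len(n_spike)) {
      at <- sample.int(n, 1)
      dur <- stats::runif(1, noise$spike_dur_range[1], noise$spike_dur_range[2])
      w <- max(2L, round(dur * fs))
      idx <- at:min(n, at + w - 1)
      shape <- exp(-((seq_along(idx) - length(idx) / 2)^2) / (2 * (w / 4)^2))
      od[idx] <- od[idx] + sample(c(-1, 1), 1) * noise$spike_amp * base_sd * shape
    }
  }
  n_shift <- if (noise$shift_rate > 0) stats::rpois(1, noise$shift_rate * dur_min) else 0L
  if (n_shift > 0) {
    for (k in seq_len(n_shift)) {
      at <- sample.int(n, 1)
      od[at:n] <- od[at:n] + sample(c(-1, 1), 1) * noise$shift_amp * base_sd
    }
  }
  od
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("fNIRS recording:", dim(x$intensity)[1], "channels x",
      dim(x$intensity)[2], "wavelengths x", dim(x$intensity)[3],
      "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Simulate a complete test-retest study
#'
#' Generates one recording per (subject, session) under a probe-placement
#' condition.  Each session displaces the whole probe by a random
#' scalp-plane vector with per-coordinate standard deviation
#' `displacement_scale`; the guided (neuronavigated) condition uses a
#' small scale, the standard (head-metric) condition a large one.
#' Per-session heart-rate and mean-arterial-pressure readings are drawn
#' with a larger spread across times of day (`"same_day"` design) than
#' across days at a fixed time (`"across_days"`), mimicking the circadian
#' component of systemic physiology.
#'
#' @param n_subjects,n_sessions study size.
#' @param condition `"guided"` or `"standard"`.
#' @param design `"across_days"` (same hour, different days) or
#'   `"same_day"` (morning/afternoon/evening of one day).
#' @param displacement_scale per-coordinate sd (cm) of the session probe
#'   displacement; defaults to 0.3 for guided (optode within the 6 mm
#'   guidance sphere most of the time) and 1.5 for standard.
#' @param probe,truth,physio,noise,fs forwarded to [simulate_session()];
#'   defaults are the package's emulated acquisition.
#' @param schedule_args list of arguments for [make_stim_schedule()].
#' @param seed integer seed for the whole study.
#' @return list of class `study`: `recordings` (list of
#'   `raw_recording`), `physio_table` (per-session HR/MAP readings) and
#'   the design descriptors.
#' @export
simulate_study <- function(n_subjects = 5, n_sessions = 3,
                           condition = c("guided", "standard"),
                           design = c("across_days", "same_day"),
                           displacement_scale = NULL,
                           probe = make_probe(),
                           truth = make_ground_truth(probe),
                           physio = physio_params(),
                           noise = noise_params(),
                           schedule_args = list(), fs = 8.9, seed = 1) {
  condition <- match.arg(condition)
  design <- match.arg(design)
  if (is.null(displacement_scale)) {
    displacement_scale <- if (condition == "guided") 0.3 else 1.5
  }
  if (displacement_scale < 0) stop("displacement scale must be >= 0")
  set.seed(seed)
  tod_levels <- c("morning", "afternoon", "evening")
  recs <- list()
  phys <- NULL
  for (s in seq_len(n_subjects)) {
    hr_base <- stats::rnorm(1, 65, 5)
    map_base <- stats::rnorm(1, 85, 6)
    ## circadian (time-of-day) spread is twice the day-to-day spread
    tod_hr <- stats::rnorm(3, 0, 4); tod_map <- stats::rnorm(3, 0, 5)
    day_hr <- stats::rnorm(n_sessions, 0, 2)
    day_map <- stats::rnorm(n_sessions, 0, 2.5)
    for (k in seq_len(n_sessions)) {
      tod <- if (design == "same_day") tod_levels[((k - 1) %% 3) + 1] else "morning"
      hr_k <- hr_base + if (design == "same_day") tod_hr[((k - 1) %% 3) + 1] else day_hr[k]
      map_k <- map_base + if (design == "same_day") tod_map[((k - 1) %% 3) + 1] else day_map[k]
      hr_pre <- hr_k + stats::rnorm(1, 0, 1); hr_post <- hr_k + stats::rnorm(1, 0, 1)
      map_pre <- map_k + stats::rnorm(1, 0, 1.5); map_post <- map_k + stats::rnorm(1, 0, 1.5)
      sched <- do.call(make_stim_schedule,
                       c(schedule_args, list(seed = sample.int(2^30, 1))))
      disp <- stats::rnorm(2, 0, displacement_scale)
      rec <- simulate_session(
        probe, sched, truth, physio, noise, displacement = disp, fs = fs,
        meta = list(subject = s, session = k, condition = condition,
                    time_of_day = tod,
                    hr_pre = hr_pre, hr_post = hr_post,
                    map_pre = map_pre, map_post = map_post),
        seed = sample.int(2^30, 1))
      recs[[length(recs) + 1]] <- rec
      phys <- rbind(phys, data.frame(
        subject = s, session = k, condition = condition,
        time_of_day = tod, hr_pre = hr_pre, hr_post = hr_post,
        map_pre = map_pre, map_post = map_post))
    }
  }
  structure(list(recordings = recs, physio_table = phys,
                 condition = condition, design = design,
                 displacement_scale = displacement_scale, seed = seed),
            class = "study")
}
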