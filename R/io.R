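#' Published per-subject reproducibility benchmarks
#'
#' Per-subject R_q/R_o values (with heart-rate and mean-arterial-pressure
#' changes) from a published 10-subject finger-tapping test-retest study,
#' shipped as plain-text tables.  `"sessions"` holds the standard-probe
#' same-day vs across-days comparison; `"conditions"` the standard vs
#' neuronavigation-guided comparison over three regions of interest.
#' Used as worked examples for [summarize_medians()] and
#' [variability_regression()].
#'
#' @param which which table to load.
#' @return data frame.
#' @export
benchmark_table <- function(which = c("sessions", "conditions")) {
  which <- match.arg(which)
  file <- switch(which,
                 sessions = "benchmark_standard_sessions.tsv",
                 conditions = "benchmark_condition_comparison.tsv")
  utils::read.delim(system.file("extdata", file, package = "nirsrep",
                                mustWork = TRUE))
}

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write a raw recording to a plain-text container
#'
#' Serializes a `raw_recording` as a directory holding a JSON header
#' (sampling rate, wavelengths, metadata, stimulus schedule, probe
#' geometry) and one TSV intensity matrix per wavelength (channels in
#' columns, samples in rows).  The container round-trips exactly through
#' [read_recording()].
#'
#' @param rec a `raw_recording`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    fs = rec$fs, wavelengths = rec$wavelengths,
    channel_ids = rec$channel_ids, meta = rec$meta,
    schedule = list(onset = rec$schedule$onset,
                    duration = rec$schedule$duration,
                    n_blocks = rec$schedule$n_blocks,
                    rest_range = rec$schedule$rest_range),
    probe = list(sources = rec$probe$sources,
                 detectors = rec$probe$detectors,
                 long_sep = rec$probe$long_sep,
                 short_sep = rec$probe$short_sep,
                 wavelengths = rec$probe$wavelengths))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (w in seq_along(rec$wavelengths)) {
    m <- t(rec$intensity[, w, , drop = TRUE])
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    utils::write.table(
      format(m, digits = 17, scientific = TRUE, trim = TRUE),
      file.path(path, sprintf("intensity_%s.tsv", rec$wavelengths[w])),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a raw recording from its plain-text container
#'
#' Inverse of [write_recording()].  A container without a stimulus
#' schedule loads with an empty schedule and a warning.
#'
#' @param path container directory.
#' @return a `raw_recording`.
#' @export
read_recording <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("not a recording container (missing header.json): ", path)
  h <- jsonlite::read_json(hf, simplifyVector = TRUE)
  for (req in c("fs", "wavelengths", "probe")) {
    if (is.null(h[[req]])) stop("header.json missing required field: ", req)
  }
  probe <- make_probe(sources = matrix(unlist(h$probe$sources), ncol = 2),
                      detectors = matrix(unlist(h$probe$detectors), ncol = 2),
                      long_sep = h$probe$long_sep,
                      short_sep = h$probe$short_sep,
                      wavelengths = h$probe$wavelengths)
  if (is.null(h$schedule) || is.null(h$schedule$onset)) {
    warning("container has no stimulus schedule; loading an empty one")
    schedule <- structure(list(onset = numeric(0), duration = numeric(0),
                               n_blocks = 0L, rest_range = c(NA, NA)),
                          class = "stim_schedule")
  } else {
    schedule <- structure(list(onset = h$schedule$onset,
                               duration = h$schedule$duration,
                               n_blocks = h$schedule$n_blocks,
                               rest_range = h$schedule$rest_range),
                          class = "stim_schedule")
  }
  mats <- lapply(h$wavelengths, function(w) {
    as.matrix(utils::read.table(
      file.path(path, sprintf("intensity_%s.tsv", w)), sep = "\t"))
  })
  n_ch <- ncol(mats[[1]]); n <- nrow(mats[[1]])
  intensity <- array(NA_real_, c(n_ch, length(h$wavelengths), n))
  for (w in seq_along(mats)) intensity[, w, ] <- t(mats[[w]])
  structure(list(intensity = intensity, fs = h$fs, probe = probe,
                 schedule = schedule,
                 channel_ids = if (!is.null(h$channel_ids)) h$channel_ids
                               else seq_len(n_ch),
                 wavelengths = h$wavelengths,
                 meta = h$meta, truth = NULL),
            class = "raw_recording")
}

#' Write an activation vector as TSV
#' @param b an `activation_vector`.
#' @param file output path.
#' @export
write_activation <- function(b, file) {
  utils::write.table(
    data.frame(channel = names(b), active = as.integer(b)),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an activation vector from TSV
#' @param file path written by [write_activation()].
#' @return an `activation_vector`.
#' @export
read_activation <- function(file) {
  d <- utils::read.delim(file)
  structure(stats::setNames(as.integer(d$active), d$channel),
            class = "activation_vector")
}

## deterministic short hash of the parameter set, for output provenance
param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2^28
  sprintf("%07x", h)
}
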