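#' Run the full test-retest analysis on a set of recordings
#'
#' Drives every stage for each session of each subject: preprocessing
#' (pruning, OD, motion correction, Beer-Lambert, bandpass), per-channel
#' AR-IRLS GLM with short-channel regression, dual-chromophore
#' activation classification, and the subject-level reproducibility
#' summaries (R_q, R_o, frequency maps, v_q with HR/MAP covariates).
#'
#' @param recordings either a `study` object from [simulate_study()], a
#'   list of `raw_recording`s, or a manifest data frame with a `path`
#'   column of recording containers plus `subject`/`session` columns.
#' @param roi ROI passed to [roi_channels()] (plus `center`/`radius` for
#'   the focal ROI).
#' @param center,radius focal ROI definition.
#' @param preprocess_args,glm_args parameter lists forwarded to
#'   [preprocess()] and [fit_session_glm()].
#' @param alpha significance level of the activation rule.
#' @param verbose print per-stage progress.
#' @return list of class `retest_result`: per-session GLM tables and
#'   activation vectors, per-subject reproducibility table, frequency
#'   maps, group medians, group betas, and a run log carrying stage
#'   parameters and the parameter-set hash.
#' @export
run_pipeline <- function(recordings, roi = "whole", center = NULL,
                         radius = 4, preprocess_args = list(),
                         glm_args = list(), alpha = 0.05,
                         verbose = FALSE) {
  physio_table <- NULL
  if (inherits(recordings, "study")) {
    physio_table <- recordings$physio_table
    recordings <- recordings$recordings
  }
  if (is.data.frame(recordings)) {
    paths <- recordings$path
    meta <- recordings
    recordings <- lapply(seq_along(paths), function(i) {
      r <- read_recording(paths[i])
      r$meta$subject <- meta$subject[i]
      r$meta$session <- meta$session[i]
      r
    })
  }
  if (length(recordings) == 0) stop("no recordings supplied")

  params <- list(roi = roi, center = center, radius = radius,
                 preprocess = preprocess_args, glm = glm_args,
                 alpha = alpha)
  hash <- param_hash(params)
  probe <- recordings[[1]]$probe
  roi_ids <- roi_channels(probe, roi, center = center, radius = radius)

  glm_tables <- list()
  activations <- list()
  log <- list(params = params, hash = hash, stages = list())
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    sid <- rec$meta$subject %||% 1
    ses <- rec$meta$session %||% i
    key <- paste0("s", sid, "_r", ses)
    if (verbose) message("session ", key, ": preprocessing")
    hb <- tryCatch(
      do.call(preprocess, c(list(rec), preprocess_args)),
      error = function(e) stop("preprocess failed for session ", key,
                               ": ", conditionMessage(e)))
    if (verbose) message("session ", key, ": GLM")
    res <- tryCatch(
      do.call(fit_session_glm, c(list(hb), glm_args)),
      error = function(e) stop("glm failed for session ", key, ": ",
                               conditionMessage(e)))
    res$subject <- sid; res$session <- ses
    glm_tables[[key]] <- res
    activations[[key]] <- classify_activation(res, probe, alpha,
                                              session = key)
    log$stages[[key]] <- list(pruned = hb$pruned$channel,
                              preprocess = hb$log)
  }

  subjects <- unique(vapply(recordings,
                            function(r) r$meta$subject %||% 1, numeric(1)))
  subj_tab <- NULL
  freq <- list()
  for (s in subjects) {
    idx <- which(vapply(recordings, function(r)
      (r$meta$subject %||% 1) == s, logical(1)))
    if (length(idx) < 2) next
    acts <- activations[idx]
    phys <- NULL
    if (!is.null(physio_table)) {
      phys <- physio_table[physio_table$subject == s, ]
    } else {
      m <- lapply(recordings[idx], `[[`, "meta")
      if (all(vapply(m, function(x) !is.null(x$hr_pre), logical(1)))) {
        phys <- do.call(rbind, lapply(m, function(x)
          data.frame(hr_pre = x$hr_pre, hr_post = x$hr_post,
                     map_pre = x$map_pre, map_post = x$map_post)))
      }
    }
    row <- subject_repro(acts, roi = roi_ids, physio = phys)
    row <- cbind(data.frame(subject = s), row)
    subj_tab <- rbind(subj_tab, row)
    freq[[as.character(s)]] <- frequency_map(acts, roi = roi_ids)
  }

  medians <- if (!is.null(subj_tab)) summarize_medians(subj_tab) else NULL
  grp <- group_betas(glm_tables, alpha = alpha)

  structure(list(glm_tables = glm_tables, activations = activations,
                 subject_table = subj_tab, frequency_maps = freq,
                 medians = medians, group = grp, roi = roi,
                 roi_channels = roi_ids, log = log),
            class = "retest_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.retest_result <- function(x, ...) {
  cat("Test-retest analysis:", length(x$activations), "sessions,",
      if (!is.null(x$subject_table)) nrow(x$subject_table) else 0,
      "subjects; ROI:", x$roi, "\n")
  if (!is.null(x$subject_table)) {
    print(x$subject_table, digits = 3)
  }
  invisible(x)
}

#' Write the result bundle of [run_pipeline()] as TSV tables
#'
#' @param result a `retest_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    cbind(d, param_hash = result$log$hash), file.path(dir, f),
    sep = "\t", row.names = FALSE, quote = FALSE)
  glm_all <- do.call(rbind, c(result$glm_tables, make.row.names = FALSE))
  w(glm_all, "glm_channels.tsv")
  act <- do.call(rbind, lapply(names(result$activations), function(k)
    data.frame(session = k, channel = names(result$activations[[k]]),
               active = as.integer(result$activations[[k]]))))
  w(act, "activation_vectors.tsv")
  if (!is.null(result$subject_table)) {
    w(result$subject_table, "subject_reproducibility.tsv")
  }
  if (!is.null(result$medians)) w(result$medians, "group_medians.tsv")
  w(result$group$betas, "group_betas.tsv")
  invisible(dir)
}
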