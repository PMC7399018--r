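#' Extinction coefficients for oxy- and deoxy-hemoglobin
#'
#' Decadic molar extinction coefficients (cm^-1 M^-1) at the two nominal
#' wavelengths of the continuous-wave instrument emulated by this package
#' (760 and 850 nm), from the widely used compiled in-vitro spectra.
#' The same table is used by the forward simulator and by the modified
#' Beer-Lambert inversion, so concentration round trips are exact by
#' construction.
#'
#' @param wavelengths numeric vector of wavelengths (nm) to return.
#' @return matrix with one row per wavelength and columns `HbO`, `HbR`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  path <- system.file("extdata", "extinction_coefficients.tsv",
                      package = "nirsrep", mustWork = TRUE)
  tab <- utils::read.delim(path)
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) {
    stop("no extinction coefficients tabulated for wavelength(s): ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  }
  out <- as.matrix(tab[idx, c("HbO", "HbR")])
  rownames(out) <- as.character(wavelengths)
  out
}

## One "hex flower" hemisphere: center source + ring of 6 sources at radius
## 3*sqrt(3) cm, so that the circumcenter of every (center, ring_k, ring_k+1)
## triangle sits exactly 3 cm from all three sources.  Detectors:
##   - 6 inner circumcenters (each forms 3 long channels),
##   - 6 outer ring-pair intersections (2 long channels each),
##   - 2 lateral detectors at 3 cm outward of ring sources 1 and 4 (1 each),
##   - 2 short-separation detectors 0.8 cm from the center and an anterior
##     ring source.
## This yields 7 sources, 16 detectors, 32 long + 2 short channels per
## hemisphere; mirroring gives the full 14/32/64/4 probe.
hemisphere_optodes <- function(center, long_sep = 3, short_sep = 0.8,
                               mirror = FALSE) {
  a <- long_sep * sqrt(3)
  ang <- (0:5) * pi / 3
  ring <- cbind(a * cos(ang), a * sin(ang))
  sources <- rbind(c(0, 0), ring)

  inner <- t(vapply(1:6, function(k) {
    (sources[1, ] + ring[k, ] + ring[(k %% 6) + 1, ]) / 3
  }, numeric(2)))
  mid_ang <- ang + pi / 6
  outer <- cbind(2 * long_sep * cos(mid_ang), 2 * long_sep * sin(mid_ang))
  lateral <- rbind((a + long_sep) * c(cos(ang[1]), sin(ang[1])),
                   (a + long_sep) * c(cos(ang[4]), sin(ang[4])))
  shorts <- rbind(c(0, short_sep), ring[2, ] + c(0, short_sep))
  detectors <- rbind(inner, outer, lateral, shorts)

  if (mirror) {
    sources[, 1] <- -sources[, 1]
    detectors[, 1] <- -detectors[, 1]
  }
  list(sources = sweep(sources, 2, center, `+`),
       detectors = sweep(detectors, 2, center, `+`))
}

#' Construct an optical probe layout
#'
#' Builds the channel table of a continuous-wave fNIRS probe from optode
#' scalp-plane coordinates.  A channel is formed by every source-detector
#' pair whose separation is within `long_tol` of `long_sep` (a long,
#' cortex-sensitive channel) or within `short_tol` of `short_sep` (a
#' short-separation channel sampling superficial tissue only).
#'
#' The default layout emulates a bilateral motor-cortex probe: 14 sources
#' and 32 detectors arranged symmetrically about the midline, giving 64
#' long channels at 3 cm and 4 short channels at 0.8 cm.
#'
#' @param sources,detectors optional n x 2 matrices of optode coordinates
#'   (cm).  When omitted the default bilateral layout is generated.
#' @param long_sep,short_sep nominal separations in cm.
#' @param long_tol,short_tol matching tolerances in cm.
#' @param hemi_offset half-distance between hemisphere centers (cm), used
#'   only for the default layout.
#' @param wavelengths nominal wavelengths (nm).
#' @return object of class `probe_layout`: list with `sources`,
#'   `detectors`, `wavelengths` and a `channels` data frame (one row per
#'   channel: source, detector, separation, type, hemisphere, midpoint).
#' @export
make_probe <- function(sources = NULL, detectors = NULL,
                       long_sep = 3, short_sep = 0.8,
                       long_tol = 0.25, short_tol = 0.1,
                       hemi_offset = 10, wavelengths = c(760, 850)) {
  if (long_sep <= 0 || short_sep <= 0) {
    stop("separations must be positive")
  }
  if (is.null(sources) != is.null(detectors)) {
    stop("supply both `sources` and `detectors`, or neither")
  }
  if (is.null(sources)) {
    left <- hemisphere_optodes(c(-hemi_offset, 0), long_sep, short_sep)
    right <- hemisphere_optodes(c(hemi_offset, 0), long_sep, short_sep,
                                mirror = TRUE)
    sources <- rbind(left$sources, right$sources)
    detectors <- rbind(left$detectors, right$detectors)
  }
  sources <- matrix(as.numeric(sources), ncol = 2)
  detectors <- matrix(as.numeric(detectors), ncol = 2)

  sep <- sqrt(outer(sources[, 1], detectors[, 1], `-`)^2 +
              outer(sources[, 2], detectors[, 2], `-`)^2)
  is_long <- abs(sep - long_sep) <= long_tol
  is_short <- abs(sep - short_sep) <= short_tol
  idx <- which(is_long | is_short, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("infeasible geometry: no source-detector pair matches the ",
         "requested separations")
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  s <- idx[, 1]; d <- idx[, 2]
  mx <- (sources[s, 1] + detectors[d, 1]) / 2
  my <- (sources[s, 2] + detectors[d, 2]) / 2
  channels <- data.frame(
    channel = seq_along(s),
    source = s,
    detector = d,
    separation = sep[idx],
    type = ifelse(is_short[idx], "short", "long"),
    hemisphere = ifelse(mx < 0, "left", "right"),
    x = mx, y = my,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(channels[, c("source", "detector")])) {
    stop("duplicate (source, detector) pairs in channel table")
  }
  structure(list(sources = sources, detectors = detectors,
                 channels = channels, wavelengths = wavelengths,
                 long_sep = long_sep, short_sep = short_sep),
            class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  ch <- x$channels
  cat("fNIRS probe layout:", nrow(x$sources), "sources,",
      nrow(x$detectors), "detectors\n")
  cat("  ", sum(ch$type == "long"), " long channels (~",
      x$long_sep, " cm), ", sum(ch$type == "short"),
      " short channels (~", x$short_sep, " cm)\n", sep = "")
  invisible(x)
}

#' Channels belonging to a region of interest
#'
#' @param probe a `probe_layout`.
#' @param roi one of `"whole"` (all long channels), `"left"` / `"right"`
#'   (hemisphere), or `"focal"` (long channels whose midpoint lies within
#'   `radius` cm of `center`).
#' @param center,radius focal ROI definition (cm).
#' @return integer channel ids (rows of `probe$channels`).
#' @export
roi_channels <- function(probe, roi = c("whole", "left", "right", "focal"),
                         center = NULL, radius = 4) {
  roi <- match.arg(roi)
  ch <- probe$channels
  keep <- ch$type == "long"
  if (roi %in% c("left", "right")) {
    keep <- keep & ch$hemisphere == roi
  } else if (roi == "focal") {
    if (is.null(center)) stop("focal ROI needs a `center`")
    keep <- keep & sqrt((ch$x - center[1])^2 + (ch$y - center[2])^2) <= radius
  }
  ch$channel[keep]
}

#' Nearest short-separation channel for a long channel
#'
#' Finds the short channel whose midpoint is closest (Euclidean distance
#' in the scalp plane) to the midpoint of the given long channel; ties are
#' broken toward the lowest channel id.  Used to pick the superficial
#' nuisance regressor for the GLM.
#'
#' @param probe a `probe_layout`.
#' @param long_channel_id channel id of a long channel.
#' @param available optional channel ids still available (e.g. after
#'   pruning); defaults to all short channels.
#' @return the short channel id.
#' @export
nearest_short_channel <- function(probe, long_channel_id, available = NULL) {
  ch <- probe$channels
  shorts <- ch[ch$type == "short", , drop = FALSE]
  if (!is.null(available)) {
    shorts <- shorts[shorts$channel %in% available, , drop = FALSE]
  }
  if (nrow(shorts) == 0) {
    stop("no short channels available; fit the GLM with use_short = FALSE ",
         "to proceed without superficial regression")
  }
  j <- ch[ch$channel == long_channel_id, , drop = FALSE]
  if (nrow(j) != 1 || j$type != "long") {
    stop("`long_channel_id` must identify a single long channel")
  }
  d <- sqrt((shorts$x - j$x)^2 + (shorts$y - j$y)^2)
  shorts$channel[order(d, shorts$channel)[1]]
}
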