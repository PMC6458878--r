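# Electrode layout on an idealized sphere (5/10 placement scheme).
#
# Positions are generated from the label grammar: the row letters give the
# anterior-posterior arc angle from the vertex and the numeric suffix the
# lateral arc angle (odd = left, even = right, z = midline).  Idealized
# spherical positions are sufficient for spline interpolation and for
# topographic artifact templates; no digitized head shape is implied.

.ROW_ANGLE <- c(Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, T = 0, C = 0,
                TP = -18, CP = -18, P = -36, PO = -54, O = -72)

#' Channel labels of the 65-channel recording montage
#'
#' The 64 recorded channels of the actiCap-style cap plus the recording
#' reference FCz (reintroduced at average referencing).
#'
#' @param include_ref Include FCz (default \code{TRUE}).
#' @return Character vector of channel labels.
#' @export
montage_channels <- function(include_ref = TRUE) {
  ch <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
          "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2",
          "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz",
          "O2", "PO10", "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
          "FT9", "FT7", "FC3", "FC4", "FT8", "FT10", "C5", "C1", "C2", "C6",
          "TP7", "CP3", "CPz", "CP4", "TP8", "P5", "P1", "P2", "P6", "PO7",
          "PO3", "POz", "PO4", "PO8")
  if (include_ref) c(ch, "FCz") else ch
}

#' Training montage electrodes
#'
#' The four electrodes used for the neurofeedback training signal,
#' referenced against linked earlobes.
#'
#' @return Character vector \code{c("FC1", "FC2", "F3", "F4")}.
#' @export
training_channels <- function() c("FC1", "FC2", "F3", "F4")

parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3) return(NULL)
  row <- m[2]
  # T7/T8 and TP/FT rows share arcs with C/CP/FC rows
  if (!row %in% names(.ROW_ANGLE)) return(NULL)
  suf <- m[3]
  if (suf == "z") {
    lat <- 0; side <- 0
  } else {
    k <- as.integer(suf)
    lat <- 18 * ceiling(k / 2)
    # T7 = C7 arc, TP9 below the equator etc. fall out of the same rule
    side <- if (k %% 2 == 1) 1 else -1   # odd = left (+y), even = right (-y)
  }
  c(ap = unname(.ROW_ANGLE[row]), lat = lat, side = side)
}

#' Idealized spherical electrode positions
#'
#' @param labels Channel labels (5/10 grammar).
#' @return Matrix with rows per channel and columns x (anterior), y (left),
#'   z (up) on the unit sphere.
#' @export
electrode_positions <- function(labels) {
  pos <- matrix(NA_real_, length(labels), 3,
                dimnames = list(labels, c("x", "y", "z")))
  for (i in seq_along(labels)) {
    p <- parse_label(labels[i])
    if (is.null(p)) stop_input("unknown electrode position: %s", labels[i])
    phi <- p[["ap"]] * pi / 180
    lam <- p[["lat"]] * pi / 180
    pos[i, ] <- c(sin(phi), p[["side"]] * sin(lam) * cos(phi),
                  cos(lam) * cos(phi))
  }
  pos
}

# frontal weighting used for blink topographies: 1 at Fp row, ~0 behind Cz
frontal_weights <- function(labels) {
  pos <- electrode_positions(labels)
  w <- pmax(0, pos[, "x"])^2
  w / max(w)
}
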