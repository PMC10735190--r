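#' Canonical 19-channel 10/20 montage
#'
#' The single canonical channel ordering used everywhere in the package:
#' the EDF reader returns channels in this order, the 570-value feature
#' layout is channel-major in this order, and topography expects power
#' values in this order.
#'
#' Sites: anterior frontal (Fp1, Fp2), frontal (F3, F4, Fz, F7, F8),
#' central (C3, C4, Cz), parietal (P3, P4, Pz), occipital (O1, O2) and
#' temporal (T3, T4, T5, T6) — the classic 19-electrode recording montage.
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8",
    "C3", "C4", "Cz", "P3", "P4", "Pz",
    "O1", "O2", "T3", "T4", "T5", "T6")
}

#' 2-D electrode coordinates on the unit head disc
#'
#' Standard schematic top-view projection of the 10/20 positions (nose up,
#' left ear at negative x). Radii follow the usual equal-angular-spacing
#' convention and are rescaled so the outermost 10% ring lies on the unit
#' circle.
#'
#' @param labels Channel labels to look up (default: the full montage).
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
electrode_positions <- function(labels = montage_1020()) {
  path <- system.file("extdata", "montage1020_xy.csv", package = "cogload",
                      mustWork = TRUE)
  xy <- utils::read.csv(path, stringsAsFactors = FALSE)
  idx <- match(labels, xy$label)
  if (anyNA(idx)) {
    stop("no coordinates for channel(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  xy[idx, , drop = FALSE]
}
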