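#' Define a Raman band extraction window
#'
#' A band is a nominal center and a half-width; intensities are extracted
#' as the maximum baseline-corrected intensity inside
#' `[center - half_window, center + half_window]`.
#'
#' @param center_cm1 Nominal band position, cm^-1.
#' @param half_window_cm1 Extraction half-width, cm^-1 (> 0). The default
#'   +/- 10 cm^-1 absorbs the ~1 cm^-1 position jitter between
#'   acquisitions.
#' @param label Band label; defaults to the center.
#' @return A `band_definition`.
#' @export
band_definition <- function(center_cm1, half_window_cm1 = 10,
                            label = as.character(center_cm1)) {
  if (!is.numeric(half_window_cm1) || half_window_cm1 <= 0)
    stop("half_window_cm1 must be > 0")
  structure(list(center_cm1 = as.numeric(center_cm1),
                 half_window_cm1 = as.numeric(half_window_cm1),
                 label = as.character(label)),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g +/- %g cm^-1\n", x$label, x$center_cm1,
              x$half_window_cm1))
  invisible(x)
}

#' Collagen reference bands
#'
#' The five collagen-related fingerprint bands used as optical-clearing
#' references: 938 (C-C stretch), 1003 (phenylalanine ring breathing),
#' 1247 and 1270 (amide III), 1665 (amide I) cm^-1. Protein is immobile
#' in the tissue, so any intensity change in these bands reflects the
#' clearing of overlying layers, not transport.
#'
#' @param half_window_cm1 Extraction half-width per band.
#' @return Named list of `band_definition`s.
#' @export
collagen_bands <- function(half_window_cm1 = 10) {
  centers <- c(938, 1003, 1247, 1270, 1665)
  stats::setNames(lapply(centers, band_definition,
                         half_window_cm1 = half_window_cm1),
                  as.character(centers))
}

#' Glycerol marker bands
#'
#' Glycerol-related fingerprint bands at 485, 849, 1054 and 1466 cm^-1.
#' The 485 cm^-1 band overlaps least with tissue bands and is the
#' quantification band throughout.
#'
#' @param half_window_cm1 Extraction half-width per band.
#' @return Named list of `band_definition`s.
#' @export
glycerol_bands <- function(half_window_cm1 = 10) {
  centers <- c(485, 849, 1054, 1466)
  stats::setNames(lapply(centers, band_definition,
                         half_window_cm1 = half_window_cm1),
                  as.character(centers))
}
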