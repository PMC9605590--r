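#' Per-band kinetic time series
#'
#' Holds one band's value versus treatment time at a fixed depth. `kind`
#' records what the values are: `"raw"` band intensity, `"oc_eff"`
#' clearing-efficiency ratio, `"trgc_intensity"` (corrected intensity) or
#' `"trgc_concentration"` (percent glycerol after calibration).
#'
#' @param depth_um Probing depth, micrometres.
#' @param band A `band_definition`.
#' @param times_s Strictly increasing treatment times, seconds.
#' @param values Matched values.
#' @param kind One of `"raw"`, `"oc_eff"`, `"trgc_intensity"`,
#'   `"trgc_concentration"`.
#' @return A `band_time_series`.
#' @export
band_time_series <- function(depth_um, band, times_s, values,
                             kind = c("raw", "oc_eff", "trgc_intensity",
                                      "trgc_concentration")) {
  kind <- match.arg(kind)
  stopifnot(inherits(band, "band_definition"))
  times_s <- as.numeric(times_s); values <- as.numeric(values)
  if (length(times_s) != length(values))
    stop("times_s and values differ in length")
  if (any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing")
  if (kind == "oc_eff" && any(values <= 0))
    stop("oc_eff values must be > 0")
  structure(list(depth_um = as.numeric(depth_um), band = band,
                 times_s = times_s, values = values, kind = kind),
            class = "band_time_series")
}

#' @export
print.band_time_series <- function(x, ...) {
  cat(sprintf("<band_time_series> %s @ %g um, %s, %d time points (%g-%g s)\n",
              x$band$label, x$depth_um, x$kind, length(x$times_s),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Optical clearing efficiency
#'
#' OC efficiency is the ratio of a collagen reference band's intensity
#' after agent treatment to its untreated value at the same depth,
#' `OC_eff = I_OC / I_0`. Protein is immobile, so the rise of a collagen
#' band quantifies how much more excitation/collection reaches the focal
#' depth as overlying layers clear.
#'
#' @param i_oc Band intensity at treatment time t (vectorized).
#' @param i_0 Untreated reference intensity at the same depth (> 0).
#' @return `i_oc / i_0`.
#' @export
oc_efficiency <- function(i_oc, i_0) {
  if (!is.finite(i_0) || i_0 <= 0)
    stop("reference error: untreated intensity I_0 must be > 0, got ", i_0)
  as.numeric(i_oc) / i_0
}

#' Optical-clearing-corrected glycerol signal
#'
#' The raw glycerol band intensity at depth is inflated by the clearing
#' of upper layers (the same mechanism that raises the collagen bands).
#' Dividing by the clearing efficiency removes that crosstalk, leaving
#' the reconstructed glycerol signal `TRGC = I_gly / OC_eff`, which
#' tracks physical penetration only.
#'
#' @param i_gly Glycerol 485 cm^-1 band intensity (vectorized).
#' @param oc_eff Matching clearing-efficiency ratio(s) (> 0).
#' @return Corrected intensity `i_gly / oc_eff`.
#' @export
trgc <- function(i_gly, oc_eff) {
  oc_eff <- as.numeric(oc_eff)
  if (any(!is.finite(oc_eff)) || any(oc_eff <= 0))
    stop("correction error: oc_eff must be > 0")
  as.numeric(i_gly) / oc_eff
}

#' Build TRGC concentration series per collagen reference band
#'
#' For each collagen reference band, divides the glycerol 485 cm^-1
#' intensity series by that band's clearing efficiency and maps the
#' corrected intensity through the calibration line, yielding one
#' reconstructed-concentration series per reference band (five per depth
#' with the standard band set). The per-band series are kept separate and
#' propagated separately through the diffusion fit; per-depth parameters
#' are averaged afterwards.
#'
#' @param gly_series `band_time_series` (kind `"raw"`) of the glycerol
#'   485 cm^-1 intensity.
#' @param collagen_series Named list of `band_time_series` (kind
#'   `"raw"`), one per collagen reference band, on the same time axis and
#'   depth.
#' @param i0_ref Named numeric: untreated reference intensity per
#'   collagen band (names matching `collagen_series`).
#' @param calibration A `calibration_model`.
#' @return Named list of `band_time_series` of kind
#'   `"trgc_concentration"`, one per reference band, each carrying
#'   attributes `oc_eff` and `trgc_intensity`.
#' @export
build_trgc_series <- function(gly_series, collagen_series, i0_ref,
                              calibration) {
  stopifnot(inherits(gly_series, "band_time_series"),
            inherits(calibration, "calibration_model"))
  out <- vector("list", length(collagen_series))
  names(out) <- names(collagen_series)
  for (nm in names(collagen_series)) {
    cs <- collagen_series[[nm]]
    if (length(cs$times_s) != length(gly_series$times_s) ||
        max(abs(cs$times_s - gly_series$times_s)) > 1e-9)
      stop("alignment error: time axis of band ", nm,
           " does not match the glycerol series")
    if (!isTRUE(cs$depth_um == gly_series$depth_um))
      stop("alignment error: depth of band ", nm,
           " does not match the glycerol series")
    if (is.null(i0_ref[[nm]]))
      stop("missing untreated reference intensity for band ", nm)
    eff <- oc_efficiency(cs$values, i0_ref[[nm]])
    ti <- trgc(gly_series$values, eff)
    conc <- predict_concentration(calibration, ti)
    ser <- band_time_series(gly_series$depth_um, cs$band,
                            gly_series$times_s, as.numeric(conc),
                            kind = "trgc_concentration")
    attr(ser, "oc_eff") <- eff
    attr(ser, "trgc_intensity") <- ti
    out[[nm]] <- ser
  }
  out
}

#' Tidy clearing-kinetics table
#'
#' Flattens TRGC series built by [build_trgc_series()] (possibly over
#' several depths) into a long table with one row per depth, reference
#' band and time.
#'
#' @param trgc_list Named list (or list of named lists) of
#'   `band_time_series` from [build_trgc_series()].
#' @param gly_series Optional matching raw glycerol series (single or
#'   list, one per depth) used to fill `raw_intensity`.
#' @return `data.frame` with columns `depth_um`, `band_cm1`, `time_s`,
#'   `raw_intensity`, `oc_eff`, `trgc_intensity`,
#'   `trgc_concentration_pct`.
#' @export
clearing_table <- function(trgc_list, gly_series = NULL) {
  if (length(trgc_list) && inherits(trgc_list[[1L]], "band_time_series")) {
    trgc_list <- list(trgc_list)
    if (!is.null(gly_series) && inherits(gly_series, "band_time_series"))
      gly_series <- list(gly_series)
  }
  rows <- list()
  for (d in seq_along(trgc_list)) {
    gs <- if (!is.null(gly_series)) gly_series[[d]] else NULL
    for (ser in trgc_list[[d]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        depth_um = ser$depth_um,
        band_cm1 = ser$band$center_cm1,
        time_s = ser$times_s,
        raw_intensity = if (!is.null(gs)) gs$values else NA_real_,
        oc_eff = attr(ser, "oc_eff"),
        trgc_intensity = attr(ser, "trgc_intensity"),
        trgc_concentration_pct = ser$values)
    }
  }
  do.call(rbind, rows)
}
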