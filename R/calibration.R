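#' Fit the glycerol calibration line
#'
#' Ordinary least-squares line through (concentration, band intensity)
#' for a series of glycerol-in-water standards. Raman band intensity is
#' directly proportional to the scatterer concentration, so a single
#' unweighted line is fitted; its R^2 reports how well the standards obey
#' that proportionality. When spectra are supplied they are
#' baseline-subtracted and the 485 cm^-1 glycerol band intensity is
#' extracted first.
#'
#' @param concentration_pct Numeric vector of standard concentrations in
#'   volume percent (at least 3 distinct values in \[0, 100\]).
#' @param intensities Either a numeric vector of band intensities or a
#'   list of `raman_spectrum` standards.
#' @param band Quantification band (default 485 cm^-1).
#' @param preprocess Baseline-subtract spectra before extraction
#'   (ignored for numeric `intensities`).
#' @return A `calibration_model` with slope (intensity per %), intercept,
#'   `r_squared`, `n_points` and the band used.
#' @export
fit_calibration <- function(concentration_pct, intensities,
                            band = band_definition(485, 10, "glycerol 485"),
                            preprocess = TRUE) {
  conc <- as.numeric(concentration_pct)
  if (length(conc) < 3L)
    stop("fit error: need at least 3 calibration standards, got ", length(conc))
  if (length(unique(conc)) < 2L)
    stop("fit error: all calibration concentrations are equal")
  if (any(conc < 0 | conc > 100))
    stop("calibration concentrations must lie in [0, 100]%")
  if (is.list(intensities) &&
      all(vapply(intensities, inherits, TRUE, "raman_spectrum"))) {
    y <- vapply(intensities, function(s) {
      if (preprocess) s <- baseline_subtract(s)
      as.numeric(band_intensity(s, band))
    }, numeric(1L))
  } else {
    y <- as.numeric(intensities)
  }
  if (length(y) != length(conc))
    stop("concentrations and intensities differ in length")
  fit <- stats::lm(y ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = min(max(r2, 0), 1),
         n_points = length(conc),
         band = band),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> I = %.4g + %.4g * C%%  (band %s, n = %d, R^2 = %.4f)\n",
    x$intercept, x$slope, x$band$label, x$n_points, x$r_squared))
  invisible(x)
}

#' Invert the calibration line
#'
#' Maps a band intensity to a glycerol concentration via
#' `(intensity - intercept) / slope`. Small negative predictions are
#' expected from noise at near-zero glycerol in deep layers; they are
#' clamped to 0% and flagged (attribute `clamped`) rather than raising an
#' error. No upper clamp is applied.
#'
#' @param model A `calibration_model`.
#' @param intensity Numeric vector of band intensities.
#' @return Concentrations in volume percent, with logical attribute
#'   `clamped` marking clamped entries.
#' @export
predict_concentration <- function(model, intensity) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.finite(model$slope) || model$slope == 0)
    stop("inversion error: calibration slope is zero")
  conc <- (as.numeric(intensity) - model$intercept) / model$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  structure(conc, clamped = clamped)
}

#' Serialize / restore a calibration model
#'
#' @param model A `calibration_model`.
#' @param path JSON file.
#' @return `path` (write) or the restored `calibration_model` (read).
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(slope = model$slope, intercept = model$intercept,
              r_squared = model$r_squared, n_points = model$n_points,
              band_center_cm1 = model$band$center_cm1,
              band_half_window_cm1 = model$band$half_window_cm1,
              band_label = model$band$label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(slope = obj$slope, intercept = obj$intercept,
         r_squared = obj$r_squared, n_points = obj$n_points,
         band = band_definition(obj$band_center_cm1,
                                obj$band_half_window_cm1, obj$band_label)),
    class = "calibration_model"
  )
}
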