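#' Raman spectrum object
#'
#' A `raman_spectrum` holds one depth-resolved confocal Raman acquisition:
#' a strictly increasing wavenumber axis with matched intensities plus the
#' acquisition metadata (spectral region, probing depth, treatment time,
#' sample label). Two regions are supported: the fingerprint region
#' (`"FP"`, 400--1800 cm^-1, collagen and glycerol marker bands) and the
#' high-wavenumber region (`"HWN"`, 2600--3800 cm^-1, CH stretch and the
#' OH-stretch water envelope).
#'
#' Untreated reference spectra (recorded before agent application) carry
#' `time_s = NA`; this sentinel distinguishes "before application" from
#' "immediately after" (`time_s = 0`).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of intensities (counts), same length.
#' @param region `"FP"` or `"HWN"`.
#' @param depth_um Probing depth below the tissue surface in micrometres
#'   (>= 0).
#' @param time_s Seconds since agent application (>= 0), or `NA` for an
#'   untreated reference.
#' @param sample_id Opaque sample label.
#' @return An object of class `raman_spectrum`.
#' @examples
#' wn <- seq(400, 1800, by = 2)
#' s <- raman_spectrum(wn, rexp(length(wn)), region = "FP", depth_um = 50)
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, region = c("FP", "HWN"),
                           depth_um = NA_real_, time_s = NA_real_,
                           sample_id = NA_character_) {
  region <- match.arg(region)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points, got ", length(wavenumbers))
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers (", length(wavenumbers), ") and intensities (",
         length(intensities), ") differ in length")
  if (anyNA(wavenumbers) || anyNA(intensities))
    stop("wavenumbers and intensities must not contain NA")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  span <- .region_span(region)
  if (wavenumbers[1L] < span[1L] || wavenumbers[length(wavenumbers)] > span[2L])
    stop(region, " spectra must lie within [", span[1L], ", ", span[2L],
         "] cm^-1; got [", wavenumbers[1L], ", ",
         wavenumbers[length(wavenumbers)], "]")
  if (!is.na(depth_um) && depth_um < 0) stop("depth_um must be >= 0")
  if (!is.na(time_s) && time_s < 0) stop("time_s must be >= 0 or NA (untreated)")
  structure(
    list(wavenumber = wavenumbers, intensity = intensities, region = region,
         depth_um = as.numeric(depth_um), time_s = as.numeric(time_s),
         sample_id = as.character(sample_id)),
    class = "raman_spectrum"
  )
}

.region_span <- function(region) {
  switch(region, FP = c(400, 1800), HWN = c(2600, 3800),
         stop("unknown region: ", region))
}

#' @export
print.raman_spectrum <- function(x, ...) {
  n <- length(x$wavenumber)
  cat(sprintf("<raman_spectrum> %s, %d points, %.1f-%.1f cm^-1\n",
              x$region, n, x$wavenumber[1L], x$wavenumber[n]))
  cat(sprintf("  depth: %s um, time: %s, sample: %s\n",
              format(x$depth_um),
              if (is.na(x$time_s)) "untreated" else paste0(x$time_s, " s"),
              x$sample_id))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' Is a spectrum an untreated reference?
#'
#' @param s A `raman_spectrum`.
#' @return `TRUE` when `time_s` carries the untreated sentinel (`NA`).
#' @export
is_untreated <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  is.na(s$time_s)
}

#' Read a two-column spectrum file
#'
#' Reads a plain-text spectrum file with two delimited columns
#' (wavenumber in cm^-1, intensity in counts). The delimiter may be a
#' comma, tab or whitespace; lines starting with `#` are comments. Rows
#' stored in descending wavenumber order are sorted ascending with the
#' intensities permuted consistently.
#'
#' @param path File to read.
#' @param region,depth_um,time_s,sample_id Acquisition metadata, see
#'   [raman_spectrum()].
#' @return A validated `raman_spectrum`.
#' @export
read_spectrum <- function(path, region = c("FP", "HWN"), depth_um = NA_real_,
                          time_s = NA_real_, sample_id = NA_character_) {
  region <- match.arg(region)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L)
    stop("parse error in ", path, ": fewer than 2 data rows")
  wn <- numeric(length(idx))
  ic <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[,\t ]+")[[1L]]
    if (length(fields) < 2L)
      stop("parse error in ", path, " at line ", idx[k],
           ": expected 2 columns, got ", length(fields))
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals))
      stop("parse error in ", path, " at line ", idx[k],
           ": non-numeric value '", fields[which(is.na(vals))[1L]], "'")
    wn[k] <- vals[1L]; ic[k] <- vals[2L]
  }
  ord <- order(wn)
  raman_spectrum(wn[ord], ic[ord], region = region, depth_um = depth_um,
                 time_s = time_s, sample_id = sample_id)
}

#' Write a spectrum to a two-column text file
#'
#' @param s A `raman_spectrum`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  header <- sprintf("# region=%s depth_um=%s time_s=%s sample_id=%s",
                    s$region, format(s$depth_um),
                    if (is.na(s$time_s)) "untreated" else format(s$time_s),
                    s$sample_id)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.6g\t%.10g", s$wavenumber, s$intensity), con)
  invisible(path)
}

#' Resample a spectrum onto a common wavenumber grid
#'
#' Wavenumber grids of different files are never interpolated silently;
#' this explicit linear-interpolation resampler is the only place where a
#' spectrum changes axis.
#'
#' @param s A `raman_spectrum`.
#' @param grid Target wavenumber grid (strictly increasing, inside the
#'   spectrum's range).
#' @return The resampled `raman_spectrum`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "raman_spectrum"))
  grid <- as.numeric(grid)
  rng <- range(s$wavenumber)
  if (min(grid) < rng[1L] || max(grid) > rng[2L])
    stop("target grid [", min(grid), ", ", max(grid),
         "] extends beyond the spectrum range [", rng[1L], ", ", rng[2L], "]")
  y <- stats::approx(s$wavenumber, s$intensity, xout = grid)$y
  raman_spectrum(grid, y, region = s$region, depth_um = s$depth_um,
                 time_s = s$time_s, sample_id = s$sample_id)
}

.check_common_axis <- function(spectra) {
  ref <- spectra[[1L]]$wavenumber
  for (s in spectra[-1L]) {
    if (length(s$wavenumber) != length(ref) ||
        max(abs(s$wavenumber - ref)) > 1e-9)
      stop("spectra do not share a wavenumber axis; ",
           "resample_spectrum() to a common grid first")
  }
  invisible(ref)
}

#' Read a manifest of spectrum files
#'
#' The manifest is a CSV with columns `path`, `region`, `depth_um`,
#' `time_s` (empty or "untreated" for untreated references) and
#' `sample_id`. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest_csv Manifest file.
#' @return A list of `raman_spectrum` objects.
#' @export
read_spectra_manifest <- function(manifest_csv) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("path", "region", "depth_um", "time_s", "sample_id")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest is missing columns: ",
                         paste(miss, collapse = ", "))
  base <- dirname(normalizePath(manifest_csv))
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    t_raw <- man$time_s[i]
    t_s <- if (is.na(t_raw) || t_raw %in% c("", "untreated"))
      NA_real_ else as.numeric(t_raw)
    read_spectrum(p, region = man$region[i], depth_um = man$depth_um[i],
                  time_s = t_s, sample_id = man$sample_id[i])
  })
}
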