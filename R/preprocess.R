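#' Estimate a lower-envelope polynomial baseline
#'
#' Fits a polynomial baseline iteratively: after each ordinary fit the
#' working intensities are clipped to the fitted curve (`min(y, fit)`), so
#' the polynomial relaxes onto the lower envelope of the spectrum and
#' peaks stop pulling it up. A final refit uses only the anchor points
#' whose residuals fall at or below the `anchor_quantile` quantile.
#'
#' In the fingerprint region the bands are narrow, so most of the axis
#' exposes bare baseline and the envelope iteration works everywhere. In
#' the high-wavenumber region the broad OH-stretch components cover the
#' whole interior — there is no exposed baseline to relax onto, and an
#' envelope fit would eat the water envelope itself. HWN baselines are
#' therefore fitted, by default, only to the signal-free edge margins
#' (2600--2700 and 3750--3800 cm^-1) via `anchor_windows`.
#'
#' @param s A `raman_spectrum`.
#' @param poly_order Polynomial order (>= 0). Defaults: 5 for FP spectra,
#'   3 for the smoother HWN envelope.
#' @param anchor_quantile Fraction in (0, 1] of lowest-residual points
#'   used for the final anchored refit.
#' @param anchor_windows Optional numeric vector of interval bounds
#'   `c(lo1, hi1, lo2, hi2, ...)`: when given, the baseline is an
#'   ordinary polynomial fit to the points inside these windows and the
#'   envelope iteration is skipped. Default for HWN spectra: the
#'   signal-free edge margins.
#' @param max_iter,tol Iteration controls for the envelope relaxation.
#' @return Numeric vector: the estimated baseline.
#' @export
estimate_baseline <- function(s, poly_order = if (s$region == "FP") 5L else 3L,
                              anchor_quantile = 0.1,
                              anchor_windows = if (s$region == "HWN")
                                c(2600, 2700, 3750, 3800) else NULL,
                              max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (poly_order < 0) stop("poly_order must be >= 0")
  n <- length(s$wavenumber)
  if (poly_order >= n - 1L)
    stop("degenerate fit: poly_order ", poly_order,
         " needs more than ", poly_order + 1L, " points, spectrum has ", n)
  if (anchor_quantile <= 0 || anchor_quantile > 1)
    stop("anchor_quantile must lie in (0, 1]")
  x <- s$wavenumber
  # center/scale the axis for numerical stability of high-order fits
  xs <- (x - mean(x)) / stats::sd(x)
  X <- stats::poly(xs, degree = max(poly_order, 1L), raw = FALSE)
  if (poly_order == 0L) X <- X[, 0, drop = FALSE]
  y <- s$intensity
  if (!is.null(anchor_windows)) {
    if (length(anchor_windows) %% 2L != 0L)
      stop("anchor_windows must be pairs of interval bounds")
    lo <- anchor_windows[c(TRUE, FALSE)]; hi <- anchor_windows[c(FALSE, TRUE)]
    sel <- Reduce(`|`, lapply(seq_along(lo), function(i)
      x >= lo[i] & x <= hi[i]))
    if (sum(sel) < poly_order + 2L)
      stop("anchor windows contain too few points for a degree-",
           poly_order, " baseline")
    co <- stats::lm.fit(cbind(1, X[sel, , drop = FALSE]), y[sel])
    return(drop(cbind(1, X) %*% co$coefficients))
  }
  yw <- y
  fit <- rep(mean(yw), n)
  for (i in seq_len(max_iter)) {
    co <- stats::lm.fit(cbind(1, X), yw)
    fit_new <- drop(cbind(1, X) %*% co$coefficients)
    res <- yw - fit_new
    dev <- stats::sd(res)
    # clip only the peak excursions above fit + dev; points at or below
    # the fit keep their original intensities so the baseline support
    # keeps pulling the polynomial up (one-sided undershoot cannot
    # self-sustain)
    yw <- pmin(y, fit_new + dev)
    delta <- max(abs(fit_new - fit))
    fit <- fit_new
    if (delta < tol * max(1, max(abs(y)))) break
  }
  res <- s$intensity - fit
  thr <- stats::quantile(res, anchor_quantile, names = FALSE)
  anchors <- which(res <= thr + 1e-12 * max(1, max(abs(res))))
  if (length(anchors) < poly_order + 2L) {
    anchors <- order(res)[seq_len(min(n, poly_order + 2L))]
  }
  # a refit through anchors clustered in one corner of the axis would
  # extrapolate wildly; keep the envelope fit in that case
  if (diff(range(x[anchors])) < 0.5 * diff(range(x))) return(fit)
  co <- stats::lm.fit(cbind(1, X[anchors, , drop = FALSE]),
                      s$intensity[anchors])
  drop(cbind(1, X) %*% co$coefficients)
}

#' Subtract a polynomial baseline
#'
#' Removes broad background (fluorescence, substrate drift) with the
#' iterative lower-envelope polynomial of [estimate_baseline()]. Applied
#' before any band-intensity extraction.
#'
#' @inheritParams estimate_baseline
#' @return The baseline-subtracted `raman_spectrum`.
#' @export
baseline_subtract <- function(s, poly_order = if (s$region == "FP") 5L else 3L,
                              anchor_quantile = 0.1) {
  bl <- estimate_baseline(s, poly_order = poly_order,
                          anchor_quantile = anchor_quantile)
  out <- s
  out$intensity <- s$intensity - bl
  out
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing by the standard Savitzky-Golay
#' convolution (default 11-point window, 3rd-order polynomial). The
#' filter reproduces any polynomial of degree <= `poly_order` exactly on
#' a uniform grid.
#'
#' @param s A `raman_spectrum`.
#' @param window_points Odd window length (> `poly_order`).
#' @param poly_order Polynomial order of the local fit.
#' @return The smoothed `raman_spectrum` (same length).
#' @export
smooth_savgol <- function(s, window_points = 11L, poly_order = 3L) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (window_points %% 2L == 0L)
    stop("window_points must be odd, got ", window_points)
  if (window_points <= poly_order)
    stop("window_points (", window_points,
         ") must exceed poly_order (", poly_order, ")")
  if (length(s$wavenumber) < window_points)
    stop("spectrum shorter than the smoothing window")
  out <- s
  out$intensity <- signal::sgolayfilt(s$intensity, p = poly_order,
                                      n = window_points)
  out
}

#' PCA denoising of a spectrum collection
#'
#' Projects mean-centered spectra onto their first `n_components`
#' principal components and reconstructs each spectrum from that
#' truncated basis, discarding the low-variability components that carry
#' mostly noise. With `n_components = n_spectra - 1` (full rank after
#' centering) the reconstruction is the identity.
#'
#' @param spectra List of `raman_spectrum` on an identical wavenumber
#'   axis; at least `n_components + 1` spectra.
#' @param n_components Number of components retained (default 3).
#' @return List of denoised `raman_spectrum` in the input order.
#' @export
pca_denoise <- function(spectra, n_components = 3L) {
  if (!length(spectra) || !all(vapply(spectra, inherits, TRUE, "raman_spectrum")))
    stop("spectra must be a non-empty list of raman_spectrum")
  if (n_components < 1L) stop("n_components must be >= 1")
  if (length(spectra) < n_components + 1L)
    stop("need at least n_components + 1 = ", n_components + 1L,
         " spectra, got ", length(spectra))
  .check_common_axis(spectra)
  X <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  k <- min(n_components, length(sv$d))
  Xhat <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  Xhat <- sweep(Xhat, 2L, mu, `+`)
  out <- spectra
  for (i in seq_along(out)) out[[i]]$intensity <- Xhat[i, ]
  out
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate acquisitions sharing region,
#' depth and treatment time; metadata is carried over from the first
#' replicate.
#'
#' @param spectra Non-empty list of `raman_spectrum` on an identical
#'   axis with matching region/depth/time.
#' @return The averaged `raman_spectrum`.
#' @export
average_replicates <- function(spectra) {
  if (!length(spectra) || !all(vapply(spectra, inherits, TRUE, "raman_spectrum")))
    stop("spectra must be a non-empty list of raman_spectrum")
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (s$region != ref$region)
      stop("grouping error: mixed regions (", ref$region, " vs ", s$region, ")")
    same_depth <- (is.na(s$depth_um) && is.na(ref$depth_um)) ||
      isTRUE(s$depth_um == ref$depth_um)
    if (!same_depth)
      stop("grouping error: mixed depths (", ref$depth_um, " vs ", s$depth_um, ")")
    same_time <- (is.na(s$time_s) && is.na(ref$time_s)) ||
      isTRUE(s$time_s == ref$time_s)
    if (!same_time)
      stop("grouping error: mixed treatment times (", ref$time_s, " vs ",
           s$time_s, ")")
  }
  .check_common_axis(spectra)
  out <- ref
  out$intensity <- rowMeans(vapply(spectra, `[[`,
                                   numeric(length(ref$intensity)), "intensity"))
  out
}

#' Extract a band intensity
#'
#' Returns the maximum (baseline-corrected) intensity inside the band
#' window, i.e. the peak height, together with the wavenumber at which it
#' occurs (attribute `"at_cm1"`). The spectrum is expected to be
#' baseline-subtracted already; no shape is assumed for the band.
#'
#' @param s A `raman_spectrum`.
#' @param band A `band_definition`.
#' @return Peak intensity (numeric scalar) with attribute `at_cm1`.
#' @export
band_intensity <- function(s, band) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(band, "band_definition"))
  lo <- band$center_cm1 - band$half_window_cm1
  hi <- band$center_cm1 + band$half_window_cm1
  sel <- s$wavenumber >= lo & s$wavenumber <= hi
  if (!any(sel))
    stop("window error: band ", band$label, " [", lo, ", ", hi,
         "] cm^-1 does not overlap the spectrum axis")
  i <- which(sel)[which.max(s$intensity[sel])]
  structure(s$intensity[i], at_cm1 = s$wavenumber[i])
}

#' Standard preprocessing chain
#'
#' Applies the canonical order baseline subtraction -> Savitzky-Golay
#' smoothing to one spectrum. PCA denoising operates across a spectrum
#' collection and is applied separately via [pca_denoise()].
#'
#' @param s A `raman_spectrum`.
#' @param baseline_order,anchor_quantile Baseline parameters, see
#'   [baseline_subtract()].
#' @param sg_window,sg_order Smoothing parameters, see [smooth_savgol()].
#' @return The preprocessed `raman_spectrum`.
#' @export
preprocess_spectrum <- function(s,
                                baseline_order = if (s$region == "FP") 5L else 3L,
                                anchor_quantile = 0.1,
                                sg_window = 11L, sg_order = 3L) {
  smooth_savgol(baseline_subtract(s, poly_order = baseline_order,
                                  anchor_quantile = anchor_quantile),
                window_points = sg_window, poly_order = sg_order)
}
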