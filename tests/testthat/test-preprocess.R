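test_that("a pure polynomial background is removed to numerical zero", {
  wn <- fp_grid()
  u <- (wn - 1100) / 700
  for (ord in c(1L, 3L, 5L)) {
    y <- 50 + 10 * u +
      (if (ord >= 3) -4 * u^2 + 2 * u^3 else 0) +
      (if (ord >= 5) 1.5 * u^5 else 0)
    s <- raman_spectrum(wn, y, region = "FP")
    out <- baseline_subtract(s, poly_order = ord)
    expect_lt(max(abs(out$intensity)), 1e-8 * max(abs(y)))
  }
})

test_that("a peak on a flat baseline keeps its amplitude after subtraction", {
  wn <- fp_grid()
  y <- 100 + gaussian_peak(wn, 1003, 8, 50)
  s <- raman_spectrum(wn, y, region = "FP")
  out <- baseline_subtract(s, poly_order = 1L)
  peak <- as.numeric(band_intensity(out, band_definition(1003, 15)))
  expect_lt(abs(peak - 50) / 50, 0.02)
})

test_that("baseline fitting rejects degenerate configurations", {
  s <- raman_spectrum(c(400, 401, 402), c(1, 2, 3), region = "FP")
  expect_error(baseline_subtract(s, poly_order = 5L), "degenerate")
  expect_error(baseline_subtract(flat_fp_spectrum(1), anchor_quantile = 0),
               "anchor_quantile")
})

test_that("HWN baselines are anchored on the signal-free edge margins", {
  wn <- hwn_grid()
  u <- (wn - 3200) / 600
  bl <- 6 - 1.6 * u + 0.8 * u^2
  y <- bl + gaussian_peak(wn, 3277, 80, 150) + gaussian_peak(wn, 2940, 20, 100)
  s <- raman_spectrum(wn, y, region = "HWN")
  est <- estimate_baseline(s)
  # the broad OH envelope must not be absorbed into the baseline
  expect_lt(max(abs(est - bl)), 0.05)
})

test_that("Savitzky-Golay reproduces polynomials and validates parameters", {
  wn <- fp_grid()
  y <- 2 + 0.01 * wn - 3e-6 * wn^2 + 1e-9 * wn^3
  s <- raman_spectrum(wn, y, region = "FP")
  sm <- smooth_savgol(s, 11L, 3L)
  expect_lt(max(abs(sm$intensity - y)) / max(abs(y)), 1e-10)
  expect_error(smooth_savgol(s, 10L, 3L), "odd")
  expect_error(smooth_savgol(s, 3L, 3L), "exceed")
})

test_that("Savitzky-Golay reduces white-noise variance", {
  set.seed(101)
  n_draw <- 1000L
  sd_in <- sd_out <- numeric(n_draw)
  wn <- seq(400, 600, by = 2)
  for (i in seq_len(n_draw)) {
    y <- 100 + rnorm(length(wn))
    s <- raman_spectrum(wn, y, region = "FP")
    sd_in[i] <- sd(y)
    sd_out[i] <- sd(smooth_savgol(s, 11L, 3L)$intensity)
  }
  expect_lt(mean(sd_out), mean(sd_in))
  expect_lt(mean(sd_out) / mean(sd_in), 0.8)
})

test_that("PCA reconstruction is the identity at full rank", {
  set.seed(7)
  spectra <- lapply(1:5, function(i) flat_fp_spectrum(0) |>
                      (\(s) { s$intensity <- rnorm(length(s$wavenumber)); s })())
  rec <- pca_denoise(spectra, n_components = 4L)
  for (i in seq_along(spectra))
    expect_equal(rec[[i]]$intensity, spectra[[i]]$intensity,
                 tolerance = 1e-8)
})

test_that("PCA denoising recovers a low-rank spectrum set to the noise floor", {
  set.seed(11)
  wn <- fp_grid()
  b1 <- gaussian_peak(wn, 900, 30, 1)
  b2 <- gaussian_peak(wn, 1400, 50, 1)
  mix <- matrix(runif(2 * 12), 12, 2)
  clean <- mix %*% rbind(b1, b2) * 100
  sigma <- 0.5
  spectra <- lapply(1:12, function(i)
    raman_spectrum(wn, clean[i, ] + sigma * rnorm(length(wn)), region = "FP"))
  rec <- pca_denoise(spectra, n_components = 2L)
  err <- vapply(1:12, function(i)
    sqrt(mean((rec[[i]]$intensity - clean[i, ])^2)), numeric(1))
  expect_lt(max(err), sigma)  # reconstruction error at or below noise floor
})

test_that("PCA requires enough spectra and a shared axis", {
  spectra <- lapply(1:2, function(i) flat_fp_spectrum(i))
  expect_error(pca_denoise(spectra, n_components = 3L), "at least")
})

test_that("replicate averaging is the pointwise mean with metadata checks", {
  s <- flat_fp_spectrum(1, depth_um = 50, time_s = 30)
  s$intensity <- gaussian_peak(s$wavenumber, 1003, 6, 3)
  s3 <- s; s3$intensity <- 3 * s$intensity
  expect_equal(average_replicates(list(s))$intensity, s$intensity)
  expect_equal(average_replicates(list(s, s3))$intensity, 2 * s$intensity)
  hw <- hwn_sum_spectrum(depth_um = 50, time_s = 30)
  expect_error(average_replicates(list(s, hw)), "mixed regions")
  s_deep <- flat_fp_spectrum(1, depth_um = 100, time_s = 30)
  expect_error(average_replicates(list(s, s_deep)), "mixed depths")
})

test_that("averaging commutes with linear smoothing", {
  set.seed(3)
  spectra <- lapply(1:4, function(i) {
    s <- flat_fp_spectrum(10, depth_um = 50)
    s$intensity <- s$intensity + rnorm(length(s$wavenumber))
    s
  })
  smooth_then_avg <- average_replicates(lapply(spectra, smooth_savgol))
  avg_then_smooth <- smooth_savgol(average_replicates(spectra))
  expect_equal(smooth_then_avg$intensity, avg_then_smooth$intensity,
               tolerance = 1e-12)
})

test_that("band intensity is the windowed peak maximum with its position", {
  wn <- fp_grid()
  s <- raman_spectrum(wn, gaussian_peak(wn, 485, 6, 7), region = "FP")
  v <- band_intensity(s, band_definition(485, 10))
  expect_equal(as.numeric(v), 7, tolerance = 1e-6)
  expect_equal(attr(v, "at_cm1"), 485)
  expect_equal(as.numeric(band_intensity(flat_fp_spectrum(0),
                                         band_definition(485, 10))), 0)
  expect_error(band_intensity(flat_fp_spectrum(0), band_definition(2000, 10)),
               "window error")
  expect_error(band_definition(485, -1), "must be > 0")
})

test_that("the full preprocessing chain perturbs band heights by < 2%", {
  wn <- fp_grid()
  u <- (wn - 1100) / 700
  y <- (40 - 10 * u + 5 * u^2) +
    gaussian_peak(wn, 485, 6, 25) + gaussian_peak(wn, 938, 6, 40) +
    gaussian_peak(wn, 1665, 6, 60)
  s <- raman_spectrum(wn, y, region = "FP")
  out <- preprocess_spectrum(s)
  for (spec in list(c(485, 25), c(938, 40), c(1665, 60))) {
    got <- as.numeric(band_intensity(out, band_definition(spec[1], 10)))
    expect_lt(abs(got - spec[2]) / spec[2], 0.02)
  }
})
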