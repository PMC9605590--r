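test_that("component areas follow the closed form and a quadrature oracle", {
  g <- gaussian_component(3005, 1, 1, "water_tight_3005")
  expect_equal(component_auc(g), sqrt(2 * pi), tolerance = 1e-12)
  g0 <- gaussian_component(3277, 10, 0, "water_strong_3277")
  expect_equal(component_auc(g0), 0)
  # numerical integral over +/- 8 sigma as an independent check
  g2 <- gaussian_component(3458, 10, 2, "water_weak_3458")
  x <- seq(3458 - 80, 3458 + 80, length.out = 20001)
  y <- 2 * exp(-(x - 3458)^2 / (2 * 100))
  quad <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  expect_equal(component_auc(g2), quad, tolerance = 1e-6)
})

test_that("component construction enforces role bounds", {
  expect_error(gaussian_component(3005, -1, 1, "water_tight_3005"),
               "sigma")
  expect_error(gaussian_component(3005, 1, -1, "water_tight_3005"),
               "amplitude")
  expect_error(gaussian_component(3020, 10, 1, "water_tight_3005"),
               "bound")
  expect_error(gaussian_component(3005, 10, 1, "water_3005"), "unknown role")
})

test_that("noise-free ten-Gaussian spectra deconvolve to the exact areas", {
  truth <- hwn_truth()
  s <- hwn_sum_spectrum(truth)
  fit <- deconvolve_hwn(s)
  expect_length(fit, 10L)
  expect_true(attr(fit, "converged"))
  auc <- vapply(fit, component_auc, numeric(1))
  names(auc) <- vapply(fit, `[[`, character(1), "role")
  rel <- abs(auc[truth$components$role] / truth$auc - 1)
  expect_lt(max(rel), 0.02)
  # sorted by center
  cen <- vapply(fit, `[[`, numeric(1), "center_cm1")
  expect_false(is.unsorted(cen))
})

test_that("zero water amplitudes stay at zero while protein is recovered", {
  truth <- hwn_truth(ratios = c(tight = 0, strong = 0, weak = 0, free = 0))
  s <- hwn_sum_spectrum(truth)
  fit <- deconvolve_hwn(s)
  p <- water_profile(fit)
  expect_lt(p$total_water, 0.01)
  auc <- vapply(fit, component_auc, numeric(1))
  names(auc) <- vapply(fit, `[[`, character(1), "role")
  expect_equal(unname(auc["protein_2940"]),
               unname(truth$auc[truth$components$role == "protein_2940"]),
               tolerance = 0.02)
})

test_that("noisy deconvolution keeps median ratio errors within 5%", {
  set.seed(77)
  n_rep <- 12L
  errs <- matrix(NA_real_, n_rep, 4L)
  for (i in seq_len(n_rep)) {
    # amplitudes drawn across the observed ratio ranges
    ratios <- c(tight = runif(1, 0.1, 0.25), strong = runif(1, 3, 7),
                weak = runif(1, 1.5, 3.5), free = runif(1, 0.3, 1.3))
    truth <- hwn_truth(ratios)
    s <- hwn_sum_spectrum(truth, noise_cv = 0.02)
    p <- water_profile(deconvolve_hwn(s))
    errs[i, ] <- abs(c(p$tight, p$strong, p$weak, p$free) / ratios - 1)
  }
  expect_lt(median(errs), 0.05)
})

test_that("deconvolution validates region and coverage", {
  expect_error(deconvolve_hwn(flat_fp_spectrum(1)), "HWN")
  wn <- seq(2800, 3300, by = 1)
  s <- raman_spectrum(wn, rep(1, length(wn)), region = "HWN")
  expect_error(deconvolve_hwn(s), "coverage error")
})

test_that("water profiles normalize to protein and obey the sum rule", {
  truth <- hwn_truth()
  comps <- lapply(seq_len(nrow(truth$components)), function(i) {
    gaussian_component(truth$components$center_cm1[i],
                       truth$components$sigma_cm1[i],
                       truth$amplitudes[i], truth$components$role[i])
  })
  p <- water_profile(comps, depth_um = 50, time_s = NA)
  expect_equal(p$tight, 0.20, tolerance = 1e-10)
  expect_equal(p$strong, 6.00, tolerance = 1e-10)
  expect_equal(p$weak, 3.49, tolerance = 1e-10)
  expect_equal(p$free, 0.73, tolerance = 1e-10)
  # the untreated 50 um ratios sum to a total water content of 10.42
  expect_equal(p$total_water, 10.42, tolerance = 1e-10)
  expect_equal(p$total_water, p$tight + p$strong + p$weak + p$free,
               tolerance = 1e-10)
})

test_that("profile ratios are invariant under global rescaling", {
  truth <- hwn_truth()
  mk <- function(scale) {
    comps <- lapply(seq_len(nrow(truth$components)), function(i) {
      gaussian_component(truth$components$center_cm1[i],
                         truth$components$sigma_cm1[i],
                         scale * truth$amplitudes[i],
                         truth$components$role[i])
    })
    water_profile(comps)
  }
  p1 <- mk(1); p2 <- mk(7.3)
  expect_equal(p2$total_water, p1$total_water, tolerance = 1e-12)
  expect_equal(p2$strong, p1$strong, tolerance = 1e-12)
})

test_that("a zero protein line raises a normalization error", {
  truth <- hwn_truth()
  comps <- lapply(seq_len(nrow(truth$components)), function(i) {
    amp <- if (truth$components$role[i] == "protein_2940") 0
           else truth$amplitudes[i]
    gaussian_component(truth$components$center_cm1[i],
                       truth$components$sigma_cm1[i], amp,
                       truth$components$role[i])
  })
  expect_error(water_profile(comps), "normalization error")
})

test_that("kinetics tables summarize before/after and flag single points", {
  mk_profile <- function(t, f) {
    truth <- hwn_truth(ratios = c(tight = 0.2 * f, strong = 6 * f,
                                  weak = 3.49 * f, free = 0.73 * f))
    comps <- lapply(seq_len(nrow(truth$components)), function(i)
      gaussian_component(truth$components$center_cm1[i],
                         truth$components$sigma_cm1[i],
                         truth$amplitudes[i], truth$components$role[i]))
    water_profile(comps, depth_um = 50, time_s = t)
  }
  flat <- lapply(c(NA, 30, 60, 90), mk_profile, f = 1)
  wk <- water_kinetics(flat, after_time_s = 90)
  expect_true(wk$sufficient)
  expect_equal(wk$summary$before, wk$summary$after, tolerance = 1e-10)
  by_state <- split(wk$kinetics$ratio, wk$kinetics$state)
  for (v in by_state) expect_lt(diff(range(v)), 1e-10)

  # monotone synthetic dehydration is reflected in the summary ordering
  decay <- lapply(list(list(NA, 1), list(30, 0.8), list(60, 0.7),
                       list(90, 0.6)),
                  function(z) mk_profile(z[[1]], z[[2]]))
  wk2 <- water_kinetics(decay, after_time_s = 90)
  expect_true(all(wk2$summary$after < wk2$summary$before))

  single <- water_kinetics(list(mk_profile(NA, 1)), after_time_s = 90)
  expect_false(single$sufficient)
  expect_equal(nrow(single$summary), 5L)
})
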