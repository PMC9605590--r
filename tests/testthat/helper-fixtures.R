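# shared fixture builders: everything is generated in code at test time

fp_grid <- function(step = 1) seq(400, 1800, by = step)
hwn_grid <- function(step = 1) seq(2600, 3800, by = step)

gaussian_peak <- function(wn, center, sigma, amplitude) {
  amplitude * exp(-(wn - center)^2 / (2 * sigma^2))
}

flat_fp_spectrum <- function(level = 0, step = 1, ...) {
  wn <- fp_grid(step)
  raman_spectrum(wn, rep(level, length(wn)), region = "FP", ...)
}

# the nominal ten-component HWN synthesis used across water-state tests:
# water amplitudes derived from protein-normalized AUC ratios
hwn_truth <- function(ratios = c(tight = 0.20, strong = 6.00, weak = 3.49,
                                 free = 0.73),
                      protein_amp = 100) {
  comps <- hwn_components()
  roles_w <- c(tight = "water_tight_3005", strong = "water_strong_3277",
               weak = "water_weak_3458", free = "water_free_3604")
  rel <- c(lipid_protein_2850 = 0.8, lipid_protein_2880 = 0.9,
           protein_2940 = 1, lipid_protein_2980 = 0.4,
           NH_3060 = 0.3, NH_3330 = 0.4)
  sig_prot <- comps$sigma_cm1[comps$role == "protein_2940"]
  amps <- vapply(seq_len(nrow(comps)), function(i) {
    role <- comps$role[i]
    if (role %in% names(rel)) protein_amp * rel[[role]]
    else ratios[[names(roles_w)[roles_w == role]]] * protein_amp * sig_prot /
      comps$sigma_cm1[i]
  }, numeric(1))
  list(components = comps, amplitudes = amps,
       auc = amps * comps$sigma_cm1 * sqrt(2 * pi), ratios = ratios)
}

hwn_sum_spectrum <- function(truth = hwn_truth(), noise_cv = 0, step = 1,
                             ...) {
  wn <- hwn_grid(step)
  y <- numeric(length(wn))
  for (i in seq_len(nrow(truth$components))) {
    y <- y + gaussian_peak(wn, truth$components$center_cm1[i],
                           truth$components$sigma_cm1[i],
                           truth$amplitudes[i])
  }
  if (noise_cv > 0) y <- y * (1 + noise_cv * rnorm(length(y)))
  raman_spectrum(wn, y, region = "HWN", ...)
}

# write a two-column text spectrum file, returning its path
write_tmp_spectrum_file <- function(lines, dir = tempdir()) {
  path <- tempfile("spec", tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}
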