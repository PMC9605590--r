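#' Specification of a synthetic clearing experiment
#'
#' Bundles every generative parameter for a simulated optical-clearing
#' measurement: the depth and time design, the true diffusion parameters
#' per depth, the clearing-gain trajectory, band shapes and responses,
#' baseline drift and the noise model. All randomness in the generators
#' flows from `seed`, so a given spec always produces bit-identical
#' data.
#'
#' Defaults encode the study conditions the pipeline targets: four
#' depths (50--200 um), spectra every 30 s from 0 to 390 s (14 time
#' points), per-depth `(D, C0)` equal to the per-depth averages of the
#' reference measurement (9.6e-6 to 3.0e-5 cm^2/s; 20 down to 0.6 %),
#' a 50% surface application, 2% multiplicative noise, and a saturating
#' clearing gain `g(t) = 1 + (g_max - 1)(1 - exp(-t/tau))` with plateau
#' 2 and rise time 60 s. As in the emulated measurement design, four
#' replicate samples are recorded per fingerprint acquisition and six
#' per high-wavenumber acquisition; the analysis averages replicates
#' before band extraction.
#'
#' @param seed Integer seed driving all generator randomness.
#' @param depths_um Probing depths, micrometres.
#' @param times_s Acquisition times, seconds (starting at 0).
#' @param true_D Per-depth diffusion coefficients, cm^2/s (recycled).
#' @param true_C0 Per-depth saturation concentrations, percent.
#' @param oc_gmax,oc_tau_s Clearing-gain plateau and rise time.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param noise_floor Additive noise standard deviation, counts.
#' @param gly_response Glycerol 485 cm^-1 peak response, counts per %.
#' @param collagen_amp Named peak heights of the collagen reference
#'   bands, counts.
#' @param band_sigma_cm1 Gaussian width (sigma) of fingerprint bands.
#' @param n_replicates_fp,n_replicates_hwn Replicate samples per
#'   acquisition in the two regions.
#' @param baseline_coef Polynomial baseline coefficients on the
#'   normalized axis (constant, linear, quadratic, ...).
#' @param grid_step_cm1 Wavenumber grid spacing.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L,
                       depths_um = c(50, 100, 150, 200),
                       times_s = seq(0, 390, by = 30),
                       true_D = c(9.6e-6, 1.2e-5, 2.2e-5, 3.0e-5),
                       true_C0 = c(20, 2.9, 1.6, 0.6),
                       oc_gmax = 2, oc_tau_s = 60,
                       noise_cv = 0.02, noise_floor = 0.05,
                       gly_response = 5,
                       collagen_amp = c(`938` = 40, `1003` = 55, `1247` = 35,
                                        `1270` = 30, `1665` = 60),
                       band_sigma_cm1 = 6,
                       baseline_coef = c(30, -8, 4),
                       grid_step_cm1 = 1,
                       n_replicates_fp = 4L, n_replicates_hwn = 6L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(true_D <= 0)) stop("true_D must be > 0")
  if (oc_gmax < 1) stop("oc_gmax must be >= 1 for a clearing scenario")
  true_D <- rep_len(true_D, length(depths_um))
  true_C0 <- rep_len(true_C0, length(depths_um))
  structure(list(seed = as.integer(seed), depths_um = depths_um,
                 times_s = times_s, true_D = true_D, true_C0 = true_C0,
                 oc_gmax = oc_gmax, oc_tau_s = oc_tau_s,
                 noise_cv = noise_cv, noise_floor = noise_floor,
                 gly_response = gly_response, collagen_amp = collagen_amp,
                 band_sigma_cm1 = band_sigma_cm1,
                 baseline_coef = baseline_coef,
                 grid_step_cm1 = grid_step_cm1,
                 n_replicates_fp = as.integer(n_replicates_fp),
                 n_replicates_hwn = as.integer(n_replicates_hwn)),
            class = "synth_spec")
}

#' Saturating clearing-gain trajectory
#'
#' `g(t) = 1 + (g_max - 1)(1 - exp(-t / tau))`: no gain at application,
#' monotone rise, plateau `g_max`. The simplest family reproducing the
#' observed depth-resolved collagen-band intensity rises.
#'
#' @param t_s Time, seconds (vectorized).
#' @param gmax Plateau gain (>= 1).
#' @param tau_s Rise time, seconds.
#' @return Gain factor(s) >= 1.
#' @export
oc_gain <- function(t_s, gmax = 2, tau_s = 60) {
  1 + (gmax - 1) * (1 - exp(-as.numeric(t_s) / tau_s))
}

.fp_grid <- function(spec) seq(400, 1800, by = spec$grid_step_cm1)
.hwn_grid <- function(spec) seq(2600, 3800, by = spec$grid_step_cm1)

.poly_baseline <- function(wn, coef) {
  u <- (wn - mean(range(wn))) / (diff(range(wn)) / 2)
  drop(outer(u, seq_along(coef) - 1, `^`) %*% coef)
}

.add_noise <- function(y, spec) {
  y * (1 + spec$noise_cv * stats::rnorm(length(y))) +
    spec$noise_floor * stats::rnorm(length(y))
}

# glycerol fingerprint bands: relative peak heights vs the 485 cm^-1 band
.gly_rel <- c(`485` = 1, `849` = 0.7, `1054` = 0.8, `1466` = 0.5)

.fp_signal <- function(wn, spec, gly485_amp, oc = 1) {
  y <- numeric(length(wn))
  for (b in names(spec$collagen_amp)) {
    y <- y + oc * spec$collagen_amp[[b]] *
      exp(-(wn - as.numeric(b))^2 / (2 * spec$band_sigma_cm1^2))
  }
  for (b in names(.gly_rel)) {
    y <- y + gly485_amp * .gly_rel[[b]] *
      exp(-(wn - as.numeric(b))^2 / (2 * spec$band_sigma_cm1^2))
  }
  y + .poly_baseline(wn, spec$baseline_coef)
}

#' Generate a glycerol calibration series
#'
#' Fingerprint spectra of glycerol-in-water standards whose 485 cm^-1
#' peak height is linear in volume fraction (`gly_response` counts per
#' percent), with the configured baseline and noise.
#'
#' @param spec A `synth_spec`.
#' @param n_standards Number of standards (>= 3), spread evenly over
#'   0--50 %.
#' @return List with `concentration_pct` (numeric) and `spectra` (list
#'   of `raman_spectrum`).
#' @export
synth_calibration_series <- function(spec, n_standards = 15L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (n_standards < 3L)
    stop("need at least 3 calibration standards, got ", n_standards)
  conc <- seq(0, 50, length.out = n_standards)
  wn <- .fp_grid(spec)
  spectra <- withr::with_seed(spec$seed + 101L, lapply(conc, function(cc) {
    y <- numeric(length(wn))
    for (b in names(.gly_rel)) {
      y <- y + spec$gly_response * cc * .gly_rel[[b]] *
        exp(-(wn - as.numeric(b))^2 / (2 * spec$band_sigma_cm1^2))
    }
    y <- y + .poly_baseline(wn, spec$baseline_coef)
    raman_spectrum(wn, .add_noise(y, spec), region = "FP",
                   sample_id = sprintf("cal_%04.1fpct", cc))
  }))
  list(concentration_pct = conc, spectra = spectra)
}

#' Generate a fingerprint depth/time clearing experiment
#'
#' For every depth and time the collagen band heights are the untreated
#' heights times the clearing gain `g(t)`, and the glycerol 485 cm^-1
#' height is `gly_response x C(x, t) x g(t)` with `C(x, t)` the erfc
#' profile for that depth's true `(D, C0)` — i.e. the deep glycerol
#' signal is inflated by the clearing of overlying layers exactly as in
#' the measurement, which is the crosstalk the TRGC correction removes.
#' Each depth also gets an untreated reference (gain 1, zero glycerol,
#' `time_s` NA).
#'
#' @param spec A `synth_spec`.
#' @param oc_gmax Override of the spec's clearing plateau (e.g. 1 for a
#'   no-clearing control run).
#' @return List with `spectra` (list of `raman_spectrum`), `manifest`
#'   (`data.frame`) and `truth` (per-depth `D`, `C0`, gain parameters).
#' @export
synth_fp_experiment <- function(spec, oc_gmax = spec$oc_gmax) {
  stopifnot(inherits(spec, "synth_spec"))
  wn <- .fp_grid(spec)
  spectra <- list(); rows <- list()
  withr::with_seed(spec$seed + 202L, {
    for (di in seq_along(spec$depths_um)) {
      d <- spec$depths_um[di]
      x_cm <- d * 1e-4
      y0 <- .fp_signal(wn, spec, gly485_amp = 0, oc = 1)
      for (r in seq_len(spec$n_replicates_fp)) {
        spectra[[length(spectra) + 1L]] <- raman_spectrum(
          wn, .add_noise(y0, spec), region = "FP", depth_um = d,
          time_s = NA_real_,
          sample_id = sprintf("d%03.0f_untreated_r%d", d, r))
        rows[[length(rows) + 1L]] <- data.frame(depth_um = d,
                                                time_s = NA_real_,
                                                replicate = r)
      }
      for (t in spec$times_s) {
        g <- oc_gain(t, gmax = oc_gmax, tau_s = spec$oc_tau_s)
        cc <- concentration_profile(spec$true_C0[di], spec$true_D[di],
                                    x_cm, t)
        y <- .fp_signal(wn, spec, gly485_amp = spec$gly_response * cc * g,
                        oc = g)
        for (r in seq_len(spec$n_replicates_fp)) {
          spectra[[length(spectra) + 1L]] <- raman_spectrum(
            wn, .add_noise(y, spec), region = "FP", depth_um = d,
            time_s = t, sample_id = sprintf("d%03.0f_t%03.0f_r%d", d, t, r))
          rows[[length(rows) + 1L]] <- data.frame(depth_um = d, time_s = t,
                                                  replicate = r)
        }
      }
    }
  })
  list(spectra = spectra, manifest = do.call(rbind, rows),
       truth = list(depths_um = spec$depths_um, D = spec$true_D,
                    C0 = spec$true_C0, oc_gmax = oc_gmax,
                    oc_tau_s = spec$oc_tau_s))
}

#' Default water-state relaxation trajectories
#'
#' Before/after normalized ratios per depth and water state, relaxing
#' exponentially from the untreated value to the post-treatment plateau
#' with rise time `tau_s` (so the plateau is effectively reached by the
#' 90 s summary time). The values span the observed range in cleared
#' collagenous tissue: strong and weak states dominant and strongly
#' reduced by dehydration, tight nearly constant, free small and
#' roughly halved.
#'
#' @param depths_um Depths to cover.
#' @param tau_s Relaxation time, seconds.
#' @return `data.frame` with `depth_um`, `state`, `before`, `after`,
#'   `tau_s`.
#' @export
default_water_trajectories <- function(depths_um = c(50, 100, 150, 200),
                                       tau_s = 30) {
  base <- data.frame(
    depth_um = rep(c(50, 100, 150, 200), each = 4),
    state = rep(c("tight", "strong", "weak", "free"), times = 4),
    before = c(0.20, 6.00, 3.49, 0.73,
               0.13, 4.57, 2.47, 0.61,
               0.22, 4.60, 2.41, 0.82,
               0.18, 6.53, 3.24, 1.27),
    after = c(0.12, 4.12, 2.18, 0.48,
              0.15, 3.42, 1.80, 0.36,
              0.19, 3.58, 1.70, 0.53,
              0.177, 4.44, 2.15, 0.66))
  out <- base[base$depth_um %in% depths_um, , drop = FALSE]
  if (!nrow(out)) stop("no default trajectories for the requested depths")
  out$tau_s <- tau_s
  rownames(out) <- NULL
  out
}

# non-water HWN component amplitudes relative to the protein 2940 line
.hwn_rel <- c(lipid_protein_2850 = 0.8, lipid_protein_2880 = 0.9,
              protein_2940 = 1.0, lipid_protein_2980 = 0.4,
              NH_3060 = 0.3, NH_3330 = 0.4)

#' Generate a high-wavenumber water-kinetics experiment
#'
#' Sum-of-ten-Gaussian HWN spectra at each depth/time with water-state
#' amplitudes following the supplied ratio trajectories (normalized to
#' the 2940 cm^-1 protein area), plus non-water components, baseline and
#' noise. Each depth also gets an untreated reference at the "before"
#' ratios.
#'
#' @param spec A `synth_spec`.
#' @param trajectories Ratio trajectories as produced by
#'   [default_water_trajectories()].
#' @param protein_amp Protein 2940 cm^-1 peak height, counts.
#' @return List with `spectra`, `manifest` and `truth` (the trajectory
#'   table plus a `ratio_at(depth, t)` function).
#' @export
synth_hwn_experiment <- function(spec,
                                 trajectories =
                                   default_water_trajectories(spec$depths_um),
                                 protein_amp = 100) {
  stopifnot(inherits(spec, "synth_spec"))
  if (protein_amp <= 0)
    stop("normalization error: protein amplitude must be > 0")
  comps <- hwn_components()
  wn <- .hwn_grid(spec)
  sig_prot <- comps$sigma_cm1[comps$role == "protein_2940"]
  ratio_at <- function(depth_um, t_s) {
    tr <- trajectories[trajectories$depth_um == depth_um, , drop = FALSE]
    if (!nrow(tr)) stop("no trajectory for depth ", depth_um)
    r <- tr$after + (tr$before - tr$after) *
      (if (is.na(t_s)) 1 else exp(-t_s / tr$tau_s))
    stats::setNames(r, tr$state)
  }
  build <- function(depth_um, t_s) {
    ratios <- ratio_at(depth_um, t_s)
    y <- numeric(length(wn))
    for (i in seq_len(nrow(comps))) {
      role <- comps$role[i]
      amp <- if (role %in% names(.hwn_rel)) {
        protein_amp * .hwn_rel[[role]]
      } else {
        state <- names(.water_roles)[.water_roles == role]
        # ratio is AUC_water / AUC_protein; convert to a peak height
        ratios[[state]] * protein_amp * sig_prot / comps$sigma_cm1[i]
      }
      y <- y + amp * exp(-(wn - comps$center_cm1[i])^2 /
                           (2 * comps$sigma_cm1[i]^2))
    }
    y + .poly_baseline(wn, spec$baseline_coef * 0.2)
  }
  spectra <- list(); rows <- list()
  withr::with_seed(spec$seed + 303L, {
    for (d in spec$depths_um) {
      y_ref <- build(d, NA)
      for (r in seq_len(spec$n_replicates_hwn)) {
        spectra[[length(spectra) + 1L]] <- raman_spectrum(
          wn, .add_noise(y_ref, spec), region = "HWN", depth_um = d,
          time_s = NA_real_,
          sample_id = sprintf("hwn_d%03.0f_untreated_r%d", d, r))
        rows[[length(rows) + 1L]] <- data.frame(depth_um = d,
                                                time_s = NA_real_,
                                                replicate = r)
      }
      for (t in spec$times_s) {
        y_t <- build(d, t)
        for (r in seq_len(spec$n_replicates_hwn)) {
          spectra[[length(spectra) + 1L]] <- raman_spectrum(
            wn, .add_noise(y_t, spec), region = "HWN", depth_um = d,
            time_s = t,
            sample_id = sprintf("hwn_d%03.0f_t%03.0f_r%d", d, t, r))
          rows[[length(rows) + 1L]] <- data.frame(depth_um = d, time_s = t,
                                                  replicate = r)
        }
      }
    }
  })
  list(spectra = spectra, manifest = do.call(rbind, rows),
       truth = list(trajectories = trajectories, ratio_at = ratio_at,
                    protein_amp = protein_amp))
}

#' Write a synthetic dataset to disk
#'
#' Writes every spectrum as a two-column text file plus the manifest CSV
#' that [read_spectra_manifest()] consumes, and the generating spec as
#' YAML.
#'
#' @param experiment Result of [synth_fp_experiment()] or
#'   [synth_hwn_experiment()].
#' @param dir Output directory (created if needed).
#' @param spec The generating `synth_spec` (serialized alongside).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_synthetic_dataset <- function(experiment, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(experiment$spectra, function(s) {
    fname <- paste0(s$sample_id, ".txt")
    write_spectrum(s, file.path(dir, fname))
    data.frame(path = fname, region = s$region, depth_um = s$depth_um,
               time_s = if (is.na(s$time_s)) "untreated" else s$time_s,
               sample_id = s$sample_id)
  })
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), man, row.names = FALSE)
  if (!is.null(spec))
    yaml::write_yaml(unclass(spec), file.path(dir, "synth_spec.yaml"))
  invisible(man)
}
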