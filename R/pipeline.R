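#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the standard
#' defaults: baseline order 5 (FP) / 3 (HWN), Savitzky-Golay 11-point
#' 3rd-order smoothing, 3 PCA components (denoising off by default and
#' grouped per depth when on), the five collagen reference bands and the
#' glycerol 485 cm^-1 quantification band with +/- 10 cm^-1 windows,
#' diffusion-fit bounds/starts, and the 90 s before/after summary time.
#'
#' @param baseline_order_fp,baseline_order_hwn Baseline polynomial
#'   orders.
#' @param anchor_quantile Baseline anchor fraction.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param pca_components PCA components kept when denoising.
#' @param use_pca Apply PCA denoising across each depth's time series.
#' @param band_half_window_cm1 Extraction half-width.
#' @param d_starts,d_bounds,c0_bounds Diffusion-fit multistart grid and
#'   bounds.
#' @param after_time_s Before/after summary time for water states.
#' @param seed Seed recorded with the run.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(baseline_order_fp = 5L, baseline_order_hwn = 3L,
                            anchor_quantile = 0.1,
                            sg_window = 11L, sg_order = 3L,
                            pca_components = 3L, use_pca = FALSE,
                            band_half_window_cm1 = 10,
                            d_starts = c(1e-6, 1e-5, 1e-4),
                            d_bounds = c(1e-8, 1e-3),
                            c0_bounds = c(0, 60),
                            after_time_s = 90, seed = 1L) {
  if (sg_window %% 2L == 0L || sg_window <= sg_order)
    stop("sg_window must be odd and exceed sg_order")
  if (anchor_quantile <= 0 || anchor_quantile > 1)
    stop("anchor_quantile must lie in (0, 1]")
  if (pca_components < 1L) stop("pca_components must be >= 1")
  if (band_half_window_cm1 <= 0) stop("band_half_window_cm1 must be > 0")
  if (d_bounds[1L] <= 0 || d_bounds[2L] <= d_bounds[1L])
    stop("d_bounds must be increasing and positive")
  structure(list(baseline_order_fp = baseline_order_fp,
                 baseline_order_hwn = baseline_order_hwn,
                 anchor_quantile = anchor_quantile,
                 sg_window = sg_window, sg_order = sg_order,
                 pca_components = pca_components, use_pca = use_pca,
                 band_half_window_cm1 = band_half_window_cm1,
                 d_starts = d_starts, d_bounds = d_bounds,
                 c0_bounds = c0_bounds, after_time_s = after_time_s,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown fields raise an error naming the field, so typos in a config
#' file fail loudly.
#'
#' @param path YAML file with any subset of [pipeline_config()]'s
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, obj)
}

# average replicate acquisitions sharing depth/time, then return one
# spectrum per (depth, time) group, untreated groups first
.average_by_time <- function(spectra) {
  keys <- vapply(spectra, function(s)
    if (is.na(s$time_s)) "untreated" else format(s$time_s), character(1L))
  lapply(split(spectra, keys), average_replicates)
}

.preprocess_group <- function(spectra, config) {
  region <- spectra[[1L]]$region
  ord <- if (region == "FP") config$baseline_order_fp else config$baseline_order_hwn
  out <- lapply(spectra, function(s) {
    preprocess_spectrum(s, baseline_order = ord,
                        anchor_quantile = config$anchor_quantile,
                        sg_window = config$sg_window,
                        sg_order = config$sg_order)
  })
  if (isTRUE(config$use_pca) && length(out) >= config$pca_components + 1L)
    out <- pca_denoise(out, n_components = config$pca_components)
  out
}

#' Fit the calibration from standard spectra
#'
#' Preprocesses each standard with the full chain and fits the 485
#' cm^-1 line, so calibration and experiment intensities go through
#' identical preprocessing.
#'
#' @param concentration_pct Standard concentrations, percent.
#' @param spectra Standard spectra (list of `raman_spectrum`).
#' @param config A `pipeline_config`.
#' @return A `calibration_model`.
#' @export
run_calibrate <- function(concentration_pct, spectra,
                          config = pipeline_config()) {
  pre <- lapply(spectra, function(s) {
    preprocess_spectrum(s, baseline_order = config$baseline_order_fp,
                        anchor_quantile = config$anchor_quantile,
                        sg_window = config$sg_window,
                        sg_order = config$sg_order)
  })
  fit_calibration(concentration_pct, pre,
                  band = band_definition(485, config$band_half_window_cm1,
                                         "glycerol 485"),
                  preprocess = FALSE)
}

#' Analyze a fingerprint clearing experiment
#'
#' Full chain from raw depth/time spectra to the per-depth diffusion
#' report: preprocessing, band-intensity extraction, clearing-efficiency
#' correction per collagen reference band, calibration to
#' concentration, per-band erfc diffusion fits and per-depth averages.
#'
#' @param spectra List of FP `raman_spectrum` covering one or more
#'   depths, each depth with an untreated reference (`time_s` NA) and a
#'   treated time series.
#' @param calibration A `calibration_model`.
#' @param config A `pipeline_config`.
#' @return List with `table` (tidy kinetics `data.frame`), `fits`
#'   (per depth: list of `diffusion_fit_result` per band), `summaries`
#'   (per depth `depth_summary`) and `report` (band x depth table with
#'   Average rows).
#' @export
analyze_fp_experiment <- function(spectra, calibration,
                                  config = pipeline_config()) {
  stopifnot(inherits(calibration, "calibration_model"))
  depths <- sort(unique(vapply(spectra, `[[`, numeric(1L), "depth_um")))
  gly_band <- band_definition(485, config$band_half_window_cm1,
                              "glycerol 485")
  ref_bands <- collagen_bands(config$band_half_window_cm1)
  trgc_by_depth <- list(); gly_by_depth <- list()
  fits <- list(); summaries <- list()
  for (d in depths) {
    grp <- spectra[vapply(spectra, function(s) isTRUE(s$depth_um == d), TRUE)]
    pre <- .preprocess_group(unname(.average_by_time(grp)), config)
    untreated <- pre[vapply(pre, is_untreated, TRUE)]
    treated <- pre[!vapply(pre, is_untreated, TRUE)]
    if (!length(untreated))
      stop("depth ", d, " um has no untreated reference spectrum")
    if (length(treated) < 2L)
      stop("depth ", d, " um has fewer than 2 treated time points")
    ref <- average_replicates(untreated)
    tt <- vapply(treated, `[[`, numeric(1L), "time_s")
    treated <- treated[order(tt)]; tt <- sort(tt)
    i0 <- vapply(ref_bands, function(b) as.numeric(band_intensity(ref, b)),
                 numeric(1L))
    gly_series <- band_time_series(
      d, gly_band, tt,
      vapply(treated, function(s) as.numeric(band_intensity(s, gly_band)),
             numeric(1L)),
      kind = "raw")
    collagen_series <- lapply(ref_bands, function(b) {
      band_time_series(
        d, b, tt,
        vapply(treated, function(s) as.numeric(band_intensity(s, b)),
               numeric(1L)),
        kind = "raw")
    })
    tser <- build_trgc_series(gly_series, collagen_series, as.list(i0),
                              calibration)
    trgc_by_depth[[as.character(d)]] <- tser
    gly_by_depth[[as.character(d)]] <- gly_series
    dfits <- lapply(tser, function(ser) {
      fit_diffusion(ser, d_starts = config$d_starts,
                    lower = c(config$d_bounds[1L], config$c0_bounds[1L]),
                    upper = c(config$d_bounds[2L], config$c0_bounds[2L]))
    })
    fits[[as.character(d)]] <- dfits
    summaries[[as.character(d)]] <- summarize_depth(unname(dfits))
  }
  list(table = clearing_table(trgc_by_depth, gly_by_depth),
       trgc = trgc_by_depth, fits = fits, summaries = summaries,
       report = diffusion_report(unname(summaries)))
}

#' Analyze a high-wavenumber water-states experiment
#'
#' Preprocesses each depth's HWN time series, deconvolves every
#' spectrum into the ten Gaussian components, and assembles the
#' water-state kinetics and before/after summary.
#'
#' @param spectra List of HWN `raman_spectrum` (untreated references
#'   flagged with `time_s` NA).
#' @param config A `pipeline_config`.
#' @return List with `profiles` (per spectrum `water_state_profile`),
#'   `kinetics` (long table) and `summary` (before/after per depth and
#'   state) as in [water_kinetics()].
#' @export
analyze_hwn_experiment <- function(spectra, config = pipeline_config()) {
  depths <- sort(unique(vapply(spectra, `[[`, numeric(1L), "depth_um")))
  profiles <- list()
  for (d in depths) {
    grp <- spectra[vapply(spectra, function(s) isTRUE(s$depth_um == d), TRUE)]
    pre <- .preprocess_group(unname(.average_by_time(grp)), config)
    for (s in pre) {
      comps <- deconvolve_hwn(s)
      profiles[[length(profiles) + 1L]] <-
        water_profile(comps, depth_um = s$depth_um, time_s = s$time_s)
    }
  }
  wk <- water_kinetics(profiles, after_time_s = config$after_time_s)
  c(list(profiles = profiles), wk)
}

#' Simulate, write and re-read a full synthetic run
#'
#' Convenience driver used by the command-line wrapper: generates the
#' calibration series and both experiments for a spec and writes them
#' under `out_dir` in the plain-text formats the readers consume.
#'
#' @param spec A `synth_spec`.
#' @param out_dir Output directory.
#' @return Paths of the written manifests, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- synth_calibration_series(spec)
  cal_rows <- lapply(seq_along(cal$spectra), function(i) {
    fname <- sprintf("cal_%02d.txt", i)
    write_spectrum(cal$spectra[[i]], file.path(out_dir, fname))
    data.frame(concentration_pct = cal$concentration_pct[i],
               spectrum_path = fname)
  })
  utils::write.csv(do.call(rbind, cal_rows),
                   file.path(out_dir, "calibration.csv"), row.names = FALSE)
  fp <- synth_fp_experiment(spec)
  man_fp <- write_synthetic_dataset(fp, file.path(out_dir, "fp"), spec)
  hwn <- synth_hwn_experiment(spec)
  man_hwn <- write_synthetic_dataset(hwn, file.path(out_dir, "hwn"))
  invisible(list(calibration = file.path(out_dir, "calibration.csv"),
                 fp = man_fp, hwn = man_hwn))
}
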