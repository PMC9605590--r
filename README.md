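# ocraman

Depth- and time-resolved optical-clearing analysis for confocal Raman
micro-spectroscopy of collagenous tissue.

When an optical clearing agent (OCA) such as 50 % aqueous glycerol is
applied to dense collagenous tissue — dura mater, sclera, dermis — it
penetrates by passive diffusion while drawing water out, temporarily
reducing light scattering. Confocal Raman depth profiling can follow both
processes in real time, but the raw signal at depth is confounded: as the
upper layers clear, *every* band at the focal depth grows, whether or not
more agent arrived there. `ocraman` implements the analysis chain that
untangles this:

1. **Clearing-efficiency correction.** Collagen bands (938, 1003, 1247,
   1270, 1665 cm⁻¹) come from immobile protein, so their rise at fixed
   depth measures the instrumental gain: `OC_eff(t) = I_OC(t) / I_0`.
   Dividing the glycerol 485 cm⁻¹ band by it gives the reconstructed
   glycerol signal `TRGC = I_gly / OC_eff`, invariant to the clearing
   crosstalk by construction, which a linear calibration (fitted to
   glycerol-in-water standards) converts to volume percent.
2. **Diffusion kinetics.** Each reconstructed concentration series is
   fitted with the semi-infinite solution of Fick's second law,
   `C(x,t) = C0 · erfc(x / (2√(Dt)))`, by bounded multi-start
   Levenberg–Marquardt, yielding a diffusion coefficient `D` (cm²/s) and
   saturation concentration `C0` (%) per reference band and depth, plus
   per-depth averages. A finite-difference solver serves as an
   independent oracle for the closed form.
3. **Water-mobility states.** High-wavenumber spectra (2600–3800 cm⁻¹)
   are deconvolved into ten Gaussians; the areas of the four OH
   components — tightly (3005), strongly (3277), weakly (3458) bound and
   free water (3604 cm⁻¹) — are normalized to the 2940 cm⁻¹ protein line
   to quantify clearing-induced dehydration per water population.

Preprocessing (iterative polynomial baseline, Savitzky–Golay smoothing,
optional PCA denoising, replicate averaging) and a fully parameterized
synthetic-experiment generator with known ground truth round out the
package; every stage is validated against that generator. The methods
vignette (`vignettes/optical-clearing-raman.Rmd`) documents the models,
parameter choices and limitations.

## Worked example

Simulate a full study at the default conditions (4 depths, 14 time
points, 2 % noise, replicate acquisitions), calibrate, and recover the
diffusion parameters:

```r
library(ocraman)

spec  <- synth_spec(seed = 1)
cal   <- synth_calibration_series(spec)
model <- run_calibrate(cal$concentration_pct, cal$spectra)
model
#> <calibration_model> I = 1.372 + 4.986 * C%  (band glycerol 485, n = 15, R^2 = 0.9995)

res <- analyze_fp_experiment(synth_fp_experiment(spec)$spectra, model)
res$report[res$report$band == "Average", ]
#>  depth_um    band D_cm2_s C0_pct
#>        50 Average 9.9e-06   20.0
#>       100 Average 1.1e-05    2.7
#>       150 Average 3.1e-05    1.3
#>       200 Average 4.2e-05    0.4
```

The generative truth was `D = {9.6e-6, 1.2e-5, 2.2e-5, 3.0e-5}` cm²/s and
`C0 = {20, 2.9, 1.6, 0.6}` %: the shallow depths are recovered within a
few percent, while the sub-percent concentrations at 150–200 µm leave `D`
only order-of-magnitude determined — the intrinsic conditioning of the
saturating erfc fit at low signal, not an optimizer artifact.

Water-state kinetics from the high-wavenumber region:

```r
hw    <- synth_hwn_experiment(synth_spec(seed = 1, depths_um = 50))
water <- analyze_hwn_experiment(hw$spectra)
water$summary
#>  depth_um  state before after
#>        50  tight  0.207 0.133
#>        50 strong  6.020 4.314
#>        50   weak  3.492 2.280
#>        50   free  0.733 0.505
#>        50  total 10.452 7.233
```

Ratios are water-area over protein-area (dimensionless); "before" is the
untreated tissue, "after" the 90 s treatment time point. The strongly and
weakly bound populations dominate and drop the most — the water flux that
drives clearing.

A thin command-line wrapper over the same functions ships in
`inst/cli/ocraman.R` (subcommands `simulate`, `calibrate`,
`fit-diffusion`, `water-states`; spectra and manifests are plain text).

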