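# odormix

Analysis of odor interaction — antagonism and synergism — in binary
odorant mixtures, for researchers in olfactory psychophysics and odor
pollution assessment.

When two odorants are mixed, the perceived intensity of the mixture is
usually *less* than the sum of the components' intensities. `odormix`
quantifies this effect for binary, within-family mixtures of typical
odor pollutants (esters, aldehydes, aromatic hydrocarbons) by:

1. **Psychophysics.** Concentrations are converted to log odor activity
   values, lnOAV = ln(C / C_thr), using a built-in registry of nine
   odorants with panel-measured thresholds; individual odor intensity on
   the 1-butanol OIRS scale follows family-specific affine laws
   (esters: OI = 1.40 lnOAV − 2.70; aldehydes: OI = 1.76 lnOAV − 1.82;
   aromatics: OI = 1.07 lnOAV).
2. **Intensity model.** A per-pair ε-SVR with an RBF kernel maps the two
   component concentrations to the mixture's panel intensity, with a
   seeded 70/30 split and (C, γ) chosen by 10-fold cross-validated MAE
   over the canonical log₂ grid.
3. **Interaction analysis.** The fitted model densifies the lnOAV
   composition plane; interaction degree is measured as
   OI reduction = OI_sum − OI_mix and
   OI reduction ratio = (OI_sum − OI_mix) / OI_sum, where
   OI_sum = OI_a + OI_b is the additive reference. Contour surfaces,
   reduction-ratio scatters against the mixing ratio
   x_a = lnOAV_a / (lnOAV_a + lnOAV_b), and summary statistics (peak
   ratio, peak x_a, intensity-independence rank correlation) are
   produced.
4. **Synthetic sensory panel.** A fully seeded generator emulates panel
   datasets (balanced mixing-ratio designs, ~30 samples per pair,
   Gaussian panel noise, OIRS-clipped readings) with a known
   ratio-dependent antagonism ground truth, so the entire pipeline is
   testable without proprietary olfactometry data.

See the vignette (`vignettes/odor-interaction-analysis.Rmd`) for the
model, the generator's assumptions, and the reasoning behind the
numerical choices.

## Worked example

```r
library(odormix)

config  <- generator_config("EA", "BA", seed = 42)   # ethyl + butyl acetate
dataset <- generate_panel_dataset(config)
parts   <- split_dataset(dataset, train_fraction = 0.7, seed = 7)
model   <- fit_intensity_model(parts$train, cv_folds = 10, seed = 11)
model
#> RBF-SVR odor-intensity model for EA + BA
#>   selected C = 32768, gamma = 0.00195312 (epsilon = 0.1), 10-fold CV
#>   CV MAE at selected cell: 0.2907 OIRS (n=21, cv_seed=11)

evaluate_model(model, parts$train, parts$test)
#> Model evaluation (n_train = 21, n_test = 9)
#>   R^2: train 0.939, test 0.913
#>   MAE: train 0.214, test 0.274 OIRS

surface <- simulate_interaction_surface(model, dataset,
                                        resolution = 50, min_oi_sum = 2)
surface
#> Interaction surface for EA + BA: 50 x 50 lnOAV grid
#>   lnOAV_a in [0.70, 7.02], lnOAV_b in [0.57, 7.70]
#>   458 / 2500 cells masked (OI_sum < 2)

summarize_surface(ratio_scatter(dataset, surface))
#> Interaction summary
#>   peak reduction ratio 0.430 at x_a = 0.464 (n = 1000)
#>   rank correlation(ratio, OI_mix) = -0.398
```

Reading the output: the SVR predicts held-out panel intensities to 0.27
OIRS — inside the ~0.4-OIRS error accepted for human panels — and the
densified surface recovers the generator's ground truth (peak
antagonism ρ_max = 0.35 at x_a = 0.5) to within the run-to-run
variability expected at 30 noisy samples. The 458 masked cells are the
low-intensity corner (OI_sum < 2 OIRS) that the analysis excludes.
`plot_interaction_surface(surface)` and
`plot_ratio_scatter(ratio_scatter(dataset, surface))` draw the contour
map with measured/predicted overlays and the ratio scatter colored by
mixture intensity. `run_pipeline()` executes all stages and writes every
artifact (CSVs, JSON reports, figures, a log with all seeds); a thin CLI
wrapper lives in `inst/cli/odormix.R`.

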