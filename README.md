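# flimetab

Metabolic fluorescence-lifetime imaging (FLIM) analysis of NADH, for
microscopists and image analysts who want a fully testable, scriptable
version of the standard per-pixel free/bound NADH workflow — from raw
TCSPC photon histograms to group-level metabolic statistics — plus a
synthetic TCSPC generator so the whole chain can be validated with known
ground truth.

## The science in one paragraph

Free NADH fluoresces with a short lifetime (≈0.1–0.5 ns), protein-bound
NADH with a long one (≈1–5 ns). Each pixel's TCSPC histogram is fitted
with the two-component decay

I(t) = a₁·exp(−t/τ₁) + a₂·exp(−t/τ₂),  a₁ + a₂ = 1,

giving the free-NADH amplitude fraction a₁ (higher a₁ = more glycolytic)
and the amplitude-weighted mean lifetime τₘ = a₁τ₁ + a₂τ₂ (shorter τₘ =
more glycolytic). The forward model accounts for the 80 MHz pulsed
excitation by folding incomplete decays over the 12.5 ns repetition
period in closed form, and optionally for a Gaussian instrument response.
Downstream, the distribution of per-pixel a₁ inside the tumor mask is
modelled with one- vs two-component Gaussian mixtures (BIC selection) to
detect coexisting metabolic subpopulations, and groups of animals are
compared with unpaired two-tailed t-tests on per-animal means and
two-way ANOVA (group × histogram-bin) on per-animal histograms.

## Worked example

Simulate a 64 × 64 tumor holding two metabolic subpopulations (true free
fractions 0.55 and 0.75), fit every pixel, and ask whether the a₁
distribution is bimodal:

```r
library(flimetab)

acq  <- acquisitionConfig()                # 80 MHz, 256 bins, 5000 photons/px
spec <- bimodalScene(a1Means = c(0.55, 0.75), a1Sd = 0.02, seed = 1L)
cube <- simulateDecayCube(buildScene(spec), acq, seed = 101L)
cube
#> DecayCube: 64 x 64 pixels x 256 time bins, 12.5 ns window
#>   total photons: 2.04813e+07 (mean 5000.3 / pixel)

maps <- fitCube(cube, mask = NULL, fitOptions())   # 2x2 binning + Poisson MLE
maps
#> ParameterMaps: 64 x 64 pixels, 4096 valid (100.0%)
#>   a1:   mean 0.6523  sd 0.1008
#>   tauM: mean 1.064 ns

regionSummary(spec, a1Map(maps))
#>     label    n      mean         sd
#> 1  low_a1 2048 0.5537855 0.02689033
#> 2 high_a1 2048 0.7508891 0.01252265

sel <- selectModality(maskedValues(maps, NULL, "a1")$value, seed = 1L)
sel$model2
#> MixtureModel: k = 2 | logLik 7945.598 | BIC -15849.607 | AIC -15881.196
#>   component 1: weight 0.485, mean 0.5501, sd 0.0167
#>   component 2: weight 0.515, mean 0.7486, sd 0.0181
```

The fit recovers both planted region means to well under 0.01, and BIC
decisively selects the bimodal description (ΔBIC ≈ 8689 in favour of
k = 2) with component means at the planted 0.55 / 0.75.

Group-level inference runs on per-animal means, never pooled pixels:

```r
compareGroups(c(0.74, 0.77, 0.72, 0.76),   # brain-like, per-fish mean a1
              c(0.61, 0.59, 0.63, 0.60))   # skeletal-like
#> GroupComparison (unpaired_t_two_tailed): statistic 10, p = 5.778e-05, direction +1
#>   group sizes: 4, 4
```

A YAML-configured end-to-end run (simulate → fit → analyze, with TIFF
maps, CSV tables, mixture/test JSONs, plots and a provenance record) is
available as `runPipeline(config, outDir)` or from the shell via
`inst/scripts/flim-pipeline.R`.

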