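# hqsar

Hologram QSAR modelling and validation for congeneric inhibitor series.

Medicinal-chemistry series built around one scaffold — here, a
dibenzofuran-containing tricyclic series of MMP-12 (macrophage
metalloelastase) inhibitors — often hide a simple structure–activity rule:
a handful of substructural features drive potency. Hologram QSAR makes
that rule estimable from 2D structure alone. Every connected heavy-atom
fragment of a molecule (sizes 4–7 by default) receives a canonical key
under configurable distinction flags (atoms + connections + hydrogens by
default) and is hashed by CRC-32 into one of *L* bins; the resulting count
vector (the *hologram*) is regressed on activity by partial least squares:

    pIC50_i = b0 + Σ_b  c_ib · β_b ,   pIC50 = −log10(IC50 µM)

with the number of latent components chosen by leave-one-out q², and *L*
chosen over a catalogue of twelve primes (53–401). Around that core the
package provides the full validation workflow used in the field:
Y-randomization, external validation (r²pred = 1 − PRESS/SD,
Golbraikh–Tropsha criteria, Roy's rm² metrics on scaled values), a
Euclidean normalized-mean-distance applicability domain, and per-atom
contribution maps in the conventional red-to-green colour vocabulary. A
synthetic congeneric-series generator with known fragment-additive
activity makes every stage testable end to end.

Everything is tidyverse-native: compound tables are plain tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

The package ships the reference activity table of the MMP-12 series (26
training + 9 test compounds, observed and published-model predictions):

```r
library(hqsar)
ref <- mmp12_reference()
activity_summary(ref, "train")
#> # A tibble: 1 × 4
#>   role  min_pic50 max_pic50     n
#>   <chr>     <dbl>     <dbl> <int>
#> 1 train      1.64         4    26

te <- ref[ref$role == "test", ]; tr <- ref[ref$role == "train", ]
r2_pred(te$actual_pic50, te$predicted_pic50, tr$actual_pic50)
#> # A tibble: 1 × 5
#>   r2_pred press    sd train_mean n_test
#>     <dbl> <dbl> <dbl>      <dbl>  <int>
#> 1   0.879 0.322  2.66       2.75      9
```

So the published model explains ~88% of the test-set activity variance
relative to the training-mean baseline (the source reports 0.8733 from its
unrounded predictions). The remaining external-validation criteria pass on
the same pairs:

```r
golbraikh_tropsha(te$actual_pic50, te$predicted_pic50, q2 = 0.697)[
  , c("r2", "k", "k_prime", "pass_all")]
#> # A tibble: 1 × 4
#>      r2     k k_prime pass_all
#>   <dbl> <dbl>   <dbl> <lgl>
#> 1 0.859  1.01   0.989 TRUE

rm2_metrics(te$actual_pic50, te$predicted_pic50)
#> # A tibble: 1 × 5
#>     rm2 rm2_prime rm2_avg rm2_delta scaled
#>   <dbl>     <dbl>   <dbl>     <dbl> <lgl>
#> 1 0.630     0.765   0.698     0.135 TRUE
```

A full modelling run on a synthetic series with known fragment-additive
truth (noise-free, short fragment window so the hash is near-injective —
see the methods vignette):

```r
cfg <- hologram_config(frag_min = 1, frag_max = 2)
series <- generate_series(series_spec(seed = 1, noise_sd = 0,
                                      config = cfg, min_support = 4))
fit <- hqsar_train(series, config = cfg, max_components = 12)
fit
#> <hqsar_model> hologram QSAR model
#>   best length: 199  components: 10
#>   q2 = 0.9545  sep = 0.1440  r2 = 1.0000  see = 0.0043
#>   ensemble (mean over 12 lengths): r2 = 0.9755  see = 0.0556

hqsar_validate(fit, series)
#> <hqsar_validation> external validation, 9 test compounds
#>   r2_pred = 0.9818 (PRESS = 0.0404, SD = 2.2183)
#>   Golbraikh-Tropsha: r2 = 0.9823, all pass: TRUE
#>   rm2 avg = 0.9343, delta = 0.0171 (scaled)
```

The cross-validated q² of 0.95 and test-set r²pred of 0.98 say the
pipeline recovered the generating fragment weights almost exactly; with
the realistic 4–7 fragment window, hash collisions cap q² near the
0.7 regime seen with real data. `y_randomize(fit)` refits after shuffling
activities (q² collapses), `applicability_domain(fit, series)` scores
every compound on the [0, 1] distance scale, and
`atom_contributions(fit, smiles)` decomposes a prediction onto atoms for
colour-coded display (`autoplot()`).

`run_hqsar_pipeline(input, out_dir)` chains all stages and writes a
self-describing JSON/CSV report bundle, including predictions with a
standard error of prediction for designed compounds.

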