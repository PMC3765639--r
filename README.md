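# basketweave

Quantify the integrity of the dermal collagen basketweave from cross-polar
photomicrographs of picrosirius-stained skin.

Healthy dermis weaves its collagen into two fibre families crossing at
roughly 90°. Ageing and disease (notably type 2 diabetes) relax that order
well before gross fibrosis appears. Under crossed polarizers the birefringent
fibres show bright on a dark field, and the loss of order is visible — this
package turns it into a number.

## The index

The orientation content of a texture lives in the shape of its 2-D Fourier
amplitude spectrum. `basketweave` measures that shape per direction:

1. grayscale conversion and a 3×3 median filter (photon-noise removal);
2. a four-channel Gabor filter bank at 0°/45°/90°/135° — each cosine-carrier
   kernel is even, so the four channels realize eight directions
   (0°+180°, 45°+225°, 90°+270°, 135°+315°);
3. per channel: Hann window → centered FFT amplitude spectrum (1/(MN)
   normalization) → binarization at a high amplitude quantile → the
   moment-equivalent ellipse of the binary scatter;
4. per channel elongation **N<sub>ω</sub> = 1 − short/long**, and per image
   the **collagen orientation index N = max N<sub>ω</sub> / min
   N<sub>ω</sub> ≥ 1**.

Equal directional ellipses (disordered texture) give N ≈ 1; an intact weave
loads the diagonal channels disproportionately and N grows. An FFT-only
baseline (the elongation of the single unfiltered spectrum, near 0 for
isotropic content) is included for method comparison, and a synthetic
basketweave phantom generator with a tunable angular-jitter degradation knob
provides the validation surface.

## A worked example

```r
library(basketweave)

img <- generate_basketweave(phantom_spec(seed = 1))  # intact 256 px weave
analyze_image(img, image_id = "demo")
#>   image    method n_omega_0 n_omega_45 n_omega_90 n_omega_135 index_N
#> 1  demo gabor_fft    0.1237     0.7948     0.1237      0.7788  6.4244
#> 2  demo  fft_only    0.0175     0.0175     0.0175      0.0175  0.0175
```

The intact 45°/135° weave loads the diagonal channels (N<sub>ω</sub> ≈ 0.78–0.79)
far above the axial ones (≈ 0.12), giving an index of 6.42. The FFT-only
baseline sees a balanced, near-circular scatter (its two families cancel) and
scores 0.017. The fully disordered control sits at the analytic floor:

```r
analyze_image_gabor(generate_isotropic(512, 512, seed = 1))$index_N
#> [1] 1.023
```

Batch work flows through tibbles end to end:

```r
run_phantoms("phantoms/", jitter_grid = c(0, 10, 20, 30, 40), n_seeds = 10)
results <- run_analyze("phantoms/", bw_config(), method = "both")
aggregate_by_animal(results, animal_map)   # >= 3 fields per animal, averaged
pearson_report(summary_df, age, mean_index)

ex <- run_experiment_monotonicity(master_seed = 1)  # degradation series
tidy(ex); glance(ex); autoplot(ex)
```

A thin command-line front-end lives at `inst/cli/basketweave`
(subcommands `analyze`, `phantoms`, `experiment-monotonicity`,
`experiment-rotation`).

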