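# dwinlm

Non-local means denoising and quality metrics for diffusion-weighted MR
(DWMR) phantom images.

Diffusion-weighted breast MRI grades lesions by their apparent diffusion
coefficient (ADC): signal in a homogeneous region decays as
S(b) = S₀·exp(−b·ADC) with the diffusion weighting b (s/mm²), so the
clinically informative high-b images are heavily attenuated and noisy, and
magnitude reconstruction makes that noise Rician. `dwinlm` is for imaging
scientists who want to tune and validate patch-based denoising on such
data. It provides:

* a **calibrated synthetic phantom**: disk inserts emulating 10–40%
  polyvinylpyrrolidone (PVP) solutions in water, mono-exponential b-decay,
  and seeded Rician noise, calibrated so the 40% insert reproduces a
  bundled reference decay table (ADC ≈ 991–1024 ×10⁻⁶ mm²/s, measured
  SNR ≈ 97 at b = 1000 s/mm²);
* the **non-local means (NLM) filter**, NL[f](m) = Σₙ ω(m,n) f(n) with
  ω(m,n) ∝ exp(−‖v(m)−v(n)‖²₂,ₐ / d²), in a direct form and a numerically
  equivalent integral-image accelerated form, on 5 × 5 patches in a
  15 × 15 search window;
* the **conventional comparators**: 5 × 5 median, locally adaptive (Lee)
  Wiener, and Rudin–Osher–Fatemi total-variation denoising (λ = 0.2,
  dual projection);
* **ROI metrics**: SNR (signal mean / background-ROI SD), CNR
  (mean difference / root-sum-square of SDs) on 25 × 25 ROIs, pairwise
  and log-linear ADC estimation, line profiles and 10–90% edge widths;
* the **analysis pipeline**: b-value scan → working b by maximal CNR →
  smoothing-factor sweep over d = 0.001…0.150 → plateau-knee optimum →
  comparison study with truncated fold-change ratios — with tibble
  outputs, `tidy()`/`glance()` methods and `autoplot()` figures
  throughout.

## Worked example

```r
library(dwinlm)

spec   <- default_phantom_spec(shape = c(128, 128), seed = 1)
series <- generate_series(spec)
rois   <- default_rois(spec)

scan <- bvalue_scan(series, rois)
scan
#> # A tibble: 11 × 7
#>    bvalue signal_mean signal_sd background_mean background_sd   snr   cnr
#>     <dbl>       <dbl>     <dbl>           <dbl>         <dbl> <dbl> <dbl>
#>  1      0        926.      3.39          914.            3.49 265.   2.44
#>  2    200        754.      3.58          577.            3.53 214.  35.3
#>  3    400        615.      3.48          364.            3.53 174.  50.5
#>  4    600        501.      3.38          230.            3.30 152.  57.4
#>  5    800        408.      3.52          145.            3.47 118.  53.2
#>  6   1000        332.      3.48           91.7           3.40  97.7 49.5
#>  ...

(b <- select_working_bvalue(scan))
#> [1] 600
```

The signal decays with b while the (constant-σ) background keeps its
noise level, so SNR falls monotonically past b = 0 but CNR — the
contrast between the restricted-diffusion insert and the fast-diffusing
water — peaks at an interior b (600 s/mm² for this geometry). The
analysis continues on the maximal-CNR image:

```r
img <- series$images[[match(b, series$bvalues)]]
sw  <- sweep_smoothing_factor(img, rois, sweep_config())
glance(sw)
#> # A tibble: 1 × 8
#>     n_d d_opt snr_input cnr_input snr_opt cnr_opt snr_max cnr_max
#>   <int> <dbl>     <dbl>     <dbl>   <dbl>   <dbl>   <dbl>   <dbl>
#> 1   150 0.014      152.      57.4   2343.    884.   2463.    929.

cmp <- run_comparison_study(img, rois, nlm_d = select_optimal_d(sw))
tidy(cmp)
#> # A tibble: 10 × 4
#>    method metric  value  fold
#>  1 none   snr     152.   1
#>  2 median snr     687.   4.51
#>  3 wiener snr     769.   5.05
#>  4 tv     snr     170.   1.11
#>  5 nlm    snr    2343.  15.4
#>  ...
```

The SNR/CNR-vs-d curves rise steeply and plateau; the plateau knee
(smallest d reaching 95% of peak CNR) lands at d = 0.014, and NLM at
that d beats every conventional filter on both metrics. The fold
improvements on this piecewise-constant phantom (≈ 15×) are much larger
than on a physical acquisition (≈ 2–3×) because synthetic compartments
are perfectly self-similar; the *ordering* of the methods is the
reproducible finding. `autoplot(sw)`, `autoplot(cmp)` and
`autoplot(scan)` draw the corresponding figures.

The package also bundles the reference ROI measurements of a published
3.0 T breast-phantom acquisition (`reference_bvalue_table()`,
`reference_sweep_table()`, `reference_comparison_table()`);
`reproduce_reference_ratios()` recomputes every arithmetic consequence of
those tables — the pairwise ADC range 991–1024 ×10⁻⁶ mm²/s and all
twelve + two truncated fold-change ratios — and reports a pass per
target.

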