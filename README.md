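# octcorrect

Depth-dependent correction of spectral-domain OCT scans by basis-function
fitting of the combined confocal × sensitivity fall-off envelope.

## The problem

Every spectral-domain OCT A-scan is shaped by two system envelopes in depth:
the **confocal function** `h(z) = 1 / (((z − z0)/zR)² + 1)` from
Gaussian-beam focusing (focal plane `z0`, apparent Rayleigh range `zR`) and
the **sensitivity fall-off** `f(z) = sinc(ζ)² exp(−w²ζ²/(2 ln 2))`,
`ζ = (π/2) z/z_RD`, set by the spectrometer's resolution and pixel spacing.
A measured scan is `I(z) = g(z) A(z)` with `g = h·f` and `A` the ideal
sample signal. Anything derived from depth profiles — above all attenuation
coefficients used in diagnosis of retinal and bladder disease — needs `g`
removed first, but estimating `h` and `f` separately requires system
parameters that clinical instruments rarely expose.

`octcorrect` implements a single-shot estimator of the *combined* envelope
from two (or more) scans of the same sample acquired at different axial
offsets Δz = m pixels. Because the sample term cancels in the shifted ratio,

```
10 log10 I1(i) − 10 log10 I2(i+m)  =  G(i) − G(i+m),     G = 10 log10 g,
```

modelling `G` as a linear combination of Chebyshev polynomials
`G(i) ≈ Σ_{k=2}^{N+1} c_k β_k(i)` turns estimation into ordinary least
squares `y = cB + ε`, solved by SVD pseudo-inverse, with the design
condition number (well-conditioned below ~6.7×10⁸) as the diagnostic for
choosing `N`. The estimate is identifiable up to one overall scale (the
`β₁` coefficient), which normalization fixes. The package also provides:

* the classical two-parameter confocal **ratio fit** baseline
  (multi-start least squares on the same dB ratio data);
* a faithful **simulator** of the three-layer attenuation phantom with
  confocal/fall-off envelopes, −30 dB signal floor, and speckle/shot noise;
* **preprocessing** (air-median debiasing, Gaussian speckle suppression,
  dB-domain low-pass smoothing), **correction** and the aligned-RMSE
  similarity metric, per scan and per lateral position;
* **attenuation extraction**: per-layer CF slopes (`μ = −slope/2` of
  `ln I` vs physical depth) and the per-pixel depth-resolved (DRC)
  estimator `μ(i) = I(i) / (2Δ Σ_{j>i} I(j))`;
* multi-depth, multi-lateral and moving-window variants of the estimator,
  TIFF/CSV scan I/O, YAML-configured pipeline runs, and a thin command-line
  front end (`inst/cli/octcorrect`).

## Worked example

Simulate the layered-phantom benchmark (three layers of 1, 2 and 4 mm⁻¹
over 2.5 mm, 512-pixel A-scans, 200 lateral positions, 50-pixel shift,
speckle + shot noise at 80 dB SNR), extract `g` with 20 basis functions,
correct the scans and read off the attenuation coefficients:

```r
library(octcorrect)

pair <- simulate_model_scene(noise = noise_spec(snr_db = 80, seed = 1),
                             n_lateral = 200)
fit <- basis_fit(pair, N = 20)
glance(fit)
#> # A tibble: 1 × 6
#>   method n_basis fit_rmse  cond ill_conditioned normalization
#>   <chr>    <int>    <dbl> <dbl> <lgl>           <chr>
#> 1 basis       20    0.410  9.70 FALSE           max-one

correction_report(pair, fit)
#> <correction_report> overlap 462 px: RMSE 2.466 dB -> 0.4101 dB

corrected <- correct_scan(lateral_average(pair$scans[[1]]), fit)
windows <- phantom_fit_windows(pair$phantom, pair$grid)
ac_layers(corrected, windows, pair$grid)
#> # A tibble: 3 × 5
#>   layer    mu window_start window_end r_squared
#>   <int> <dbl>        <dbl>      <dbl>     <dbl>
#> 1     1 0.953           20        109     0.917
#> 2     2 2.00           120        210     0.980
#> 3     3 3.96           221        347     0.997
```

The fit report shows a well-conditioned design (cond 9.70 ≪ 6.7×10⁸); the
correction shrinks the shifted-scan dB mismatch from 2.47 to 0.41 dB
(the speckle-noise floor of the laterally averaged data); and the CF slopes
of the corrected scan recover the configured 1/2/4 mm⁻¹ to a few percent.
`tidy(fit)` returns the per-pixel curve as a tibble and `autoplot(fit)`
plots it; noise-free runs (`noise_spec(speckle = FALSE, shot = FALSE)`)
recover `g` to sub-millidecibel accuracy. The same workflow runs from the
shell via `inst/cli/octcorrect run --config inst/extdata/simulation_A.yaml
--out-dir out/`.

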