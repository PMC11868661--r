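---
title: "Estimating and removing the combined confocal and fall-off envelope of OCT scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and removing the combined confocal and fall-off envelope of OCT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcorrect)
```

## The measurement model

A spectral-domain OCT A-scan records backscattered intensity against depth
`z`. Two instrument envelopes multiply the ideal sample signal `A(z)`:

* the confocal envelope `h(z) = 1 / (((z − z0)/zR)² + 1)`, a Lorentzian in
  depth with its peak at the focal plane `z0` (mm) and half-width set by
  the apparent Rayleigh range `zR` (mm), both of which shift with the
  sample's refractive index;
* the spectrometer fall-off `f(z) = sinc(ζ)² exp(−w² ζ² / (2 ln 2))`, with
  `ζ = (π/2) z / z_RD`, the maximum ranging depth
  `z_RD = λ0² / (4 Δλ)`, and `w = δλ/Δλ` the spectral resolution (FWHM)
  in units of the pixel spacing. The sinc here is unnormalized,
  `sin(x)/x`, the standard form for spectrometer pixel integration; with
  `ζ` already carrying the factor `π/2`, `ζ` stays below `π/2` inside the
  ranging depth.

The measured scan is `I(z) = g(z) A(z)` with `g = h · f` (times any other
depth-dependent system effect). `octcorrect` estimates `g` without knowing
`z0`, `zR` or the spectrometer constants, from two or more scans of the
same sample shifted axially by a known pixel offset `m`. Shifting the
sample turns `A₂(z) = A₁(z − Δz)`, so the dB-scale ratio of the aligned
scans cancels the sample entirely:

```
y(i) = 10 log10 I₁(i) − 10 log10 I₂(i+m) = G(i) − G(i+m),   G = 10 log10 g.
```

Intensities are squared amplitudes, hence the `10 log10` convention
throughout.

## The basis-fit estimator

`G` is expanded in Chebyshev polynomials of the first kind sampled on the
pixel grid, `G(i) ≈ Σ_{k=2}^{N+1} c_k β_k(i)`. The constant `β₁` drops out
of the difference, which is exactly why the overall scale of `g` is not
identifiable — correction is defined up to one multiplicative constant,
fixed afterwards by normalization (`max-one` by default; an
`air-min-one` mode rescales by the minimum over a user-supplied air range
for display purposes). Each depth pair contributes the linear system

```
y(i) = Σ_k c_k (β_k(i) − β_k(i+m)) + ε(i),   i = 1 .. p − m,
```

assembled as `y = cB + ε` and solved by SVD pseudo-inverse with a
machine-precision relative cutoff and no regularization: plain least
squares is the estimator's definition, and conditioning problems are
handled by restructuring (below), not damping. Two structural identities
follow directly and are asserted in the test suite:

* the fit residual `ε` equals, elementwise, the dB difference of the two
  corrected, aligned scans — minimizing the model-to-data misfit *is*
  minimizing the post-correction mismatch;
* with several B-scan columns sharing one shift, solving the concatenated
  per-column system equals solving once against the pixel-wise mean of the
  per-column data vectors, because the model block is column-independent.

**Pixel mapping.** The grid index is mapped to the Chebyshev domain by
`x_i = −1 + 2(i−1)/(p−1)` over the *full* grid `1..p`, so that the shifted
samples `β_k(i+m)` stay inside the domain. An alternative cell-centred map
`x_i = 2i/p − 1` is selectable. The default is the one whose difference
design reproduces the reference condition number 9.7020 for
`N = 20, p = 512, m = 50`; the alternative gives 10.89, so the two are
distinguishable and the choice is pinned by that diagnostic rather than by
convention.

**Conditioning.** The condition number of `B` (largest over smallest
singular value) is computed for every design. Beyond ~6.7×10⁸ — the usual
double-precision working-precision threshold — the solve is flagged
ill-conditioned via a warning, but the estimate is still returned so the
user can see the characteristic breakdown. The two remedies surfaced by
`check_conditioning()` are fewer basis functions (fewer rows) or scans at
additional depths (more, linearly independent, columns): on the benchmark
grid a single 50-pixel pair supports `N = 20` comfortably
(cond ≈ 9.7) while `N = 60` collapses (cond ≈ 9 × 10¹²), and adding a
third scan at an 80-pixel offset restores `N = 60` to cond ≈ 9.06.

**Choosing N.** Between roughly 5 and 20 basis functions suffices for
realistic envelope shapes; the fit RMSE decreases monotonically in `N`
until ill-conditioning sets in. `N` is deliberately a user parameter — the
conditioning report is the guidance, and no automatic selection is
attempted.

**Variants.** Multiple depths contribute all pairwise blocks
(`[B₁₂ | B₁₃ | B₂₃]`); the moving-window mode fits an odd-width window of
lateral columns and assigns the estimate to the window centre, reusing the
first/last window beyond the first/last centre, which yields a laterally
resolved `g` for samples whose refractive-index profile varies across the
scan.

## The ratio-fit baseline

The classical alternative fits only the two-parameter confocal model: the
same data vector `y` is fit by
`10 log10 h(i; z0, zR) − 10 log10 h(i+m; z0, zR)` in the dB domain. The
objective is non-convex, so the fit multi-starts from a 16 × 16 grid
(`z0` uniform over `[0, zmax]`, `zR` log-spaced over `[pitch, zmax]`,
bounded below by one pixel pitch to avoid singular evaluations), refines
each start with Nelder–Mead, and polishes the winner with restarted
simplexes down to machine level. The dB-domain objective makes the
reported fit RMSE identical to the corrected-scan RMSE metric, i.e. the
best value the confocal-only model family can achieve on that metric. On
confocal-only data the fit recovers `(z0, zR)` to machine precision; a
flat data vector is flagged non-identifiable (any focus fits). When a
separately measured fall-off curve is available it is divided out before
the fit and multiplied back into the returned estimate, mirroring how the
baseline is used in practice.

Because the Chebyshev span and the log-Lorentzian family are not nested,
the basis fit is not guaranteed to win at very small `N` (with `N = 5` it
does not); from `N ≈ 10` upward it dominates the baseline on every
scenario in the test suite, most visibly when fall-off is present or the
true confocal shape is perturbed away from the Lorentzian form.

## The simulator

The synthetic scenes exist to make the estimator's benchmarks exactly
reproducible, and their defaults are the benchmark conditions themselves:
512-pixel A-scans over 2.5 mm (`z_i = i·zmax/p`, so pixel 150 ↔ 0.7324 mm),
a three-layer sample with attenuation 1, 2 and 4 mm⁻¹ between boundaries
at 0.073, 0.561, 1.050 and 2.5 mm, detection scalars
`k = 1000, α = β = 0.75, L0 = 5`, confocal `z0 = 0.7324` mm,
`zR = 0.3662` mm, fall-off from λ0 = 1310 nm, Δλ = 7.1875×10⁻¹¹ m,
δλ = 1.1055×10⁻¹⁰ m (z_RD = 5.969 mm, w = 1.538), a 50-pixel shift and
200 lateral columns.

The ideal profile follows the single-scattering Beer–Lambert model
`A(z) = kαβL0 μ(z) e^(−2∫₀ᶻ μ)`, with the integral evaluated in closed
form per layer (μ is piecewise constant, so no quadrature tolerance
enters). A −30 dB signal floor relative to the profile maximum is applied
to the noise-free profile *before* noise in every branch, noise-free runs
included, which keeps the noise-free and noisy benchmarks on the same
footing; because the floor level is identical for both scans of a shifted
pair, it cancels from the ratio data exactly. Scans shifted deeper expose
air at the top (filled with the air value, then floored); pixels pushed
past the grid are discarded.

Noise is drawn per pixel, per lateral column and per scan from a single
configured seed (runs are bit-reproducible). Speckle multiplies the
*intensity* by `n_sp = −(4/π) ln u` (mean 4/π) — equivalently the
amplitude by its square root. The source expressions for the noise terms
are typographically ambiguous; this reading is the one whose
speckle-limited corrected-scan RMSE matches the reference benchmark
(≈0.43 dB at 200 columns, versus ≈0.93 dB for the amplitude-domain
reading), and the generator accepts replacement draw functions so either
convention can be configured. Shot noise adds
`σ·(−(4/π) ln u − 4/π)` (zero mean, sd ∝ σ) to the amplitude, with
`σ = C·10^(−SNR/20)` and `C` the square root of the grid-wide mean ideal
intensity, air pixels included. At the benchmark SNR of 80 dB shot noise
is three orders of magnitude below speckle, so results are insensitive to
its exact algebra.

What the simulator does *not* emulate: interferogram/k-space acquisition,
dispersion, aliasing from beyond the ranging depth (signals are assumed
fully attenuated within range), lateral translation or rotation between
scans, and sample-dependent speckle correlation. Passing tests on these
scenes therefore validates the estimator's algebra and conditioning
behaviour, not robustness to registration error or to real detector noise
statistics.

## Preprocessing

Measured scans are cleaned before extraction in this order: (1) debias by
subtracting the median intensity of the air rows (skipped if a supplied
background estimate undercuts the image minimum); (2) suppress speckle
with a rotationally symmetric Gaussian of σ = 0.5 px in the linear domain;
(3) convert to dB with a floor 30 dB below the image maximum; (4) smooth
in the dB domain with a size-10, σ = 5 px Gaussian — high spatial
frequencies corrupt envelope extraction, and the final attenuation values
are insensitive to these parameters. Filters use symmetric-reflection
boundary handling, chosen because edge darkening from zero padding would
bias the estimate exactly where the envelope matters most (near `z = 0`);
even kernel sizes centre at `(size+1)/2`. Lateral averaging is done in
linear intensity, with dB conversion as a subsequent step. The air-row
range is a required user parameter — there is no robust automatic surface
detection across instruments.

## Correction, metric and attenuation

Correction is elementwise division by the (strictly positive) estimated
envelope; the similarity metric is the RMSE of the dB difference of the
two corrected scans aligned at their known shift, over the `p − m`
overlapping pixels, excluding nothing by default (an optional mask can
drop floor-clamped depths). The metric is invariant to the estimate's
normalization constant. Per-lateral-position values pool quadratically
into the global value.

Attenuation comes in two forms. The CF (curve-fit) method takes the
least-squares slope of `ln I` against *physical* depth (optical depth
divided by the refractive index) inside a homogeneous window; under single
scattering `μ = −slope/2`. The depth-resolved (DRC) estimator
`μ(i) = I(i) / (2Δ Σ_{j>i} I(j))` gives a per-pixel map, is
scale-invariant, and assumes the signal is substantially attenuated within
range — pixels with an empty tail are flagged invalid, and a clamped deep
tail biases it low, so CF windows are preferred where layers are known.
Multiple-scattering models are out of scope.

For the simulated benchmark the per-layer CF windows are derived once from
the phantom definition: each layer's pixel interior with a 5-pixel margin
at both ends (keeping clear of the boundary transitions), truncated where
the noise-free floored profile of the shallower scan reaches the −30 dB
clamp — a clamped tail is constant and carries no slope information. On
the benchmark grid this yields windows 20–109, 120–210 and 221–347.
The windows are configurable and recorded in the per-layer output table.

## Problem sizes and determinism

All benchmark computations are desk-scale: the deterministic RMSE ladder
and condition numbers take seconds, and the stochastic per-layer
attenuation quantities are averaged over 40 independently seeded
realizations of the full 200-column scene (each realization is itself a
complete simulate–extract–correct–fit run; the seed-to-seed spread of a
single layer estimate is ≈0.03 mm⁻¹, so the 40-seed mean is stable to
≈0.005 mm⁻¹). Every stochastic stage flows from one integer seed;
rerunning any configuration with the same seed reproduces scans, fits and
reports bit-for-bit.

## Known limitations

* The axial shift `m` must be known; it is not estimated, and no
  lateral/rotational registration is attempted.
* The estimate carries an unidentifiable overall scale; quantities that
  need absolute sensitivity require an external calibration.
* dB-domain fitting weights all depths equally; floor-clamped pixels of
  *both* scans carry no sample information and can optionally be masked,
  but are included by default to keep the metric definition unambiguous.
* The DRC estimator is biased wherever the recorded tail is truncated or
  clamped; its per-pixel map is best read qualitatively, with CF slopes as
  the quantitative reference.
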