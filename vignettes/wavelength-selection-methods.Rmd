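---
title: "Wavelength selection for quantitative diffuse reflectance imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveopt)
```

## The problem

A spectral imaging probe for intraoperative tissue assessment measures
diffuse reflectance — light re-emitted after multiple scattering — and
inverts a photon-transport model to recover the tissue parameters that
carry diagnostic contrast: total hemoglobin concentration [THb]
(vascularity), beta-carotene concentration [βc] (adipose content), and
the reduced scattering coefficient µs′ (fibroglandular content),
summarized as its 450–600 nm mean ⟨µs′⟩. A broadband spectrometer
samples this window densely (61 wavelengths at 2.5 nm), but a compact,
fast, inexpensive device wants a handful of discrete sources. The
package answers the design question: *which* few center wavelengths,
and *how wide* a source bandpass, still recover the same parameters the
full spectrum would?

The workflow has four layers, each a module with a narrow surface:

1. **Optics** — absorption built from chromophore extinction curves,
   µa(λ) = ln 10 · Σᵢ εᵢ(λ)·cᵢ (decadic extinctions in cm⁻¹ M⁻¹,
   concentrations converted from µM to molar), and reduced scattering
   from either a power law a·(λ/λ₀)⁻ᵇ or Mie theory for sphere
   suspensions.
2. **Forward model** — optical properties to probe-geometry reflectance.
3. **Inverse model** — bound-constrained least squares recovering the
   parameters from reflectance sampled at an arbitrary wavelength
   subset.
4. **Search and studies** — a genetic algorithm over wavelength subsets
   scored by extraction error, plus bandpass-degradation and agreement
   studies.

## Forward models

The forward model is a contract — anything mapping `optical_properties`
to a reflectance spectrum — with two reference implementations.

**Dipole diffusion.** The closed-form steady-state solution for a
semi-infinite medium: an isotropic point source at depth z₀ = 1/µt′
(µt′ = µa + µs′), a negative image across the extrapolated boundary at
distance 2zb (zb = 2AD with the internal-reflection parameter A from
the angular moments of the Fresnel coefficient), and the detected
signal assembled from fluence and flux with partial-current
coefficients (1 − R_φ)/4 and (1 − R_j)/2. The default geometry is a
single 0.75 mm source–detector separation (the inner radius of an
annular photodiode around the delivery fiber) and a relative refractive
index of 1.4.

**Scaled photon-record Monte Carlo.** A small seeded transport
simulation (isotropic scattering at a baseline µs, absorption-free,
Fresnel boundary with internal reflection) records exit weight and
total path length for every photon detected in the annulus. Any target
optical properties are then evaluated by Beer–Lambert rescaling,
R(λ) = (1/N)·Σⱼ wⱼ·exp(−µa(λ)·Lⱼ·µs,base/µs′(λ)), normalized per
detector area. The transport core was verified against the exact
Chandrasekhar H-function total reflectance for an isotropic-scattering
half-space (agreement to 0.2%).

**Where the two models agree.** At the default separation — about 0.75
transport mean free paths at tissue-like µs′ = 10 cm⁻¹ — diffusion
theory is at the edge of its validity. The two models agree within a
few percent at low absorption, but the deviation grows with µa/µs′:
roughly 10% at a ratio of 0.05 and ~15–20% by 0.09, because the dipole
source under-represents the long photon paths that absorption
preferentially removes at sub-mfp distances. The cross-model sanity
test therefore asserts 15% agreement over µa/µs′ ∈ [0.01, 0.065], the
envelope where both models are genuinely reliable; a distributed-depth
source variant was evaluated and did not improve the near-field
behavior. All quantitative studies in the package use one model for
both generation and inversion, so this forward-model disagreement never
enters their error budgets.

**Bandpass degradation.** Illumination through a filter or LED of
finite spectral width averages the reflectance over the band. This is
modeled by convolution with a Gaussian of the source's FWHM
(σ = FWHM/(2√(2 ln 2))), discretized on the grid, truncated at ±3σ and
renormalized per output sample — band edges are averaged over the
in-band neighbors rather than padded with invented reflectance. A
caller-supplied unit-sum kernel generalizes this to measured LED line
shapes; the Gaussian is the only shape exercised by the tests.

## The absorber basis

Two bases ship with the package. The *surrogate* basis is fully
synthetic: Gaussian bands placed to echo the qualitative structure of
the real chromophores (an oxyhemoglobin α/β doublet at 542/577 nm over
a blue-side Soret tail, one broad deoxyhemoglobin band at 555 nm, a
broad beta-carotene band below 520 nm, a crocin band near 440 nm), with
peak extinctions giving tissue-realistic absorption at micromolar
concentrations. Every test and every reported number uses it, so the
package is self-contained and download-free. The *bundled* CSV tables
are coarse 10 nm approximations of the published curve shapes, provided
for realistic-looking demonstrations and file-format examples only.

Because the surrogate bands are smooth and exactly known, closure tests
(generate → invert → compare) isolate the numerical behavior of the
method itself. What they deliberately do *not* probe: calibration
error, chromophores missing from the basis, probe pressure and contact
variation, and spatial heterogeneity under the probe — the error
sources that dominate real tissue data. Synthetic noise
(`cohort_spec`) injects a controllable stand-in for these.

## Inverse model

`extract_properties()` fits five free parameters — c_HbO₂, c_dHb, c_βc
and the two scattering power-law parameters (a, b) — by minimizing the
sum of squared reflectance residuals at the chosen wavelengths, so at
least 5 center wavelengths are required; fewer raises an explicit
under-determination error. Bounds: concentrations up to three times the
top of the tissue design ranges, a ∈ (0, 30] cm⁻¹, b ∈ [0.1, 3].
Whether scattering counts as one parameter or two is a modeling choice;
fitting both power-law parameters (the package default) is the
conservative reading consistent with the 5-wavelength minimum.

Initialization matters more than polish here. The objective has a
strong spurious basin (high THb compensating low scattering) that traps
plain uniform multistarts for dim, lightly scattering tissue, so the
package uses:

- **log-scale Latin-hypercube starts** for the concentration and
  amplitude coordinates (geometric spread, floor at 1/300 of the upper
  bound), so the low-concentration corner is sampled as densely as the
  bulk;
- a **two-stage fit per start** — Levenberg–Marquardt on
  log-reflectance residuals first (wide, well-conditioned basin), then
  a raw-residual polish that defines the reported objective;
- **early exit** once a start reaches a numerically perfect fit
  (residual norm < 1e-9 of the observation norm), and **escalation**
  from 5 to up to 15 starts when the best relative residual exceeds
  `escalate_tol`. The tight default (1e-6) suits noiseless spectra; the
  studies on noisy cohorts pass 0.05, just above their ~3% noise floor.
  Ties between starts resolve to the lower THb, making extraction
  deterministic.

With this scheme, full-grid extraction recovers all 15 training
fixtures and 100-draw synthetic cohorts to machine precision (the
0.5% closure requirement is met with orders of magnitude to spare).

## Genetic search over wavelength sets

A candidate solution is a set of k distinct on-grid center wavelengths.
Fitness is the RMS of the 45 absolute percent errors (15 training
spectra × 3 summaries) of reduced-set extraction against the
full-spectrum reference of the same spectrum. The generational loop
uses rank-based elitism (top 15 of 50 copied unchanged — which makes
the best-of-generation fitness provably non-increasing), roulette
parent selection with probability proportional to 1/fitness (zero
floored at 1e-12), single-point crossover on the sorted parents with
duplicate repair by fresh uniform draws, and Gaussian mutation of one
uniformly chosen member (σ defaults to 3 grid steps — the protocol
fixes no value; mutation could equally draw a fresh wavelength over the
whole range, and the perturbation reading was chosen as the more local
operator), snapped to the grid and clamped to the range. With the
default 20% crossover fraction, each generation breeds
round(0.2 × 35) = 7 crossovers and 28 mutations. Termination: the
generation minimum unchanged (relative tolerance 1e-9) for 10
generations, or 50 generations.

Fitness values are cached by wavelength-set key within a run, and the
entire evolution trace is reproducible from `rng_seed`.

Two properties anchor correctness. On a deterministic toy problem —
three narrow-band absorbers on a 10-point grid, concentrations
recovered by linear unmixing from 3 chosen wavelengths against a fixed
noise realization, all C(10,3) = 120 subsets enumerable — the GA
reaches the exhaustive-search optimum from multiple seeds. And on noisy
tissue-like cohorts, extraction error falls steeply from 5 to 8
wavelengths with much smaller change from 8 to 12 — the diminishing
returns knee that motivates an 8-wavelength design. Note that on
*noiseless* synthetic training spectra nearly any well-conditioned
subset of ≥ 5 wavelengths inverts exactly (the model has only 5
unknowns), so meaningful wavelength optimization requires the noise
model; the knee study uses fixed nested sets (5 ⊂ 8 ⊂ 12, placed on
the surrogate's band structure: Hb doublet flanks, the βc shoulder
below 520 nm, and red-end scattering anchors) rather than re-running
the GA per cohort, keeping the study fast and deterministic.

## Synthetic data

`generate_cohort()` draws THb ∈ [10.7, 97.9] µM, βc ∈ [7.0, 37.6] µM
and ⟨µs′⟩ ∈ [3.7, 11.9] cm⁻¹ uniformly — the spread of extracted
ex vivo breast tissue properties the method is designed around — with
hemoglobin split by a configurable oxygen saturation (default 0.7; the
tissue tables the ranges come from report only totals, so tests compare
THb, never the oxy/deoxy split). The scattering exponent is drawn from
[0.5, 1.5] and the amplitude calibrated so the 450–600 nm mean µs′
equals the drawn target exactly. Uniform draws (rather than an
empirical cdf shape) are used because the percentile-based training
selector consumes only order statistics. Noise follows
R·(1 + ε_m) + ε_a with Gaussian terms (defaults: 3% multiplicative,
additive 0.5% of the mean reflectance — chosen once so full-spectrum
extraction errors land in the single-digit-percent regime of a
well-calibrated instrument; these are tuning knobs, not measured
characterizations). Negative values are clipped at zero; clip events
are counted and rare (< 0.1% at the defaults).

`generate_phantom_set()` builds the 20-phantom validation design: 5
crocin steps × 2 hemoglobin levels × 2 polystyrene-sphere scattering
levels (mean µs′ 9 and 12 cm⁻¹, representative of malignant and normal
breast tissue). Component concentrations are calibrated by linearity so
each phantom's 450–600 nm mean component µa matches its design cell
exactly, and sphere number density likewise for ⟨µs′⟩. Phantom spectra
are generated with Mie scattering but *extracted* with the power-law
scattering model — deliberate, realistic model mismatch, which is why
phantom RMS errors (a few percent) are the package's most honest
accuracy figures.

## Validation statistics

- `bland_altman()`: differences reduced − full, bias and 1.96·SD limits
  of agreement (positive bias = over-estimation by the reduced set).
- `rank_sum_compare()`: two-sided Wilcoxon rank-sum via the
  tie-corrected normal approximation (no continuity correction); a
  fully tied pooled sample returns p = 1.
- `map_correlation()` / `classify_margin()`: Pearson r over the shared
  valid-pixel mask, and the margin rule — positive when ≥ 98% of valid
  pixels have βc/⟨µs′⟩ strictly below 6. Strict inequality at the pixel
  threshold and ≥ at the fraction follow the clinical rule's wording;
  `classify_margin` is monotone in the ratio threshold.
- `run_bandpass_study()`: extraction error of degraded spectra against
  the *undegraded* full-spectrum reference, mean absolute percent error
  per (set, FWHM) cell, flagged acceptable below 10%. On the packaged
  training fixtures the full-grid error passes 10% between 10 and 20 nm
  FWHM, reproducing the design guidance that sources should stay below
  ~10 nm FWHM.

## Numerical choices and degenerate inputs

- Grid arithmetic is integer-index based, so 2.5 nm steps never
  accumulate float drift; grid membership and subset matching use half
  a step as the tolerance.
- Absorber curves are linearly interpolated within their tabulated
  support; extrapolation is refused rather than guessed.
- Mie efficiencies use the Bohren–Huffman series (downward recurrence
  for the logarithmic derivative, Wiscombe truncation); an independent
  half-integer-order Bessel implementation serves as the test oracle.
- The diffusion boundary moments are integrated with the critical-angle
  kink split out analytically and are memoized per refractive index.
- Degenerate inputs fail loudly: empty masks, constant maps (undefined
  correlation), under-determined subsets, reversed grids, negative
  FWHM, duplicate wavelengths.

## Problem sizes

The shipped studies use 100-draw cohorts for closure and knee studies,
15 training fixtures × 8 FWHM levels for the bandpass sweep, 10⁵ draws
for roulette calibration, 5 × 10⁴ photons for the photon-record
fixture, and the 120-subset toy benchmark for GA correctness — sizes at
which every study is exactly reproducible from its seed and the whole
suite runs in a couple of minutes on one core.

## Known limitations

- The forward models are reference implementations of the contract, not
  reproductions of any probe-calibrated lookup table; absolute
  reflectance units are arbitrary-but-consistent, which the inverse
  model tolerates because generation and inversion share the model.
- Diffusion accuracy at the default sub-mfp separation degrades with
  absorption (see above); the scaled-MC model is the better reference
  when absolute near-field accuracy matters.
- The noise model is spectrally white; real instruments drift and their
  noise is structured.
- Wavelength sets optimized against the surrogate basis are not the
  sets one would deploy against real tissue — the *method* transfers,
  the specific wavelengths do not.
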