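---
title: "Recognising SERS mixtures from pure-compound training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising SERS mixtures from pure-compound training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) gives molecular fingerprint
spectra at trace concentrations, but spectra of *mixtures* are hard to
recognise: co-adsorbing analytes compete for the enhancing surface, so
bands overlap, attenuate, or disappear outright, and collecting labelled
spectra for every possible combination of analytes scales
combinatorially. `sersmix` implements a recognition strategy that trains
only on pure-compound spectra and still assigns mixture categories. The
working system is three pesticides — paraquat (A), thiram (B) and
tricyclazole (C) — with seven categories: A, B, C, AB, AC, BC, ABC.

The pipeline has four parts:

1. a **synthetic SERS generator** producing pure and mixed spectra with
   the statistical structure of the emulated measurements;
2. a **preprocessing chain** mapping a raw spectrum to a fixed-length
   feature vector;
3. a **dual-branch spectral network**: a shared 1-D residual encoder
   with a large-margin cosine classification head and a sigmoid
   component-evidence head, trained on pure spectra only;
4. **two-stage inference**: set-likelihood ranking of candidate
   component sets, followed by a nonnegative-least-squares (NNLS)
   residual test that can upgrade a binary prediction to the ternary
   category.

## Preprocessing

A raw spectrum (wavenumber, intensity) is mapped to the model input by,
in order:

1. **Crop + resample**: restrict to the fingerprint region
   [500, 1800] cm⁻¹ and linearly interpolate onto `n_points = 2048`
   uniform points.
2. **Savitzky–Golay smoothing**, window 5, polynomial order 2
   (`signal::sgolayfilt`; edge points use the polynomial-fit edge rows
   of the projection matrix, avoiding padding artefacts that min–max
   scaling would amplify).
3. **Iterative polynomial baseline correction** (modified polyfit):
   fit a polynomial of order 5, clip the spectrum to the fit from
   above, refit; stop at 100 iterations or when the baseline changes by
   less than 1e-6 of the intensity scale. The corrected spectrum is
   floored at zero (SERS intensities are nonnegative, and flooring
   keeps the subsequent power transform real). The polynomial order,
   iteration cap and tolerance are exposed in `preproc_config()`
   because the method family fixes none of them.
4. **Min–max normalisation + power transform**
   `y = ((s - min)/(max - min))^1.5`, mapping the spectrum to [0, 1]
   and sharpening peak-to-valley contrast.

Smoothing precedes baseline correction; the reverse order is defensible
too, but the chain is fixed this way and all stated tolerances refer to
it. One numerical caveat worth knowing: the clip-above-fit baseline
scheme has no exact fixed point — re-running the full chain on its own
output moves intensities by about 5 × 10⁻⁵ (the polynomial lower
envelope of a zero-floored spectrum is a small wiggle, not exactly
zero). The test suite asserts idempotence at 1e-4.

## The dual-branch network

The encoder is a 1-D residual convolutional network: a stem convolution
(kernel 7, stride 2) with batch norm, ReLU and max-pooling, a stack of
basic residual blocks (stride 2 between stages), global average pooling
and a linear projection to a `d`-dimensional embedding `f`. Two heads
read the same embedding:

* **Classification head** (pure classes): large-margin cosine logits
  `s_cls · (cos θ_k − m·1[k = y])` with margin `m = 0.35` and scale
  `s_cls = 16`, trained with cross-entropy. The margin widens
  inter-class angular separation.
* **Evidence head** (per-component presence): evidence scores `u_k`
  mapped to probabilities `p_k = σ(u_k)`, trained with binary
  cross-entropy against the one-hot component indicator of the pure
  class, plus a clipping regulariser `mean_k max(0, |u_k| − 6)²`
  (weight 0.01) that keeps evidence magnitudes calibrated.

Whether the evidence head is cosine-parameterised or a plain affine
layer is genuinely open; both are implemented
(`model_config(evidence_head = )`). The default is the cosine form: the
presence of an evidence *scaling factor* (16.0) among the method's
stated hyper-parameters presupposes a bounded pre-scale score, which the
cosine gives and an affine layer does not.

The whole network — convolutions, batch norm, pooling, backpropagation
and AdamW — is implemented in base-R matrix algebra (BLAS-backed im2col
convolutions). Gradients are verified against central finite differences
to ~1e-7 relative error in the test suite's supporting experiments.

## Training and checkpoint selection

Training uses AdamW (lr 1e-3 cosine-annealed to 1e-5, weight decay
1e-4, batch 32, 3000 steps at the default profile) on **pure spectra
only**; a guard raises an error if a mixture category ever reaches the
loss. Batches are class-balanced. Every 50 steps the model is evaluated:
pure-spectrum validation accuracy from the classification branch, and
seven-category validation accuracy from unified two-stage inference.
Checkpoint selection mirrors the mixture-aware protocol: among
evaluations after step 500 with pure validation accuracy ≥ 0.95, keep
the one with the highest seven-category validation accuracy; ties go to
the latest step (most annealed weights). Optimal pure-class accuracy
does not imply optimal mixture transfer, which is exactly why selection
uses the seven-category criterion.

## Two-stage inference

Stage 1 scores candidate component sets with the log-domain
set-likelihood

    Score(S) = Σ_{k∈S} log p_k + Σ_{k∉S} log(1 − p_k),

with probabilities clamped to [1e-7, 1 − 1e-7]. In `pairs_only` mode the
candidates are AB, AC, BC (the mixture-only evaluation); in `unified`
mode singletons compete too, and a singleton winner is returned as a
pure prediction. The ternary category never competes in stage 1 — it is
reachable only through refinement. Exact ties break to the
lexicographically smallest candidate.

Stage 2 reconstructs the spectrum by NNLS (`pracma::lsqnonneg`,
Lawson–Hanson) on class-mean prototype spectra under the winning binary
hypothesis and under the full ternary hypothesis, giving residuals
`e_bin ≥ e_tri` (nesting is guaranteed by the enlarged nonnegative
support and asserted at run time). With residual gain
`g = (e_bin − e_tri)/e_bin` (0 when `e_bin = 0`) and missing-component
ratio `ρ = β_missing / Σβ` (0 when all weights vanish), the decision is
ternary iff `g ≥ τ_g = 0.040` **and** `ρ ≥ τ_ρ = 0.080`; otherwise the
binary prediction stands. The residual metric is squared L2 by default;
since `g` changes under plain L2, the metric is a config field rather
than a constant.

## The synthetic generator

No measured spectra are distributed with the package, so the generator
stands in for them and is itself first-class, tested code. It emulates:

* **Band structure**: Lorentzian lines (near-Lorentzian shapes are the
  Raman norm; Gaussian available for tests) at the characteristic
  positions of the three compounds, FWHM drawn once per configuration
  from 10–16 cm⁻¹; relative amplitudes drawn once from [0.3, 1] with the
  reference band (840, 1380, 1589 cm⁻¹ for A, B, C) fixed at 1.
* **Enhancement imbalance**: per-component scalars A:B:C = 3:1.5:1,
  emulating paraquat's much stronger SERS response.
* **Replicate variability**: per-band amplitude jitter with 8% relative
  SD and ±2 cm⁻¹ position jitter, reproducing the reported ~7–8%
  replicate RSD of reference bands at fixed concentration.
* **Concentration series**: each dataset sample draws a log-uniform
  concentration factor from [0.25, 1] scaling the analyte signal but not
  the baseline or noise floor. The emulated experiments span a
  decade-scale dilution series, which gives the pure classes substantial
  within-class diversity in signal-to-background ratio; without it the
  synthetic classes are unrealistically tight and a classifier can
  succeed with global-shape features that do not transfer to mixtures.
* **Baseline**: order-2 polynomial drift plus one broad Gaussian
  fluorescence hump (FWHM 300–600 cm⁻¹), matching the usual sources of
  SERS background (scattering, instrument drift, fluorescence).
* **Non-linear mixing**: mixtures are weighted sums of jittered
  component profiles followed by competitive masking. A weaker
  component's band is attenuated by `1 − masking_strength · dom · κ`,
  where `dom = 1 − I_weak/I_strong` on effective intensities
  (weight × enhancement), `κ = 1` when the band lies within one FWHM of
  a stronger component's band, and `κ = 0.5` otherwise. The two-level
  `κ` reflects the two mechanisms seen in mixed SERS spectra: direct
  band overlap, and whole-spectrum suppression of the weaker analyte by
  competitive adsorption (tricyclazole bands far from any paraquat band
  are still visibly suppressed in paraquat–tricyclazole mixtures).
  `masking_strength` defaults to 0.5; 0 recovers exact linear
  superposition.
* **Mixing ratios**: the emulated mixtures are prepared at equal volume
  ratios of equal-concentration stocks, so per-component weights are
  drawn as Normal(1, 0.05) (pipetting variability), not from a wide
  ad-hoc range.
* **Split design**: training 157/215/220 pure spectra for A/B/C;
  validation and test cover all seven categories at 50 and 53 per
  category. Mixtures never enter the training split (attempting to
  raises an error).

All randomness derives from one master seed through named sub-streams
(library, jitter, baseline, noise, weights, concentration), so a
configuration reproduces its dataset bit for bit, and a mixture with
weights (1, 0) over {A, B} is *exactly* the corresponding pure-A
replicate.

What the generator does **not** model: physical
electromagnetic/chemical enhancement, concentration–response curves,
cosmic-ray spikes, wavelength miscalibration, or instrument-specific
line-shape asymmetries. Passing tests on synthetic data therefore show
that the pipeline's logic and statistics behave as specified — not that
the accuracy figures transfer to any particular instrument's data.

## Problem sizes and the reduced profile

The default profile is the full-size configuration: 2048-point features,
stem 32 channels, stages 32/64/128/256, embedding 128, 3000 steps. The
package also defines a documented reduced `"ci"` profile for quick
single-CPU runs — 512-point features, stem 16, stages 16/32/64,
embedding 64, 800 steps — used by the test suite and the acceptance
script. All method-level hyper-parameters (margin, scales, clip,
learning-rate schedule, weight decay, batch size, eligibility floor,
warm-up, τ_g, τ_ρ) are identical across profiles.

## Known limitations

* Evidence learned from pure spectra transfers to mixtures only insofar
  as mixture embeddings interpolate between pure-class embeddings. On
  the default synthetic conditions this holds down to a minority-share
  of roughly 35%: probing trained models, a pure-thiram feature vector
  scaled to 0.3 still receives evidence p_B ≈ 0.6, and a 50/50 linear
  feature blend of paraquat and thiram ranks correctly, but a 70/30
  blend collapses to the dominant class (p_B ≈ 0.005). Since paraquat's
  2:1 effective-intensity advantage over thiram (and 3:1 over
  tricyclazole) puts the minority share of equal-part AB and AC
  mixtures at ~25–30%, stage-1 ranking fails for a large fraction of
  those spectra, and mixture recognition accuracy plateaus at ~0.70–0.76
  across seeds and across every encoder variant tried (including the
  full-size 3000-step configuration): pure-class training pushes the
  minority component's evidence score toward its floor whenever the
  dominant component's features are present, and the mixture-aware
  checkpoint selection cannot rescue this because no checkpoint after
  the warm-up transfers any better. BC (the most balanced pair) and ABC
  are recognised nearly perfectly. The residual-based refinement is
  insensitive to this failure mode (it works directly on the spectrum,
  and separates true binaries from ternaries cleanly when the binary
  hypothesis is right), but by design it can only upgrade a pair to the
  ternary category, not repair a wrong pair — so a stage-1 error on AB
  typically surfaces as a spurious ABC.
* `K` is general in the code, but the refinement logic upgrades exactly
  one missing component (binary → ternary), as designed.
* Quantification (concentrations, mixing ratios) is out of scope; NNLS
  weights are used only for the missing-component ratio.
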