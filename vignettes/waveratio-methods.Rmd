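---
title: "Wavelet de-noising for isotope-ratio quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet de-noising for isotope-ratio quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveratio)
```

## The signal model and what the de-noiser assumes

An extracted-ion chromatogram is modelled as x(t) = s(t) + n(t): a smooth,
mostly-sparse elution signal plus additive Gaussian white noise of constant
level σ. Everything downstream leans on three consequences of this model:

* under an **orthonormal** DWT, white noise stays white with the same σ at
  every scale, while s(t) concentrates into few large coefficients;
* the noise level is estimable robustly as σ̂ = MAD/0.6745 of the
  finest-scale details, because genuine signal is sparse there;
* noise coefficients stay below the universal threshold T = σ̂√(2 ln N)
  with high probability, so coefficients under T can be discarded.

Heteroscedastic (intensity-dependent) shot noise, chemical background with
structure, and retention-time drift between partners are *not* part of this
model; see "Limitations".

## The de-noising pipeline

`denoise_signal()` chains: DWT (4 levels) → σ̂ from scale 1 → spatial
adaptive mask → threshold re-calculation on unmasked coefficients → hybrid
shrinkage of unmasked details → inverse DWT. Masked coefficients and the
approximation band pass through untouched.

### Hybrid shrinkage

Hard thresholding keeps surviving coefficients intact (sharp peaks, rough
reconstruction); soft thresholding shrinks them by T (smooth, but biased
amplitudes and therefore biased areas). The hybrid rule

  out = 0 if |w| ≤ T, else sign(w)·(|w| − λT)

is the unique linear-in-λ interpolation that is exactly hard at λ = 0 and
exactly soft at λ = 1. The λ-endpoint equivalence is asserted exactly in the
test suite on 1000 random (w, T) pairs. Default λ = 0.25, the midpoint of
the documented 0.1–0.4 operating range; raise λ for smoother traces, lower
it for better amplitude fidelity.

### The spatial adaptive algorithm

A genuine singularity (peak flank, step edge) produces large coefficients
at *aligned positions across adjacent scales*; white noise decorrelates
across scales. The per-position product of adjacent-scale coefficients,
Corr₂(j,n) = W(j,n)·W(j+1,n′) (n′ the coarser position covering n under
dyadic decimation), therefore amplifies signal and suppresses noise. After
rescaling each Corr₂(j,·) to the energy of W(j,·) — making the two
magnitude-comparable — positions where |NewCorr₂| ≥ |W| are classified as
signal, extracted from the working copy, and protected from thresholding;
the comparison repeats on the residue until the residual energy at a scale
reaches the white-noise floor stop_factor·σ̂ⱼ²·nⱼ.

Two choices here were genuinely open:

* **Loop structure.** The extraction loop is guarded: a scale whose energy
  already sits at the noise floor never extracts anything. The alternative
  (extract at least one pass everywhere) classifies roughly a third of
  pure-noise coefficients as signal — those positions then bypass
  thresholding and the de-noising benefit collapses. With the guard, a
  pure-noise trace yields an (almost always) empty mask.
* **Ties.** |NewCorr₂| = |W| classifies as signal: deterministic, and errs
  towards retaining signal.

`detect_edges()` exposes the mask's localization power directly: it
reconstructs a trace from the masked coefficients alone and reports energy
centroids of the evidence clusters. Haar analysis is used there by default
because its two-tap support localizes position most sharply.

### Threshold scope

The noise σ is estimated **once, on the finest scale** (after masking), and
the resulting threshold is applied on every detail scale — valid because an
orthonormal transform keeps white noise at equal σ across scales. The
alternative mode (`threshold_scope = "per-scale"`) re-estimates σⱼ per
scale; it is kept behind a flag because coarse-scale MAD is contaminated by
the peak itself, which inflates thresholds and measurably biases peak areas
downward (≈ −13% on the standard fixture at high noise).

### Boundaries, lengths, degenerate inputs

* Periodic extension is the default: it preserves exact energy conservation
  (Parseval) and perfect reconstruction (both asserted at 1e-8). The
  `"reflect"` mode mirrors the signal to twice its length first, avoiding
  wrap-around artefacts on traces whose ends differ, at doubled cost.
* Lengths that are not multiples of 2^J are edge-padded internally; the
  padding is stripped after reconstruction. Signals shorter than 2^J reduce
  the depth to the largest feasible J rather than failing.
* A zero trace de-noises to a zero trace; the all-noise case yields an
  empty mask and plain universal thresholding.

## Chromatogram quantification

* **Region finding** walks outward from the de-noised apex until the trace
  decays to background + 5% of the apex height above background
  (`boundary_factor = 0.05`, cutting a Gaussian at ±2.45σ).
  Apex ties break to the earlier scan.
* **Overlap splitting** cuts a region at a valley whose depth below the
  smaller flanking apex exceeds 50% of that apex's height above background
  (`valley_fraction = 0.5`), keeping the sub-peak nearest the expected
  retention time. Fully merged peaks (no qualifying valley) are left whole
  — a deliberately conservative rule.
* **Background** is the median of the de-noised trace in 10-scan flanks
  outside the region. After a split, the flank on the valley side sits on
  the co-eluting species and is excluded; without that exclusion the
  neighbour peak inflates the background and the area error grows by an
  order of magnitude.
* **Areas** are trapezoidal integrals of max(denoised − background, 0)
  over retention time in seconds, so they carry physical units and tolerate
  uneven scan spacing.

## Ratio aggregation

Charge states merge by a weighted arithmetic mean with weight
light + heavy area (total ion current ≈ reliability); peptides with zero
heavy area are flagged undefined and excluded, never imputed. Protein
ratios are arithmetic means of unique-peptide ratios after recursive
elimination: round 1 keeps ratios in median m ± √m, later rounds in mean
A ± √A (closed intervals), until the survivor set is stable or a single
ratio remains. The √-width adapts the acceptance band to the ratio's
magnitude. Ratios are averaged directly, not in log space; a log-space mode
would treat L/H and H/L symmetrically but is not the default because the
aggregation rule is defined on the plain ratios. One guard was added: if a
round's band excludes *every* ratio (possible for pathological spreads,
e.g. {0.01, 100}), the ratios closest to that round's centre are kept —
the aggregate must always have at least one survivor.

## The synthetic world

`synthetic_spec()` states the world the tests live in: Gaussian elution
peaks (amplitude 100, width 5 scans ≈ 12 s FWHM at 1 s/scan) on a flat
baseline with additive white noise, light partner = heavy geometry ×
mixing ratio with independent noise. Defaults are 5% apex noise and a
baseline of 3× the noise σ, so that clipping intensities at zero stays
negligible. The ratio sweep {0.5, 0.67, 1, 1.5, 2} with 20 pairs per ratio
replicates the design of a known-mixture yeast benchmark. True areas are
closed-form (amplitude·σ·√2π), so every stage has an analytic oracle.

What the generator does **not** emulate: isotope envelopes, chemical noise,
intensity-dependent noise, retention-time drift between partners, and
detector saturation. A green ratio-sweep test therefore establishes that
the engine recovers ratios under its own noise model — not that it
reproduces any particular instrument's behaviour.

## Known limitations

* At very high noise (S/N ≈ 5 in the chromatographic height-over-noise
  sense, i.e. noise at 20% of the apex), the rectified residual noise that
  survives under protected coefficients can make de-noised *area* errors
  comparable to or slightly worse than raw-trace integration, even though
  the de-noised trace's RMSE is less than half the noisy trace's. At the
  5–10% noise levels of the standard fixtures, de-noised integration is
  strictly better.
* The mzML reader/writer covers the minimal subset the pipeline needs
  (MS1 spectra, uncompressed 64-bit arrays); it is not a general-purpose
  mzML implementation, and mzXML is not supported.
* Quantification assumes centroided (or near-centroided) spectra and an
  absolute m/z tolerance (0.5 Th default; ppm mode available).
* The dynamic range of ratio recovery is bounded by the noise on the weaker
  partner; ratios far outside [0.5, 2] degrade as the weak partner's area
  approaches the noise floor.
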