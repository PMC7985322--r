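---
title: "Quantifying condensate disruption: models, conventions, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate disruption: models, conventions, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensr)
```

## The measurement problem

A cell expressing a condensate-forming scaffold protein partitions that
protein between a dense phase (bright droplets) and a dilute pool
(cytosol or nucleoplasm). Disruption experiments ask two questions: how
much of the condensed material is lost after a treatment, and how fast.
Both reduce to one per-frame decomposition. After background
subtraction, with a condensate mask and a cell mask:

$$F \;=\; \frac{A_{dense}\,( \bar I_{dense} - \bar I_{dilute})}{\sum_{cell} I}$$

is the fraction of the cell's total signal held in condensates. The
numerator is the *excess* integrated intensity of the dense phase — the
dilute mean is subtracted because condensate pixels also contain pool
signal. Percent disruption efficiency between a pre-treatment and a
post-treatment image is

$$E = 100\,\frac{F_{pre}-F_{post}}{F_{pre}},$$

reported next to the pre-treatment partition ratio
$\bar I_{dense}/\bar I_{dilute}$. Negative efficiencies (growth) are
reported and flagged, never clipped — growth is informative.

Assumptions worth stating: intensities are proportional to fluorophore
concentration (no saturation), the background is spatially flat enough
that a scalar estimate suffices, and the cell does not move appreciably
over the timecourse (no registration is performed).

## Segmentation conventions

Thresholds are histogram-derived with 256 bins spanning the per-image
`[min, max]` range, the convention of common interactive analysis tools
on 8-bit-like data; a pixel is foreground when *strictly greater* than
the threshold. Otsu maximizes between-class variance; the
maximum-entropy method maximizes the sum of class-conditional Shannon
entropies; the Mean method (cell masks) is simply the image mean. Ties
break toward the lower threshold. Both histogram thresholds are verified
against exhaustive search over every candidate bin edge, and all masks
are invariant to affine intensity rescaling by construction. Cell masks
are morphologically closed (5-px disc) and hole-filled; condensate
objects smaller than `min_object_px` (default 4 px) are discarded to
suppress single-pixel shot noise — the size filter is a choice, not an
established convention, and is exposed and logged.

### Held threshold vs held footprint

Timecourse analysis of a dissolving movie must not re-threshold every
frame independently: once the droplets dim, the histogram method
hallucinates foreground elsewhere. `segment_stack()` therefore computes
the condensate threshold once on a reference (pre-treatment) frame and
holds it. But a held *threshold* still yields a shrinking *mask* as
pixels fall below it, which conflates area loss with intensity loss and
biases fitted time constants low (we measure ~35% low on noiseless
sigmoid movies). For kinetics and for pre/post efficiency the package
therefore measures on the *fixed footprint*: the pre-treatment
segmentation applied to every frame (`condensate_timecourse()` accepts a
single segmentation; the pipeline and the recovery studies use this
convention). The per-frame held-threshold masks remain available — their
shrinking area is itself a useful property (and is tested) — but the
quantified observable is intensity on a fixed region. Which convention
the field's interactive workflows used is typically unstated; this
package makes the choice explicit and documents it.

## Kinetic models

The condensate observable (default: the integrated excess
$A(\bar I_{dense}-\bar I_{dilute})$ on the fixed footprint) is fitted
with either

- sigmoid: $v(t) = base + A/(1+\exp((t-t_{1/2})/\tau))$, the logistic
  with $\tau$ as the characteristic time. Users comparing against other
  parameterizations (10–90% rise time $= 2\ln 9\,\tau \approx 4.39\tau$)
  can convert directly.
- exponential: $v(t) = base + A\exp(-(t-t_{start})/\tau)$, fitted only
  to points at $t \ge t_{start}$ (pre-treatment frames pin the sigmoid's
  plateau but are excluded from exponential fits, which model the decay
  after treatment addition).

Fitting is bounded Levenberg–Marquardt least squares (`minpack.lm`) with
$\tau > 0$, relative tolerance $10^{-8}$, at most 1000 iterations.
Initialization is derivative-free: base and amplitude from the series
extremes, $t_{1/2}$ from the half-crossing, $\tau$ from the 25–75%
crossing span divided by $2\ln 3$. A degenerate (flat) series or an
optimizer failure returns `converged = FALSE` with a reason — never a
fabricated $\tau$. Fold changes between two fitted $\tau$'s carry
first-order propagated uncertainty.

One documented ambiguity: published descriptions of this workflow state
that cluster-reversion data were fitted to an exponential while the
characteristic times were "calculated from sigmoidal fits" — an internal
inconsistency we do not resolve by guessing. Both models are provided;
in the far post-midpoint regime they agree on $\tau$ within 5% (tested),
so the distinction rarely matters for well-sampled decays.

## FRAP normalization

The bleached-region integrated density is divided by the whole-cell
background-free integrated density — a ratio that cancels global
acquisition photobleaching exactly (tested against a simulated
whole-field exponential dimming) — then mapped to $[0,1]$ with the
bleach frame at 0 and the pre-bleach average at 1. Post-bleach values
above 1 are left unclipped: the expectation stays in $[0,1]$, noise may
not, and clipping would bias plateau estimates. The apparent bleach
depth is checked against the 60–85% band instrument calibrations
typically target, with a classed warning outside it. The bleached-region
mask is drawn at the bleach frame and held fixed; region tracking is out
of scope.

## The synthetic movie generator

The simulator renders an elliptical cell (optional nested nucleus) at a
uniform dilute level over a dark background, with non-overlapping
anti-aliased droplet discs (area-weighted edge pixels, because sub-pixel
rims are what stress thresholding in real images) carrying a dense-phase
excess of `dilute_level * (partition_coefficient - 1)` photons/pixel.
Dissolution multiplies that excess by a closed-form profile — logistic,
exponential, constant, or rising logistic — and redistributes the lost
integrated intensity uniformly into the cell, so the expected photon
total is constant in every frame (conservation is tested at $10^{-9}$
relative; mass balance is what makes the dilute-pool rise a real
signal). Noise is applied last: Poisson shot noise at `noise_gain`
photon scaling plus Gaussian read noise, with per-frame streams derived
from the master seed by fixed jumps so stacks are bit-identical for
identical configs and frame-count changes do not reshuffle earlier
frames.

Two conventions deserve a note:

- *Sigmoid timing.* "Decay from the onset" cannot hold exactly for a
  logistic, which never equals 1 at finite time. The midpoint defaults
  to `onset_s + 3 * tau_s`, leaving ≥95% of the transition after the
  onset, and the profile is a pure logistic so the true condensate
  fraction obeys `fraction(t) = fraction(0) * f(t)/f(0)` in closed form
  (tested against an independently coded scalar logistic).
- *FRAP recovery amplitude.* After destroying `depth · I_region`
  photons, the mobile material re-equilibrates with a pool that is
  itself depleted; the recovery amplitude is
  `mobile_fraction · depth · I_region · (1 − I_region/T_cell)`. With
  this (physically correct) amplitude the *normalized* plateau equals
  `mobile_fraction` exactly, because the normalization denominator is
  the post-bleach total. Naively recovering the full lost signal would
  overshoot the plateau by `T/(T − I_region)`.

Dissolution is intensity-excess decay at a fixed droplet footprint;
whether real condensates dim in place or shrink in radius during
disruption is generally not resolvable from published figures, and the
quantified observable is intensity, so excess decay is the default.
What the generator does *not* emulate: optical blur (no PSF), droplet
motion, fusion or ripening, cell movement or shape change, spatially
structured background, and 3-D rendering beyond trivially stackable Z
planes for projection testing. Passing recovery tests therefore
demonstrates the *estimators* are unbiased under the stated noise model,
not that segmentation survives optically challenging real data.

## Study conditions and degenerate inputs

The recovery studies (tests, `analysis/` drivers, and
`scripts/acceptance.R`) use 96×96-px cells with 6 droplets of 3–5 px
radius, dilute level 50, partition coefficient 6, background 10,
unit-gain shot noise and read noise sd 2 — a dense-phase SNR around 14 —
with 20 seeds per condition and 80–100-frame movies sized so sigmoid
regimes span the full transition and exponential regimes cover ≥3 decay
constants (τ regimes 22 and 30 s sigmoid; 65 and 472 s exponential,
matching which model suits fast ligand-induced dissolution vs slow
cluster reversion). Tighter sampling would only shrink the error bars;
these sizes keep a full verification run in tens of seconds.

Degenerate inputs are explicit errors, not silent numbers: constant
images for histogram thresholds, all-covering cell masks for background
estimation, `fraction_pre ≤ 0` for efficiency, non-positive totals for
ratios, traces with no bleaching, and non-converged fits in fold
changes. Empty condensate masks are *flagged results* (fraction 0),
since "no condensates" is a finding.

## Known limitations

- Whole-frame global thresholds fail at low dense/dilute contrast
  (partition coefficient ≲ 3): the histogram's dominant split is
  cell-vs-background and the condensate mask floods the cell (see
  `analysis/02_segmentation_fidelity.R`). Real workflows crop to the
  cell first; supplying `cell_mask` and thresholding within it is the
  equivalent here.
- One cell per scene: multi-cell fields need user- or truth-supplied
  instance masks; only the field-level aggregate ratio is computed
  without them.
- No FRAP diffusion modeling: the exchange fit is a single-exponential
  convenience summary, clearly a step beyond plotting the normalized
  curves, and says nothing about diffusion- vs reaction-limited
  recovery.
- TIFF round trips quantize to one part in $2^{32}$ (scaled 32-bit
  storage with a sidecar scale factor); byte-identical reproduction
  holds for repeated writes of the same stack.
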