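# condensr

Quantification of biomolecular condensates in fluorescence timelapse
microscopy, for cell biologists measuring how fast and how completely
condensates (FUS-like droplets, polyQ aggregates, optogenetic clusters)
dissolve after a treatment — a recruited disruptor ligand, a chemical
dimerizer, dark reversion — and how their material state shows up in FRAP.

Because raw condensate-imaging datasets are rarely deposited, the package
ships a ground-truthed synthetic movie generator that emulates the same
experiments (bright dense-phase droplets over a dilute pool, conservative
dissolution kinetics, bleach events, Poisson + Gaussian camera noise), so
the entire measurement chain is verified by parameter recovery rather than
by eye.

## What it computes

For each cell, after maximal Z-projection and histogram-threshold
segmentation (Otsu or maximum-entropy for condensates, Mean for the cell
footprint, all background-subtracted):

- **Condensate fraction** — the share of total signal held in the dense
  phase:
  `F = Area_dense · (MeanI_dense − MeanI_dilute) / TotalIntegratedDensity`
- **% disruption efficiency** between pre- and post-treatment images:
  `E = 100 · (F_pre − F_post) / F_pre`, reported alongside the
  pre-treatment dense/dilute intensity ratio `MeanI_dense / MeanI_dilute`
  and their per-cohort linear correlation
- **Condensate intensity ratio** — integrated condensate intensity over
  total cell integrated density (endpoint/field-level assays)
- **Dissolution kinetics** — the characteristic time τ from least-squares
  fits of `v(t) = base + A / (1 + exp((t − t_half)/τ))` (sigmoid) or
  `v(t) = base + A·exp(−(t − t_start)/τ)` (exponential) to the
  condensate-signal timecourse, plus fold changes between fitted τ's with
  propagated uncertainty
- **FRAP normalization** — region integrated density over total cell
  integrated density (cancelling acquisition bleaching), mapped to [0, 1]
  with the bleach frame at 0 and the pre-bleach mean at 1; recovery
  plateaus and an optional exponential exchange fit
- **Uptake percent** — background-subtracted marker intensity in
  transfected cells as a percent of untransfected neighbours

## Worked example

Simulate a dissolution movie (τ = 30 s, treatment at 60 s), segment the
pre-treatment frame, and quantify:

```r
library(condensr)

cfg <- sim_config(n_frames = 100, frame_interval_s = 3, tau_s = 30,
                  onset_s = 60, seed = 7)
sim <- simulate_dissolution_movie(cfg)

seg <- make_masks(get_frame(sim$stack, 1), condensate_method = "otsu")
bg  <- estimate_background(get_frame(sim$stack, 1), seg$cell_mask)

pre  <- partition_stats(get_frame(sim$stack, sim$truth$pre_frame), seg, bg)
post <- partition_stats(get_frame(sim$stack, 100), seg, bg)
disruption_efficiency(pre, post)
#> disruption: pre=0.2558 post=0.0011 efficiency=99.6% dense/dilute=5.23

tc <- condensate_timecourse(sim$stack, seg, bg, onset_s = 60)
fit_sigmoid(tc)
#> kinetic_fit (sigmoid): tau=29.98 s, base=-29.11, amplitude=8.53e+04, t_half=149.9 s, R2=0.9999
```

The segmentation found 376 dense-phase pixels over a 4625-px cell with an
Otsu threshold of 160; a quarter of the cell's signal sits in condensates
before treatment (`fraction = 0.256`). The estimated background (10.01)
matches the configured 10, the fitted τ of 29.98 s recovers the generating
30 s, and the 99.6% measured efficiency matches the movie's ground truth
of 99.2% (the logistic leaves a trace of excess at the final frame).

`run_pipeline(run_config(...))` chains the same steps end to end and
writes stack/mask TIFFs, tidy CSV tables and a JSON manifest; the
numbered scripts under `analysis/` run the full simulation studies
(segmentation fidelity, efficiency recovery, τ recovery, FRAP plateaus)
and leave their tables under `results/`.

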