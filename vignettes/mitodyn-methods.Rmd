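---
title: "Models and methods behind mitodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
modeling choices were genuinely open, how we resolved them, and what the
synthetic benchmarks do and do not show about real recordings.

## The measurement model

The photoactivation assay reads mitochondrial fusion through the mixing of
two soluble matrix markers: photoactivatable GFP (dark until a two-photon
pulse) and DsRed (bright, bleached by the pulse). All four imaging readouts
are deterministic functions of a two-channel series plus calibration
(`image_series`): pixel size (µm), frame interval (s), the 0-based index of
the first frame after the pulse (`t_act`), the activation squares in pixel
coordinates, and an optional cell mask. Frames before `t_act` are
pre-activation; analysis starts at `t_act`, the "immediately after
photoactivation" image, which is also the normalization frame of the ratio
time course. Treating `t_act` as already activated (the pulse is applied in
the transition into that frame) matters: the first ratio sample must see
the activated GFP still confined to the RPA, before any post-activation
mixing, otherwise the decay of a well-connected network is invisible.

### Thresholding conventions

Three thresholding rules are used, all with the convention that a pixel is
*suprathreshold* when `value >= t` (for masks) and strictly `> 32` for the
motility constant, which the source procedure phrases as "above the
threshold":

* **Series-level Otsu** (`otsu_threshold_series`): one pooled histogram per
  channel over the post-activation frames (restricted to the cell mask),
  exhaustive search for the level maximizing between-class variance, ties
  broken toward the lowest level. We search at native gray-level resolution
  for 16-bit data too: the cumulative-histogram search is linear in the
  number of levels, so the usual coarse-bin-then-refine approximation buys
  nothing and costs exactness. Pooling post-activation frames (rather than
  all frames, or a projection) is a documented choice: pre-activation GFP
  frames are empty and would drag the split downward.
* **Noise-ratio threshold** (`noise_ratio_threshold`): the smallest `t`
  such that at most 0.1% of in-cell pre-activation pixels satisfy
  `value >= t`. Pre-activation GFP is pure noise, so this operationalizes
  "thresholded to reach a 0.1% noise-to-signal ratio" as a bound on the
  false-positive pixel fraction; it equals the empirical 99.9th-percentile
  order statistic plus one gray level.
* **Despeckle** (`despeckle`): the ImageJ 3×3 median with edge replication,
  applied before any Otsu thresholding in the fusion analyses.

### The ratio decay and its oracle

`rpa_decay` reports `decay_500s = 1 - R(500 s)` with R normalized at
`t_act`; 500 s values are linearly interpolated between bracketing frames,
and a series that ends earlier is summarized at its last frame with
`at_500s = FALSE`. Whether the printed decay is `1 - R(500)` or
`R(0) - R(500)` is ambiguous in prose; under normalization the two
coincide, which is why we normalize first. The DsRed ROI mean must exceed a
floor (default: mean + 3 sd of the pre-activation GFP channel — the only
pure-noise data in the series) or the ratio is refused as undefined.

On simulations the ledger oracle `rpa_from_ledger` recomputes the same
ratio from ground-truth segment amounts: for a single connected component
the equilibrium ratio is the activated fraction of the content, so the
decay has a closed form against which the image-based measurement is
checked (10% agreement on noise-free renders; the residual comes from
partial-pixel coverage of capsules at the ROI border).

## The simulator

`simulate_mito` is intentionally the simplest generative model the
measures can grade, with one seeded RNG stream consumed in a fixed order
(motion by ascending component label, fission by junction order, fusion by
ascending pair ids, then rendering):

* **Motion**: per-frame Gaussian displacement with per-axis variance
  2·D·Δt; connected components move rigidly, clamped to the field.
* **Fusion**: a pair of segments from different components whose capsule
  boundaries come within `contact_dist_um` fuses with per-frame probability
  1 − e^(−k·Δt); a segment fuses at most once per frame, candidates are
  processed in ascending id order. `simulate_held_pair` pins two segments
  in permanent contact, making the first-fusion frame exactly geometric —
  the calibration the acceptance checks enforce to three Monte-Carlo
  standard errors over 200 seeds.
* **Fission**: each junction breaks independently with probability
  1 − e^(−k_fiss·Δt); fragments keep their current amounts.
* **Mixing**: matrix content re-equilibrates proportionally to segment
  length within every connected component at every frame. We model mixing
  as instantaneous at frame resolution (4 s ≫ matrix diffusion times over
  micron scales) rather than only at fusion events: a soluble marker in an
  already-connected component must spread whether or not a new junction
  formed that frame. Per-component totals of DsRed and dark+bright PA-GFP
  are exactly conserved through all three processes; DsRed changes only at
  the bleach step, dark+bright never (activation converts one into the
  other within each segment).
* **Photoactivation**: segments whose centroid lies in an activation
  square have all dark PA-GFP switched bright and DsRed multiplied by
  `bleach_survival`. Neither the activation efficiency nor the bleach depth
  is an experimentally reported constant; `bleach_survival = 0.2` is a
  configuration default, not a claim.
* **Rendering**: capsules of fixed width with per-pixel intensity equal to
  amount per unit length, Gaussian PSF, background added to the expected
  photon rate *before* Poisson sampling (camera offset and stray light are
  shot-limited too; `photons_per_unit = Inf` is the exact noiseless
  limit), then quantization to 8 or 16 bits.

Defaults mirror the standard acquisition: 512×512 px at 0.1 µm/px, 4 s
frames, 5×5 µm activation squares, a 120-frame (8-min) post window.

## Benchmark scenes and problem sizes

The tests and the reproduction script run desk-scale versions of the study
conditions; sizes below are the package's validation choices.

* `benchmark_params`: 16 µm field (160 px), 60 uniform 1.2-µm segments,
  D = 5×10⁻⁴ µm²/s, **four dispersed 3.5 µm activation squares**, 100-frame
  post window. Dispersing the activated population matters: a single large
  activated block shields its interior (only boundary segments can meet
  unbleached partners), producing plateau-then-crash count curves that a
  single exponential cannot summarize. Several small squares — which is
  also how multi-ROI recordings are acquired — keep each activated segment
  exposed, and the green-only loss stays in the exponential regime. Uniform
  segment lengths remove a second nuisance (the event-size lottery) from
  the rate estimate.
* The benchmark deliberately stays in the *shallow-decay regime*, where
  fitted half-times exceed the recording length — the regime the real assay
  operates in (control and patient half-times of 700–1,900 s against a
  480-s recording). At rates fast enough to exhaust the green-only pool
  within the window the count curve saturates and 1/half-time stops
  tracking events; those rates are outside the method's design envelope and
  outside the benchmark. The motility default matters for specificity: at
  faster drift, unbleached red mitochondria slide over green-only pixels
  and mimic fusion at zero rate, eroding the requirement that a
  fusion-free network fit an essentially flat line.
* The decay-vs-rate validation runs 35 simulations across a 16× fusion-rate
  range (4×10⁻⁴–6.4×10⁻³ /s, 7 seeds each) and requires R² ≥ 0.6 between
  the ground-truth count of *content-mixing* fusions (one partner bright,
  one dark — the only events a fluorophore-transfer readout or a manual
  counter can see; `mixing_fusion_count`) and 1/half-time. The
  monotonicity ladder uses {0, 5×10⁻⁴, 2×10⁻³, 8×10⁻³} /s with 5 seeds per
  rate and additionally requires the zero-rate median half-time to exceed
  ten recordings.
* `chain_params`/`simulate_chain`: a static, noise-free chain of 15
  segments within contact distance, activation square over the first two.
  With a high fusion rate it zips into one component and dilutes the
  activated GFP ~7.5-fold (decay ≈ 0.97); with the rate at zero the decay
  is exactly 0. These bracket the measure; real cells sit between.
* `scripted_fusion_run`: deterministic donor/acceptor pairs with
  prescribed fusion (and optional fission) frames, high SNR, ≥6-frame
  separation; the acceptance bar for the detector is recall and precision
  ≥ 0.8 with ≤1-frame timing error. The acceptor approaches in two steps
  because overlap tracking cannot follow an object that jumps farther than
  its own length in one frame — a real constraint of overlap trackers, not
  an artifact.

## Event detection choices

The exchange threshold δ defaults to 20% of the series-wide range of
object mean intensities per channel; "abrupt" means within one frame
interval. Contact is intersection of 1-px-dilated masks. Orientation is
classified from the contact centroid against the principal-axis endpoint
pixels of each partner (3-px radius): both ends → end-to-end, one →
end-to-side, neither → side-to-side. The orientation categories are a
documented convention — the three-class scheme is geometrically natural,
but no published enumeration exists to match against. After a merge the
union object inherits the larger parent's track id; a later split marks
the event transient with the fused interval as its duration. For
exchange-path events (partners that mix without their masks merging),
separation means loss of dilated-mask contact.

## Exponential fit

`exp_decay_fit` minimizes unweighted least squares for y = a·e^(−bx)
(x in seconds — half-times are reported in seconds), initialized from a
log-linear regression on the positive counts; zeros are allowed in the
objective. Non-convergence falls back to the log-linear solution with
`converged = FALSE`. A perfectly flat series is fit exactly with b = 0 and
the half-time ln(2)/b reported as +Inf, flagged rather than fabricated.

## Sequence permutation test

`smith_waterman` is an exact affine-gap local alignment (Gotoh, in C++)
under BLOSUM62 with protein-default costs (open 11, extend 1; a gap of
length L costs open + L·extend), X scoring 0 against everything. The
original procedure used a heuristic database search with word size 3; an
exact DP has no word-size analogue, and we prefer it because it makes the
null reproducible. Raw scores are used without bit-score conversion: the
permutation test only compares ranks within one fixed scheme, where the
conversion is monotone. `scramble_test` builds the null from
composition-preserving Fisher–Yates permutations of each sequence (n per
direction), seeded; the reported exceedance fraction uses ≥, so a
length-1 sequence degenerates to an all-equal null and an exceedance of
exactly 0 or 1. Calibration: when the "observed" pair is itself a scramble,
the exceedance fraction is uniform — its mean over 50 random 100-mers must
sit at 0.5 ± 0.1.

## Group reporting

The cell is the unit of replication: group means and s.e.m. are computed
over cells. The two-group test defaults to Welch's unequal-variance t
(the safer reading of an unqualified "t-test"; `var_equal = TRUE` restores
the pooled form), with one-way ANOVA alongside for ≥2 groups. The
pipeline derives each simulated cell's seed deterministically from the run
seed, so a configuration reruns to byte-identical tables.

## What passing these benchmarks does not show

The simulator has no directed motor transport, no 3-D optics, no
photophysics beyond the single bleach step, no cristae substructure, and
its mitochondria are rigid capsules. Detector scores on scripted scenes
bound what clean, well-separated events look like — crowded scenes with
overlapping events will do worse. The continuity decay magnitudes depend
on the activated fraction of the network, so simulated values (≈0.97 for a
fully connected chain) are not comparable to per-cell figures from real
fibroblasts, where the activated fraction and network topology differ;
only directions of effect and internal consistency transfer.
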