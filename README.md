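# mitodyn

Quantification of mitochondrial fusion dynamics and matrix continuity from
two-channel photoactivation time-lapse microscopy, with a ground-truthed
network simulator that makes every analysis stage verifiable without any
microscope data.

## The assay and the measures

Cells co-express two mitochondrial-matrix markers: photoactivatable GFP
(mtPA-GFP, dark until a two-photon pulse switches it on) and DsRed
(constitutively bright, photobleached by the same pulse). The pulse is
applied to small square regions (the regions of photoactivation, RPA;
classically 5×5 µm in 512×512-px recordings at 0.25 frames/s). Because both
markers are soluble matrix proteins, every subsequent fusion event mixes
them between the partner mitochondria. The package implements the four
quantitative readouts built on this idea:

1. **RPA ratio decay** (`rpa_decay`). Per frame, the ratio
   R(t) = F(mtPA-GFP)/F(mtDsRed) averaged over the RPA, normalized to the
   first post-activation frame; the summary statistic is the decay at 500 s,
   `decay_500s = 1 − R(500 s)`. Connected, actively fusing networks dilute
   the activated GFP out of the RPA (large decay); fragmented networks keep
   it in place (decay ≈ 0). `spreading_curve` counts suprathreshold GFP
   pixels outside the RPA (threshold set so that at most 0.1% of
   pre-activation in-cell pixels exceed it).
2. **GFP-only pixel loss** (`gfp_only_decay`). Activation simultaneously
   brightens PA-GFP and bleaches DsRed inside the RPA, creating *green-only*
   pixels (above the GFP threshold, below the RFP threshold). Each fusion
   with an unbleached mitochondrion re-reddens matrix, so the green-only
   count y(t) decays; it is fit by y = a·e^(−bx) and summarized by the
   half-time ln(2)/b. Thresholds are single per-series pooled Otsu splits
   after 3×3 median despeckling (`despeckle`, `otsu_threshold_series`).
3. **Object-level fusion events** (`detect_fusion_events`,
   `summarize_fusion`). Objects are segmented and tracked by mask overlap;
   an event is an abrupt, complementary exchange — one partner loses GFP and
   gains DsRed while the other does the opposite, or the two tracks merge
   with complementary pre-merge intensities. Events are classified
   transient (kiss-and-run, with the fused duration) vs complete, and
   end-to-end / end-to-side / side-to-side from the contact geometry.
4. **Motility index and colocalization** (`motility_index`,
   `coloc_percent`). The channels are summed, successive frames
   differenced, both thresholded at the constant 32 (8-bit scale); the
   index is median(diff counts)/median(summed counts). Colocalization is
   the Manders-style binary-mask overlap percentage of two Otsu masks.

A fifth, independent component (`smith_waterman`, `scramble_test`)
implements the scrambled-protein significance test: an exact affine-gap
local alignment (BLOSUM62, gap open 11 / extend 1) whose observed score is
compared against alignments with composition-preserving random permutations
of each sequence; the reported quantity is the fraction of null scores at
or above the observed one.

## The simulator

`simulate_mito` generates the whole experiment in silico: mobile
mitochondrial segments carrying the two fluorophore pools, per-frame
Bernoulli fusion (p = 1 − e^(−k·Δt) per contacting pair) and fission,
instantaneous matrix mixing within connected components, the
activation/bleach step, and rendering with capsule drawing, Gaussian PSF,
Poisson shot noise and quantization. Every fusion and fission is logged
with ground-truth partners, time, type and orientation, so detector recall,
fit calibration and conservation laws can be checked exactly
(`component_totals`, `rpa_from_ledger`, `mixing_fusion_count`). Scene
builders cover the standard study conditions: `benchmark_params` (dispersed
activation squares, the decay-vs-rate benchmark), `chain_params`/
`simulate_chain` (connected vs fragmented continuity probe),
`simulate_held_pair` (hazard calibration) and `scripted_fusion_run`
(deterministic, well-separated events for detector grading).

## Worked example

```r
library(mitodyn)

run <- simulate_mito(benchmark_params(k_fuse = 0.004, seed = 42))
sum(run$truth_events$event == "fusion")
#> [1] 44
mixing_fusion_count(run)      # fusions that transfer detectable content
#> [1] 13
fit <- gfp_only_decay(run$series)
fit
#> decay_fit: a = 1510, b = 0.002847 /s, half-time = 243.4 s, R^2 = 0.931
rpa_decay(run$series)$decay_500s
#> [1] 0.6151    # series ends at 400 s; flagged via $at_500s
```

The half-time is the fusion measure: it shortens as the fusion rate rises
and diverges when fusion is off — the same direction of effect as
fusion-competent control fibroblasts versus fusion-deficient patient
cells. The numbered scripts under `analysis/` run the full narrative
(simulate a two-group cohort, continuity, fusion, motility, alignment
significance, group report) and write their tables under `results/`.

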