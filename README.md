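# laminatad

Chromatin architecture analysis for nuclear-lamina perturbation studies in
*Drosophila*, plus a coarse-grained polymer model of lamina attachment.

When the nuclear lamina is disrupted (lamin Dm0 RNAi), lamina-associated
domains (LADs) detach from the nuclear envelope. This package implements the
computational workflow used to characterise what happens next in Hi-C maps
and expression/chromatin tracks, and a dissipative-particle-dynamics (DPD)
polymer simulation showing that surface attachment per se is sufficient to
compact attached chromatin blocks. A synthetic-data module generates contact
maps, annotations and tracks with planted structure, so the entire pipeline
is testable end to end without any downloads.

It is aimed at computational chromatin biologists who want the individual
building blocks (balancing, TAD calling, compartment statistics, LAD-aware
fold changes, a sticky-copolymer simulator) as composable, tested R
functions returning tibbles.

## What is implemented

* **Contact maps** — dense/COO TSV I/O, bin masking, iterative correction
  (ICE, 20 iterations): `raw[i,j] = b_i b_j · corrected[i,j]` with equal
  unmasked marginals; expected-by-distance profiles and observed/expected
  (O/E) maps.
* **TAD calling** — Armatus-style γ-scaled dynamic programming: each window
  `[i,j]` of length `L` scores `q = S/L^γ − μ(L)` (within-window contact sum
  against the arm-wide mean of same-length windows); the DP maximises the
  sum of positive window scores, exactly. Two-step annotation: re-partition
  TADs > 600 kb at 2γ, then relabel TADs ≤ 60 kb as inter-TADs.
* **TAD statistics** — average contact frequency (ACF) over interior-bin
  pairs (inter-TAD variant includes adjacent boundary bins), the four-ratio
  replicate-concordance filter (≥ 3 of `KD_r/Ctrl_s` with one direction),
  LAD / active-chromatin composition, a per-TAD Jaccard score
  `|LAD∩T| / |(LAD∪active)∩T|` ranking TADs into four equal groups A–D, and
  per-group fold-change summaries.
* **Compartments** — PC1 of the correlation of the O/E map, sign-oriented by
  transcription; 20×20 saddle plots on control-PC1 quantiles; saddle
  subtraction; within/between active–inactive contact-change distributions.
* **Tracks** — overlap-weighted signal binning, TSS/overlap LAD assignment
  with the 1-kb distance rule, per-replicate sum normalisation with a
  minimal-positive-value pseudocount, LAD vs inter-LAD log2 fold changes.
* **Polymer model** — Groot–Warren DPD (a = 25, γ_f = 4.5, kT = 1, dt = 0.04)
  of a block copolymer (inactive/sticky + active/inert beads) in solvent at
  an attractive wall; reversible *saturating* bonds (≤ 1 per inactive bead;
  creation 0.001 bead–bead / 0.007 bead–wall, break 0.01, checked every 200
  steps); block-level gyration analysis (contacts, volume, oblateness) and
  ensemble distance maps. The published-scale 50³ box with 375,000 particles
  is expressible; tests and examples run desk-scale systems.

## Worked example

```r
library(laminatad)

res <- run_full_analysis(pipeline_config(seed = 11))
res
#> <pipeline_result> 25 retained TADs in 4 groups; 20x20 saddle per condition; 1000 track features

res$group_summary_acf
#> # A tibble: 4 × 7
#>   group     n    median      q25     q75 variance p_wilcoxon
#>   <chr> <int>     <dbl>    <dbl>   <dbl>    <dbl>      <dbl>
#> 1 A         6  0.0451    0.0152   0.0598 0.00154      0.0938
#> 2 B         6  0.0292   -0.00276  0.0653 0.00384      0.156
#> 3 C         6 -0.000395 -0.0249   0.0401 0.00356      1
#> 4 D         7 -0.0920   -0.101   -0.0789 0.000278     0.0156

res$track_changes$by_class
#> # A tibble: 2 × 6
#>   lad_class     n   median    q25   q75 p_vs_zero
#>   <chr>     <int>    <dbl>  <dbl> <dbl>     <dbl>
#> 1 LAD         423  0.472    0.332 0.628  5.48e-71
#> 2 interLAD    568 -0.00659 -0.134 0.143  9.54e- 1
```

Read: after the simulated knock-down, contact density rises in the most
active TADs (group A median log2FC > 0) and falls in the most
lamina-associated ones (group D < 0) — the groups are the quartiles of the
per-TAD Jaccard score — and the weak background transcription inside LADs
rises by ~0.47 log2 units (the generator plants 0.5; total-sum
normalisation and the pseudocount shrink the estimate slightly) while
inter-LAD genes are unchanged. `plot_group_changes(res$tad_table)`,
`plot_saddle(res$saddle_diff)` and `plot_contact_map()` visualise these
results.

The polymer side:

```r
p <- sim_params(box = c(10, 10, 12), n_steps = 60000, n_runs = 3, seed = 11)
runs <- run_simulation(p)
attachment_trends(analyze_runs(runs))
#> # A tibble: 1 × 6
#>   cor_contacts cor_volume oblateness_attached oblateness_detached n_attached n_detached
#>          <dbl>      <dbl>               <dbl>               <dbl>      <int>      <int>
#> 1        0.484     -0.415               0.180               0.281        266         94
```

Blocks touching the wall make more internal contacts (positive
correlation), occupy less volume (negative correlation) and flatten from
sphere towards pancake (lower oblateness) — attachment alone compacts them.

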