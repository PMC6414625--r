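---
title: "Methods: lamina-associated chromatin analysis and polymer model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lamina-associated chromatin analysis and polymer model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(laminatad)
```

`laminatad` implements the computational core of a study design in which the
nuclear lamina of *Drosophila* cells is disrupted (lamin Dm0 knock-down) and
the consequences for chromatin architecture are read out from Hi-C maps,
RNA-seq/ChIP-seq tracks, and a coarse-grained polymer simulation. This
vignette explains the models and procedures, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Hi-C maps: balancing, expected profiles, O/E

A `contact_map` is a dense symmetric matrix of contact counts for one
chromosome arm at a fixed bin size (20 kb throughout), with a per-bin
exclusion mask. Before balancing, `mask_bins()` drops bins whose marginal is
zero or below a fraction (default 0.1) of the median non-zero marginal. The
threshold is a stability choice — weakly covered bins make bias factors
ill-conditioned — and is exposed as a parameter; published ICE pipelines
apply a comparable filter without a universal value.

`ice_normalize()` runs iterative correction for a fixed 20 iterations (the
count used for the fly maps), factorising the counts as
`raw[i,j] = b_i * b_j * corrected[i,j]` with equal unmasked marginals. There
is no early stopping: a fixed iteration count keeps runs bit-reproducible.
The corrected map is rescaled so the mean unmasked marginal is 1, which
makes average contact frequencies comparable across conditions and
replicates. On inputs of the form `b_i * b_j * M` with `M` doubly balanced,
the factorisation is exact up to a global scale, which the tests verify to
high precision.

`expected_profile()` averages corrected counts per diagonal over unmasked
pairs; `observed_over_expected()` divides by the expected value at each
distance. Distances with no unmasked pairs, and zero-expected distances,
propagate as missing rather than zero — dividing by an empty mean would
silently fabricate enrichment.

## TAD calling

Domains are scored by scaled density: for a candidate window of `L` bins,
`q = S / L^gamma - mu(L)`, where `S` is the within-window contact sum
(diagonal excluded) and `mu(L)` the arm-wide mean of the scaled density over
all length-`L` windows. The centering means a window scores positively only
if it is denser than a typical same-length window, and `gamma` sets the size
scale: higher values favour shorter domains. A dynamic program maximises the
sum of positive-part window scores over all segmentations; bins in no
positive-scoring window become inter-TADs. The DP is exact — the tests
compare it against exhaustive enumeration of all segmentations for small
arms — and resolves ties towards the leftmost-starting domain so results
are deterministic.

The two-step annotation reproduces the published procedure: call at
`gamma`; re-partition every TAD strictly larger than 600 kb with `2 * gamma`;
then relabel TADs of 60 kb or less ("equal or less" — inclusive) as
inter-TADs and merge them into their neighbours. The thresholds are bp
values converted to bins (30 and 3 bins at 20 kb).

`gamma` is calibrated per dataset by design — the original analysis chose it
manually per condition (1.12 control, 1.20 knock-down for the fly maps).
For the synthetic arm the calibration is 0.7 for both conditions, at which
the caller partitions the planted structure cleanly; the fly values are kept
as documented reference points and propagate through configuration into the
annotation metadata.

Masked bins contribute zero contacts but do not break domains: a masked bin
inside an otherwise dense region stays inside the domain. Armatus-style
top-k consensus is not implemented; the single optimal segmentation is used.

## ACF, concordance, and TAD groups

The average contact frequency (ACF) of a TAD is the mean corrected contact
over all unordered pairs of its *interior* bins — the two boundary bins are
excluded, as is the diagonal (self-ligation dominated). A TAD therefore
needs at least 4 bins for a defined ACF. The inter-TAD ACF averages over the
inter-TAD bins plus the nearest boundary bin of each adjacent TAD.

Replicate concordance forms the four ratios `KD_r / Ctrl_s` and keeps a TAD
when at least three agree in direction. "Direction" is the sign of the log2
ratio; a ratio of exactly 1 counts for neither side (ratios are positive, so
a literal sign test would be vacuous). The stricter all-four variant is
available behind a flag. The headline per-group log2 fold change uses the
merged-replicate maps (counts summed, re-balanced); per-replicate ACFs feed
only the concordance filter.

Each TAD gets a score `|LAD ∩ T| / |(LAD ∪ active) ∩ T|` in base pairs,
where "active" is the union of the active-TSS ("red") and elongation
("purple") chromatin types. This set-based form reproduces the intended
ranking extremes — 0 for active, LAD-free TADs and 1 for fully
lamina-associated ones — and equals a set Jaccard of the LAD set against
LAD ∪ active when the two are disjoint, which they nearly are. The ranked
TADs split into four equal-sized groups A–D (sizes differ by at most one;
ties keep genomic order). Group summaries report medians, quartiles,
variances and a Wilcoxon signed-rank test per group; hypothesis tests are
delegated to `stats`, not re-implemented.

## Compartments and saddle plots

PC1 is the first principal component of the Pearson correlation matrix of
the O/E map over unmasked bins. Two numerical choices matter and both are
exposed as parameters:

* the first `ignore_diags = 2` diagonals are excluded from the correlation —
  they carry TAD-scale rather than compartment-scale structure;
* O/E values are winsorised at the `clip_quantile = 0.995` quantile before
  correlating. O/E is heavy-tailed at weakly covered long-range distances,
  where a single stray count over a tiny expected value produces an extreme
  ratio, and Pearson correlation is not robust to such outliers.

Whether the original analysis ran PCA on the correlation matrix or on O/E
directly is not stated in its methods; the correlation matrix is the form
used by the compartment-calling literature it cites, and is what the
package uses. The eigenvector sign is arbitrary, so the track is oriented
against binned transcription (positive PC1 = active); a fallback reference
is the active-chromatin fraction.

Saddle plots sort unmasked bins by control PC1 (ties broken by bin index,
guaranteeing equal-count groups), split them into 20 quantile groups, and
record `log2` of the mean O/E per group pair, diagonal excluded. The
knock-down saddle uses the *control* ordering, so the subtraction
`saddle_kd - saddle_ctrl` is defined cell by cell. `ab_contact_changes()`
pools per-pair `log2(O/E_kd / O/E_ctrl)` into within-active,
within-inactive and between classes by the control PC1 sign.

## Tracks: LAD assignment and fold changes

`bin_signal()` distributes interval weights over bins by overlap fraction,
so total signal is conserved. Genes are assigned by their strand-aware TSS:
inside a LAD → LAD; at least 1 kb from every LAD → inter-LAD; the strip in
between is unassigned and excluded from both classes (the two classes do
not tile the genome by construction). Regions and reads use the any-overlap
variant of the same rule; a read spanning several LADs is counted once per
overlapped region.

`normalize_and_log2fc()` follows the published pipeline: divide each
replicate by its total, drop features with zero signal in every replicate,
add a single pseudocount to every entry, average replicates per condition,
and take `log2(KD / control)`. The pseudocount is the minimal *positive*
value of the pooled normalised table: after dropping only all-zero
features, zeros can remain, and the literal minimum would be zero and
useless — the minimal positive value is the only reading under which every
retained feature gets a finite fold change. Differential-expression calling
(edgeR/TMM) is out of scope; the module stops at normalised fold changes
and class summaries.

Two properties of this pipeline are worth knowing when interpreting
recovered effect sizes: total-sum normalisation couples classes (a genuine
LAD-specific up-shift slightly deflates everything else), and the
pseudocount shrinks fold changes of weakly expressed features towards zero.
Both biases are small at realistic expression contrasts but are visible in
the planted-effect recovery numbers, which sit a few hundredths of a log2
unit below the planted shift.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
the raw data: no restriction fragments, no reads, no mappability. One arm
of 500 bins at 20 kb is tiled with TADs of 5–25 bins separated by 1–2-bin
gaps. Each TAD carries a lamina fraction `lam` in [0, 1]; fractions are
drawn through a standardised AR(1) series (coefficient 0.6) so
lamina-associated TADs cluster into contiguous blocks, as LADs do on real
chromosomes, and each arm has a stable ~50% lamina share. LAD intervals
cover the `lam` fraction of each TAD; active-chromatin intervals cover 60%
of the remainder plus the inter-TAD gaps, except gaps buried inside
inactive blocks. A TAD is compartment-B when `lam > 0.5`; buried gaps
inherit B. Truth groups A–D are the `lam` quartiles.

Contact intensity is
`lambda_ij ∝ (|i-j|+1)^-1 × 3^[same TAD] × 1.6^[same compartment]`,
scaled to 2×10^5 total contacts per map, multiplied by log-normal per-bin
biases (sdlog 0.25, redrawn per replicate), with Poisson counts drawn on
the upper triangle and mirrored. The knock-down condition multiplies
intra-TAD intensity by 1.2 in truth-group-A TADs and 0.8 in group D, and
optionally scales between-compartment contacts (off by default). Note that
balancing partially absorbs a block-wise multiplier into the bias factors —
the recovered group medians are attenuated relative to log2(1.2) and
log2(0.8), but their signs are stable, which is what the analysis reads
out.

Tracks: 1000 genes (the density of a ~10-Mb fly arm) with log-normal
baselines, mean 1 inside LADs versus 100 outside — background transcription
in lamina-associated chromatin is very weak — replicate noise of sdlog 0.15
(a well-sequenced RNA-seq replicate), and a +0.5 log2 knock-down shift for
LAD genes only.

What passing tests do *not* show about real data: the generator has no
mappability structure, no copy-number variation, no distance-decay change
between conditions, and its TAD boundaries are sharp. Recovery rates on
real maps will be lower than the planted-structure numbers.

## The polymer model

The simulator is standard Groot–Warren DPD: soft repulsion
`a(1 - r/r_c)`, pair friction `-gamma_f (1 - r/r_c)^2 (r̂·v_rel)`, and a
random pair force with amplitude tied by the fluctuation–dissipation
relation `sigma^2 = 2 gamma_f kT`. The published description fixes the box
(50³, density 3, 375,000 particles), the block composition (64 blocks of
500 inactive + 50 active), the bond probabilities (0.001 particle–particle,
0.007 particle–surface, 0.01 break) and the 200-step check interval; the
remaining constants are the conventional DPD values `a = 25`,
`gamma_f = 4.5`, `kT = 1`, `r_c = 1`, `dt = 0.04`, with harmonic springs
(`K = 4`, zero rest length) for the backbone and the reversible bonds.
Random pair forces use a uniform variate of unit variance, the standard
DPD substitution for a Gaussian.

Boundary conditions follow the published phrase "periodic for the solvent
and impermeable for other particles": x/y are periodic for everything;
chain particles reflect specularly at both z faces; solvent wraps in z and
does not interact with the wall layer. Three implementation notes with
physical consequences: (1) reflection is a mirror transform and must be
applied to the whole per-particle integrator state — position, velocity,
and the stored half-step velocity and old force — or the bounce is
silently undone by the second velocity half-kick; (2) solvent–solvent
interactions keep the z minimum image even with a wall present, because a
wrapping particle that loses its cross-boundary neighbours is effectively
teleported into overlaps, injecting energy; (3) the immobile wall layer
couples to the chain through the conservative repulsion only — treating a
static layer as a dissipative/random partner creates a friction gradient
whose uncorrected spurious drift piles chain particles onto the wall.
The wall is a geometric boundary; thermostatting comes from mobile pairs.
With all three in place the kinetic temperature holds within a few percent
of `kT` and the wall-free periodic system conserves momentum to machine
precision.

Reversible bonds are saturating: an inactive particle holds at most one at
a time. Each check sweep first breaks existing bonds with probability 0.01,
then visits unbonded inactive particles in random order; each picks one
uniformly random eligible partner (unbonded inactive particle or any wall
particle) within `r_c` and bonds with the corresponding probability. A
creation attempt consumes the turn of both the chooser and a chosen
inactive partner, so an isolated pair forms a bond with probability exactly
`p_on` per check — the two-state Markov chain whose stationary bonded
fraction `p_on / (p_on + p_off)` the tests verify. Wall particles have
unlimited valence (the published constraint is on inactive particles only).

Block analysis works on chain snapshots: surface contacts are particles
within `r_c` of the wall plane (the same cutoff as bond eligibility, for
consistency); intra-block contacts are non-backbone pairs within `r_c`;
shape comes from the gyration-tensor eigenvalues, with an
ellipsoid-equivalent volume `(4π/3)√(27 λ1 λ2 λ3)` and oblateness
`λ3/√(λ1 λ2)` (small = pancake). A block is lamina-associated when at least
one particle touches the surface. Averaged 3-D block shapes are summarised
through these eigenvalue spectra rather than voxel averaging of aligned
clouds.

### Problem sizes and experiment design

The package runs its simulations at desk scale: the structural-trend
experiments use a 10 x 10 x 12 box at density 3 (3600 particles) with 8
blocks of 55 + 5 beads, three independent runs of 6×10^4 steps each,
snapshots every 2000 steps and the first half of each trajectory discarded
as equilibration. These sizes are the package's own choice of a
configuration in which the attachment trends are resolvable with
comfortable statistics; the published-scale 375,000-particle configuration
is supported by the same code path and differs only in parameters.

Two initial-condition choices matter at this scale. For the attraction
experiment the chain starts in the wall-adjacent half of the box
(`init_near_wall = TRUE`): the published-scale chain is macroscopic and
always in contact with the surface, and a desk-scale blob must start
within diffusive reach of the wall to emulate that regime. The
no-attraction null control instead starts as a central slab clear of both
z faces, in a taller box (10 x 10 x 20, 4×10^4 steps): an unattracted blob
that still spans the box height *rests* on the impermeable boundary, and a
blob resting on a floor genuinely compresses its contact face — real
confinement physics, but not the question the null asks. In the taller box
the free blob floats clear of both walls, so any residual volume–distance
relation reflects the wall's action at a distance, which is absent. The
null is summarised on per block-run means, since consecutive snapshots of
the same block are strongly autocorrelated. The
temperature and momentum checks use a pure-solvent 10³ box over 10^4
steps, and the bond-kinetics toy runs 10^5 checks.

## Known limitations

* Only intra-arm (cis) maps are modelled; trans contacts, multi-resolution
  formats and read-level processing are out of scope.
* The Jaccard score formalisation is one of two defensible readings of the
  published description (two interval sets versus two scalar metrics); the
  set-based reading is used and documented above.
* PC1 on very unbalanced compartment compositions (one class ≪ 20% of the
  arm) degrades gracefully but is not guaranteed to separate classes.
* The DPD engine is single-threaded; published-scale runs are supported in
  principle but take supercomputer-scale time in practice.
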