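---
title: "Detecting common insertion sites and selection signatures in insertional mutagenesis screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting common insertion sites and selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical model it
implements, the choices that were genuinely open, and what its tests do
and do not demonstrate.

## The inference problem

A gamma-retroviral screen yields, per tumour, a set of unique
retroviral insertion sites (RIS): genomic positions with a strand (the
provirus orientation relative to the reference + strand) and a read
count that is a semi-quantitative proxy for the clone size carrying the
insertion. Two processes put insertions in the same place across
tumours: the virus's intrinsic integration preference (concentrated
near transcription start sites and active chromatin) and
post-integration oncogenic selection. Common-insertion-site (CIS)
calling asks where recurrence exceeds a *random-integration* null;
orientation-bias, clonality and saturation statistics then probe
whether selection, rather than integration preference alone, explains a
locus.

## Kernel convolution and the Monte-Carlo null

`call_cis()` smooths the pooled unique insertion positions at a ladder
of Gaussian kernel widths,

$$ f_\sigma(x) = \sum_i \exp\!\left(-\frac{(x-x_i)^2}{2\sigma^2}\right), $$

with every unique RIS weighted 1: recurrence is about independent
integration events, not clone size, so read depth deliberately does not
enter the density (a read-weighted variant would conflate expansion
with recurrence).

The null model places the same number of sites uniformly over the
chromosomes, with per-chromosome probability proportional to length.
`null_thresholds()` records, per scale, the genome-wide maximum of
$f_\sigma$ in each of `n_null` such cohorts and takes the empirical
$(1-\alpha)$ quantile (upper order statistic). Using the *maximum*
statistic makes "any CIS called on a random cohort" a genome-wide
level-$\alpha$ event per scale, which is the property the screen's
"0–3 CISs expected under random integration" control checks. The
thresholds depend only on cohort size, genome and scale, so one
computation serves every same-size cohort; for cohorts differing by
under a percent in size the threshold error is of the same relative
order and is ignored.

Assumptions worth stating: the null is uniform within chromosomes
(no mappability or chromatin structure), insertions are independent
across tumours, and the per-scale tests are calibrated marginally, not
jointly across the ladder.

### Scales, grid, truncation

* **Scale ladder** (default 2, 5, 10, 15, 30, 60, 120, 250, 500 kb):
  spans tight intragenic clusters through long-range enhancer-mode
  targets; 15 kb and 30 kb are the anchor widths used in the screen
  analyses this package re-implements.
* **Grid step** `grid_step * sigma` (default 0.25 σ), anchored at
  integer multiples of the step, plus exact evaluation at every
  insertion position. Anchoring makes profiles exactly equivariant
  under joint rescaling of positions and σ (a property the test suite
  asserts).
* **Truncation** at 6 σ: a dropped contribution is at most
  `exp(-18) ≈ 1.5e-8` per site, far below any threshold in use. The
  kernel sums and grid construction are implemented in C++ (`src/kde.cpp`)
  with two-pointer sweeps over sorted positions.
* **Ties** at the density argmax break towards the smaller coordinate;
  all outputs are deterministic given the seed.

### Candidates and cross-scale consolidation

Per scale, contiguous above-threshold grid runs become candidates;
members are the insertions inside the run; candidates with fewer than
two members are discarded (a single insertion is never a CIS). The peak
is the density argmax restricted to the member span so that
`start ≤ peak ≤ end` always holds, with the extent defined as the
minimum and maximum member positions.

Candidates overlapping by ≥ 1 nt across scales describe one underlying
cluster at different resolutions. Two consolidation modes are provided:

* `consolidate = "smallest_scale"` (default): report the candidate at
  the **smallest scale at which a single candidate spans every
  candidate of the component at that scale or below** — the scale-space
  point where the cluster is one blob. At smaller scales the cluster
  fragments into sub-peaks; at much larger scales the above-threshold
  run can extend hundreds of kilobases and absorb unrelated background
  insertions. Both failure modes were observed on simulated screens
  (fragmentation costs orientation-test power; absorption dilutes it
  and inflates extents to ~0.5 Mb, an order of magnitude beyond the
  ~30 kb CIS widths typical of these screens). The cross-scale member
  union is still recorded in the `members_union` column.
* `consolidate = "union"`: the member union defines the CIS, the
  representative scale being the smallest present. This is the more
  literal multi-scale merge and is kept for comparability.

`cluster_window()` implements the separate fixed-window rule used for
near-baseline vector integration sets: a greedy left-to-right scan
emitting disjoint clusters of ≥ `min_sites` sites whose span (max −
min + 1) stays within the window (12,587 nt by default, boundary
inclusive).

## Orientation bias and multiple testing

For each CIS, members are split into forward and reverse orientations
and compared against the strand frequencies of all remaining
insertions by a one-tailed Fisher's exact test. The tested tail is the
CIS's *majority* orientation — the direction is not specified a priori,
so an exact forward/reverse tie is defined as `p = 1`. `bh_adjust()`
(Benjamini–Hochberg step-up, delegated to `stats::p.adjust`) corrects
across CISs, and the biased set is `q < 0.05`, strict, mirroring the
way such screens define their biased-CIS lists after correction.

Because the majority tail is chosen post hoc, the per-CIS null flag
probability is roughly twice the effective BH threshold; with many
truly biased CISs in the same family the adaptive threshold rises and
the null flag rate approaches `2·α·(fraction of true positives)`. Only
the discreteness of small-count Fisher tests keeps it near `α`. This is
a property of the published procedure itself, visible in the package's
simulations, and worth remembering when interpreting borderline flags.

## TSS distances, enrichment and genotype comparisons

* `tss_distance_profile()` maps each insertion to its nearest TSS by
  absolute distance (ties to the lexicographically smaller gene id) and
  signs distances in gene orientation (negative upstream); the sign
  convention is a package choice, stated because published figures of
  this kind rarely state theirs.
* `bin_enrichment()` tiles the genome into fixed bins (30 kb default,
  the average CIS size in the screens compared), marks bins
  intersecting a region set, assigns each CIS to the bin containing its
  peak (extent-overlap mode available), and applies a one-sided Fisher
  test; it can also run directly from printed contingency counts.
* `genotype_presence_test()` (two-sided Fisher on per-tumour presence
  of an expanded insertion at a locus, focal genotype versus the rest
  by default — the published contingency construction for such tests is
  ambiguous between 12-vs-12 and 12-vs-36 tumour designs, so both are
  exposed via `other=`) and `genotype_reads_test()` (two-sided
  Mann–Whitney on per-tumour reads/RIS, zeros included by default).
  The Mann–Whitney is exact by enumeration of group assignments up to
  a combined n of 16 (correct under ties) and a tie-corrected normal
  approximation with continuity correction beyond.
* `geneset_enrichment()` is a one-sided hypergeometric test per gene
  set with optional removal of the top-k most-hit targets, reproducing
  the robustness analysis that asks whether enrichment survives without
  the dominant loci.

## Saturation analysis

`pseudo_kernel_regions()` replaces each insertion with a fixed
±7.5 kb interval (approximating a 15-kb Gaussian kernel), merged within
sample. The ±half-width phrasing is ambiguous at ±1 bp; this package
uses half-open arithmetic `[pos − hw, pos + hw)` clipped to the
chromosome, so an interior kernel is exactly 15,000 bp and a kernel at
position 1,000 clips to 8,500 bp. `coverage_curve()` evaluates union
coverage over sample subsets of every size — exhaustively while the
number of subsets is within `max_combos` (default 1,000), otherwise
over that many distinct subsets sampled under the seed; quartiles
converge quickly, and exhaustive enumeration over 2^28 subsets of a
28-sample screen is not attempted. `random_control()` redraws each
sample's positions uniformly, preserving counts. A plateauing real
curve against a linearly growing control is the saturation signature.

## The synthetic-cohort generator

`simulate_cohort()` generates what the analysis assumes, not more:

* **Background**: with probability `tss_weight` a site is placed at a
  uniformly chosen TSS plus a double-exponential (Laplace) offset of
  scale `tss_decay`; otherwise uniformly. The Laplace shape reflects
  the heavy shoulders of observed TSS-distance profiles (a Gaussian
  decays too fast); no quantitative integration-preference model is
  published for these data, so the mixture parameters are knobs, not
  estimates. Background reads are geometric, capped at 99.
* **Drivers**: per sample and driver (respecting genotype
  restriction), with `selection_prob` one insertion lands uniformly in
  the driver window, forward with probability `orientation_prob`, reads
  `100 + ⌊lognormal⌋` — the 100-read floor matches the screen's clonal
  expansion threshold, the log-normal tail its rank-read curves.
* **Passengers**: a Poisson number per selected clone, uniform
  positions, *sharing the clone's read count exactly* — the
  co-amplification logic by which a passenger rides its clone.
* **Truth**: every row is labelled background/driver/passenger with its
  driver and clone identity, and each driver records its carrier
  samples, so `score_recovery()` can compute sensitivity, false-CIS
  rate and biased-set recall/false-flag/precision without ambiguity.
  A driver counts as recovered when a called CIS extent contains its
  locus or any of its planted insertions (smallest-scale extents track
  the dense subcluster, which can sit off the window centre).

`default_screen_config()` fixes the study-sized conditions used
throughout the tests: 28 tumours on mm9-sized chromosomes; 407
background sites per tumour with `tss_weight = 0.25` and
`tss_decay = 10 kb` (a moderate TSS preference that leaves the
random-integration null approximately valid at the calling scales); 50
driver loci placed deterministically across chromosomes proportionally
to length (≥ 2 Mb apart), each with a ±10 kb window and per-sample
selection probability 0.7 (strong drivers, of the order of the most
recurrent loci in such screens), in a 60/40 mix of enhancer-mode
(`orientation_prob = 0.9`) and unbiased (0.5) drivers; passenger rate
0.12 per clone. Expected cohort size ≈ 12,485 unique insertions,
matching the screen scale the package is calibrated against.

What the simulations do **not** emulate: mappability and restriction-
site artefacts, chromatin-feature-specific hotspots beyond the generic
TSS mechanism, PCR efficiency differences between junctions, multiple
insertions per clone beyond one driver plus passengers, and tumour
phylogenies. Passing recovery tests therefore demonstrates correctness
of the statistics under the stated generative model, not performance on
any real screen.

## Problem sizes and seeds in the test suite

The suite regenerates all fixtures in code. The expensive object — the
null thresholds for a 12,485-site cohort on the mm9-sized genome at
nine scales, 300 Monte-Carlo draws — is computed once per run and
shared. Calibration checks use a 100-Mb toy genome (1,000 sites, 400
null draws, 300 fresh cohorts for the family-wise error rate);
driver-recovery checks run ten simulated screens; the orientation null
runs 100 strand-randomised cohorts of 2,000 sites; oracle-equivalence
checks run ≥ 1,000 randomized instances per operation against
brute-force enumeration. Every stochastic step takes an explicit seed,
and the pipeline derives all stage seeds from one top-level seed.

## Known limitations

* The uniform null ignores mappability; on real data a
  mappability-aware null would lower thresholds in unique regions.
* Thresholds are calibrated per scale; no correction is applied across
  the nine scales of the ladder (the consolidation step removes
  duplicate calls but the family of tests is the ladder).
* Nearest-TSS annotation is the only target-gene assignment; curated
  assignment of CISs to genes is out of scope.
* The exact Mann–Whitney enumerates up to combined n = 16; beyond that
  the tie-corrected normal approximation is used.
* `genotype_presence_test()` derives the tumour list from the cohort
  unless given explicitly; tumours with zero insertions must be
  supplied via `samples=` to be counted in the denominators.
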