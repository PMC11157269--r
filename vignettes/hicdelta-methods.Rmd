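---
title: "hicdelta: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicdelta: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hicdelta` is a paired-condition Hi-C analysis toolkit for studies that
ask how a single genetic change — for example, correction of a mutated
cohesin subunit in a cancer cell line — reorganizes the 3D genome. It
covers the full path from raw read pairs to biology-level statements:
read-pair filtering, contact-matrix balancing, A/B compartment calling
and per-bin switch testing, differential chromatin-loop calling with
loop-size statistics, integration of loop and compartment calls with
differential expression, and spike-in normalization of ChIP-seq tag
counts. A synthetic-data generator with a complete ground-truth record
makes every claim testable end to end without any external dataset.

# The read-pair filter cascade

Hi-C libraries built with a GANTC-cutting enzyme are filtered in a
fixed order: non-uniquely mapped pairs are dropped; positional
duplicates (same chromosome and start sites, strand ignored, first
occurrence kept) are dropped; trans pairs are set aside; both mates
are assigned to digest fragments (half-open `[cut_k, cut_k+1)`
intervals, binary search); pairs inside one fragment are dropped; and
orientation rules remove self-ligation artifacts — inward (`+,-`)
pairs are kept only when the fragment distance exceeds 1 kb, outward
(`-,+`) pairs only beyond 5 kb, while same-strand pairs are kept at
any distance. Survivors are the cis set, binned to 5 kb anchor pairs.

Two conventions needed a decision because the protocol text does not
fix them: the inward/outward *distance* is measured between assigned
**fragment midpoints** (symmetric in the two mates), and positional
de-duplication keys on `(chrom1, pos1, chrom2, pos2)` after mates are
ordered lexicographically. Coordinates are 0-based half-open
internally; `.pairs` files are 1-based on disk and shifted on
ingestion.

# The synthetic world

`sim_config()` states the world once; `simulate_truth()` plants it and
`simulate_contacts()` draws one condition's map. The expected
intensity of a pixel at bin separation `d` is

```
E[x_ij] ~ (max(d,1) * resolution)^(-gamma)
          * (1 + alpha * c_i * c_j)        # compartment checkerboard
          * tad_boost^[same TAD]
          * loop factor                    # boost at planted pixels
```

scaled so the total expected cis count equals `sequencing_depth`, with
independent Poisson pixel noise. Poisson (rather than negative
binomial) noise keeps the null calibration of every downstream test
interpretable. Key defaults and why:

* `resolution = 5000`, `compartment_block_size = 250000`: the working
  grids of loop-level and compartment-level analysis; block labels are
  broadcast to working bins so one generator serves both.
* `decay_exponent = 1`: the canonical contact-decay slope in the
  0.1–2 Mb range.
* `compartment_strength = 0.3`: produces O/E correlation checkerboards
  comparable to real 250 kb maps.
* `loop_boost = 4` with a single-pixel peak and a half-boost one-pixel
  shoulder: the smallest structure the scoring window can detect.
* Loop-size medians 700 kb (condition-A-specific) and 200 kb
  (B-specific and common): the size contrast reported between
  mutant-specific and wild-type-specific loop sets. Planted sizes are
  log-normal **quantiles** (`ppoints`) at the configured median and
  `sdlog`, shuffled before placement, so the planted sample median
  equals the configured median exactly; only anchor placement is
  random. The common class uses a broader `sdlog` (0.8) so the shared
  loop landscape populates every separation stratum, as the all-loop
  size distribution of real maps does.
* `loop_size_min = 100 kb`: local-background enrichment cannot be
  measured for pixels whose window straddles the main diagonal, so
  loops below roughly twice the background window are not planted.
* TAD boundaries are shared between conditions and placed with a
  minimum spacing (`tad_min_size`, default 200 kb): real TADs have a
  size floor and insulation cannot resolve domains below its window.
* `sequencing_depth` is a free parameter (replicate depth is never
  stated for the motivating experiments). The loop-analysis worlds in
  the acceptance suite use 2e7 cis contacts on a 10 Mb chromosome.
  This is deliberately deep: the published pipeline denoises maps with
  a trained CNN before ranking loops, and the box-filter stand-in used
  here (below) trades that learned prior for raw counts.
* One master `seed`; every random stream derives from it through
  `substream_seed()`, so a configuration is bit-reproducible and the
  two conditions never share a noise stream.

What the generator does *not* emulate: sequence content, ligation and
mappability biases, trans-chromosomal structure beyond nothing at all,
replicate-to-replicate biological variance, and the coupling of loop
anchors to CTCF orientation. A green recovery test therefore
establishes that the *statistics* behave as designed on maps with the
assumed structure, not that the pipeline is robust to every real-data
artifact.

# Balancing, expected model, and loop scoring

`balance()` is iterative proportional fitting on the symmetric counts:
bins with zero coverage, plus bins strictly below the 2% coverage
quantile, are masked; remaining row sums are equalized to within
`tol = 1e-4` (relative), with non-convergence flagged, never silent.
When two conditions are compared, both are balanced under the **union
of their masks** (`shared_low_coverage_mask()`): a bin unreliable in
one condition must not survive in the other, or mask-mismatched rows
read as spurious condition-specific signal.

`expected_by_distance()` is the mean balanced count per bin
separation over unmasked pixels; `loop_score()` scores each pixel as

```
score = value / max(background, floor_frac * expected[d])
```

where the background is the mean over a `(2w+1)^2` window (default
`w = 5`) excluding a central core so a peak cannot inflate its own
background. Three documented refinements stand in for the published
HiCorr + DeepLoop path, which is out of scope as an external learned
method:

1. **Smoothing** (`smooth = 1`): a 3x3 box filter applied before
   scoring. Focal loops are spatially coherent (peak + shoulder);
   isolated low-count pixels at large separations are not. Without
   this, single-read fluctuations at 1.5–2 Mb outrank genuine loops in
   any ratio-based ranking. Pixels whose smoothing footprint touches a
   masked bin are not scored, and the central background exclusion
   widens to keep the smeared peak out of its own background.
2. **Background refinement** (`refine = TRUE`): pixels scoring above 2
   in a first pass are flattened to their local background and the
   background recomputed, so one loop does not depress the scores of
   loops in its neighborhood (the same reason donut-style callers
   exclude peaks from background estimates).
3. **A count-evidence gate** in `top_k_loops()`
   (`min_enrichment_z = 2` in the pipeline, 0 by default): a loop
   candidate must show a background excess of at least twice the
   Poisson scale of its background in at least one condition. This
   removes the handful of ~30-count blips that reach high enrichment
   *ratios* on a few reads — the pixels a CNN denoiser deletes.

`insulation_profile()` reports, per bin, the log2 ratio of the mean
contact count in the `window x window` square crossing the bin to the
profile-wide mean of that statistic; boundaries are local minima at or
below `-delta`, with candidates within half a window collapsed to the
deepest (side-lobe minima on the slopes of one dip are not separate
boundaries). The fully-crossing square spans a two-bin plateau at a
sharp domain junction, so a boundary position is identifiable only up
to one bin; comparisons across conditions should use that tolerance.
On the synthetic worlds insulation is computed on raw counts (coverage
is uniform by construction); on real data balance first.

# Compartments and switches

`oe_correlation()` forms the O/E transform and the Pearson correlation
matrix of bin profiles (at least 10 unmasked bins, masked bins and
zero-variance profiles propagate as NA). `pc1()` takes the leading
eigenvector, oriented so its correlation with a per-bin activity proxy
is positive (the planted compartment sign for synthetic data; gene
density is the natural proxy for real data); `A` is positive PC1. A
near-degenerate leading eigenvalue is flagged. PCA is per chromosome.

`call_switches()` standardizes the per-bin change in PC1 against its
genome-wide empirical distribution with robust center and scale
(median, MAD) and two-sided normal p-values; a switch requires both a
sign flip and `p < 0.01`. The motivating analysis does not say how its
switch p-values were computed; this empirical-standardization z-test
was chosen because it needs no replicate model and is calibrated under
the null by construction (verified by the null-pair acceptance test).
Replicate-aware testing would be the natural extension.

# Differential loops

`top_k_loops()` scales both score maps to equal total mass, takes the
K highest-scoring anchor pairs per condition (ties at rank K broken by
smaller size, then lexicographic anchors), and attaches both
conditions' scores to the union. K mirrors the top-100k-per-condition
convention of genome-scale analyses, scaled to the synthetic region
and then widened so planted anchors sit above the shoulder-pixel rank
band (the acceptance worlds use K = 4000 on 10 Mb).

`differential_loops()` computes `r = log2((s2+eps)/(s1+eps))` with
`eps` defaulting to 1% of the mean merged score, standardizes `r`
robustly — `z = (r - median) / (1.4826 MAD)` — and calls `lost` /
`gained` at two-sided normal `p < 0.05`. One refinement over the plain
global z: the standardization runs **within genomic-separation
strata** (at least 100 loops each; small tables collapse to a single
global stratum, which is exactly the plain formula). Ratio noise grows
with separation as counts thin out; a single global scale is inflated
by the far strata, which both overcalls far pixels and starves power
at loop-range separations.

`condition_specific_loops()` produces the high-confidence sets used
for size analysis: differential calls that also pass an effect-size
floor (`|log2 ratio| >= 1`), collapsed to one call per loop (adjacent
called pixels within one bin are one loop). The effect-size floor is
the analogue of the fold-change-based specificity used when isogenic
replicates are unavailable. `loop_size_stats()` reports medians and
the two-sided Mann–Whitney test (normal approximation with tie
correction); `overlap_enrichment()` gives the upper-tail
hypergeometric p for set overlaps.

# Integration with expression

`classify_degs()` applies `p < 0.01` and `|log2FC| > 1`, with an
extreme tier at `|log2FC| >= 6` (at least 64-fold, inclusive).
`deg_summary()` rounds percentages half away from zero, reproducing
the printed whole-percent fractions. `link_loops_to_genes()` links a
gene to a loop when its TSS lies within 3 kb of **either** anchor
interval (distance 0 inside an anchor, strand ignored); linkage is
monotone in the window. `loop_gene_association()` tests gene direction
against adjacent-loop fate with a two-sided Fisher exact test computed
by hypergeometric enumeration; because the counting unit is ambiguous
(genes versus loop-gene combinations), both tallies are emitted.
`compartment_expression_shift()` assigns genes to switch classes by
the TSS-containing bin and compares each switched class to the stable
class with Wilcoxon rank-sum tests. `ddct()` implements relative qPCR
quantification (`2^-ddCt`) against a housekeeping gene and reference
sample. DE p-values are consumed as given — the thresholds mirror
printed unadjusted values, so no multiple-testing correction is
added.

# Spike-in ChIP normalization

`normalization_factors()` anchors the sample with the fewest uniquely
aligned spike-in tags at factor 1 and scales every other sample by
`min_count / count` (ties resolved by sample-name order);
`normalize_peaks()` multiplies RPKM by the factor. The two scalings
commute, so their order cannot affect any between-sample ratio.

# Numerical choices and degenerate inputs

* Balancing: relative row-sum tolerance 1e-4, 200 iterations,
  convergence flagged on the result.
* `differential_loops()` and `call_switches()` refuse to emit calls
  when the MAD of their statistic is zero (degenerate distribution),
  rather than calling everything or nothing silently.
* Fisher/hypergeometric p-values are exact sums with a 1e-7 relative
  tie tolerance on table probabilities; both equal full-enumeration
  oracles to machine precision for margins up to 12.
* Division floors: loop scores use `floor_frac * expected`;
  expression ratios add 0.5 to means before logs; `ddct` needs no
  floor because Ct values are bounded.
* Percent rounding is half away from zero (base `round()` is
  half-even and would print 3.5% as 4% but 4.5% as 4%).

# Known limitations

* The HiCorr/DeepLoop stand-in (balancing + smoothed local-background
  enrichment) needs deeper maps than the CNN to reach comparable
  signal-to-noise, and has no learned model of protocol biases.
* Compartment-edge pixels carry a mild enrichment-score bias (the
  background window mixes checkerboard phases); it is identical in
  both conditions and so cancels from differential calls, but it
  perturbs absolute rankings near block edges.
* Loops at or below the insulation-window scale genuinely alter
  insulation profiles; the TAD-stability claim is therefore tested
  with condition-specific loops above that scale.
* Single-replicate design throughout: all null calibration is against
  technical (counting) noise, not biological replicate variance.
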