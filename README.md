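# hicdelta

Differential Hi-C analysis of chromatin loops, A/B compartments, and
their coupling to gene expression.

## The problem

Cohesin extrudes the chromatin loops that organize mammalian genomes,
and truncating mutations in its STAG2 subunit are among the most
common cohesin lesions in cancer. Studies that correct such a mutation
in an isogenic cell pair and re-map the genome with Hi-C face a
recurring analysis stack: filter raw read pairs into clean cis
contacts, balance the contact matrices, call A/B compartments at
coarse resolution and test which bins switch between conditions, score
focal loop enrichment at kilobase resolution and call lost / gained /
common loops between conditions, compare the size distributions of
condition-specific loops, link loop anchors and switched compartments
to transcription start sites, and normalize ChIP-seq signal with
exogenous spike-in chromatin. `hicdelta` implements that stack as
composable, tested R functions, plus a synthetic-data generator that
plants compartments, TADs, loops, coupled expression, and spike-in
counts with a full ground-truth record — so every statistical claim in
the pipeline is verified by recovery tests, not by eye.

## The statistics at the core

* **Read-pair cascade** — uniqueness, positional de-duplication,
  GANTC-fragment assignment, same-fragment removal, and orientation
  rules (inward pairs kept at fragment distance > 1 kb, outward
  > 5 kb, same-strand always), then binning to 5 kb anchor pairs.
* **Matrix balancing** — iterative proportional fitting with
  low-coverage masking; differential comparisons share one mask.
* **Compartments** — PC1 of the observed/expected correlation matrix
  at 250 kb; bins switch when the oriented PC1 flips sign *and* the
  robustly standardized change is significant
  (`z = (dPC1 - median) / (1.4826 MAD)`, two-sided p < 0.01).
* **Loops** — local-background enrichment `value / max(bg, floor)`
  with smoothing and peak-masked background as a documented stand-in
  for CNN denoising; top-K loops per condition merged; robust Z on
  `log2` score ratios within separation strata, two-sided p < 0.05,
  gives lost / gained / common.
* **Sizes and overlaps** — exact medians with Mann–Whitney tests;
  upper-tail hypergeometric enrichment for set overlaps; two-sided
  Fisher exact tests (full enumeration) for loop-gene association.
* **Expression integration** — DEGs at p < 0.01 and |log2FC| > 1
  (extreme tier at >= 64-fold), TSS-to-anchor linkage within 3 kb,
  Wilcoxon shift tests for switched compartments, and `2^-ddCt`
  relative quantification.
* **Spike-in ChIP normalization** — the lowest spike-in tag count
  anchors the factor scale: `factor = min_count / count`, applied to
  RPKM.

## Worked example

Simulate a 10 Mb isogenic pair in which the mutant condition (A)
carries 40 private loops of median size 700 kb, the corrected
condition (B) carries 40 private loops of median 200 kb, and 600 loops
are shared; then recover the contrast:

```r
library(hicdelta)

cfg <- sim_config(chrom_length = 10e6, resolution = 5000, tad_boost = 1,
                  n_loops_common = 600L, n_loops_condA_only = 40L,
                  n_loops_condB_only = 40L,
                  loop_size_median_A = 700000, loop_size_median_B = 200000,
                  loop_size_median_common = 250000,
                  n_switch_a_to_b = 0L, n_switch_b_to_a = 0L,
                  sequencing_depth = 2e7, seed = 101L)
sim <- simulate_condition_pair(cfg)
sim$mat_a
#> <contact_matrix> 2000 bins @ 5000 bp (1e+07 bp), raw, nnz pixels = 1571500

msk  <- shared_low_coverage_mask(sim$mat_a, sim$mat_b)
bm_a <- balance(sim$mat_a, extra_mask = msk)
bm_b <- balance(sim$mat_b, extra_mask = msk)
map_a <- loop_score(bm_a, smooth = 1, refine = TRUE)
map_b <- loop_score(bm_b, smooth = 1, refine = TRUE)

merged <- top_k_loops(map_a, map_b, k = 4000, min_enrichment_z = 2)
dl <- differential_loops(merged, alpha = 0.05, min_stratum = 300)
table(dl$status)
#> common gained   lost
#>   4058    316    287

sets <- condition_specific_loops(dl)   # p + fold filter, one call/loop
st <- loop_size_stats(sets$lost$size_bp, sets$gained$size_bp)
st$median_x / 1e3   # mutant-specific loops
#> 682.5 kb
st$median_y / 1e3   # corrected-specific loops
#> 200 kb
st$p
#> 1.68e-13
```

The loops lost on correction are three-and-a-half-fold larger than the
loops gained (682 kb vs 200 kb median here, against planted medians of
700 kb and 200 kb), mirroring the reported behavior of
mutant-specific versus wild-type-specific loop sets; the Mann–Whitney
p-value states that the two size distributions differ decisively.

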