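# shared fixtures: all built in code at test time

# regular 1 kb digest on two small chromosomes; fragment midpoints land
# on 500, 1500, 2500, ... so hand traces are easy
fixture_digest <- function() {
  digest_index(
    cuts = list(chrT = seq(1000, 49000, by = 1000),
                chrU = seq(1000, 19000, by = 1000)),
    chrom_sizes = c(chrT = 50000, chrU = 20000))
}

# ten pairs exercising every cascade rule exactly once; expected
# dispositions from a hand trace against fixture_digest()
fixture_ten_pairs <- function() {
  dt <- data.table::data.table(
    chrom1 = c("chrT", "chrT", "chrT", "chrT", "chrT",
               "chrT", "chrT", "chrT", "chrT", "chrT"),
    pos1 = c(2100, 3100, 10100, 20100, 30100,
             5100, 2100, 7100, 8100, 43100),
    strand1 = c("+", "+", "-", "+", "-", "+", "-", "+", "+", "-"),
    chrom2 = c("chrT", "chrT", "chrT", "chrT", "chrT",
               "chrT", "chrT", "chrT", "chrU", "chrT"),
    pos2 = c(40200, 4200, 14200, 24200, 36200,
             5800, 40200, 9200, 1200, 48200),
    strand2 = c("-", "-", "+", "+", "+", "-", "+", "-", "-", "+"),
    unique_flag = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, FALSE, TRUE, TRUE))
  expected <- c("cis_kept",        # inward, mid distance 38000 > 1000
                "inward_close",    # inward, mid distance 1000 (not > 1 kb)
                "outward_close",   # outward, 4000 <= 5 kb
                "cis_kept",        # same-strand at 4000: kept
                "cis_kept",        # outward, 6000 > 5 kb
                "same_fragment",   # both mates in fragment [5000,6000)
                "positional_duplicate", # same start sites as pair 1
                "non_unique",
                "trans_kept",
                "outward_close")   # outward at exactly 5000: dropped
  list(pairs = dt, expected = expected)
}

# small paired world for unit-scale recovery tests (fast)
small_world_cfg <- function(seed = 7L) {
  sim_config(chrom_length = 5e6, resolution = 25000, tad_boost = 1,
             compartment_strength = 0.3,
             n_loops_common = 5L, n_loops_condA_only = 5L,
             n_loops_condB_only = 5L,
             loop_size_median_A = 700000, loop_size_median_B = 200000,
             n_switch_a_to_b = 1L, n_switch_b_to_a = 2L,
             sequencing_depth = 5e5, seed = seed)
}

# fraction of planted loops with a call within one bin of their
# anchors (the planted footprint is a 3x3 peak + shoulder)
detect_planted <- function(calls, loops, tol = 1L) {
  if (!nrow(calls) || !nrow(loops)) return(0)
  mean(vapply(seq_len(nrow(loops)), function(q) {
    any(abs(calls$i - loops$a1[q]) <= tol &
          abs(calls$j - loops$a2[q]) <= tol)
  }, logical(1)))
}

# 1:1 boundary-set matching within a localization tolerance
match_boundary_sets <- function(a, b, tol = 1L) {
  all(vapply(a, function(x) any(abs(b - x) <= tol), logical(1))) &&
    all(vapply(b, function(x) any(abs(a - x) <= tol), logical(1)))
}

# full differential-loop pipeline: balance -> expected -> score both
# conditions -> merge top-k -> z calls
run_diff_pipeline <- function(mat_a, mat_b, k, alpha = 0.05,
                              max_sep_bp = 2e6, smooth = 1L) {
  msk <- shared_low_coverage_mask(mat_a, mat_b)
  bm_a <- balance(mat_a, extra_mask = msk)
  bm_b <- balance(mat_b, extra_mask = msk)
  map_a <- loop_score(bm_a, max_separation_bp = max_sep_bp,
                      smooth = smooth)
  map_b <- loop_score(bm_b, max_separation_bp = max_sep_bp,
                      smooth = smooth)
  merged <- top_k_loops(map_a, map_b, k, min_enrichment_z = 2)
  differential_loops(merged, alpha = alpha, min_stratum = 300L)
}
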