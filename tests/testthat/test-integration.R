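# integration module: DEG classification and summaries, loop-gene
# linkage, exact tests, compartment expression shifts, ddCt

test_that("classify_degs applies thresholds with an inclusive extreme tier", {
  de <- data.table::data.table(
    gene = paste0("g", 1:6),
    log2FC = c(1.5, 0.9, 6.0, -6.0, -1.2, 2.0),
    p = c(0.005, 0.005, 0.001, 0.001, 0.5, 0.02))
  sets <- classify_degs(de)
  expect_setequal(sets$up, c("g1", "g3"))
  expect_setequal(sets$down, "g4")
  expect_setequal(sets$extreme_up, "g3")     # >= 64-fold is inclusive
  expect_setequal(sets$extreme_down, "g4")
  # g2 fails |lfc| > 1, g5 fails p, g6 fails p < 0.01
  expect_false("g2" %in% unlist(sets))
  expect_false("g5" %in% unlist(sets))
  # extreme sets nest in their parents; up/down disjoint
  expect_true(all(sets$extreme_up %in% sets$up))
  expect_true(all(sets$extreme_down %in% sets$down))
  expect_length(intersect(sets$up, sets$down), 0)
})

test_that("deg_summary reproduces the printed whole-percent fractions", {
  mk <- function(n_up, n_down, total) {
    data.table::data.table(
      gene = paste0("g", seq_len(total)),
      log2FC = c(rep(2, n_up), rep(-2, n_down),
                 rep(0, total - n_up - n_down)),
      p = c(rep(1e-4, n_up + n_down), rep(0.5, total - n_up - n_down)))
  }
  de1 <- mk(1031L, 703L, 23272L)
  s1 <- deg_summary(de1, classify_degs(de1))
  expect_identical(s1[set == "up", count], 1031L)
  expect_identical(s1[set == "up", percent], 4)
  expect_identical(s1[set == "down", percent], 3)
  de2 <- mk(789L, 971L, 22405L)
  s2 <- deg_summary(de2, classify_degs(de2))
  expect_identical(s2[set == "up", percent], 4)
  expect_identical(s2[set == "down", percent], 4)
  expect_identical(deg_summary(de1, list(none = character(0)))$percent, 0)
})

test_that("link_loops_to_genes measures TSS-to-anchor distance on either anchor", {
  loops <- data.table::data.table(i = c(3L, 10L), j = c(40L, 30L))
  data.table::setattr(loops, "resolution", 5000)
  tss <- data.table::data.table(
    gene = c("inA", "nearA", "farA", "nearB"),
    tss = c(10000, 7200, 1000, 198000))
  lk <- link_loops_to_genes(loops, tss, window = 3000)
  expect_setequal(lk$gene, c("inA", "nearA", "nearB"))
  expect_identical(lk[gene == "inA", distance], 0)
  expect_identical(lk[gene == "nearA", distance], 2800)
  # monotone in window: larger window is a superset
  lk_small <- link_loops_to_genes(loops, tss, window = 500)
  expect_true(all(paste(lk_small$gene, lk_small$loop_id) %in%
                    paste(lk$gene, lk$loop_id)))
  # brute-force all-pairs oracle on random layouts
  set.seed(71)
  loops2 <- data.table::data.table(i = sample(1:200, 30),
                                   j = sample(201:400, 30))
  data.table::setattr(loops2, "resolution", 5000)
  tss2 <- data.table::data.table(gene = paste0("g", 1:300),
                                 tss = sample(0:2e6, 300))
  lk2 <- link_loops_to_genes(loops2, tss2, window = 3000)
  dist_pt <- function(p, s, e) if (p < s) s - p else if (p >= e) p - e + 1 else 0
  oracle <- character(0)
  for (gi in seq_len(300)) {
    for (li in seq_len(30)) {
      d1 <- dist_pt(tss2$tss[gi], (loops2$i[li] - 1) * 5000,
                    loops2$i[li] * 5000)
      d2 <- dist_pt(tss2$tss[gi], (loops2$j[li] - 1) * 5000,
                    loops2$j[li] * 5000)
      if (min(d1, d2) <= 3000) {
        oracle <- c(oracle, paste(tss2$gene[gi], li))
      }
    }
  }
  expect_setequal(paste(lk2$gene, lk2$loop_id), oracle)
})

test_that("fisher_exact_2x2 equals stats::fisher.test and handles the null table", {
  t_null <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(fisher_exact_2x2(t_null)$p, 1)
  t_diag <- matrix(c(10, 0, 0, 10), 2)
  ft <- stats::fisher.test(t_diag)
  expect_equal(fisher_exact_2x2(t_diag)$p, ft$p.value, tolerance = 1e-12)
  set.seed(72)
  for (rep in 1:25) {
    tab <- matrix(sample(0:8, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("loop_gene_association recovers planted loop-expression coupling", {
  cfg <- sim_config(chrom_length = 10e6, resolution = 5000,
                    n_loops_common = 10L, n_loops_condA_only = 25L,
                    n_loops_condB_only = 25L, seed = 73L)
  truth <- simulate_truth(cfg)
  ex <- simulate_expression(truth, n_genes = 3000L, n_reps = 6L,
                            lfc_loop = 3, seed = 73)
  sets <- classify_degs(ex$de, p_thresh = 0.05)
  # diff-loop table straight from the planted truth
  loops <- data.table::data.table(
    i = truth$loops$a1, j = truth$loops$a2,
    status = c(common = "common", A_only = "lost",
               B_only = "gained")[truth$loops$condition])
  data.table::setattr(loops, "resolution", 5000)
  lk <- link_loops_to_genes(loops, ex$de[, .(gene, tss)], window = 3000)
  assoc <- loop_gene_association(loops, sets, lk)
  expect_gt(assoc$pairs_test$odds_ratio, 1)
  expect_lt(assoc$pairs_test$p, 0.05)
  expect_identical(sum(assoc$pairs_table), nrow(
    lk[loops$status[lk$loop_id] != "common"][
      gene %in% c(sets$up, sets$down)]))
})

test_that("compartment_expression_shift separates planted switch classes", {
  cfg <- sim_config(chrom_length = 20e6, resolution = 250000,
                    n_loops_common = 0L, n_loops_condA_only = 0L,
                    n_loops_condB_only = 0L,
                    n_switch_a_to_b = 4L, n_switch_b_to_a = 4L, seed = 74L)
  truth <- simulate_truth(cfg)
  ex <- simulate_expression(truth, n_genes = 2000L, n_reps = 6L,
                            lfc_comp = 1, seed = 74)
  # switch table from truth labels
  sw <- data.table::data.table(
    bin = truth$blocks$block,
    class = "stable")
  sw[truth$switched_blocks$block, class := truth$switched_blocks$class]
  shift <- compartment_expression_shift(sw, ex$de)
  expect_gte(shift[class == "B_to_A", n], 50)
  expect_lt(shift[class == "B_to_A", p], 0.001)
  expect_gt(shift[class == "B_to_A", median_lfc],
            shift[class == "stable", median_lfc])
  expect_lt(shift[class == "A_to_B", median_lfc],
            shift[class == "stable", median_lfc])
  # an empty switch class is reported absent, without error
  sw_empty <- data.table::copy(sw)[class == "A_to_B", class := "stable"]
  shift2 <- compartment_expression_shift(sw_empty, ex$de)
  expect_identical(shift2[class == "A_to_B", n], 0L)
  expect_true(is.na(shift2[class == "A_to_B", p]))
})

test_that("ddct reproduces hand-computed relative expression", {
  ct <- data.table::data.table(
    sample = rep(c("ref", "s2"), each = 2),
    gene = rep(c("GAPDH", "tgt"), 2),
    ct = c(15, 22, 15, 20))
  out <- ddct(ct, ref_gene = "GAPDH", ref_sample = "ref")
  expect_equal(out[sample == "ref", rel_expr], 1)   # reference sample
  expect_equal(out[sample == "s2", rel_expr], 4)    # dCt 5 vs 7 -> 2^2
  expect_error(ddct(ct, "ACTB", "ref"), "reference gene")
  expect_error(ddct(ct, "GAPDH", "nope"), "reference sample")
  # spreadsheet-style oracle on a random table
  set.seed(75)
  samples <- paste0("s", 1:4)
  genes <- c("GAPDH", paste0("g", 1:5))
  tab <- data.table::CJ(sample = samples, gene = genes)
  tab[, ct := runif(.N, 15, 30)]
  out2 <- ddct(tab, "GAPDH", "s1")
  for (r in seq_len(nrow(out2))) {
    s <- out2$sample[r]; g <- out2$gene[r]
    dct_s <- tab[sample == s & gene == g, ct] -
      tab[sample == s & gene == "GAPDH", ct]
    dct_r <- tab[sample == "s1" & gene == g, ct] -
      tab[sample == "s1" & gene == "GAPDH", ct]
    expect_equal(out2$rel_expr[r], 2^(-(dct_s - dct_r)), tolerance = 1e-12)
  }
})

test_that("deg_overlap_enrichment restricts to the shared universe", {
  uniA <- paste0("g", 1:100)
  uniB <- paste0("g", 51:150)
  r <- deg_overlap_enrichment(paste0("g", 60:69), paste0("g", 60:69),
                              uniA, uniB)
  expect_identical(r$universe_size, 50L)
  expect_equal(r$fold, 50 / 10)   # identical sets: fold = N / |X|
  r0 <- deg_overlap_enrichment(paste0("g", 60:64), paste0("g", 70:74),
                               uniA, uniB)
  expect_equal(r0$fold, 0)
})
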