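# synthetic_data module: determinism, planted-structure readback,
# decay law, labeled artifact proportions, coupled expression, spike-in

test_that("simulate_condition_pair is deterministic and symmetric", {
  cfg <- small_world_cfg(seed = 3L)
  s1 <- simulate_condition_pair(cfg)
  s2 <- simulate_condition_pair(cfg)
  expect_identical(as.matrix(s1$mat_a$counts), as.matrix(s2$mat_a$counts))
  expect_identical(as.matrix(s1$mat_b$counts), as.matrix(s2$mat_b$counts))
  M <- as.matrix(s1$mat_a$counts)
  expect_identical(M, t(M))
  expect_true(all(M >= 0) && all(M == round(M)))
})

test_that("planted truth reads back: loop counts, classes, size medians", {
  cfg <- sim_config(chrom_length = 20e6, resolution = 5000,
                    n_loops_common = 0L, n_loops_condA_only = 20L,
                    n_loops_condB_only = 0L,
                    loop_size_median_A = 700000, seed = 12L)
  truth <- simulate_truth(cfg)
  expect_identical(nrow(truth$loops), 20L)
  expect_true(all(truth$loops$condition == "A_only"))
  # quantile-matched sizes: planted median within one bin of 700 kb
  expect_lte(abs(median(truth$loops$size_bp) - 700000), 5000)
  # switched blocks are exactly the label disagreements
  blocks <- truth$blocks
  expect_setequal(truth$switched_blocks$block,
                  blocks[label_A != label_B, block])
})

test_that("with all modulations off the mean per diagonal follows the decay law", {
  cfg <- sim_config(chrom_length = 5e6, resolution = 25000,
                    compartment_strength = 0, tad_boost = 1,
                    n_loops_common = 0L, n_loops_condA_only = 0L,
                    n_loops_condB_only = 0L, n_switch_a_to_b = 0L,
                    n_switch_b_to_a = 0L,
                    sequencing_depth = 1e6, seed = 4L)
  truth <- simulate_truth(cfg)
  m <- simulate_contacts(truth, "A")
  n <- n_bins(m)
  res <- cfg$resolution
  decay <- (pmax(0:(n - 1), 1) * res)^(-1)
  scale <- cfg$sequencing_depth / sum(decay * (n - (0:(n - 1))))
  M <- as.matrix(m$counts)
  for (d in c(1L, 5L, 20L, 80L)) {
    vals <- M[cbind(seq_len(n - d), seq_len(n - d) + d)]
    mu <- scale * decay[d + 1]
    se <- sqrt(mu / (n - d))
    expect_lt(abs(mean(vals) - mu), 3 * se)
  }
})

test_that("condition-specific loops are absent from the other condition's intensity", {
  cfg <- small_world_cfg(seed = 8L)
  truth <- simulate_truth(cfg)
  # same noise seed, conditions differing only in planted structure:
  # B_only loop pixels must not be boosted in condition A's mean field
  m_a <- simulate_contacts(truth, "A", depth = 5e6)
  m_b <- simulate_contacts(truth, "B", depth = 5e6)
  Ma <- as.matrix(m_a$counts)
  Mb <- as.matrix(m_b$counts)
  bo <- truth$loops[condition == "B_only"]
  expect_gt(sum(Mb[cbind(bo$a1, bo$a2)]), 2 * sum(Ma[cbind(bo$a1, bo$a2)]))
})

test_that("simulate_read_pairs plants labeled artifact classes at the stated rates", {
  digest <- simulate_digest(c(chrA = 2e6, chrB = 1e6), seed = 21)
  n <- 1000L
  stream <- simulate_read_pairs(
    n, digest, artifact_rates = list(duplicate = 0.1, same_fragment = 0.2),
    seed = 21)
  expect_identical(nrow(stream), n)
  expect_identical(sum(stream$truth == "duplicate"), 100L)
  expect_identical(sum(stream$truth == "same_fragment"), 200L)
  # planted same-fragment pairs verify against direct digest lookup
  sf <- stream[truth == "same_fragment"]
  f1 <- assign_fragment("chrA", sf$pos1, digest)
  f2 <- assign_fragment("chrA", sf$pos2, digest)
  expect_true(all(f1 == f2))
  expect_error(
    simulate_read_pairs(100, digest,
                        artifact_rates = list(duplicate = 0.6, trans = 0.5)),
    "sum")
})

test_that("expression coupling plants the configured fold changes", {
  cfg <- small_world_cfg(seed = 13L)
  truth <- simulate_truth(cfg)
  ex <- simulate_expression(truth, n_genes = 800L, n_reps = 20L,
                            lfc_loop = 2, lfc_comp = 1, seed = 13)
  # determinism
  ex2 <- simulate_expression(truth, n_genes = 800L, n_reps = 20L,
                             lfc_loop = 2, lfc_comp = 1, seed = 13)
  expect_identical(ex$counts, ex2$counts)
  # loop-coupled genes: counts ratio approx 4 at lfc 2 (20 reps)
  lg <- ex$truth_de[mechanism == "loop" & true_log2fc < 0, gene]
  if (length(lg)) {
    idx <- match(lg, rownames(ex$counts))
    ratio <- rowMeans(ex$counts[idx, 1:20, drop = FALSE]) /
      rowMeans(ex$counts[idx, 21:40, drop = FALSE])
    expect_lt(abs(median(ratio) - 4), 1)
  }
  # all-zero effect config gives all-zero truth
  ex0 <- simulate_expression(truth, n_genes = 100L, lfc_loop = 0,
                             lfc_comp = 0, seed = 2)
  expect_true(all(ex0$truth_de$true_log2fc == 0))
})

test_that("spike-in counts are centered on configured means; zero-variance is exact", {
  means <- c(s1 = 1000, s2 = 2000)
  draws <- vapply(1:200, function(k) {
    simulate_spikein(means, seed = k)$spikein_tags
  }, numeric(2))
  for (q in 1:2) {
    se <- sqrt(means[q] / 200)
    expect_lt(abs(mean(draws[q, ]) - means[q]), 3 * se)
  }
  exact <- simulate_spikein(means, noise = "none")
  expect_identical(exact$spikein_tags, c(1000, 2000))
})
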