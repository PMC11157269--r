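# contact_matrix module: construction, balancing, expected model,
# loop scoring, insulation

test_that("build_matrix fills symmetrically and matches a dense oracle", {
  empty <- build_matrix(data.table::data.table(bin1 = integer(),
                                               bin2 = integer(),
                                               count = integer()),
                        1e5, 5000)
  expect_identical(dim(empty$counts), c(20L, 20L))
  expect_identical(sum(empty$counts), 0)

  one <- build_matrix(data.table::data.table(bin1 = 2L, bin2 = 7L,
                                             count = 1L), 1e5, 5000)
  M <- as.matrix(one$counts)
  expect_identical(M[3, 8], 1)
  expect_identical(M[8, 3], 1)

  set.seed(31)
  tab <- data.table::data.table(bin1 = sample(0:19, 200, TRUE),
                                bin2 = sample(0:19, 200, TRUE))
  tab[, `:=`(b1 = pmin(bin1, bin2), b2 = pmax(bin1, bin2))]
  tab <- tab[, .(count = .N), by = .(bin1 = b1, bin2 = b2)]
  m <- build_matrix(tab, 1e5, 5000)
  dense <- matrix(0, 20, 20)
  for (r in seq_len(nrow(tab))) {
    dense[tab$bin1[r] + 1, tab$bin2[r] + 1] <-
      dense[tab$bin1[r] + 1, tab$bin2[r] + 1] + tab$count[r]
    if (tab$bin1[r] != tab$bin2[r]) {
      dense[tab$bin2[r] + 1, tab$bin1[r] + 1] <-
        dense[tab$bin2[r] + 1, tab$bin1[r] + 1] + tab$count[r]
    }
  }
  expect_equal(as.matrix(m$counts), dense, ignore_attr = TRUE)
  expect_error(build_matrix(data.table::data.table(bin1 = 0L, bin2 = 20L,
                                                   count = 1L), 1e5, 5000),
               "beyond")
})

test_that("balance equalizes unmasked row sums and preserves structure", {
  cst <- build_matrix(data.table::CJ(bin1 = 0:9, bin2 = 0:9)[bin1 <= bin2][
    , count := 5], 10 * 5000, 5000)
  b <- balance(cst, mask_low_frac = 0)
  expect_true(b$converged)
  expect_equal(stats::sd(b$weights), 0, tolerance = 1e-12)

  two <- build_matrix(data.table::data.table(bin1 = c(0L, 0L, 1L),
                                             bin2 = c(0L, 1L, 1L),
                                             count = c(2L, 1L, 2L)),
                      2 * 5000, 5000)
  bt <- balance(two, mask_low_frac = 0)
  rs <- Matrix::rowSums(bt$counts)
  expect_equal(rs[1], rs[2], tolerance = 1e-3)

  set.seed(32)
  A <- matrix(runif(50 * 50, 1, 10), 50, 50)
  A <- round((A + t(A)) / 2)
  tr <- data.table::as.data.table(which(upper.tri(A, diag = TRUE),
                                        arr.ind = TRUE))
  anch <- data.table::data.table(bin1 = tr$row - 1L, bin2 = tr$col - 1L,
                                 count = A[cbind(tr$row, tr$col)])
  m <- build_matrix(anch, 50 * 5000, 5000)
  bm <- balance(m, tol = 1e-5)
  expect_true(bm$converged)
  rs <- Matrix::rowSums(bm$counts)[!bm$masked]
  expect_lt(stats::sd(rs) / mean(rs), 1e-4)
  # symmetry and zero pattern preserved
  B <- as.matrix(bm$counts)
  expect_equal(B, t(B), ignore_attr = TRUE)
  M0 <- as.matrix(m$counts)
  keep <- !bm$masked
  expect_identical(B[keep, keep] == 0, M0[keep, keep] == 0)
})

test_that("expected_by_distance averages per diagonal", {
  cst <- build_matrix(data.table::CJ(bin1 = 0:9, bin2 = 0:9)[bin1 <= bin2][
    , count := 3], 10 * 5000, 5000)
  cst$masked <- rep(FALSE, 10)
  expect_equal(expected_by_distance(cst), rep(3, 10))

  diag1 <- build_matrix(
    data.table::data.table(bin1 = 0:8, bin2 = 1:9, count = 2L),
    10 * 5000, 5000)
  e <- expected_by_distance(diag1)
  expect_equal(e[2], 2)
  expect_equal(e[-2], rep(0, 9))

  # decay-law world: expected vector proportional to d^-1
  cfg <- sim_config(chrom_length = 5e6, resolution = 25000,
                    compartment_strength = 0, tad_boost = 1,
                    n_loops_common = 0L, n_loops_condA_only = 0L,
                    n_loops_condB_only = 0L, sequencing_depth = 2e6,
                    seed = 33L)
  m <- simulate_contacts(simulate_truth(cfg), "A")
  bm <- balance(m)
  e <- expected_by_distance(bm)
  d <- c(2, 4, 8, 16, 32)
  ratio <- e[d + 1] * d
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.15)
})

test_that("loop_score flags planted peaks and is scale invariant", {
  # smooth decay with one planted 5x pixel
  n <- 60L
  anch <- data.table::CJ(bin1 = 0:(n - 1), bin2 = 0:(n - 1))[bin1 <= bin2]
  anch[, count := round(1000 / pmax(bin2 - bin1, 1))]
  anch[bin1 == 19L & bin2 == 39L, count := count * 5L]
  m <- build_matrix(anch, n * 5000, 5000)
  bm <- balance(m, tol = 1e-6, mask_low_frac = 0)
  sm <- loop_score(bm, min_separation = 2, max_separation_bp = 2e6)
  peak <- sm[i == 20 & j == 40]
  expect_equal(peak$score, 5, tolerance = 0.35)
  # off-pixels whose window is clear of the main diagonal score ~1
  # flat matrix: every score is exactly 1
  flat <- build_matrix(
    data.table::CJ(bin1 = 0:29, bin2 = 0:29)[bin1 <= bin2][, count := 8L],
    30 * 5000, 5000)
  flat$masked <- rep(FALSE, 30)
  smf <- loop_score(flat, min_separation = 2)
  expect_equal(smf$score, rep(1, nrow(smf)))
  # off-pixels: window clear of the diagonal (where 1/d is locally
  # flat) and of the planted peak
  off <- sm[!(abs(i - 20) <= 5 & abs(j - 40) <= 5) & sep >= 15]
  expect_lt(max(abs(off$score - 1)), 0.35)
  # zero-count pixel scores 0
  anch2 <- data.table::copy(anch)[!(bin1 == 10L & bin2 == 30L)]
  m2 <- build_matrix(anch2, n * 5000, 5000)
  bm2 <- balance(m2, tol = 1e-6, mask_low_frac = 0)
  sm2 <- loop_score(bm2)
  expect_identical(sm2[i == 11 & j == 31, score], 0)
  # global scalar invariance
  m3 <- m
  m3$counts <- m$counts * 7
  sm3 <- loop_score(balance(m3, tol = 1e-6, mask_low_frac = 0))
  expect_equal(sm3$score, sm$score, tolerance = 1e-6)
})

test_that("insulation finds block junctions and is translation equivariant", {
  blockmat <- function(n, cut) {
    anch <- data.table::CJ(bin1 = 0:(n - 1), bin2 = 0:(n - 1))[bin1 <= bin2]
    anch[, count := data.table::fifelse(
      (bin1 < cut) == (bin2 < cut), 10L, 0L)]
    build_matrix(anch[count > 0], n * 5000, 5000)
  }
  m <- blockmat(40L, 20L)
  ip <- insulation_profile(m, window = 5, delta = 0.7)
  expect_identical(ip$boundaries, 20L)
  # constant matrix: flat profile, no boundaries
  cst <- build_matrix(
    data.table::CJ(bin1 = 0:39, bin2 = 0:39)[bin1 <= bin2][, count := 10L],
    40 * 5000, 5000)
  ipc <- insulation_profile(cst, window = 5)
  expect_length(ipc$boundaries, 0L)
  expect_lt(max(abs(ipc$profile$score)), 1e-10)
  # translation equivariance
  m2 <- blockmat(40L, 24L)
  ip2 <- insulation_profile(m2, window = 5, delta = 0.7)
  expect_identical(ip2$boundaries, 24L)
  expect_identical(ip2$boundaries - ip$boundaries, 4L)
})

test_that("coarsen sums counts into larger bins", {
  anch <- data.table::data.table(bin1 = c(0L, 1L, 4L), bin2 = c(1L, 2L, 9L),
                                 count = c(1L, 2L, 3L))
  m <- build_matrix(anch, 10 * 5000, 5000)
  cm <- coarsen(m, 5L)
  M <- as.matrix(cm$counts)
  expect_identical(M[1, 1], 3)   # pixels (0,1) and (1,2) fold into (0,0)
  expect_identical(M[1, 2], 3)
  M0 <- as.matrix(m$counts)
  expect_identical(sum(M[upper.tri(M, diag = TRUE)]),
                   sum(M0[upper.tri(M0, diag = TRUE)]))
})
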