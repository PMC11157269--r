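# ContactMatrix container and matrix-level operations:
# construction, iterative balancing, distance-decay expected model,
# local-background loop scoring, insulation profiling.

new_contact_matrix <- function(counts, resolution, chrom_length,
                               weights = NULL, masked = NULL,
                               balanced = FALSE, converged = NA) {
  structure(
    list(counts = counts, resolution = as.numeric(resolution),
         chrom_length = as.numeric(chrom_length),
         weights = weights, masked = masked,
         balanced = balanced, converged = converged),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d bins @ %g bp (%.3g bp), %s, nnz pixels = %d\n",
    n_bins(x), x$resolution, x$chrom_length,
    if (isTRUE(x$balanced)) "balanced" else "raw",
    length(cm_triplets(x)$x)))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param m a `contact_matrix`.
#' @return integer bin count.
#' @export
n_bins <- function(m) nrow(m$counts)

# upper-triangle (i <= j) triplets, 1-based bin indices
cm_triplets <- function(m) {
  Tm <- methods::as(methods::as(m$counts, "generalMatrix"), "TsparseMatrix")
  keep <- Tm@i <= Tm@j
  data.table::data.table(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L,
                         x = Tm@x[keep])
}

#' Build a symmetric contact matrix from binned anchor-pair counts
#'
#' @param anchors a data.frame/data.table with columns `bin1`, `bin2`
#'   (0-based bin indices, `bin1 <= bin2`) and `count`.
#' @param chrom_length chromosome length in bp.
#' @param resolution bin size in bp.
#' @return a `contact_matrix` with symmetric sparse integer counts; the
#'   total count of the input table is preserved (each unordered anchor
#'   pair is stored once on the upper triangle).
#' @export
build_matrix <- function(anchors, chrom_length, resolution) {
  stop_if_not_scalar_num(resolution, "resolution")
  stop_if_not_scalar_num(chrom_length, "chrom_length")
  anchors <- data.table::as.data.table(anchors)
  n <- as.integer(ceiling(chrom_length / resolution))
  if (nrow(anchors)) {
    if (any(anchors$bin1 < 0L) || any(anchors$bin2 >= n)) {
      stop("anchor bin beyond chromosome end", call. = FALSE)
    }
    if (any(anchors$bin1 > anchors$bin2)) {
      stop("anchors must satisfy bin1 <= bin2", call. = FALSE)
    }
  }
  counts <- Matrix::sparseMatrix(
    i = anchors$bin1 + 1L, j = anchors$bin2 + 1L, x = anchors$count,
    dims = c(n, n), symmetric = TRUE)
  new_contact_matrix(counts, resolution, chrom_length)
}

#' Aggregate a contact matrix to a coarser resolution
#'
#' @param m a `contact_matrix`.
#' @param factor integer coarsening factor (new resolution =
#'   `factor * m$resolution`).
#' @return a raw `contact_matrix` at the coarser resolution; counts are
#'   summed within the new bins.
#' @export
coarsen <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(m)
  tr <- cm_triplets(m)
  tr[, `:=`(i = (i - 1L) %/% factor, j = (j - 1L) %/% factor)]
  tr[, `:=`(bin1 = pmin(i, j), bin2 = pmax(i, j))]
  agg <- tr[, .(count = sum(x)), by = .(bin1, bin2)]
  build_matrix(agg, m$chrom_length, m$resolution * factor)
}

#' Balance a contact matrix by iterative proportional fitting
#'
#' Low-coverage bins (zero coverage, plus bins strictly below the
#' `mask_low_frac` quantile of nonzero coverage) are masked and excluded
#' from balancing and every downstream statistic. Remaining bins are
#' rescaled by per-bin weights until every unmasked row sum is within
#' `tol` (relative) of the mean unmasked row sum.
#'
#' @param m a raw `contact_matrix`.
#' @param tol relative row-sum tolerance declaring convergence.
#' @param max_iter iteration cap; non-convergence is flagged on the
#'   result (`converged = FALSE`), never silent.
#' @param mask_low_frac coverage quantile below which bins are masked.
#' @param extra_mask optional logical vector of bins to mask in
#'   addition to the coverage rule. When two conditions are compared,
#'   balance both with the union of their coverage masks (see
#'   [shared_low_coverage_mask()]) so the compared score maps live on
#'   an identical bin grid.
#' @return a `contact_matrix` with balanced (double) counts, per-bin
#'   `weights` (0 for masked bins), logical `masked`, and a `converged`
#'   flag. Symmetry and the sparsity pattern of unmasked pixels are
#'   preserved.
#' @export
balance <- function(m, tol = 1e-4, max_iter = 200L, mask_low_frac = 0.02,
                    extra_mask = NULL) {
  A <- m$counts
  n <- nrow(A)
  cov <- Matrix::rowSums(A)
  masked <- low_coverage_mask_(cov, mask_low_frac)
  if (!is.null(extra_mask)) masked <- masked | extra_mask
  if (all(masked)) stop("all bins masked; nothing to balance", call. = FALSE)
  w <- as.numeric(!masked)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.numeric(A %*% w) * w
    su <- s[!masked]
    mu <- mean(su)
    if (mu > 0 && max(abs(su / mu - 1)) < tol) {
      converged <- TRUE
      break
    }
    adj <- sqrt(s / mu)
    adj[masked | s <= 0] <- 1
    w <- w / adj
  }
  D <- Matrix::Diagonal(x = w)
  B <- Matrix::forceSymmetric(D %*% A %*% D)
  new_contact_matrix(B, m$resolution, m$chrom_length,
                     weights = w, masked = masked,
                     balanced = TRUE, converged = converged)
}

low_coverage_mask_ <- function(cov, frac) {
  masked <- cov == 0
  if (any(!masked) && frac > 0) {
    thr <- stats::quantile(cov[!masked], frac, names = FALSE)
    masked <- masked | cov < thr
  }
  masked
}

#' Union of the low-coverage masks of two raw matrices
#'
#' Differential comparisons require both conditions' score maps on one
#' bin grid: a bin that is unreliable in either condition is dropped
#' from both, otherwise mask-mismatched rows appear as spurious
#' condition-specific signal.
#'
#' @param m1,m2 raw `contact_matrix` objects on the same grid.
#' @param frac coverage quantile below which bins are masked.
#' @return logical vector over bins.
#' @export
shared_low_coverage_mask <- function(m1, m2, frac = 0.02) {
  low_coverage_mask_(Matrix::rowSums(m1$counts), frac) |
    low_coverage_mask_(Matrix::rowSums(m2$counts), frac)
}

#' Mean contact value per bin separation (distance-decay expected model)
#'
#' @param m a `contact_matrix` (typically balanced).
#' @return numeric vector `e` of length `n_bins(m)` where `e[d + 1]` is
#'   the mean (balanced) count over all pixels at bin separation `d`
#'   whose two bins are both unmasked.
#' @export
expected_by_distance <- function(m) {
  n <- n_bins(m)
  masked <- m$masked %||% rep(FALSE, n)
  v <- as.numeric(!masked)
  tr <- cm_triplets(m)
  tr <- tr[v[i] > 0 & v[j] > 0]
  sums <- numeric(n)
  if (nrow(tr)) {
    agg <- tr[, .(s = sum(x)), by = .(d = j - i)]
    sums[agg$d + 1L] <- agg$s
  }
  nv <- vapply(0:(n - 1L), function(d) {
    sum(v[seq_len(n - d)] * v[seq_len(n - d) + d])
  }, numeric(1))
  e <- ifelse(nv > 0, sums / nv, NA_real_)
  e
}

# dense balanced values with masked bins zeroed; internal
cm_dense <- function(m) {
  M <- as.matrix(m$counts)
  masked <- m$masked %||% rep(FALSE, nrow(M))
  if (any(masked)) {
    M[masked, ] <- 0
    M[, masked] <- 0
  }
  M
}

#' Score pixels for focal (loop) enrichment over a local background
#'
#' For every pixel (i, j) with `min_separation <= j - i` and genomic
#' separation at most `max_separation_bp`, the local background is the
#' mean balanced count over the (2w+1)^2 square centered on the pixel,
#' excluding the central 3x3 (so a focal peak cannot inflate its own
#' background) and excluding masked bins. The enrichment score is
#' `value / max(background, floor)` with
#' `floor = floor_frac * expected[separation]`, which caps the score at
#' pixels whose neighborhood is nearly empty. Pixels whose full window
#' would leave the matrix are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param m a balanced `contact_matrix`.
#' @param expected per-separation expected vector from
#'   [expected_by_distance()]; computed internally when `NULL`.
#' @param w background window half-width in bins.
#' @param min_separation smallest bin separation scored.
#' @param max_separation_bp largest genomic separation scored, bp.
#' @param floor_frac background floor as a fraction of the expected
#'   value at the pixel's separation.
#' @param smooth half-width of a box filter applied to the balanced
#'   matrix before scoring (`0` disables). Smoothing is the package's
#'   minimal stand-in for CNN-style denoising of sparse maps: focal
#'   loops are spatially coherent (peak plus shoulder) while shot noise
#'   is not, so a small box filter suppresses isolated low-count pixels
#'   that would otherwise dominate the score ranking at large
#'   separations. The central background exclusion widens with `smooth`
#'   so the smeared peak stays out of its own background.
#' @param refine when `TRUE`, a second pass recomputes each pixel's
#'   background on a copy of the matrix in which first-pass peaks
#'   (score above `refine_threshold`) are flattened to their local
#'   background. Without this, a strong loop sitting inside another
#'   pixel's background window inflates that background and deflates
#'   its score (the same reason donut-style loop callers exclude
#'   peaks from their background estimates).
#' @param refine_threshold first-pass score above which a pixel is
#'   treated as a peak during background refinement.
#' @return a `data.table` (class `loop_score_map`) with columns `i`,
#'   `j` (1-based bins), `sep`, `size_bp`, `value`, `expected`,
#'   `background`, `score`.
#' @export
loop_score <- function(m, expected = NULL, w = 5L, min_separation = 2L,
                       max_separation_bp = 2e6, floor_frac = 0.1,
                       smooth = 0L, refine = FALSE,
                       refine_threshold = 2) {
  n <- n_bins(m)
  if (is.null(expected)) expected <- expected_by_distance(m)
  masked <- m$masked %||% rep(FALSE, n)
  M <- cm_dense(m)
  v <- !masked
  smooth <- as.integer(smooth)
  if (smooth > 0L) {
    Sm <- sat2(M)
    cnt_s <- outer(win_counts(v, smooth), win_counts(v, smooth))
    idx <- seq_len(n)
    lo <- pmax(idx - smooth, 1L)
    hi <- pmin(idx + smooth, n)
    Ms <- matrix(0, n, n)
    for (col in idx) {
      Ms[, col] <- sat_query(Sm, lo, hi,
                             rep(lo[col], n), rep(hi[col], n))
    }
    M <- ifelse(cnt_s > 0, Ms / cnt_s, 0)
    M[masked, ] <- 0
    M[, masked] <- 0
  }
  core <- 1L + smooth
  if (w <= core) stop("background window w must exceed smooth + 1",
                      call. = FALSE)
  S <- sat2(M)
  rs_w <- win_counts(v, w)       # valid bins in [i-w, i+w]
  rs_1 <- win_counts(v, core)    # valid bins in the core exclusion
  # a pixel is scoreable only with full smoothing support: bins whose
  # smoothing footprint touches a masked bin inherit its unreliability
  v_eff <- if (smooth > 0L) {
    v & win_counts(v, smooth) == 2L * smooth + 1L
  } else v
  max_sep <- min(n - 1L, as.integer(floor(max_separation_bp / m$resolution)))
  n_skipped <- 0L
  scoring_pass <- function(S_bg) {
    out <- vector("list", max(0L, max_sep - min_separation + 1L))
    n_skipped <<- 0L
    for (d in seq(min_separation, max_sep)) {
      i <- seq_len(n - d)
      j <- i + d
      inb <- (i - w) >= 1L & (j + w) <= n
      n_skipped <<- n_skipped + sum(!inb) # window out of bounds
      keep <- inb & v_eff[i] & v_eff[j]
      if (!any(keep)) next
      i <- i[keep]; j <- j[keep]
      sum_win <- sat_query(S_bg, i - w, i + w, j - w, j + w)
      sum_core <- sat_query(S_bg, i - core, i + core, j - core, j + core)
      cnt_win <- rs_w[i] * rs_w[j]
      cnt_core <- rs_1[i] * rs_1[j]
      denom <- cnt_win - cnt_core
      ok <- denom > 0
      if (!any(ok)) next
      i <- i[ok]; j <- j[ok]
      bg <- (sum_win[ok] - sum_core[ok]) / denom[ok]
      val <- M[cbind(i, j)]
      flr <- floor_frac * expected[d + 1L]
      sc <- val / pmax(bg, flr)
      # Poisson-scaled excess over background (up to a global factor):
      # ranking by this favors well-supported peaks over low-count
      # ratio flukes at large separations
      ez <- (val - bg) / sqrt(pmax(bg, flr))
      out[[d - min_separation + 1L]] <- data.table::data.table(
        i = i, j = j, sep = d, value = val,
        expected = expected[d + 1L], background = bg, score = sc,
        enrichment_z = ez)
    }
    data.table::rbindlist(out)
  }
  res <- scoring_pass(S)
  if (isTRUE(refine) && nrow(res)) {
    peaks <- res[res$score > refine_threshold, ]
    if (nrow(peaks)) {
      M2 <- M
      M2[cbind(peaks$i, peaks$j)] <- peaks$background
      M2[cbind(peaks$j, peaks$i)] <- peaks$background
      res <- scoring_pass(sat2(M2))
    }
  }
  if (!nrow(res)) {
    res <- data.table::data.table(
      i = integer(), j = integer(), sep = integer(), value = numeric(),
      expected = numeric(), background = numeric(), score = numeric(),
      enrichment_z = numeric())
  }
  res[, size_bp := sep * m$resolution]
  data.table::setcolorder(res, c("i", "j", "sep", "size_bp", "value",
                                 "expected", "background", "score",
                                 "enrichment_z"))
  data.table::setattr(res, "n_skipped", n_skipped)
  data.table::setattr(res, "resolution", m$resolution)
  data.table::setattr(res, "class",
                      c("loop_score_map", class(res)))
  res[]
}

#' Insulation profile and TAD boundary calls
#'
#' The insulation statistic at bin i is the mean count in the
#' `window x window` square of contacts crossing the bin (rows
#' `i-window .. i-1` against columns `i+1 .. i+window`), log2-scaled
#' against the profile-wide mean of that statistic. Boundaries are local
#' minima with score at or below `-delta`.
#'
#' @param m a `contact_matrix` (raw counts are appropriate when coverage
#'   is even; a balanced matrix otherwise).
#' @param window square size in bins.
#' @param delta boundary depth threshold in log2 units.
#' @param merge_gap boundary candidates closer than this many bins
#'   collapse to the deepest one (side-lobe minima on the slopes of a
#'   strong dip are not separate boundaries); defaults to half the
#'   window.
#' @return list with `profile` (data.table `bin`, `raw`, `score`) and
#'   `boundaries` (integer bin indices).
#' @export
insulation_profile <- function(m, window = 10L, delta = 0.7,
                               merge_gap = NULL) {
  n <- n_bins(m)
  window <- as.integer(window)
  if (n < 2L * window + 1L) stop("matrix too small for window", call. = FALSE)
  M <- cm_dense(m)
  S <- sat2(M)
  i <- seq(window + 1L, n - window)
  raw <- sat_query(S, i - window, i - 1L, i + 1L, i + window) / window^2
  norm <- mean(raw)
  score <- log2(raw / norm)
  k <- length(i)
  left <- c(Inf, score[-k])
  right <- c(score[-1L], Inf)
  is_min <- score <= left & score <= right & (score < left | score < right)
  boundaries <- i[is_min & score <= -delta]
  # collapse candidates within merge_gap (plateaus and slope side
  # lobes of one dip) to the deepest; ties keep the first bin
  merge_gap <- merge_gap %||% max(1L, window %/% 2L)
  if (length(boundaries) > 1L) {
    s <- score[match(boundaries, i)]
    grp <- cumsum(c(1L, diff(boundaries) > merge_gap))
    boundaries <- vapply(split(seq_along(boundaries), grp), function(ix) {
      boundaries[ix][which.min(s[ix])]
    }, integer(1))
    boundaries <- unname(sort(boundaries))
  }
  list(profile = data.table::data.table(bin = i, raw = raw, score = score),
       boundaries = boundaries)
}
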