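# Differential chromatin loop calling: merge top-K loops per condition,
# robust Z-score on log2 score ratios, loop-size and set-overlap
# statistics.

norm_score_maps <- function(map1, map2) {
  t1 <- sum(map1$score)
  t2 <- sum(map2$score)
  if (t1 <= 0 || t2 <= 0) stop("score maps must have positive mass",
                               call. = FALSE)
  target <- (t1 + t2) / 2
  a <- data.table::data.table(i = map1$i, j = map1$j, sep = map1$sep,
                              score1 = map1$score * target / t1)
  b <- data.table::data.table(i = map2$i, j = map2$j, sep = map2$sep,
                              score2 = map2$score * target / t2)
  merged <- merge(a, b, by = c("i", "j", "sep"), all = TRUE)
  merged[is.na(score1), score1 := 0]
  merged[is.na(score2), score2 := 0]
  merged
}

#' Merge the top-K scored anchor pairs from two conditions
#'
#' Each map is depth-normalized (scaled to equal total score mass), the
#' K highest-scoring anchor pairs are taken from each condition, and the
#' union is returned with both conditions' normalized scores attached.
#' Ties at rank K are broken by smaller genomic size, then by
#' lexicographic anchors.
#'
#' @param map1,map2 `loop_score_map`s on identical grids.
#' @param k number of top loops per condition.
#' @param min_enrichment_z count-evidence gate: a pixel is a loop
#'   candidate only if its background excess scaled by the Poisson
#'   noise of the background (`enrichment_z`) reaches this value in at
#'   least one condition. `0` disables the gate. Genuine loops carry a
#'   large absolute count excess; low-count pixels at large
#'   separations can reach high enrichment *ratios* on a handful of
#'   reads and would otherwise pollute the merged ranking — the same
#'   pixels the denoising step of CNN-based pipelines removes.
#' @return a `loop_table` data.table: `i`, `j`, `sep`, `size_bp`,
#'   `score1`, `score2`.
#' @export
top_k_loops <- function(map1, map2, k, min_enrichment_z = 0) {
  if (k > nrow(map1) || k > nrow(map2)) {
    stop("k exceeds the number of scored pixels", call. = FALSE)
  }
  res <- attr(map1, "resolution") %||% attr(map2, "resolution") %||% NA_real_
  merged <- norm_score_maps(map1, map2)
  if (min_enrichment_z > 0 && "enrichment_z" %in% names(map1)) {
    e1 <- data.table::data.table(i = map1$i, j = map1$j, ez1 = map1$enrichment_z)
    e2 <- data.table::data.table(i = map2$i, j = map2$j, ez2 = map2$enrichment_z)
    merged <- merge(merge(merged, e1, by = c("i", "j"), all.x = TRUE),
                    e2, by = c("i", "j"), all.x = TRUE)
    merged <- merged[pmax(ez1, ez2, na.rm = TRUE) >= min_enrichment_z]
    merged[, c("ez1", "ez2") := NULL]
    if (k > nrow(merged)) {
      stop("k exceeds the number of gated pixels", call. = FALSE)
    }
  }
  ord1 <- merged[order(-score1, sep, i, j)][seq_len(k), .(i, j)]
  ord2 <- merged[order(-score2, sep, i, j)][seq_len(k), .(i, j)]
  keys <- unique(rbind(ord1, ord2))
  out <- merged[keys, on = c("i", "j")]
  out[, size_bp := sep * res]
  data.table::setorder(out, i, j)
  data.table::setattr(out, "resolution", res)
  data.table::setattr(out, "class", c("loop_table", class(out)))
  out[]
}

#' Call lost / gained / common loops by robust Z-score
#'
#' Per loop, `r = log2((score2 + eps) / (score1 + eps))` is standardized
#' robustly against the merged-table distribution,
#' `z = (r - median(r)) / (1.4826 * MAD(r))`, with two-sided normal
#' p-values. Loops with `p < alpha` are `lost` (weaker in condition 2)
#' or `gained` by the sign of `r`; all others are `common`.
#'
#' @param merged a `loop_table` from [top_k_loops()].
#' @param alpha two-sided significance threshold.
#' @param eps pseudocount; defaults to 1% of the mean merged score.
#' @param min_stratum smallest separation stratum for the robust
#'   standardization. Ratio noise grows with genomic separation
#'   (counts thin out), so the robust center and scale are estimated
#'   within separation strata of at least this many loops; tables
#'   smaller than two strata fall back to a single global stratum.
#' @return a `diff_loop_table` data.table adding `log2_ratio`, `z`,
#'   `p`, `status`.
#' @export
differential_loops <- function(merged, alpha = 0.05, eps = NULL,
                               min_stratum = 100L) {
  out <- data.table::copy(merged)
  if (is.null(eps)) eps <- 0.01 * mean(c(out$score1, out$score2))
  out[, log2_ratio := log2((score2 + eps) / (score1 + eps))]
  n <- nrow(out)
  stratum_size <- max(min_stratum, ceiling(n / 8))
  out[, stratum := ceiling(data.table::frank(sep, ties.method = "first") /
                             stratum_size)]
  scl_all <- out[, stats::mad(log2_ratio), by = stratum]$V1
  if (any(!is.finite(scl_all) | scl_all == 0)) {
    stop("degenerate log-ratio distribution (MAD = 0); no calls emitted",
         call. = FALSE)
  }
  out[, z := (log2_ratio - stats::median(log2_ratio)) /
        stats::mad(log2_ratio), by = stratum]
  out[, p := 2 * stats::pnorm(-abs(z))]
  out[, status := "common"]
  out[p < alpha & log2_ratio < 0, status := "lost"]
  out[p < alpha & log2_ratio > 0, status := "gained"]
  data.table::setattr(out, "alpha", alpha)
  data.table::setattr(out, "eps", eps)
  data.table::setattr(out, "class",
                      c("diff_loop_table",
                        setdiff(class(out), "diff_loop_table")))
  out[]
}

#' Collapse adjacent called pixels into distinct loop calls
#'
#' A called loop occupies a small pixel neighborhood (peak plus
#' shoulder); this greedy pass keeps the strongest pixel (largest
#' `|z|`, falling back to `score1 + score2`) of every group of calls
#' within `gap` bins in both anchors.
#'
#' @param calls a subset of a `diff_loop_table`.
#' @param gap maximum anchor distance (bins) merged into one call.
#' @return the deduplicated calls.
#' @export
cluster_loop_calls <- function(calls, gap = 1L) {
  cl <- data.table::as.data.table(calls)
  if (!nrow(cl)) return(cl)
  strength <- if ("z" %in% names(cl)) abs(cl$z) else cl$score1 + cl$score2
  cl <- cl[order(-strength)]
  keep <- rep(TRUE, nrow(cl))
  for (q in seq_len(nrow(cl))) {
    if (!keep[q]) next
    later <- seq_len(nrow(cl)) > q
    keep[later & abs(cl$i - cl$i[q]) <= gap &
           abs(cl$j - cl$j[q]) <= gap] <- FALSE
  }
  cl[keep]
}

#' High-confidence condition-specific loop sets
#'
#' Loops that are specific to one condition must both be called
#' differential (`status` lost/gained at the table's alpha) and show a
#' substantial normalized score change (`|log2_ratio|` at or above
#' `min_abs_log2_ratio`), mirroring the fold-change-based specificity
#' used for non-isogenic comparisons; adjacent called pixels collapse
#' to one loop via [cluster_loop_calls()].
#'
#' @param diff a `diff_loop_table`.
#' @param min_abs_log2_ratio effect-size floor on the normalized score
#'   ratio (default 1, a two-fold change).
#' @param gap clustering gap in bins.
#' @return list with `lost` and `gained` deduplicated loop tables.
#' @export
condition_specific_loops <- function(diff, min_abs_log2_ratio = 1,
                                     gap = 1L) {
  list(
    lost = cluster_loop_calls(
      diff[diff$status == "lost" &
             diff$log2_ratio <= -min_abs_log2_ratio, ], gap),
    gained = cluster_loop_calls(
      diff[diff$status == "gained" &
             diff$log2_ratio >= min_abs_log2_ratio, ], gap))
}

#' Compare two loop-size distributions
#'
#' @param sizes_x,sizes_y loop sizes in bp.
#' @return list with both medians, the two-sided Mann-Whitney rank-sum
#'   statistic (normal approximation with tie correction), and its
#'   p-value.
#' @export
loop_size_stats <- function(sizes_x, sizes_y) {
  wt <- stats::wilcox.test(sizes_x, sizes_y, exact = FALSE, correct = TRUE)
  list(median_x = stats::median(sizes_x),
       median_y = stats::median(sizes_y),
       statistic = unname(wt$statistic),
       p = wt$p.value)
}

#' Overlap enrichment of two sets under a hypergeometric null
#'
#' @param set_x,set_y vectors of element identifiers (subsets of a
#'   universe of `universe_size` elements).
#' @param universe_size universe size N.
#' @return list with `observed`, `expected = |X||Y|/N`, `fold`, and the
#'   upper-tail hypergeometric p-value `P(overlap >= observed)`.
#' @export
overlap_enrichment <- function(set_x, set_y, universe_size) {
  set_x <- unique(set_x)
  set_y <- unique(set_y)
  nx <- length(set_x)
  ny <- length(set_y)
  if (nx > universe_size || ny > universe_size) {
    stop("set larger than the universe", call. = FALSE)
  }
  obs <- length(intersect(set_x, set_y))
  expected <- nx * ny / universe_size
  fold <- if (expected > 0) obs / expected else NA_real_
  p <- stats::phyper(obs - 1, nx, universe_size - nx, ny,
                     lower.tail = FALSE)
  list(observed = obs, expected = expected, fold = fold, p = p)
}

#' Condition-specific loops by score fold change
#'
#' Labels anchor pairs whose depth-normalized score ratio exceeds
#' `fc_threshold` (strictly) in either direction; used for comparisons
#' without isogenic replicates.
#'
#' @param map1,map2 `loop_score_map`s on identical grids.
#' @param fc_threshold fold-change cutoff (strict inequality).
#' @param eps pseudocount added to both normalized scores; defaults to
#'   1% of the mean normalized score mass per pixel.
#' @return a data.table of pixels with `ratio` (condition 2 over
#'   condition 1) and `label` in `{cond1_specific, cond2_specific}`.
#' @export
fold_change_specific_loops <- function(map1, map2, fc_threshold = 4,
                                       eps = NULL) {
  merged <- norm_score_maps(map1, map2)
  if (is.null(eps)) eps <- 0.01 * mean(c(merged$score1, merged$score2))
  merged[, r := (score2 + eps) / (score1 + eps)]
  out <- merged[r > fc_threshold | r < 1 / fc_threshold]
  out[, label := ifelse(r > fc_threshold, "cond2_specific",
                        "cond1_specific")]
  data.table::setnames(out, "r", "ratio")
  out[]
}
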