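# A/B compartment calling at coarse resolution from the O/E correlation
# matrix, and per-bin compartment switch testing between two conditions.

#' Observed/expected correlation matrix
#'
#' Transforms a balanced contact matrix to observed/expected (each pixel
#' divided by the mean value at its bin separation) and returns the
#' Pearson correlation matrix of the O/E bin profiles. Masked bins, and
#' bins whose O/E profile has zero variance, propagate as `NA`
#' rows/columns.
#'
#' @param m a balanced `contact_matrix` (typically at 250 kb).
#' @param min_bins minimum number of unmasked bins required.
#' @return a symmetric correlation matrix with unit diagonal on valid
#'   bins and a logical `masked` attribute.
#' @export
oe_correlation <- function(m, min_bins = 10L) {
  n <- n_bins(m)
  masked <- m$masked %||% rep(FALSE, n)
  if (sum(!masked) < min_bins) {
    stop(sprintf("only %d unmasked bins (< %d); PCA is meaningless",
                 sum(!masked), min_bins), call. = FALSE)
  }
  e <- expected_by_distance(m)
  M <- cm_dense(m)
  idx <- which(!masked)
  OE <- M[idx, idx, drop = FALSE]
  dmat <- abs(outer(idx, idx, "-"))
  OE <- OE / matrix(e[dmat + 1L], nrow(OE), ncol(OE))
  cc <- suppressWarnings(stats::cor(OE))
  # zero-variance profiles give NA columns; treat them as masked
  bad <- apply(is.na(cc), 2L, all) | is.na(diag(cc))
  out <- matrix(NA_real_, n, n)
  out[idx, idx] <- cc
  diag(out)[idx[!bad]] <- 1
  full_masked <- masked
  full_masked[idx[bad]] <- TRUE
  out[full_masked, ] <- NA_real_
  out[, full_masked] <- NA_real_
  attr(out, "masked") <- full_masked
  out
}

#' Leading eigenvector (PC1) compartment profile
#'
#' The compartment profile is the leading eigenvector of the O/E
#' correlation matrix, oriented so that its correlation with a per-bin
#' activity proxy is positive; bins with `PC1 > 0` are labeled `A`,
#' bins with `PC1 < 0` are `B`. A near-degenerate leading eigenvalue
#' (within `degeneracy_tol` of the second, relative) is flagged.
#'
#' @param corr correlation matrix from [oe_correlation()].
#' @param orientation_track per-bin activity proxy (e.g. planted
#'   compartment sign for synthetic data, gene density for real data).
#' @param degeneracy_tol relative eigengap below which the leading
#'   eigenvector is flagged degenerate.
#' @return a `compartment_profile` data.table (`bin`, `pc1`, `label`
#'   in A/B/masked) with `degenerate` and `eigengap` attributes.
#' @export
pc1 <- function(corr, orientation_track, degeneracy_tol = 1e-6) {
  n <- nrow(corr)
  if (length(orientation_track) != n) {
    stop("orientation_track length must match the bin grid", call. = FALSE)
  }
  masked <- attr(corr, "masked") %||% apply(is.na(corr), 1L, all)
  idx <- which(!masked)
  es <- eigen(corr[idx, idx, drop = FALSE], symmetric = TRUE)
  v <- es$vectors[, 1L]
  gap <- (es$values[1L] - es$values[2L]) / max(abs(es$values[1L]), 1e-12)
  ori <- orientation_track[idx]
  al <- suppressWarnings(stats::cor(v, ori))
  if (!is.na(al) && al < 0) v <- -v
  pc <- rep(NA_real_, n)
  pc[idx] <- v
  label <- rep("masked", n)
  label[idx] <- ifelse(v > 0, "A", ifelse(v < 0, "B", "masked"))
  out <- data.table::data.table(bin = seq_len(n), pc1 = pc, label = label)
  data.table::setattr(out, "degenerate", gap < degeneracy_tol)
  data.table::setattr(out, "eigengap", gap)
  data.table::setattr(out, "class",
                      c("compartment_profile", class(out)))
  out[]
}

#' Call compartment switches between two conditions
#'
#' The per-bin change in PC1 is standardized against its genome-wide
#' empirical distribution with robust center and scale (median and
#' MAD); two-sided normal p-values follow. A switch requires both a
#' sign flip of the oriented PC1 and `p < alpha`.
#'
#' @param p1,p2 `compartment_profile`s for the two conditions on an
#'   identical bin grid.
#' @param alpha switch significance threshold.
#' @return a `switch_table` data.table: `bin`, `label1`, `label2`,
#'   `delta_pc1`, `z`, `p`, and `class` in
#'   `{A_to_B, B_to_A, stable, masked}`.
#' @export
call_switches <- function(p1, p2, alpha = 0.01) {
  if (nrow(p1) != nrow(p2)) stop("bin grid mismatch", call. = FALSE)
  out <- data.table::data.table(
    bin = p1$bin, label1 = p1$label, label2 = p2$label,
    delta_pc1 = p2$pc1 - p1$pc1)
  ok <- !is.na(out$delta_pc1)
  ctr <- stats::median(out$delta_pc1[ok])
  scl <- stats::mad(out$delta_pc1[ok])
  if (!is.finite(scl) || scl == 0) {
    stop("degenerate delta-PC1 distribution (MAD = 0)", call. = FALSE)
  }
  out[, z := (delta_pc1 - ctr) / scl]
  out[, p := 2 * stats::pnorm(-abs(z))]
  out[, class := "stable"]
  out[!ok, class := "masked"]
  out[label1 == "A" & label2 == "B" & p < alpha, class := "A_to_B"]
  out[label1 == "B" & label2 == "A" & p < alpha, class := "B_to_A"]
  data.table::setattr(out, "alpha", alpha)
  data.table::setattr(out, "class", c("switch_table", class(out)))
  out[]
}
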