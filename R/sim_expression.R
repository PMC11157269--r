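# Expression generator coupled to the planted 3D structure: genes whose
# TSS sits near a condition-specific loop anchor, or inside a switched
# compartment block, receive a configured log2 fold-change on a
# negative-binomial baseline.

#' Simulate replicate expression counts coupled to planted structure
#'
#' Log2 fold-changes are reported as condition 2 (B) over condition 1
#' (A): a gene near an A-only loop anchor loses its loop in condition B
#' and gets `-lfc_loop`; a gene near a B-only anchor gets `+lfc_loop`;
#' genes in switched blocks get `-lfc_comp` (A_to_B) or `+lfc_comp`
#' (B_to_A). Loop coupling takes precedence when both apply. Baseline
#' counts are negative binomial; the planted effect is split
#' symmetrically across conditions.
#'
#' @param truth a `hic_truth`.
#' @param n_genes number of genes (TSS uniform on the chromosome).
#' @param n_reps replicates per condition.
#' @param base_mu baseline mean count.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param lfc_loop planted |log2FC| for loop-coupled genes.
#' @param lfc_comp planted |log2FC| for switched-compartment genes.
#' @param window TSS-to-anchor linkage window, bp.
#' @param seed integer seed.
#' @return list with `counts` (genes x 2*n_reps matrix), `de` (a
#'   `de_table`: `gene`, `tss`, `mean1`, `mean2`, `log2FC`, `p` from a
#'   Welch t-test on log2 counts), and `truth_de`
#'   (`gene`, `true_log2fc`, `mechanism`).
#' @export
simulate_expression <- function(truth, n_genes = 1000L, n_reps = 3L,
                                base_mu = 100, nb_size = 10,
                                lfc_loop = 2, lfc_comp = 1,
                                window = 3000, seed = 1L) {
  cfg <- truth$config
  res <- cfg$resolution
  L <- cfg$chrom_length
  set.seed(substream_seed(seed, 51L))
  tss <- sort(sample.int(L, n_genes)) - 1L
  gene <- sprintf("gene%05d", seq_len(n_genes))

  true_lfc <- rep(0, n_genes)
  mech <- rep("none", n_genes)
  # compartment coupling by TSS block
  if (nrow(truth$switched_blocks)) {
    blk <- (tss %/% cfg$compartment_block_size) + 1L
    for (q in seq_len(nrow(truth$switched_blocks))) {
      hit <- blk == truth$switched_blocks$block[q]
      dirn <- if (truth$switched_blocks$class[q] == "B_to_A") 1 else -1
      true_lfc[hit] <- dirn * lfc_comp
      mech[hit] <- "compartment"
    }
  }
  # loop coupling by TSS-to-anchor distance (either anchor)
  spec <- truth$loops[truth$loops$condition != "common", ]
  if (nrow(spec)) {
    anchors <- data.table::data.table(
      start = c(spec$a1 - 1L, spec$a2 - 1L) * res,
      condition = rep(spec$condition, 2L))
    anchors[, `:=`(end = start + res)]
    for (q in seq_len(nrow(anchors))) {
      d <- ifelse(tss < anchors$start[q], anchors$start[q] - tss,
                  ifelse(tss >= anchors$end[q], tss - anchors$end[q] + 1L, 0L))
      hit <- d <= window
      if (any(hit)) {
        dirn <- if (anchors$condition[q] == "B_only") 1 else -1
        true_lfc[hit] <- dirn * lfc_loop
        mech[hit] <- "loop"
      }
    }
  }
  mu1 <- base_mu * 2^(-true_lfc / 2)
  mu2 <- base_mu * 2^(true_lfc / 2)
  set.seed(substream_seed(seed, 52L))
  c1 <- matrix(stats::rnbinom(n_genes * n_reps, mu = rep(mu1, n_reps),
                              size = nb_size), n_genes, n_reps)
  c2 <- matrix(stats::rnbinom(n_genes * n_reps, mu = rep(mu2, n_reps),
                              size = nb_size), n_genes, n_reps)
  counts <- cbind(c1, c2)
  colnames(counts) <- c(paste0("cond1_rep", seq_len(n_reps)),
                        paste0("cond2_rep", seq_len(n_reps)))
  rownames(counts) <- gene
  m1 <- rowMeans(c1)
  m2 <- rowMeans(c2)
  lfc_hat <- log2((m2 + 0.5) / (m1 + 0.5))
  pvals <- vapply(seq_len(n_genes), function(g) {
    x <- log2(c1[g, ] + 1)
    y <- log2(c2[g, ] + 1)
    if (stats::sd(c(x, y)) == 0) return(1)
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  de <- data.table::data.table(gene = gene, chrom = "chrSim", tss = tss,
                               strand = "+", mean1 = m1, mean2 = m2,
                               log2FC = lfc_hat, p = pvals)
  data.table::setattr(de, "class", c("de_table", class(de)))
  list(counts = counts, de = de[],
       truth_de = data.table::data.table(gene = gene,
                                         true_log2fc = true_lfc,
                                         mechanism = mech))
}

#' Simulate per-sample spike-in and primary-genome tag counts
#'
#' @param spikein_means named numeric vector: expected spike-in tag
#'   count per sample.
#' @param primary_means expected primary-genome tag count per sample
#'   (recycled).
#' @param noise `"poisson"` for Poisson counts around the means,
#'   `"none"` for exact configured counts.
#' @param seed integer seed.
#' @return data.table `sample`, `primary_tags`, `spikein_tags`.
#' @export
simulate_spikein <- function(spikein_means, primary_means = 1e6,
                             noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  k <- length(spikein_means)
  samples <- names(spikein_means) %||% paste0("sample", seq_len(k))
  primary_means <- rep_len(primary_means, k)
  if (noise == "poisson") {
    set.seed(substream_seed(seed, 61L))
    sp <- stats::rpois(k, spikein_means)
    pr <- stats::rpois(k, primary_means)
  } else {
    sp <- round(spikein_means)
    pr <- round(primary_means)
  }
  data.table::data.table(sample = samples,
                         primary_tags = as.numeric(pr),
                         spikein_tags = as.numeric(sp))
}
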