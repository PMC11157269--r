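# Integration of loop and compartment calls with expression:
# DEG classification, TSS-to-anchor linkage, exact association tests,
# compartment-switch expression shifts, and delta-delta-Ct.

#' Classify differentially expressed genes
#'
#' `up` genes satisfy `p < p_thresh` and `log2FC > lfc_thresh`;
#' `down` is symmetric. The extreme tiers additionally require
#' `|log2FC| >= extreme_lfc` (inclusive, i.e. at least a
#' `2^extreme_lfc`-fold difference).
#'
#' @param de a `de_table` (columns `gene`, `log2FC`, `p`).
#' @param p_thresh p-value cutoff.
#' @param lfc_thresh |log2FC| cutoff (strict).
#' @param extreme_lfc |log2FC| cutoff for the extreme tier (inclusive).
#' @return list of gene-id vectors: `up`, `down`, `extreme_up`,
#'   `extreme_down`.
#' @export
classify_degs <- function(de, p_thresh = 0.01, lfc_thresh = 1,
                          extreme_lfc = 6) {
  de <- data.table::as.data.table(de)
  up <- de[p < p_thresh & log2FC > lfc_thresh, gene]
  down <- de[p < p_thresh & log2FC < -lfc_thresh, gene]
  xup <- de[p < p_thresh & log2FC > lfc_thresh & log2FC >= extreme_lfc, gene]
  xdn <- de[p < p_thresh & log2FC < -lfc_thresh & log2FC <= -extreme_lfc,
            gene]
  list(up = up, down = down, extreme_up = xup, extreme_down = xdn)
}

#' Summarize DEG set sizes as counts and whole-percent fractions
#'
#' Percentages are of the total expressed genes, rounded to the nearest
#' whole percent with halves away from zero (1031/23272 prints as 4%).
#'
#' @param de a `de_table` (defines the expressed universe).
#' @param sets named list of gene-id vectors, e.g. from
#'   [classify_degs()].
#' @return data.table `set`, `count`, `total`, `percent`.
#' @export
deg_summary <- function(de, sets) {
  total <- nrow(data.table::as.data.table(de))
  data.table::data.table(
    set = names(sets),
    count = vapply(sets, length, 1L),
    total = total,
    percent = vapply(sets, function(s) {
      as.numeric(round_half_away(100 * length(s) / total))
    }, numeric(1)))
}

# distance from a point to a half-open interval [start, end); 0 inside
point_interval_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos,
         ifelse(pos >= end, pos - end + 1, 0))
}

#' Link loops to genes by TSS-to-anchor distance
#'
#' A loop-gene pair is emitted when the minimum distance from the TSS
#' to either anchor interval is at most `window` (0 inside an anchor;
#' strand is ignored).
#'
#' @param loops a loop table with anchor bins `i`, `j` (1-based) and a
#'   `resolution` attribute, or columns `anchor1_start`/`anchor2_start`
#'   with `resolution` passed explicitly.
#' @param tss_table data.table with columns `gene`, `tss` (bp).
#' @param window linkage window in bp.
#' @param resolution anchor width in bp (taken from the loop table
#'   attribute when `NULL`).
#' @return data.table `gene`, `loop_id` (row index into `loops`),
#'   `anchor` (1 or 2), `distance`.
#' @export
link_loops_to_genes <- function(loops, tss_table, window = 3000,
                                resolution = NULL) {
  loops <- data.table::as.data.table(loops)
  resolution <- resolution %||% attr(loops, "resolution")
  if (is.null(resolution)) stop("resolution is required", call. = FALSE)
  tssdt <- data.table::as.data.table(tss_table)
  if (!nrow(loops) || !nrow(tssdt)) {
    return(data.table::data.table(gene = character(), loop_id = integer(),
                                  anchor = integer(), distance = numeric()))
  }
  anc <- data.table::data.table(
    loop_id = rep(seq_len(nrow(loops)), 2L),
    anchor = rep(1:2, each = nrow(loops)),
    start = c(loops$i - 1L, loops$j - 1L) * resolution)
  anc[, end := start + resolution]
  grid <- data.table::CJ(gi = seq_len(nrow(tssdt)), ai = seq_len(nrow(anc)))
  d <- point_interval_distance(tssdt$tss[grid$gi], anc$start[grid$ai],
                               anc$end[grid$ai])
  keep <- d <= window
  out <- data.table::data.table(
    gene = tssdt$gene[grid$gi[keep]],
    loop_id = anc$loop_id[grid$ai[keep]],
    anchor = anc$anchor[grid$ai[keep]],
    distance = as.numeric(d[keep]))
  # one row per (gene, loop): keep the nearest anchor
  data.table::setorder(out, gene, loop_id, distance, anchor)
  out <- out[!duplicated(out[, .(gene, loop_id)])]
  out[]
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Computed by enumeration of the conditional hypergeometric
#' distribution: the p-value sums the probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (with a small relative tolerance).
#'
#' @param tab 2x2 integer matrix.
#' @return list `p`, `odds_ratio` (sample odds ratio, `ad/bc`).
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  a <- tab[1L, 1L]; b <- tab[1L, 2L]
  c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  m <- a + c_   # column-1 total
  nn <- b + d   # column-2 total
  k <- a + b    # row-1 total
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  orr <- (a * d) / (b * c_)
  list(p = min(1, p), odds_ratio = orr)
}

#' Association between gene regulation direction and adjacent loop fate
#'
#' Builds the 2x2 contingency of gene direction (up/down) against the
#' status (gained/lost) of linked differential loops and tests it with
#' the two-sided Fisher exact test. Both tallies of the ambiguous
#' counting unit are emitted: loop-gene combinations (every linked
#' pair counts) and genes (only genes whose linked differential loops
#' have a single status).
#'
#' @param diff_loops a `diff_loop_table` (with `status`).
#' @param degs list with `up` and `down` gene-id vectors.
#' @param linked_pairs output of [link_loops_to_genes()] computed on
#'   `diff_loops` (loop_id indexes its rows).
#' @return list with `pairs_table`, `pairs_test`, `genes_table`,
#'   `genes_test`.
#' @export
loop_gene_association <- function(diff_loops, degs, linked_pairs) {
  lp <- data.table::as.data.table(linked_pairs)
  lp[, status := diff_loops$status[loop_id]]
  lp <- lp[status %in% c("gained", "lost")]
  lp[, direction := data.table::fifelse(gene %in% degs$up, "up",
                        data.table::fifelse(gene %in% degs$down, "down",
                                            NA_character_))]
  lp <- lp[!is.na(direction)]
  mk_tab <- function(dirs, stats_) {
    matrix(c(sum(dirs == "up" & stats_ == "gained"),
             sum(dirs == "up" & stats_ == "lost"),
             sum(dirs == "down" & stats_ == "gained"),
             sum(dirs == "down" & stats_ == "lost")),
           2L, 2L, byrow = TRUE,
           dimnames = list(c("up", "down"), c("gained", "lost")))
  }
  pairs_tab <- mk_tab(lp$direction, lp$status)
  bygene <- lp[, .(status = if (data.table::uniqueN(status) == 1L)
    status[1L] else NA_character_,
    direction = direction[1L]), by = gene]
  bygene <- bygene[!is.na(status)]
  genes_tab <- mk_tab(bygene$direction, bygene$status)
  list(pairs_table = pairs_tab,
       pairs_test = fisher_exact_2x2(pairs_tab),
       genes_table = genes_tab,
       genes_test = fisher_exact_2x2(genes_tab))
}

#' Expression shift of genes in switched compartments
#'
#' Genes are assigned to switch classes by the compartment bin holding
#' their TSS; each switched class is compared to the stable class with
#' a two-sided Wilcoxon rank-sum test on log2 fold-changes.
#'
#' @param switches a `switch_table`.
#' @param de a `de_table` with `tss` positions.
#' @param block_size compartment bin size in bp.
#' @return data.table per class (`A_to_B`, `B_to_A`, `stable`):
#'   `n`, `median_lfc`, and `p` against the stable class (`NA` for an
#'   empty class and for stable itself).
#' @export
compartment_expression_shift <- function(switches, de, block_size = 250000) {
  dedt <- data.table::as.data.table(de)
  blk <- (dedt$tss %/% block_size) + 1L
  cls <- switches$class[match(blk, switches$bin)]
  lfc <- dedt$log2FC
  stable_lfc <- lfc[!is.na(cls) & cls == "stable"]
  one <- function(name) {
    v <- lfc[!is.na(cls) & cls == name]
    p <- if (name == "stable" || !length(v) || !length(stable_lfc)) {
      NA_real_
    } else {
      stats::wilcox.test(v, stable_lfc, exact = FALSE)$p.value
    }
    data.table::data.table(class = name, n = length(v),
                           median_lfc = if (length(v)) stats::median(v)
                           else NA_real_, p = p)
  }
  data.table::rbindlist(lapply(c("A_to_B", "B_to_A", "stable"), one))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference_gene`; per gene,
#' `ddCt = dCt_sample - dCt_reference_sample`; relative expression is
#' `2^-ddCt` (exactly 1 for the reference sample).
#'
#' @param ct data.table with columns `sample`, `gene`, `ct`.
#' @param ref_gene housekeeping reference gene (e.g. GAPDH).
#' @param ref_sample reference sample.
#' @return data.table `sample`, `gene`, `rel_expr` (reference gene rows
#'   excluded).
#' @export
ddct <- function(ct, ref_gene, ref_sample) {
  dt <- data.table::as.data.table(ct)
  stopifnot(all(c("sample", "gene", "ct") %in% names(dt)))
  if (!ref_gene %in% dt$gene) stop("reference gene not in table",
                                   call. = FALSE)
  if (!ref_sample %in% dt$sample) stop("reference sample not in table",
                                       call. = FALSE)
  refg <- dt[gene == ref_gene, .(sample, ref_ct = ct)]
  if (anyDuplicated(refg$sample)) {
    refg <- refg[, .(ref_ct = mean(ref_ct)), by = sample]
  }
  dt <- merge(dt[gene != ref_gene], refg, by = "sample")
  if (any(is.na(dt$ref_ct))) stop("reference gene missing for a sample",
                                  call. = FALSE)
  dt[, dct := ct - ref_ct]
  base <- dt[sample == ref_sample, .(gene, base_dct = dct)]
  dt <- merge(dt, base, by = "gene")
  dt[, rel_expr := 2^(-(dct - base_dct))]
  out <- dt[, .(sample, gene, rel_expr)]
  data.table::setorder(out, gene, sample)
  out[]
}

#' Cross-system DEG overlap enrichment
#'
#' The universe is the intersection of the two expressed-gene
#' universes; sets are restricted to it and tested as in
#' [overlap_enrichment()].
#'
#' @param set_a,set_b DEG id vectors from the two systems.
#' @param universe_a,universe_b expressed-gene universes.
#' @return list as [overlap_enrichment()], plus `universe_size`.
#' @export
deg_overlap_enrichment <- function(set_a, set_b, universe_a, universe_b) {
  universe <- intersect(universe_a, universe_b)
  res <- overlap_enrichment(intersect(set_a, universe),
                            intersect(set_b, universe),
                            length(universe))
  res$universe_size <- length(universe)
  res
}
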