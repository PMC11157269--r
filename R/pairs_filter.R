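# Hi-C read-pair filtering cascade: uniqueness, positional
# de-duplication, fragment assignment, same-fragment removal,
# orientation/distance rules, and binning of surviving cis pairs to
# fixed-size anchors.

#' Filtering parameters for the read-pair cascade
#'
#' @param inward_min_distance minimum fragment-midpoint distance (bp)
#'   for an inward pair to be kept (strictly greater).
#' @param outward_min_distance minimum fragment-midpoint distance (bp)
#'   for an outward pair to be kept (strictly greater).
#' @param anchor_resolution bin size (bp) used by [bin_to_anchors()].
#' @return a `filter_config` list.
#' @export
filter_config <- function(inward_min_distance = 1000,
                          outward_min_distance = 5000,
                          anchor_resolution = 5000) {
  stop_if_not_scalar_num(inward_min_distance, "inward_min_distance")
  stop_if_not_scalar_num(outward_min_distance, "outward_min_distance")
  stop_if_not_scalar_num(anchor_resolution, "anchor_resolution")
  structure(list(inward_min_distance = inward_min_distance,
                 outward_min_distance = outward_min_distance,
                 anchor_resolution = anchor_resolution),
            class = "filter_config")
}

#' Classify a cis pair's strand orientation
#'
#' With mates ordered by position, `(+,-)` is inward, `(-,+)` is
#' outward, and equal strands are same-strand. Vectorized.
#'
#' @param strand1,strand2 strand characters of the position-ordered
#'   mates.
#' @return character vector in `{inward, outward, same_strand}`.
#' @export
classify_orientation <- function(strand1, strand2) {
  out <- rep("same_strand", length(strand1))
  out[strand1 == "+" & strand2 == "-"] <- "inward"
  out[strand1 == "-" & strand2 == "+"] <- "outward"
  out
}

#' Apply the read-pair filtering cascade
#'
#' Rules are applied in order: (1) drop non-uniquely mapped pairs;
#' (2) drop positional duplicates, keyed on
#' `(chrom1, pos1, chrom2, pos2)` ignoring strand, keeping the first
#' occurrence in stream order; (3) set trans pairs aside (retained
#' separately); (4) assign mates to digest fragments and drop pairs
#' whose mates share one fragment; (5) drop inward pairs with
#' fragment-midpoint distance `<= inward_min_distance` and outward
#' pairs with distance `<= outward_min_distance`; same-strand pairs are
#' kept at any distance. Survivors of (5) form the cis pair set.
#'
#' @param pairs a data.frame/data.table with columns `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, optional `unique_flag`
#'   (assumed `TRUE` when absent). Positions are 0-based; mates are
#'   reordered lexicographically on ingestion.
#' @param digest a `digest_index` covering every chromosome present.
#' @param cfg a [filter_config()].
#' @return list of class `filtered_pairs` with `cis` (surviving pairs,
#'   annotated with fragments, midpoint distance, and orientation),
#'   `trans`, `qc` (per-disposition counts partitioning the input),
#'   and `disposition` (per input row, in input order).
#' @export
filter_pairs <- function(pairs, digest, cfg = filter_config()) {
  dt <- data.table::as.data.table(pairs)
  req <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(req %in% names(dt))) {
    stop("pairs must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"unique_flag" %in% names(dt)) dt[, unique_flag := TRUE]
  chroms <- unique(c(dt$chrom1, dt$chrom2))
  missing_ch <- setdiff(chroms, names(digest$boundaries))
  if (length(missing_ch)) {
    stop("unknown chromosome(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  # enforce lexicographic mate order
  swap <- dt$chrom2 < dt$chrom1 |
    (dt$chrom1 == dt$chrom2 & dt$pos2 < dt$pos1)
  if (any(swap)) {
    tmp <- dt[swap, .(chrom1, pos1, strand1)]
    dt[swap, `:=`(chrom1 = chrom2, pos1 = pos2, strand1 = strand2)]
    dt[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1,
                  strand2 = tmp$strand1)]
  }
  n <- nrow(dt)
  disp <- rep(NA_character_, n)
  disp[!dt$unique_flag] <- "non_unique"
  live <- is.na(disp)
  dupkey <- paste(dt$chrom1, dt$pos1, dt$chrom2, dt$pos2, sep = "\r")
  isdup <- rep(FALSE, n)
  isdup[live] <- duplicated(dupkey[live])
  disp[isdup] <- "positional_duplicate"
  live <- is.na(disp)
  is_trans <- dt$chrom1 != dt$chrom2
  disp[live & is_trans] <- "trans_kept"
  live <- is.na(disp)
  # fragment assignment per chromosome for remaining cis pairs
  frag1 <- frag2 <- rep(NA_integer_, n)
  middist <- rep(NA_real_, n)
  for (ch in unique(dt$chrom1[live])) {
    sel <- which(live & dt$chrom1 == ch)
    f1 <- assign_fragment(ch, dt$pos1[sel], digest)
    f2 <- assign_fragment(ch, dt$pos2[sel], digest)
    frag1[sel] <- f1
    frag2[sel] <- f2
    middist[sel] <- abs(fragment_mid(ch, f2, digest) -
                          fragment_mid(ch, f1, digest))
  }
  disp[live & frag1 == frag2] <- "same_fragment"
  live <- is.na(disp)
  orient <- classify_orientation(dt$strand1, dt$strand2)
  disp[live & orient == "inward" &
         middist <= cfg$inward_min_distance] <- "inward_close"
  live <- is.na(disp)
  disp[live & orient == "outward" &
         middist <= cfg$outward_min_distance] <- "outward_close"
  disp[is.na(disp)] <- "cis_kept"

  dt[, `:=`(frag1 = frag1, frag2 = frag2, mid_distance = middist,
            orientation = ifelse(dt$chrom1 == dt$chrom2, orient,
                                 NA_character_))]
  lv <- c("non_unique", "positional_duplicate", "same_fragment",
          "inward_close", "outward_close", "trans_kept", "cis_kept")
  qc <- data.table::data.table(
    disposition = lv,
    count = as.integer(table(factor(disp, levels = lv))))
  structure(list(cis = dt[disp == "cis_kept"],
                 trans = dt[disp == "trans_kept"],
                 qc = qc,
                 disposition = disp,
                 config = cfg),
            class = "filtered_pairs")
}

#' @export
print.filtered_pairs <- function(x, ...) {
  cat("<filtered_pairs>\n")
  print(x$qc)
  invisible(x)
}

#' Bin cis pairs to fixed-size anchor pairs
#'
#' Each mate maps to `floor(pos / resolution)`; counts are aggregated
#' on unordered anchor pairs. The total count equals the number of
#' input pairs.
#'
#' @param cis a data.table of cis pairs (e.g. `filter_pairs(...)$cis`).
#' @param resolution anchor bin size in bp.
#' @return data.table `bin1`, `bin2` (0-based, `bin1 <= bin2`),
#'   `count`.
#' @export
bin_to_anchors <- function(cis, resolution = 5000) {
  dt <- data.table::as.data.table(cis)
  b1 <- as.integer(dt$pos1 %/% resolution)
  b2 <- as.integer(dt$pos2 %/% resolution)
  out <- data.table::data.table(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2))
  out <- out[, .(count = .N), by = .(bin1, bin2)]
  data.table::setorder(out, bin1, bin2)
  out[]
}
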