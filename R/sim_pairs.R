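# Labeled read-pair stream generator: plants known proportions of the
# artifact classes the filtering cascade must remove, with truth labels
# attached so disposition precision/recall can be asserted exactly.

#' Simulate a labeled Hi-C read-pair stream
#'
#' Clean pairs are placed with fragment-midpoint separations well above
#' the outward cutoff so they survive every rule; artifact classes are
#' planted at `round(n * rate)` counts each. Positional duplicates are
#' exact copies of clean pairs appended after their source (the
#' keep-first de-duplication rule then maps labels onto dispositions
#' 1:1). All non-duplicate pairs have unique position keys.
#'
#' @param n total number of read pairs.
#' @param digest a `digest_index`; the first chromosome hosts cis
#'   pairs, a second chromosome is required when `trans > 0`.
#' @param artifact_rates named list of fractions: `duplicate`,
#'   `same_fragment`, `inward_close`, `outward_close`, `trans`,
#'   `non_unique` (missing entries default to 0). Must sum to < 1.
#' @param seed integer seed.
#' @return data.table of `read_pair` records (`chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, `unique_flag`) with a
#'   `truth` label column.
#' @export
simulate_read_pairs <- function(n, digest,
                                artifact_rates = list(), seed = 1L) {
  rates <- list(duplicate = 0, same_fragment = 0, inward_close = 0,
                outward_close = 0, trans = 0, non_unique = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (sum(unlist(rates)) >= 1) {
    stop("artifact rates must sum to < 1", call. = FALSE)
  }
  counts <- lapply(rates, function(r) as.integer(round(n * r)))
  n_clean <- n - sum(unlist(counts))
  ch <- names(digest$boundaries)[1L]
  L <- as.numeric(digest$chrom_sizes[[ch]])
  b <- digest$boundaries[[ch]]
  nfrag <- length(b) - 1L
  mids <- (b[-length(b)] + b[-1L]) / 2
  flen <- diff(b)
  set.seed(substream_seed(seed, 41L))
  used <- new.env(hash = TRUE)
  key_of <- function(p1, p2) paste(p1, p2)
  claim <- function(p1, p2) {
    k <- key_of(p1, p2)
    if (!is.null(used[[k]])) return(FALSE)
    used[[k]] <- TRUE
    TRUE
  }
  rand_strand <- function(k) sample(c("+", "-"), k, replace = TRUE)

  draw_clean <- function(k) {
    out <- vector("list", k)
    for (q in seq_len(k)) {
      repeat {
        p1 <- sample.int(L - 20001L, 1L) - 1L
        off <- sample(20000:min(1000000, L - p1 - 1L), 1L)
        p2 <- p1 + off
        f1 <- assign_fragment(ch, p1, digest)
        f2 <- assign_fragment(ch, p2, digest)
        if (f1 != f2 && abs(mids[f2 + 1L] - mids[f1 + 1L]) > 5000 &&
            claim(p1, p2)) break
      }
      out[[q]] <- data.table::data.table(
        chrom1 = ch, pos1 = p1, strand1 = rand_strand(1L),
        chrom2 = ch, pos2 = p2, strand2 = rand_strand(1L),
        unique_flag = TRUE, truth = "clean")
    }
    data.table::rbindlist(out)
  }

  # pick a fragment pair (f, g > f) whose midpoint gap lies in (lo, hi]
  draw_gapped <- function(k, lo, hi, s1, s2, lab) {
    out <- vector("list", k)
    for (q in seq_len(k)) {
      repeat {
        f <- sample.int(nfrag - 5L, 1L)
        g <- f + which(mids[(f + 1L):min(nfrag, f + 30L)] - mids[f] <= hi &
                         mids[(f + 1L):min(nfrag, f + 30L)] - mids[f] > lo)
        if (!length(g)) next
        g <- g[length(g)]
        p1 <- b[f] + sample.int(max(1L, flen[f]), 1L) - 1L
        p2 <- b[g] + sample.int(max(1L, flen[g]), 1L) - 1L
        if (p1 < p2 && claim(p1, p2)) break
      }
      out[[q]] <- data.table::data.table(
        chrom1 = ch, pos1 = p1, strand1 = s1,
        chrom2 = ch, pos2 = p2, strand2 = s2,
        unique_flag = TRUE, truth = lab)
    }
    data.table::rbindlist(out)
  }

  draw_same_fragment <- function(k) {
    out <- vector("list", k)
    big <- which(flen >= 4)
    for (q in seq_len(k)) {
      repeat {
        f <- sample(big, 1L)
        ps <- b[f] + sample.int(flen[f], 2L) - 1L
        p1 <- min(ps); p2 <- max(ps)
        if (p1 < p2 && claim(p1, p2)) break
      }
      out[[q]] <- data.table::data.table(
        chrom1 = ch, pos1 = p1, strand1 = rand_strand(1L),
        chrom2 = ch, pos2 = p2, strand2 = rand_strand(1L),
        unique_flag = TRUE, truth = "same_fragment")
    }
    data.table::rbindlist(out)
  }

  draw_trans <- function(k) {
    if (k > 0L && length(digest$boundaries) < 2L) {
      stop("trans pairs require a second chromosome in the digest",
           call. = FALSE)
    }
    if (k == 0L) return(NULL)
    ch2 <- names(digest$boundaries)[2L]
    L2 <- as.numeric(digest$chrom_sizes[[ch2]])
    data.table::data.table(
      chrom1 = ch, pos1 = sample.int(L, k) - 1L,
      strand1 = rand_strand(k),
      chrom2 = ch2, pos2 = sample.int(L2, k) - 1L,
      strand2 = rand_strand(k), unique_flag = TRUE, truth = "trans")
  }

  clean <- draw_clean(n_clean)
  parts <- list(
    clean,
    if (counts$same_fragment > 0L) draw_same_fragment(counts$same_fragment),
    if (counts$inward_close > 0L)
      draw_gapped(counts$inward_close, 0, 1000, "+", "-", "inward_close"),
    if (counts$outward_close > 0L)
      draw_gapped(counts$outward_close, 0, 5000, "-", "+", "outward_close"),
    draw_trans(counts$trans),
    if (counts$non_unique > 0L) {
      nu <- draw_clean(counts$non_unique)
      nu[, `:=`(unique_flag = FALSE, truth = "non_unique")]
      nu
    })
  stream <- data.table::rbindlist(Filter(Negate(is.null), parts))
  if (counts$duplicate > 0L) {
    if (!nrow(clean)) stop("cannot plant duplicates without clean pairs",
                           call. = FALSE)
    src <- clean[sample.int(nrow(clean), counts$duplicate, replace = TRUE)]
    src[, truth := "duplicate"]
    stream <- rbind(stream, src)
  }
  stream[]
}
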