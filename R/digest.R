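# Restriction-digest index: per-chromosome sorted cut positions for a
# motif (GANTC for the Arima-style protocol), with half-open fragment
# semantics [cut_k, cut_{k+1}).

#' Build a restriction-digest index
#'
#' @param cuts named list of numeric vectors: per-chromosome internal
#'   cut positions (bp, 0-based, strictly increasing). A leading 0 is
#'   tolerated and ignored; the first fragment always starts at 0 and
#'   the last ends at the chromosome length.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return a `digest_index` object.
#' @export
digest_index <- function(cuts, chrom_sizes) {
  stopifnot(is.list(cuts), !is.null(names(cuts)),
            all(names(cuts) %in% names(chrom_sizes)))
  boundaries <- lapply(names(cuts), function(ch) {
    cc <- sort(unique(as.numeric(cuts[[ch]])))
    cc <- cc[cc > 0 & cc < chrom_sizes[[ch]]]
    if (any(diff(cc) <= 0)) stop("cut positions must be strictly increasing",
                                 call. = FALSE)
    c(0, cc, as.numeric(chrom_sizes[[ch]]))
  })
  names(boundaries) <- names(cuts)
  structure(list(boundaries = boundaries,
                 chrom_sizes = chrom_sizes),
            class = "digest_index")
}

#' @export
print.digest_index <- function(x, ...) {
  cat(sprintf("<digest_index> %d chromosome(s), %d fragments\n",
              length(x$boundaries),
              sum(vapply(x$boundaries, length, 1L)) - length(x$boundaries)))
  invisible(x)
}

#' Assign a genomic position to its digest fragment
#'
#' Fragments are half-open `[cut_k, cut_k+1)` intervals indexed from 0;
#' a position equal to a cut site belongs to the fragment starting
#' there. Vectorized over `pos`.
#'
#' @param chrom chromosome name (scalar).
#' @param pos 0-based positions in bp.
#' @param digest a `digest_index`.
#' @return integer fragment ids (0-based).
#' @export
assign_fragment <- function(chrom, pos, digest) {
  b <- digest$boundaries[[chrom]]
  if (is.null(b)) stop(sprintf("unknown chromosome '%s'", chrom),
                       call. = FALSE)
  if (any(pos < 0 | pos >= digest$chrom_sizes[[chrom]])) {
    stop(sprintf("position outside chromosome '%s'", chrom), call. = FALSE)
  }
  findInterval(pos, b) - 1L
}

# fragment midpoints for given fragment ids (0-based); internal
fragment_mid <- function(chrom, frag, digest) {
  b <- digest$boundaries[[chrom]]
  (b[frag + 1L] + b[frag + 2L]) / 2
}

#' Simulate a digest index with geometric-like cut spacing
#'
#' Cut sites for a 5-bp degenerate motif such as GANTC land roughly
#' every 256 bp in random sequence; `mean_spacing` controls that rate.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param mean_spacing expected fragment length in bp.
#' @param seed integer seed.
#' @return a `digest_index`.
#' @export
simulate_digest <- function(chrom_sizes, mean_spacing = 300, seed = 1L) {
  set.seed(substream_seed(seed, 31L))
  cuts <- lapply(chrom_sizes, function(L) {
    k <- max(1L, as.integer(L %/% mean_spacing))
    sort(sample.int(L - 1L, min(k, L - 1L)))
  })
  names(cuts) <- names(chrom_sizes)
  digest_index(cuts, chrom_sizes)
}
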