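# Spike-in normalization of ChIP-seq tag counts and normalized peak
# intensities.

#' Spike-in normalization factors
#'
#' The reference is the sample with the minimum spike-in tag count
#' (ties broken by sample-name order); each sample's factor is
#' `reference_count / sample_count`, so the reference factor is exactly
#' 1 and all factors lie in (0, 1].
#'
#' @param spikein_counts named numeric vector of uniquely-aligned
#'   spike-in tag counts per sample.
#' @return named numeric vector of factors.
#' @export
normalization_factors <- function(spikein_counts) {
  if (is.null(names(spikein_counts))) {
    names(spikein_counts) <- paste0("sample", seq_along(spikein_counts))
  }
  zero <- names(spikein_counts)[spikein_counts <= 0]
  if (length(zero)) {
    stop("zero spike-in count for sample(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  ord <- order(spikein_counts, names(spikein_counts))
  ref <- spikein_counts[ord[1L]]
  stats::setNames(as.numeric(ref) / as.numeric(spikein_counts),
                  names(spikein_counts))
}

#' Spike-in-scaled normalized peak intensities (RPKM x factor)
#'
#' RPKM is `count / (length_kb * primary_total / 1e6)`; the sample's
#' spike-in factor then scales it. The two scalings commute, so their
#' order does not affect any between-sample ratio.
#'
#' @param peaks data.table with columns `sample`, `count` (raw tags in
#'   the peak), `length_bp`.
#' @param factors named factor vector from [normalization_factors()].
#' @param primary_totals named numeric vector of total primary-genome
#'   tags per sample.
#' @return the peak table with `rpkm` and `normalized` columns added.
#' @export
normalize_peaks <- function(peaks, factors, primary_totals) {
  dt <- data.table::copy(data.table::as.data.table(peaks))
  stopifnot(all(c("sample", "count", "length_bp") %in% names(dt)))
  miss <- setdiff(unique(dt$sample), names(factors))
  if (length(miss)) stop("no factor for sample(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tot <- primary_totals[dt$sample]
  dt[, rpkm := count / ((length_bp / 1000) * (tot / 1e6))]
  dt[, normalized := rpkm * factors[sample]]
  dt[]
}
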