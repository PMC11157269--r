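# Plain-text interchange: 4DN .pairs, sparse triplet TSV, chrom sizes,
# bedGraph, BEDPE, digest cut tables, JSON truth sidecars, and a flat
# key:value config reader.

#' Write read pairs in 4DN .pairs text format
#'
#' Positions are stored 1-based in the file (the in-memory convention
#' is 0-based half-open).
#'
#' @param pairs data.table of read pairs.
#' @param path output path.
#' @param chrom_sizes optional named vector, written as `#chromsize`
#'   header lines.
#' @export
write_pairs_file <- function(pairs, path, chrom_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  if (!is.null(chrom_sizes)) {
    writeLines(sprintf("#chromsize: %s %d", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  }
  writeLines(
    "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2", con)
  dt <- data.table::as.data.table(pairs)
  body <- sprintf("read%07d\t%s\t%d\t%s\t%d\t%s\t%s",
                  seq_len(nrow(dt)), dt$chrom1, dt$pos1 + 1L,
                  dt$chrom2, dt$pos2 + 1L, dt$strand1, dt$strand2)
  writeLines(body, con)
  invisible(path)
}

#' Read a 4DN .pairs text file
#'
#' @param path input path.
#' @return data.table with 0-based positions and `unique_flag = TRUE`.
#' @export
read_pairs_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "## pairs format")) {
    stop("not a .pairs file (missing '## pairs format' header)",
         call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.table::data.table(
      chrom1 = character(), pos1 = integer(), strand1 = character(),
      chrom2 = character(), pos2 = integer(), strand2 = character(),
      unique_flag = logical()))
  }
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(fields) < 7L) {
    bad <- which(vapply(strsplit(body, "\t", fixed = TRUE), length, 1L) < 7L)
    stop(sprintf("unparseable .pairs line %d", bad[1L]), call. = FALSE)
  }
  data.table::data.table(
    chrom1 = fields[[2L]], pos1 = as.integer(fields[[3L]]) - 1L,
    strand1 = fields[[6L]],
    chrom2 = fields[[4L]], pos2 = as.integer(fields[[5L]]) - 1L,
    strand2 = fields[[7L]], unique_flag = TRUE)
}

#' Write a contact matrix as sparse triplet TSV
#'
#' Columns are `bin1_start`, `bin2_start` (bp) and `count`; one row per
#' upper-triangle pixel.
#'
#' @param m a `contact_matrix`.
#' @param path output path.
#' @export
write_triplet_tsv <- function(m, path) {
  tr <- cm_triplets(m)
  out <- data.table::data.table(
    bin1_start = (tr$i - 1L) * as.integer(m$resolution),
    bin2_start = (tr$j - 1L) * as.integer(m$resolution),
    count = tr$x)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sparse triplet TSV into a contact matrix
#'
#' @param path input path.
#' @param chrom_length chromosome length, bp.
#' @param resolution bin size, bp.
#' @return a raw `contact_matrix`.
#' @export
read_triplet_tsv <- function(path, chrom_length, resolution) {
  dt <- data.table::fread(path)
  data.table::setnames(dt, c("bin1_start", "bin2_start", "count"))
  anchors <- data.table::data.table(
    bin1 = as.integer(dt$bin1_start %/% resolution),
    bin2 = as.integer(dt$bin2_start %/% resolution),
    count = dt$count)
  build_matrix(anchors, chrom_length, resolution)
}

#' Write a per-bin track as bedGraph
#' @param dt data.table with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_bedgraph <- function(dt, path) {
  data.table::fwrite(data.table::as.data.table(dt)[,
    .(chrom, start, end, value)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a loop table as BEDPE with score columns
#'
#' @param loops a loop/diff-loop table with bins `i`, `j`.
#' @param path output path.
#' @param chrom chromosome name.
#' @param resolution anchor width, bp (loop-table attribute when NULL).
#' @export
write_bedpe <- function(loops, path, chrom = "chrSim", resolution = NULL) {
  loops <- data.table::as.data.table(loops)
  resolution <- resolution %||% attr(loops, "resolution")
  out <- data.table::data.table(
    chrom1 = chrom, start1 = (loops$i - 1L) * resolution,
    end1 = loops$i * resolution,
    chrom2 = chrom, start2 = (loops$j - 1L) * resolution,
    end2 = loops$j * resolution)
  extra <- intersect(c("score", "score1", "score2", "log2_ratio", "z",
                       "p", "status", "size_bp"), names(loops))
  out <- cbind(out, loops[, extra, with = FALSE])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write the ground-truth record as a JSON sidecar
#' @param truth a `hic_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(config = unclass(truth$config),
              blocks = truth$blocks,
              switched_blocks = truth$switched_blocks,
              tad_boundaries = truth$tad_boundaries,
              loops = truth$loops)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write / read a digest cut-site table (TSV: chrom, cut)
#' @param digest a `digest_index`.
#' @param path file path.
#' @export
write_digest_tsv <- function(digest, path) {
  rows <- lapply(names(digest$boundaries), function(ch) {
    b <- digest$boundaries[[ch]]
    data.table::data.table(chrom = ch, cut = b[-c(1L, length(b))])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' @rdname write_digest_tsv
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @export
read_digest_tsv <- function(path, chrom_sizes) {
  dt <- data.table::fread(path)
  cuts <- split(dt$cut, dt$chrom)
  digest_index(cuts, chrom_sizes)
}

# flat config reader: JSON when the extension says so, otherwise a
# minimal "key: value" subset of YAML (comments and blank lines ok)
read_flat_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("unparseable config line: ", lines[bad][1L],
                     call. = FALSE)
  vals <- lapply(kv, function(m) {
    v <- m[[3L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, "", 2L))
}
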