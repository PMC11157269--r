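# Paired-condition Hi-C simulator: plants compartment checkerboard,
# TAD blocks, and focal loops with condition-specific gains/losses on a
# power-law distance decay, draws Poisson pixel counts, and records the
# full ground truth.

#' Plant the ground-truth structure for a simulated condition pair
#'
#' Compartment labels are assigned per block and broadcast to working
#' bins; a configured number of blocks switch label between the two
#' conditions. TAD boundaries are shared between conditions. Planted
#' loop sizes are log-normal *quantiles* at the configured median and
#' sdlog (so the planted sample median equals the configured median by
#' construction); anchors are placed uniformly on-grid without pixel
#' collisions.
#'
#' @param config a [sim_config()].
#' @return a `hic_truth` list: `config`, `blocks` (per-block labels in
#'   both conditions), `switched_blocks`, `tad_boundaries` (working-bin
#'   indices), `loops` (anchor bins, condition class, boost, size).
#' @export
simulate_truth <- function(config) {
  cfg <- config
  res <- cfg$resolution
  n <- as.integer(cfg$chrom_length %/% res)
  bpb <- as.integer(cfg$compartment_block_size %/% res)
  nb <- as.integer(ceiling(n / bpb))
  set.seed(substream_seed(cfg$seed, 11L))
  lab <- sample(c("A", "B"), nb, replace = TRUE)
  if (all(lab == lab[1L])) lab[1L] <- setdiff(c("A", "B"), lab[1L])
  lab_a <- lab
  lab_b <- lab
  pool_a <- which(lab == "A")
  pool_b <- which(lab == "B")
  sw_ab <- sort(sample(pool_a, min(cfg$n_switch_a_to_b, length(pool_a))))
  sw_ba <- sort(sample(pool_b, min(cfg$n_switch_b_to_a, length(pool_b))))
  lab_b[sw_ab] <- "B"
  lab_b[sw_ba] <- "A"
  set.seed(substream_seed(cfg$seed, 12L))
  tad_boundaries <- integer(0)
  if (cfg$tad_mean_size < cfg$chrom_length && n > 2L) {
    min_gap <- max(1L, as.integer(round((cfg$tad_min_size %||% 0) / res)))
    mean_gap <- max(min_gap + 1L, as.integer(round(cfg$tad_mean_size / res)))
    pos <- 1L
    repeat {
      gap <- min_gap + stats::rgeom(1L, 1 / (mean_gap - min_gap + 1L))
      pos <- pos + gap
      if (pos >= n - min_gap) break
      tad_boundaries <- c(tad_boundaries, pos)
    }
  }
  set.seed(substream_seed(cfg$seed, 13L))
  used <- character(0)
  place <- function(k, med, cls, sdlog = cfg$loop_size_sdlog) {
    if (k <= 0L) return(NULL)
    sizes <- stats::qlnorm(stats::ppoints(k), meanlog = log(med),
                           sdlog = sdlog)
    sizes <- sample(sizes)
    min_sep <- max(4L, as.integer(round((cfg$loop_size_min %||% 0) / res)))
    seps <- pmax(min_sep, as.integer(round(sizes / res)))
    if (any(seps >= n)) {
      stop("planted loop size exceeds the chromosome", call. = FALSE)
    }
    a1 <- integer(k)
    for (q in seq_len(k)) {
      for (try in seq_len(1000L)) {
        cand <- sample.int(n - seps[q], 1L)
        key <- paste(cand, cand + seps[q])
        if (!key %in% used) break
      }
      used <<- c(used, key)
      a1[q] <- cand
    }
    data.table::data.table(a1 = a1, a2 = a1 + seps, condition = cls,
                           boost = cfg$loop_boost,
                           size_bp = as.numeric(seps) * res)
  }
  loops <- data.table::rbindlist(list(
    place(cfg$n_loops_common, cfg$loop_size_median_common, "common",
          cfg$loop_size_sdlog_common %||% cfg$loop_size_sdlog),
    place(cfg$n_loops_condA_only, cfg$loop_size_median_A, "A_only"),
    place(cfg$n_loops_condB_only, cfg$loop_size_median_B, "B_only")))
  if (is.null(loops) || !nrow(loops)) {
    loops <- data.table::data.table(a1 = integer(), a2 = integer(),
                                    condition = character(),
                                    boost = numeric(), size_bp = numeric())
  }
  structure(list(
    config = cfg,
    blocks = data.table::data.table(block = seq_len(nb),
                                    label_A = lab_a, label_B = lab_b),
    switched_blocks = data.table::data.table(
      block = c(sw_ab, sw_ba),
      class = rep(c("A_to_B", "B_to_A"), c(length(sw_ab), length(sw_ba)))),
    tad_boundaries = tad_boundaries,
    loops = loops), class = "hic_truth")
}

#' Per-bin planted compartment sign for one condition
#'
#' Broadcasts the block-level labels to working bins as +1 (A) / -1
#' (B); the natural orientation track for [pc1()] on synthetic data.
#'
#' @param truth a `hic_truth`.
#' @param condition `"A"` or `"B"`.
#' @return numeric vector over working bins.
#' @export
truth_comp_sign <- function(truth, condition = c("A", "B")) {
  condition <- match.arg(condition)
  cfg <- truth$config
  n <- as.integer(cfg$chrom_length %/% cfg$resolution)
  bpb <- as.integer(cfg$compartment_block_size %/% cfg$resolution)
  lab <- if (condition == "A") truth$blocks$label_A else truth$blocks$label_B
  block_of <- ((seq_len(n) - 1L) %/% bpb) + 1L
  ifelse(lab[block_of] == "A", 1, -1)
}

#' Draw one condition's contact matrix from a planted truth
#'
#' The expected intensity for bins i < j at separation d bins is
#' `(max(d, 1) * resolution)^(-decay_exponent)` modulated by the
#' compartment checkerboard (`1 + alpha * c_i * c_j`), a within-TAD
#' factor, and planted loop boosts (full boost at the loop pixel, half
#' boost on the surrounding 1-pixel shoulder), then scaled so the total
#' expected cis count equals `depth`. Counts are independent Poisson
#' draws per pixel; the same seed reproduces the matrix bit for bit.
#'
#' @param truth a `hic_truth` from [simulate_truth()].
#' @param condition `"A"` or `"B"`.
#' @param depth expected total cis contacts; defaults to the
#'   configuration value.
#' @param noise_seed seed for the Poisson draw (defaults to a
#'   condition-specific substream of the master seed). Supplying a
#'   fresh value yields an independent technical replicate of the same
#'   planted structure, which is how null (no-signal) condition pairs
#'   are made.
#' @return a raw `contact_matrix`.
#' @export
simulate_contacts <- function(truth, condition = c("A", "B"),
                              depth = NULL, noise_seed = NULL) {
  condition <- match.arg(condition)
  cfg <- truth$config
  res <- cfg$resolution
  n <- as.integer(cfg$chrom_length %/% res)
  depth <- depth %||% cfg$sequencing_depth
  noise_seed <- noise_seed %||%
    substream_seed(cfg$seed, if (condition == "A") 21L else 22L)
  cvec <- truth_comp_sign(truth, condition)
  tad_id <- findInterval(seq_len(n), truth$tad_boundaries)
  alpha <- cfg$compartment_strength
  gamma <- cfg$decay_exponent
  decay <- (pmax(0:(n - 1L), 1L) * res)^(-gamma)
  mu <- vector("list", n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    f <- decay[d + 1L] * (1 + alpha * cvec[i] * cvec[j])
    f <- f * (1 + (cfg$tad_boost - 1) * (tad_id[i] == tad_id[j]))
    mu[[d + 1L]] <- f
  }
  cls <- paste0(condition, "_only")
  active <- truth$loops[truth$loops$condition %in% c("common", cls), ]
  if (nrow(active)) {
    offs <- data.table::CJ(di = -1L:1L, dj = -1L:1L)
    for (q in seq_len(nrow(active))) {
      b <- active$boost[q]
      pi <- active$a1[q] + offs$di
      pj <- active$a2[q] + offs$dj
      fac <- ifelse(offs$di == 0L & offs$dj == 0L, b, (1 + b) / 2)
      keep <- pi >= 1L & pj <= n & pj > pi
      for (t in which(keep)) {
        dd <- pj[t] - pi[t]
        mu[[dd + 1L]][pi[t]] <- mu[[dd + 1L]][pi[t]] * fac[t]
      }
    }
  }
  total <- sum(vapply(mu, sum, numeric(1)))
  scale <- depth / total
  set.seed(noise_seed)
  ii <- vector("list", n)
  jj <- vector("list", n)
  xx <- vector("list", n)
  for (d in 0:(n - 1L)) {
    x <- stats::rpois(n - d, mu[[d + 1L]] * scale)
    nz <- which(x > 0L)
    if (length(nz)) {
      ii[[d + 1L]] <- nz
      jj[[d + 1L]] <- nz + d
      xx[[d + 1L]] <- x[nz]
    }
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = as.numeric(unlist(xx)),
    dims = c(n, n), symmetric = TRUE)
  new_contact_matrix(counts, res, cfg$chrom_length)
}

#' Simulate a paired-condition Hi-C experiment with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `mat_a`, `mat_b` (raw `contact_matrix` per
#'   condition) and `truth` (the planted `hic_truth`).
#' @export
simulate_condition_pair <- function(config) {
  truth <- simulate_truth(config)
  list(mat_a = simulate_contacts(truth, "A"),
       mat_b = simulate_contacts(truth, "B"),
       truth = truth)
}
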