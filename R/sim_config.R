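# Simulation configuration: the stated world for the synthetic
# generator (chromosome geometry, decay, compartment/TAD/loop
# modulations, depth, seed).

#' Configuration for the paired-condition Hi-C simulator
#'
#' Defaults encode the world the downstream analysis assumes: 5 kb
#' working resolution, 250 kb compartment blocks, power-law distance
#' decay with exponent 1, and condition-specific loop populations whose
#' size medians mirror the ~700 kb (condition-A-specific) versus
#' ~200 kb (condition-B-specific) contrast between mutant- and
#' wild-type-specific loop sets.
#'
#' @param chrom_length chromosome length, bp.
#' @param resolution bin size, bp; must divide
#'   `compartment_block_size`.
#' @param compartment_block_size compartment block size, bp.
#' @param decay_exponent power-law exponent of the distance decay.
#' @param compartment_strength checkerboard modulation `alpha` in
#'   `[0, 1)`: pixel means are scaled by `1 + alpha * c_i * c_j` with
#'   `c = +/-1` for A/B bins.
#' @param tad_boost fold enrichment of within-TAD pixels (> 0; 1
#'   disables TADs).
#' @param loop_boost fold enrichment `lambda` at planted loop pixels.
#' @param n_loops_common,n_loops_condA_only,n_loops_condB_only planted
#'   loop counts per class.
#' @param loop_size_median_A,loop_size_median_B,loop_size_median_common
#'   median planted loop size (bp) for A-only, B-only and common loops.
#' @param loop_size_sdlog log-normal sdlog of condition-specific
#'   planted loop sizes (kept tight so each class sits near its stated
#'   median).
#' @param loop_size_min smallest planted loop size, bp. Loops shorter
#'   than roughly twice the loop-scoring background window sit in the
#'   near-diagonal zone where local enrichment is not measurable, so
#'   the generator does not plant them by default.
#' @param loop_size_sdlog_common sdlog of the common (background) loop
#'   class; broad by default so the shared loop landscape populates
#'   every separation stratum, as the all-loop size distribution of
#'   real maps does.
#' @param n_switch_a_to_b,n_switch_b_to_a compartment blocks switched
#'   between conditions.
#' @param tad_mean_size mean TAD length, bp.
#' @param tad_min_size smallest TAD length, bp; boundaries are planted
#'   with at least this spacing (real TADs rarely drop below
#'   ~100-200 kb, and insulation cannot resolve domains much smaller
#'   than its window).
#' @param sequencing_depth expected total cis contact count.
#' @param seed master seed; every substream derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(chrom_length = 20e6,
                       resolution = 5000,
                       compartment_block_size = 250000,
                       decay_exponent = 1,
                       compartment_strength = 0.3,
                       tad_boost = 3,
                       loop_boost = 4,
                       n_loops_common = 40L,
                       n_loops_condA_only = 20L,
                       n_loops_condB_only = 20L,
                       loop_size_median_A = 700000,
                       loop_size_median_B = 200000,
                       loop_size_median_common = 200000,
                       loop_size_sdlog = 0.4,
                       loop_size_sdlog_common = 0.8,
                       loop_size_min = 100000,
                       n_switch_a_to_b = 3L,
                       n_switch_b_to_a = 5L,
                       tad_mean_size = 500000,
                       tad_min_size = 200000,
                       sequencing_depth = 2e6,
                       seed = 1L) {
  stop_if_not_scalar_num(chrom_length, "chrom_length")
  stop_if_not_scalar_num(resolution, "resolution")
  stop_if_not_scalar_num(compartment_block_size, "compartment_block_size")
  if (compartment_block_size %% resolution != 0) {
    stop("resolution must divide compartment_block_size", call. = FALSE)
  }
  if (!is.numeric(compartment_strength) || compartment_strength < 0 ||
      compartment_strength >= 1) {
    stop("compartment_strength must lie in [0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_num(tad_boost, "tad_boost")
  stop_if_not_scalar_num(loop_boost, "loop_boost")
  stop_if_not_scalar_num(sequencing_depth, "sequencing_depth")
  for (nm in c("loop_size_median_A", "loop_size_median_B",
               "loop_size_median_common")) {
    val <- get(nm)
    stop_if_not_scalar_num(val, nm)
    if (val >= chrom_length) {
      stop(sprintf("%s exceeds the chromosome length", nm), call. = FALSE)
    }
  }
  structure(list(
    chrom_length = chrom_length, resolution = resolution,
    compartment_block_size = compartment_block_size,
    decay_exponent = decay_exponent,
    compartment_strength = compartment_strength,
    tad_boost = tad_boost, loop_boost = loop_boost,
    n_loops_common = as.integer(n_loops_common),
    n_loops_condA_only = as.integer(n_loops_condA_only),
    n_loops_condB_only = as.integer(n_loops_condB_only),
    loop_size_median_A = loop_size_median_A,
    loop_size_median_B = loop_size_median_B,
    loop_size_median_common = loop_size_median_common,
    loop_size_sdlog = loop_size_sdlog,
    loop_size_sdlog_common = loop_size_sdlog_common,
    loop_size_min = loop_size_min,
    n_switch_a_to_b = as.integer(n_switch_a_to_b),
    n_switch_b_to_a = as.integer(n_switch_b_to_a),
    tad_mean_size = tad_mean_size,
    tad_min_size = tad_min_size,
    sequencing_depth = sequencing_depth,
    seed = as.integer(seed)), class = "sim_config")
}
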