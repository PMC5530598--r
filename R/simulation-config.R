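#' Configuration for the synthetic longitudinal cohort generator
#'
#' Bundles and validates every knob of the simulator. Defaults emulate the
#' sequencing design the pipeline was built for: serial bone-marrow /
#' peripheral-blood samples of low-risk MDS patients followed for years,
#' genotyped by amplicon deep sequencing at roughly 10,000x on top of
#' ~110x whole-exome discovery, with a handful of driver mutations among
#' mostly passenger events.
#'
#' @param seed integer seed; fixing it fixes every emitted byte.
#' @param times sampling times in days, strictly increasing. Default: five
#'   samples over ~5.5 years, inside the 2.5-11 year follow-up range the
#'   generator is meant to emulate.
#' @param depth_targeted mean depth of the targeted amplicon assay
#'   (default 10000 reads).
#' @param depth_wes mean depth of the whole-exome assay (default 110).
#' @param error_rate per-base, per-alternative-allele substitution error
#'   probability (default 5e-4, Ion-Torrent-like).
#' @param n_clones number of clones in the primary tree (>= 1).
#' @param topology one of `"single"`, `"linear"`, `"branching"`, `"random"`.
#' @param p_unrelated probability that one extra, genetically unrelated
#'   root clone is added to the forest.
#' @param n_driver integer range (length-2) of driver mutations per patient;
#'   default 0-6 (cohort median 4).
#' @param n_passenger integer range of passenger mutations; default chosen
#'   so patient totals fall in the 8-27 range (median ~17).
#' @param treatment_windows list of windows, each a list with elements
#'   `start`, `end` (days) and `factor` (suppression multiplier in (0,1]
#'   applied to the primary root's tree inside the window), optionally
#'   `root` (index of the suppressed root, default 1).
#' @param contamination tumour-in-germline fraction (default 0).
#' @param cn_events optional list of copy-number events, each a list with
#'   `clone` (index), `chrom`, `start`, `end`, `cn_total`, `cn_minor`,
#'   `is_cnloh`. `cn_scenario` presets populate this.
#' @param cn_scenario convenience preset: `"none"`, `"del5q"` (hemizygous
#'   5q deletion on the founding clone), `"monosomy7"`, or `"cnloh"`
#'   (telomeric copy-neutral LOH on 4q).
#'
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              times = c(0, 400, 900, 1400, 2000),
                              depth_targeted = 10000,
                              depth_wes = 110,
                              error_rate = 5e-4,
                              n_clones = 3L,
                              topology = c("random", "single", "linear", "branching"),
                              p_unrelated = 0,
                              n_driver = c(0L, 6L),
                              n_passenger = c(8L, 21L),
                              treatment_windows = list(),
                              contamination = 0,
                              cn_events = NULL,
                              cn_scenario = c("none", "del5q", "monosomy7", "cnloh")) {
  topology <- match.arg(topology)
  cn_scenario <- match.arg(cn_scenario)
  if (length(times) < 1 || any(diff(times) <= 0))
    .stop_invalid("`times` must be strictly increasing")
  if (depth_targeted < 1 || depth_wes < 1)
    .stop_invalid("sequencing depths must be >= 1")
  if (error_rate < 0 || error_rate > 1 || p_unrelated < 0 || p_unrelated > 1 ||
      contamination < 0 || contamination > 1)
    .stop_invalid("probabilities must lie in [0, 1]")
  if (n_clones < 1) .stop_invalid("`n_clones` must be >= 1")
  if (topology == "single" && n_clones != 1)
    .stop_invalid("topology 'single' requires n_clones = 1")
  if (topology == "branching" && n_clones < 3)
    .stop_invalid("topology 'branching' requires n_clones >= 3")
  for (w in treatment_windows) {
    if (is.null(w$start) || is.null(w$end) || is.null(w$factor))
      .stop_invalid("each treatment window needs start, end and factor")
    if (w$factor <= 0 || w$factor > 1)
      .stop_invalid("suppression factor must be in (0, 1]")
  }
  if (is.null(cn_events) && cn_scenario != "none") {
    cn_events <- switch(cn_scenario,
      del5q = list(list(clone = 1L, chrom = "5", start = 75e6, end = 170e6,
                        cn_total = 1L, cn_minor = 0L, is_cnloh = FALSE)),
      monosomy7 = list(list(clone = 1L, chrom = "7", start = 0, end = 159e6,
                            cn_total = 1L, cn_minor = 0L, is_cnloh = FALSE)),
      cnloh = list(list(clone = 1L, chrom = "4", start = 120e6, end = 191e6,
                        cn_total = 2L, cn_minor = 0L, is_cnloh = TRUE)))
  }
  structure(list(seed = as.integer(seed), times = as.numeric(times),
                 depth_targeted = depth_targeted, depth_wes = depth_wes,
                 error_rate = error_rate, n_clones = as.integer(n_clones),
                 topology = topology, p_unrelated = p_unrelated,
                 n_driver = as.integer(n_driver),
                 n_passenger = as.integer(n_passenger),
                 treatment_windows = treatment_windows,
                 contamination = contamination, cn_events = cn_events),
            class = "sim_config")
}
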