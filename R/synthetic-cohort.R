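# Ground-truthed synthetic longitudinal patients: clone forests, logistic
# growth trajectories with treatment bottlenecks, deep targeted + exome
# read counts, germline controls and CFU-GEMM colony genotypes.

.CHROM_SIZES <- c(`1` = 249e6, `2` = 243e6, `3` = 198e6, `4` = 191e6,
                  `5` = 181e6, `6` = 171e6, `7` = 159e6, `8` = 146e6,
                  `9` = 141e6, `10` = 136e6, `11` = 135e6, `12` = 134e6,
                  `13` = 115e6, `14` = 107e6, `15` = 103e6, `16` = 90e6,
                  `17` = 81e6, `18` = 78e6, `19` = 59e6, `20` = 63e6,
                  `21` = 48e6, `22` = 51e6, X = 155e6)

# strand-symmetric substitution classes; the first two are transitions.
.SUB_CLASSES <- c("G:C>A:T", "A:T>G:C", "G:C>T:A", "G:C>C:G",
                  "A:T>T:A", "A:T>C:G")
# spectrum the generator emulates: 65% transitions, G:C>A:T predominant
.SUB_PROBS <- c(0.53, 0.12, 0.14, 0.07, 0.07, 0.07)
.CONSEQ_CLASSES <- c("nonsynonymous SNV", "stopgain SNV", "splice site",
                     "frameshift indel", "inframe indel")
.CONSEQ_PROBS <- c(0.82, 0.06, 0.03, 0.065, 0.025)

#' Bundled myeloid driver gene list
#'
#' Genes recurrently mutated in myeloid malignancies, used by the
#' simulator to label driver mutations and by [patient_summary()] as the
#' default driver catalogue.
#'
#' @return character vector of gene symbols.
#' @export
myeloid_driver_genes <- function() {
  readLines(system.file("extdata", "myeloid_genes.txt",
                        package = "cloneforest"))
}

.draw_substitution <- function(n) {
  cls <- sample(.SUB_CLASSES, n, replace = TRUE, prob = .SUB_PROBS)
  # pick the concrete ref base (strand) uniformly within the class
  pairs <- list(`G:C>A:T` = list(c("C", "T"), c("G", "A")),
                `A:T>G:C` = list(c("A", "G"), c("T", "C")),
                `G:C>T:A` = list(c("C", "A"), c("G", "T")),
                `G:C>C:G` = list(c("C", "G"), c("G", "C")),
                `A:T>T:A` = list(c("A", "T"), c("T", "A")),
                `A:T>C:G` = list(c("A", "C"), c("T", "G")))
  t(vapply(cls, function(cl) pairs[[cl]][[sample.int(2, 1)]],
           character(2)))
}

#' Simulate a clone forest with mutations
#'
#' Builds the ground-truth clonal architecture of one patient: a rooted
#' tree of `n_clones` nested clones (shape controlled by
#' `config$topology`) plus, with probability `config$p_unrelated`, one
#' extra genetically unrelated root clone carrying only private
#' mutations. Driver mutations are drawn from the bundled myeloid gene
#' list, passengers get arbitrary labels. Uses the current RNG state;
#' seed it (or use [simulate_patient()]) for reproducibility.
#'
#' @param config a [simulation_config()].
#' @return an object of class `clone_forest`: list with `nodes`
#'   (clone_id, parent_id) and `mutations` (mutation_id, clone_id, chrom,
#'   pos, ref, alt, gene, is_driver, consequence) data.frames.
#' @export
simulate_clone_forest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_clones
  parent <- rep(NA_character_, k)
  ids <- paste0("C", seq_len(k))
  if (config$topology == "linear" && k > 1) {
    parent[2:k] <- ids[1:(k - 1)]
  } else if (config$topology == "branching") {
    parent[2:3] <- ids[1]                         # forced branch at the root
    if (k > 3) parent[4:k] <- ids[sample.int(3, k - 3, replace = TRUE)]
  } else if (config$topology == "random" && k > 1) {
    for (i in 2:k) parent[i] <- ids[sample.int(i - 1, 1)]
  }
  nodes <- data.frame(clone_id = ids, parent_id = parent,
                      stringsAsFactors = FALSE)
  if (stats::runif(1) < config$p_unrelated) {
    nodes <- rbind(nodes, data.frame(clone_id = "U1",
                                     parent_id = NA_character_))
  }
  nodes$cn_event <- NA_integer_
  if (!is.null(config$cn_events)) {
    for (j in seq_along(config$cn_events))
      nodes$cn_event[config$cn_events[[j]]$clone] <- j
  }

  n_drv <- sample(seq(config$n_driver[1], config$n_driver[2]), 1)
  n_pas <- sample(seq(config$n_passenger[1], config$n_passenger[2]), 1)
  n_mut <- max(n_drv + n_pas, nrow(nodes))   # every clone needs >=1 private
  is_driver <- c(rep(TRUE, n_drv), rep(FALSE, n_mut - n_drv))

  # every clone gets one private mutation, the rest land uniformly
  clone_of <- c(nodes$clone_id,
                sample(nodes$clone_id, n_mut - nrow(nodes), replace = TRUE))
  clone_of <- sample(clone_of)    # decouple driver status from clone order

  drv_pool <- myeloid_driver_genes()
  genes <- ifelse(is_driver,
                  sample(drv_pool, n_mut, replace = n_mut > length(drv_pool)),
                  paste0("GENE", seq_len(n_mut)))
  conseq <- sample(.CONSEQ_CLASSES, n_mut, replace = TRUE,
                   prob = .CONSEQ_PROBS)
  chrom <- sample(names(.CHROM_SIZES), n_mut, replace = TRUE)
  pos <- floor(stats::runif(n_mut, 1, .CHROM_SIZES[chrom]))
  refalt <- .draw_substitution(n_mut)
  ref <- refalt[, 1]; alt <- refalt[, 2]
  indel <- grepl("indel", conseq)
  alt[indel & conseq == "frameshift indel"] <-
    paste0(ref[indel & conseq == "frameshift indel"], "A")
  alt[indel & conseq == "inframe indel"] <-
    paste0(ref[indel & conseq == "inframe indel"], "AGG")

  # pin one mutation of each CN-event clone inside its segment so the
  # copy-number correction is actually exercised
  if (!is.null(config$cn_events)) {
    for (j in seq_along(config$cn_events)) {
      ev <- config$cn_events[[j]]
      cand <- which(clone_of == nodes$clone_id[ev$clone])
      if (length(cand)) {
        i <- cand[1]
        chrom[i] <- ev$chrom
        pos[i] <- floor((ev$start + ev$end) / 2)
      }
    }
  }

  mutations <- data.frame(
    mutation_id = sprintf("M%02d", seq_len(n_mut)),
    clone_id = clone_of, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = genes, is_driver = is_driver, consequence = conseq,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, mutations = mutations),
            class = "clone_forest")
}

.forest_roots <- function(nodes) nodes$clone_id[is.na(nodes$parent_id)]

.forest_children <- function(nodes, id) nodes$clone_id[
  !is.na(nodes$parent_id) & nodes$parent_id == id]

# clone ids on the path from the root down to (and including) `id`
.root_path <- function(nodes, id) {
  path <- id
  while (!is.na(nodes$parent_id[nodes$clone_id == id])) {
    id <- nodes$parent_id[nodes$clone_id == id]
    path <- c(id, path)
  }
  path
}

#' Simulate clone CCF trajectories
#'
#' Growth follows a competitive replacement model. Each clone carries a
#' fitness weight `w_i(t) = exp(r_i (t - t0_i))` (exponential expansion
#' from its emergence midpoint `t0_i`); within every sibling group
#' (clones sharing a parent, or the set of roots) the fraction of the
#' parent occupied by clone i is
#' \deqn{f_i(t) = L_i\, w_i(t) / (1 + \sum_j w_j(t))}
#' with plateau `L_i < 1`. A lone clone follows an ordinary logistic
#' curve; competing siblings displace each other, with later-emerging
#' siblings assigned the larger growth rates — a clone observed rising
#' against an established sibling must carry a fitness advantage, which
#' is what produces the clonal replacement seen in serial MDS samples.
#' Sibling fractions sum below 1 by construction, so the nesting
#' constraints hold exactly once CCFs are composed top-down. Inside each
#' treatment window the whole tree of the designated root is multiplied
#' by the window's suppression factor, emulating a therapy bottleneck
#' through which genetically unrelated clones can expand.
#'
#' @param forest a `clone_forest`.
#' @param config a [simulation_config()].
#' @return object of class `trajectory_set`: list with `ccf` (clone x
#'   timepoint matrix) and `times`.
#' @export
simulate_trajectories <- function(forest, config) {
  nodes <- forest$nodes
  times <- config$times
  n <- nrow(nodes)
  ids <- nodes$clone_id
  roots <- .forest_roots(nodes)
  t_range <- diff(range(times)) + 1

  cap <- stats::runif(n, 0.45, 0.95)
  rate <- stats::runif(n, 0.004, 0.015)
  mid <- numeric(n); names(mid) <- ids; names(rate) <- ids
  for (i in seq_len(n)) {
    p <- nodes$parent_id[i]
    if (is.na(p)) {
      mid[i] <- stats::runif(1, min(times) - t_range / 2, min(times))
    } else {
      mid[i] <- mid[p] + stats::runif(1, 150, 700)
    }
  }
  # Competing lineages (siblings within a tree, or an unrelated root
  # against the established clone) exchange dominance at a crossover
  # time inside the observation window: a clone observed rising against
  # an established competitor must be fitter, and the study's divergent
  # subclones visibly traded places within the sampled follow-up
  groups <- c(list(roots), lapply(ids, .forest_children, nodes = nodes))
  for (g in groups) {
    if (length(g) < 2) next
    g <- g[order(mid[g])]
    for (j in 2:length(g)) {
      prev <- g[j - 1]
      # at least one sample lies beyond the crossover, so the exchange
      # of dominance is actually observed
      t_last_but_one <- if (length(times) > 1)
        times[length(times) - 1] else max(times)
      t_cross <- stats::runif(1, stats::quantile(times, 0.25),
                              t_last_but_one)
      rate[g[j]] <- min(rate[prev] * stats::runif(1, 1.5, 3), 0.02)
      mid[g[j]] <- t_cross - (rate[prev] / rate[g[j]]) *
        (t_cross - mid[prev])
    }
  }

  # fraction-within-parent by sibling group, with competitive
  # displacement
  frac <- matrix(0, n, length(times), dimnames = list(ids, NULL))
  for (g in groups) {
    if (length(g) < 1) next
    w <- sapply(times, function(t)
      pmin(exp(rate[g] * (t - mid[g])), 1e20))
    w <- matrix(w, nrow = length(g))
    frac[g, ] <- cap[match(g, ids)] * w /
      rep(1 + colSums(w), each = length(g))
  }

  # top-down CCF: root ccf = fraction of all cells; child = frac * parent
  ccf <- matrix(0, n, length(times), dimnames = list(ids, NULL))
  order_td <- .topological_order(nodes)
  for (id in order_td) {
    p <- nodes$parent_id[nodes$clone_id == id]
    ccf[id, ] <- if (is.na(p)) frac[id, ] else frac[id, ] * ccf[p, ]
  }

  for (w in config$treatment_windows) {
    root <- roots[if (is.null(w$root)) 1 else w$root]
    tree <- ids[vapply(ids, function(i) root %in% .root_path(nodes, i),
                       logical(1))]
    in_win <- times >= w$start & times <= w$end
    ccf[tree, in_win] <- pmax(ccf[tree, in_win, drop = FALSE] * w$factor, 0)
  }
  structure(list(ccf = ccf, times = times), class = "trajectory_set")
}

.topological_order <- function(nodes) {
  ord <- character(0)
  todo <- .forest_roots(nodes)
  while (length(todo)) {
    id <- todo[1]; todo <- todo[-1]
    ord <- c(ord, id)
    todo <- c(todo, .forest_children(nodes, id))
  }
  ord
}

#' Simulate read counts for expected VAFs
#'
#' Depth is Poisson around the assay mean; the variant-read count is
#' binomial at `vaf + error_rate * (1 - vaf)`; the two remaining
#' (non-reference, non-variant) bases each receive binomial counts at
#' `error_rate`, so the second-highest-base rule of the deep-sequencing
#' caller can be applied to simulated data.
#'
#' @param vafs vector of expected VAFs in [0, 1].
#' @param mean_depth mean sequencing depth.
#' @param error_rate per-base, per-alternative-allele error probability.
#' @return data.frame with `depth`, `alt_count`, `err1_count`,
#'   `err2_count`, `ref_count` (one row per element of `vafs`).
#' @export
simulate_read_counts <- function(vafs, mean_depth, error_rate = 5e-4) {
  if (any(vafs < 0 | vafs > 1)) .stop_invalid("vafs must lie in [0, 1]")
  n <- length(vafs)
  depth <- pmax(stats::rpois(n, mean_depth), 1L)
  alt <- stats::rbinom(n, depth, vafs + error_rate * (1 - vafs))
  e1 <- stats::rbinom(n, depth, error_rate)
  e2 <- stats::rbinom(n, depth, error_rate)
  ref <- pmax(depth - alt - e1 - e2, 0L)
  data.frame(depth = depth, alt_count = alt, err1_count = e1,
             err2_count = e2, ref_count = ref)
}

#' Simulate single-cell-derived (CFU-GEMM) colony VAFs
#'
#' Each colony is founded by one cell drawn in proportion to the
#' exclusive clone fractions at the chosen timepoint (residual normal
#' cells can found mutation-free colonies). Mutations carried by the
#' founder (those of the clones on its root path) are heterozygous, so
#' their per-colony VAF is Binomial(200, 0.5)/200; all other mutations
#' see only sequencing error. With probability `p_mixed` two founders are
#' blended 50:50, producing the intermediate VAFs that the >40% / <5%
#' genotyping rule is designed to reject.
#'
#' @param forest a `clone_forest`.
#' @param trajectories a `trajectory_set`.
#' @param timepoint index into `trajectories$times` (default: last).
#' @param n_colonies number of colonies (>= 1).
#' @param p_mixed probability a colony is a 50:50 doublet.
#' @param error_rate sequencing error probability.
#' @param colony_depth per-mutation read depth in a colony (default 200).
#' @return long data.frame: `colony_id`, `mutation_id`, `vaf`, plus the
#'   true `founder` clone id(s) for ground truth.
#' @export
simulate_colonies <- function(forest, trajectories, timepoint = NULL,
                              n_colonies = 30, p_mixed = 0,
                              error_rate = 5e-4, colony_depth = 200) {
  if (n_colonies < 1) .stop_invalid("n_colonies must be >= 1")
  if (is.null(timepoint)) timepoint <- length(trajectories$times)
  nodes <- forest$nodes
  ccf_t <- trajectories$ccf[, timepoint]
  excl <- vapply(nodes$clone_id, function(id) {
    kids <- .forest_children(nodes, id)
    max(ccf_t[id] - sum(ccf_t[kids]), 0)
  }, numeric(1))
  normal <- max(1 - sum(ccf_t[.forest_roots(nodes)]), 0)
  pool <- c(excl, normal = normal)
  muts <- forest$mutations
  path_mut <- function(founder) {
    if (founder == "normal") return(rep(FALSE, nrow(muts)))
    muts$clone_id %in% .root_path(nodes, founder)
  }
  out <- vector("list", n_colonies)
  for (i in seq_len(n_colonies)) {
    n_found <- if (stats::runif(1) < p_mixed) 2 else 1
    founders <- sample(names(pool), n_found, replace = TRUE, prob = pool)
    carrier <- Reduce(`+`, lapply(founders, path_mut)) / n_found
    p <- 0.5 * carrier
    p <- p + error_rate * (1 - p)
    vaf <- stats::rbinom(nrow(muts), colony_depth, p) / colony_depth
    out[[i]] <- data.frame(colony_id = sprintf("col%03d", i),
                           mutation_id = muts$mutation_id, vaf = vaf,
                           founder = paste(founders, collapse = "+"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate one complete longitudinal patient
#'
#' End-to-end generator: clone forest, trajectories (optionally redrawn
#' until every clone pair is separated by at least `min_separation` CCF
#' in some sample — the regime in which trajectory clustering is
#' identifiable), expected VAFs under each mutation's copy-number state,
#' read counts for each serial tumour sample and a germline control, the
#' sample sheet, copy-number segments and (optionally) colonies.
#'
#' @param config a [simulation_config()].
#' @param patient_id label written into all tables.
#' @param n_colonies colonies to simulate at the last timepoint (0 = none).
#' @param min_separation minimum pairwise clone CCF separation; the
#'   trajectory draw is rejected (up to 100 times) until satisfied.
#' @return an object of class `patient_bundle`: list with `patient_id`,
#'   `config`, `forest`, `trajectories`, `counts`, `samples`, `segments`,
#'   `colonies`, `truth`.
#' @export
simulate_patient <- function(config, patient_id = "P1", n_colonies = 0,
                             min_separation = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  forest <- simulate_clone_forest(config)
  traj <- simulate_trajectories(forest, config)
  tries <- 1
  while (min_separation > 0 && !.separated(traj$ccf, min_separation) &&
         tries < 100) {
    traj <- simulate_trajectories(forest, config)
    tries <- tries + 1
  }

  segments <- .segments_from_events(config$cn_events)
  times <- config$times
  sids <- sprintf("S%02d", seq_along(times))
  samples <- data.frame(
    patient = patient_id,
    sample_id = c(sids, "GL"),
    tissue = c(rep("BM", length(times)), "T_cells"),
    time_days = c(times, times[1]),
    platform = "amplicon",
    treatment_label = vapply(c(times, times[1]), function(t) {
      for (w in config$treatment_windows)
        if (t >= w$start && t <= w$end) return("on_treatment")
      "none"
    }, character(1)),
    stringsAsFactors = FALSE)

  muts <- forest$mutations
  states <- lapply(seq_len(nrow(muts)), function(i)
    assign_cn_state(muts$chrom[i], muts$pos[i], segments, sex = "female"))
  names(states) <- muts$mutation_id

  counts <- NULL
  for (j in seq_along(times)) {
    vafs <- vapply(seq_len(nrow(muts)), function(i)
      expected_vaf(traj$ccf[muts$clone_id[i], j], states[[i]]), numeric(1))
    rc <- simulate_read_counts(vafs, config$depth_targeted,
                               config$error_rate)
    counts <- rbind(counts, data.frame(
      patient = patient_id, sample_id = sids[j],
      mutation_id = muts$mutation_id, chrom = muts$chrom, pos = muts$pos,
      ref = muts$ref, alt = muts$alt, alt_count = rc$alt_count,
      depth = rc$depth, err1_count = rc$err1_count,
      err2_count = rc$err2_count, consequence = muts$consequence,
      gene = muts$gene, stringsAsFactors = FALSE))
  }
  gl_vaf <- config$contamination *
    vapply(seq_len(nrow(muts)), function(i)
      expected_vaf(traj$ccf[muts$clone_id[i], 1], states[[i]]), numeric(1))
  rc <- simulate_read_counts(gl_vaf, config$depth_targeted,
                             config$error_rate)
  counts <- rbind(counts, data.frame(
    patient = patient_id, sample_id = "GL",
    mutation_id = muts$mutation_id, chrom = muts$chrom, pos = muts$pos,
    ref = muts$ref, alt = muts$alt, alt_count = rc$alt_count,
    depth = rc$depth, err1_count = rc$err1_count,
    err2_count = rc$err2_count, consequence = muts$consequence,
    gene = muts$gene, stringsAsFactors = FALSE))

  colonies <- NULL
  if (n_colonies > 0) {
    # sample colonies where the root populations coexist best (the
    # sample an investigator would pick to genotype a rising clone
    # against the residual disease); with one root this is simply the
    # sample with the largest tumour load
    root_ccf <- traj$ccf[.forest_roots(forest$nodes), , drop = FALSE]
    tp <- which.max(apply(root_ccf, 2, min))
    cols <- simulate_colonies(forest, traj, timepoint = tp,
                              n_colonies = n_colonies,
                              error_rate = config$error_rate)
    colonies <- data.frame(patient = patient_id,
                           time_days = times[tp],
                           cols, stringsAsFactors = FALSE)
  }

  truth <- list(
    clones = forest$nodes$clone_id,
    parents = forest$nodes$parent_id,
    mutation_clone = stats::setNames(muts$clone_id, muts$mutation_id),
    ccf = traj$ccf, times = times)
  structure(list(patient_id = patient_id, config = config, forest = forest,
                 trajectories = traj, counts = counts, samples = samples,
                 segments = segments, colonies = colonies, truth = truth),
            class = "patient_bundle")
}

.separated <- function(ccf, min_sep) {
  k <- nrow(ccf)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (max(abs(ccf[i, ] - ccf[j, ])) < min_sep) return(FALSE)
  TRUE
}

.segments_from_events <- function(events) {
  if (is.null(events) || !length(events)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cn_total = integer(),
                      cn_minor = integer(), is_cnloh = logical(),
                      reaches_telomere = logical(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(events, function(ev) data.frame(
    chrom = ev$chrom, start = ev$start, end = ev$end,
    cn_total = ev$cn_total, cn_minor = ev$cn_minor,
    is_cnloh = isTRUE(ev$is_cnloh),
    reaches_telomere = ev$end >= .CHROM_SIZES[[ev$chrom]] - 1e6 ||
      ev$start <= 1e6,
    genes = "", stringsAsFactors = FALSE)))
}

#' Write a simulated patient bundle to disk
#'
#' Emits plain-text files: `counts.tsv` (long read-count table),
#' `samples.tsv` (sample sheet), `segments.tsv` (copy-number segments,
#' 0-based half-open), `colonies.tsv` (when simulated) and `truth.json`
#' (forest, trajectories and mutation-to-clone assignment).
#' [read_cohort()] restores the tables losslessly.
#'
#' @param bundle a `patient_bundle` from [simulate_patient()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "patient_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             segments = file.path(out_dir, "segments.tsv"),
             truth = file.path(out_dir, "truth.json"))
  .write_tsv(bundle$counts, paths["counts"])
  .write_tsv(bundle$samples, paths["samples"])
  .write_tsv(bundle$segments, paths["segments"])
  if (!is.null(bundle$colonies)) {
    paths["colonies"] <- file.path(out_dir, "colonies.tsv")
    .write_tsv(bundle$colonies, paths["colonies"])
  }
  truth <- bundle$truth
  truth$ccf <- as.data.frame(truth$ccf)
  truth$mutation_clone <- as.list(truth$mutation_clone)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a patient bundle written by [write_cohort()]
#'
#' @param dir directory holding the cohort files.
#' @return list with `counts`, `samples`, `segments`, `colonies` (NULL if
#'   absent) and `truth`.
#' @export
read_cohort <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$ccf <- as.matrix(truth$ccf)
  rownames(truth$ccf) <- truth$clones
  truth$mutation_clone <- unlist(truth$mutation_clone)
  colonies_path <- file.path(dir, "colonies.tsv")
  list(counts = .read_tsv(file.path(dir, "counts.tsv")),
       samples = .read_tsv(file.path(dir, "samples.tsv")),
       segments = .read_tsv(file.path(dir, "segments.tsv")),
       colonies = if (file.exists(colonies_path)) .read_tsv(colonies_path),
       truth = truth)
}
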