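# Cohort-level summaries: mutation spectrum, transition/transversion
# classes, early-vs-late therapy comparison, age correlation, per-patient
# mutation counts and deterministic file export of a reconstruction.

.TRANSITION_CLASSES <- c("G:C>A:T", "A:T>G:C")

.substitution_class <- function(ref, alt) {
  key <- paste0(ref, ">", alt)
  map <- c(`C>T` = "G:C>A:T", `G>A` = "G:C>A:T",
           `A>G` = "A:T>G:C", `T>C` = "A:T>G:C",
           `C>A` = "G:C>T:A", `G>T` = "G:C>T:A",
           `C>G` = "G:C>C:G", `G>C` = "G:C>C:G",
           `A>T` = "A:T>T:A", `T>A` = "A:T>T:A",
           `A>C` = "A:T>C:G", `T>G` = "A:T>C:G")
  out <- map[key]
  if (anyNA(out)) .stop_invalid("non-ACGT substitution encountered")
  unname(out)
}

#' Mutation spectrum summary
#'
#' Counts alterations by consequence class and, for single-nucleotide
#' variants, by the six strand-symmetric substitution classes (C>T and
#' G>A both count as G:C>A:T, etc.); transitions are G:C>A:T and
#' A:T>G:C. Every mutation is counted exactly once.
#'
#' @param mutations data.frame with `ref`, `alt`, `consequence`.
#' @return object of class `spectrum_summary`: list with
#'   `consequence_counts`, `substitution_counts`, `n_snv`,
#'   `n_transitions`, `n_transversions`, `transition_fraction`.
#' @export
mutation_spectrum <- function(mutations) {
  conseq <- table(mutations$consequence)
  is_snv <- nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1
  snv <- mutations[is_snv, , drop = FALSE]
  if (nrow(snv) > 0 &&
      !all(c(snv$ref, snv$alt) %in% c("A", "C", "G", "T")))
    .stop_invalid("non-ACGT base in an SNV")
  cls <- if (nrow(snv)) .substitution_class(snv$ref, snv$alt) else character()
  sub_counts <- table(factor(cls, levels = c(.TRANSITION_CLASSES,
                                             "G:C>T:A", "G:C>C:G",
                                             "A:T>T:A", "A:T>C:G")))
  n_ti <- sum(sub_counts[.TRANSITION_CLASSES])
  structure(list(consequence_counts = conseq,
                 substitution_counts = sub_counts,
                 n_snv = nrow(snv), n_transitions = n_ti,
                 n_transversions = nrow(snv) - n_ti,
                 transition_fraction =
                   if (nrow(snv)) n_ti / nrow(snv) else NA_real_),
            class = "spectrum_summary")
}

#' Early vs late mutation spectrum within a treatment group
#'
#' Splits mutations into those present at the first sample (early) and
#' those arising later, summarises each stratum's transition /
#' transversion composition, and reports a two-sided Fisher exact
#' comparison of the transition fractions. Purely descriptive: no
#' decision threshold is applied.
#'
#' @param mutations data.frame with `ref`, `alt`, `consequence` and a
#'   logical column `early`.
#' @return list with `early`, `late` ([mutation_spectrum()] objects or
#'   NULL for an empty stratum), `p_value` (NA when a stratum is empty)
#'   and `note`.
#' @export
early_late_spectrum <- function(mutations) {
  stopifnot("early" %in% names(mutations))
  strat <- split(mutations, mutations$early)
  early <- strat[["TRUE"]]; late <- strat[["FALSE"]]
  spec_e <- if (!is.null(early)) mutation_spectrum(early)
  spec_l <- if (!is.null(late)) mutation_spectrum(late)
  if (is.null(spec_e) || is.null(spec_l) ||
      spec_e$n_snv == 0 || spec_l$n_snv == 0) {
    return(list(early = spec_e, late = spec_l, p_value = NA_real_,
                note = "empty stratum: comparison undefined"))
  }
  tab <- matrix(c(spec_e$n_transitions, spec_e$n_transversions,
                  spec_l$n_transitions, spec_l$n_transversions), 2)
  list(early = spec_e, late = spec_l,
       p_value = stats::fisher.test(tab)$p.value, note = "")
}

#' Pearson correlation between patient age and genetic defect count
#'
#' Pearson's r with a two-tailed p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom,
#' quantifying the accumulation of somatic alterations with age.
#'
#' @param age,defects numeric vectors, one value per patient (n >= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
age_defect_correlation <- function(age, defects) {
  stopifnot(length(age) == length(defects))
  if (length(age) < 3) .stop_invalid("need at least 3 patients")
  if (stats::sd(age) == 0 || stats::sd(defects) == 0)
    .stop_invalid("zero variance: correlation undefined")
  ct <- stats::cor.test(age, defects, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(age))
}

#' Per-patient and cohort mutation counts
#'
#' @param mutations data.frame with `patient`, `mutation_id`, `gene`
#'   (one row per distinct mutation per patient).
#' @param driver_genes character vector; defaults to the bundled myeloid
#'   list.
#' @return list with `per_patient` (data.frame `patient`, `n_mutations`,
#'   `n_driver`) and cohort `median`/`range` for both counts.
#' @export
patient_summary <- function(mutations, driver_genes = NULL) {
  if (is.null(driver_genes)) driver_genes <- myeloid_driver_genes()
  per <- do.call(rbind, lapply(split(mutations, mutations$patient),
    function(df) data.frame(
      patient = df$patient[1],
      n_mutations = length(unique(df$mutation_id)),
      n_driver = length(unique(df$mutation_id[df$gene %in% driver_genes])),
      stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  list(per_patient = per,
       median_mutations = stats::median(per$n_mutations),
       range_mutations = range(per$n_mutations),
       median_drivers = stats::median(per$n_driver),
       range_drivers = range(per$n_driver))
}

#' Export a clonal reconstruction to plain-text files
#'
#' Writes, deterministically byte-for-byte: `clusters.tsv` (mutation ->
#' cluster assignment), `clone_fractions.tsv` (fishplot-ready long
#' table: clone, parent, time, fraction), and `forest.json` (parent
#' vector, score, admissibility, violations, pattern, unrelated roots).
#'
#' @param reconstruction a `clone_reconstruction`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
export_outputs <- function(reconstruction, out_dir) {
  stopifnot(inherits(reconstruction, "clone_reconstruction"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clusters = file.path(out_dir, "clusters.tsv"),
             fractions = file.path(out_dir, "clone_fractions.tsv"),
             forest = file.path(out_dir, "forest.json"))
  asg <- reconstruction$clusters$assignment
  .write_tsv(data.frame(mutation_id = names(asg), cluster = unname(asg)),
             paths["clusters"])

  est <- reconstruction$estimate
  frac <- reconstruction$fractions
  times <- reconstruction$samples$time_days
  k <- length(est$parent)
  long <- do.call(rbind, lapply(seq_len(nrow(frac)), function(i) {
    data.frame(clone = rownames(frac)[i],
               parent = if (i > k) NA_character_
                        else if (est$parent[i] == 0L) "root"
                        else rownames(frac)[est$parent[i]],
               time_days = times, fraction = frac[i, ],
               stringsAsFactors = FALSE)
  }))
  .write_tsv(long, paths["fractions"])

  jsonlite::write_json(
    list(parent = est$parent, score = est$score,
         admissible = est$admissible, n_admissible = est$n_admissible,
         violations = est$violations, pattern = reconstruction$pattern,
         unrelated = reconstruction$unrelated),
    paths["forest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
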