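# Somatic variant filtering: tumour-vs-germline Fisher test, WES candidate
# filter, deep-sequencing caller with the second-highest-base rule,
# validation rule, FISH cutoff and SNP-array segment filtering.

#' One-sided Fisher's exact test for tumour enrichment
#'
#' Exact hypergeometric tail probability that the tumour alternative-read
#' fraction is at least as extreme as observed, under independence of the
#' 2x2 table (tumour alt/ref vs control alt/ref). One-sided in the
#' tumour-enriched direction by default, because a somatic call requires
#' the variant fraction to be significantly higher in tumour than in the
#' germline control; a two-sided option is exposed but is not the
#' filtering default.
#'
#' @param alt_t,ref_t alt/ref read counts in the tumour sample.
#' @param alt_c,ref_c alt/ref read counts in the control sample.
#' @param alternative `"greater"` (tumour-enriched, default) or
#'   `"two.sided"`.
#' @return the p-value.
#' @export
fisher_exact_one_sided <- function(alt_t, ref_t, alt_c, ref_c,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(alt_t, ref_t, alt_c, ref_c)
  if (any(counts < 0)) .stop_invalid("read counts must be >= 0")
  n_t <- alt_t + ref_t
  n_c <- alt_c + ref_c
  if (n_t == 0 || n_c == 0)
    .stop_invalid("undefined test: a sample has zero depth")
  k <- alt_t + alt_c
  if (alternative == "greater") {
    # P(X >= alt_t), X ~ Hypergeometric(n_t draws from k alt, n_c+n_t-k ref)
    return(stats::phyper(alt_t - 1, k, n_t + n_c - k, n_t,
                         lower.tail = FALSE))
  }
  # two-sided: sum of all table probabilities <= that of the observed table
  x <- max(0, k - n_c):min(k, n_t)
  p_all <- stats::dhyper(x, k, n_t + n_c - k, n_t)
  p_obs <- stats::dhyper(alt_t, k, n_t + n_c - k, n_t)
  min(sum(p_all[p_all <= p_obs * (1 + 1e-7)]), 1)
}

#' Whole-exome candidate mutation filter
#'
#' Applies, per candidate variant, the full WES selection rule: one-sided
#' Fisher's exact p <= 0.001 against the paired germline control, tumour
#' VAF >= 0.07 (in at least one tumour sample when several are given),
#' not a synonymous SNV, not listed in any supplied SNP database, and not
#' in a gene flagged as lacking a complete open-reading-frame annotation.
#' Each decision records the first rule that failed.
#'
#' @param records long data.frame of tumour read counts with columns
#'   `mutation_id`, `sample_id`, `alt_count`, `depth`, `consequence`,
#'   `gene`, plus variant key columns `chrom`, `pos`, `ref`, `alt` for
#'   SNP-list lookup.
#' @param germline data.frame with one row per mutation: `mutation_id`,
#'   `alt_count`, `depth` in the germline control.
#' @param snp_dbs optional list of data.frames, each with columns `chrom`,
#'   `pos`, `ref`, `alt`, identifying known germline SNPs.
#' @param incomplete_orf_genes character vector of gene symbols whose
#'   annotation is incomplete.
#' @param p_max,vaf_min thresholds (defaults 0.001 and 0.07).
#' @param vaf_scope `"any_sample"` (default: the VAF floor must be met in
#'   at least one tumour sample) or `"per_sample"`.
#' @return data.frame of decisions: `mutation_id`, `passed`, `rule`
#'   (first failing rule or `"pass"`), `p_value`, `max_vaf`.
#' @export
wes_candidate_filter <- function(records, germline, snp_dbs = list(),
                                 incomplete_orf_genes = character(),
                                 p_max = 0.001, vaf_min = 0.07,
                                 vaf_scope = c("any_sample", "per_sample")) {
  vaf_scope <- match.arg(vaf_scope)
  muts <- unique(records$mutation_id)
  missing_gl <- setdiff(muts, germline$mutation_id)
  if (length(missing_gl))
    .stop_invalid(paste("no paired germline record for:",
                        paste(missing_gl, collapse = ", ")))
  out <- lapply(muts, function(mu) {
    rec <- records[records$mutation_id == mu, ]
    gl <- germline[germline$mutation_id == mu, ][1, ]
    vafs <- rec$alt_count / rec$depth
    p <- min(vapply(seq_len(nrow(rec)), function(i)
      fisher_exact_one_sided(rec$alt_count[i],
                             rec$depth[i] - rec$alt_count[i],
                             gl$alt_count, gl$depth - gl$alt_count),
      numeric(1)))
    vaf_ok <- if (vaf_scope == "any_sample") max(vafs) >= vaf_min
              else all(vafs >= vaf_min)
    in_snp_db <- any(vapply(snp_dbs, function(db) {
      any(db$chrom == rec$chrom[1] & db$pos == rec$pos[1] &
          db$ref == rec$ref[1] & db$alt == rec$alt[1])
    }, logical(1)))
    rule <- if (p > p_max) "fisher_p"
      else if (!vaf_ok) "vaf_floor"
      else if (grepl("^synonymous", rec$consequence[1])) "synonymous"
      else if (in_snp_db) "snp_database"
      else if (rec$gene[1] %in% incomplete_orf_genes) "incomplete_orf"
      else "pass"
    data.frame(mutation_id = mu, passed = rule == "pass", rule = rule,
               p_value = p, max_vaf = max(vafs), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Deep-sequencing caller: VAF cutoff plus second-highest-base rule
#'
#' A variant is called at a position when its VAF is at least 0.2% (at
#' 10,000x: at least 20 variant reads) AND the variant base count ranks
#' at least second among the four base counts (the reference being
#' highest). The ranking requirement guards against noisy sequence
#' contexts where several error bases exceed the nominal cutoff. A tie
#' between the variant and another non-reference base still ranks as
#' second-highest (the call is allowed, and flagged as a tie); a variant
#' count exceeding the reference count trivially satisfies the rule.
#'
#' @param base_counts named numeric vector of length 4 with names
#'   `A`, `C`, `G`, `T`: read counts per base at the position.
#' @param ref_base,alt_base single bases; must differ.
#' @param vaf_cutoff default 0.002.
#' @return list with `called`, `vaf`, `tie` (alt tied with another
#'   non-reference base) and `rule` (`"pass"`, `"vaf_below_cutoff"` or
#'   `"not_second_highest"`).
#' @export
deep_seq_call <- function(base_counts, ref_base, alt_base,
                          vaf_cutoff = 0.002) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(base_counts)))
  if (ref_base == alt_base)
    .stop_invalid("alt base equals the reference base")
  depth <- sum(base_counts)
  if (depth <= 0) .stop_invalid("depth must be > 0")
  alt_n <- base_counts[[alt_base]]
  vaf <- alt_n / depth
  others <- base_counts[setdiff(names(base_counts),
                                c(ref_base, alt_base))]
  second_ok <- alt_n >= max(others)
  tie <- second_ok && alt_n == max(others)
  rule <- if (vaf < vaf_cutoff) "vaf_below_cutoff"
    else if (!second_ok) "not_second_highest"
    else "pass"
  list(called = rule == "pass", vaf = vaf, tie = tie, rule = rule)
}

#' Validation rule for targeted deep sequencing
#'
#' A candidate mutation is validated when its VAF in the tumour sample
#' exceeds the germline VAF by at least 5 percentage points.
#'
#' @param tumour_vaf,germline_vaf VAFs in [0, 1] (vectorised).
#' @param min_difference default 0.05.
#' @return logical vector.
#' @export
validate_mutation <- function(tumour_vaf, germline_vaf,
                              min_difference = 0.05) {
  if (any(c(tumour_vaf, germline_vaf) < 0 | c(tumour_vaf, germline_vaf) > 1))
    .stop_invalid("VAFs must lie in [0, 1]")
  # tolerate floating-point representation at the inclusive boundary
  tumour_vaf - germline_vaf >= min_difference - 1e-12
}

#' FISH positivity cutoff from control hybridisations
#'
#' Cutoff level for scoring interphase FISH gains/losses: the mean plus
#' three sample standard deviations of the false-positive nucleus
#' fractions observed in control tissue.
#'
#' @param control_fractions numeric vector (>= 2 values) of false-positive
#'   fractions from control hybridisations.
#' @return the cutoff fraction.
#' @export
fish_cutoff <- function(control_fractions) {
  if (length(control_fractions) < 2)
    .stop_invalid("need >= 2 control values to estimate a cutoff")
  mean(control_fractions) + 3 * stats::sd(control_fractions)
}

#' Filter SNP-array copy-number segments
#'
#' Keeps a copy-number aberration when it is larger than 5 Mb (the
#' resolution of conventional karyotyping, kept regardless of gene
#' content) or when a smaller segment coincides with a known cancer
#' gene. Copy-neutral LOH segments are kept only when larger than 10 Mb
#' and extending to a telomere. Segments matching known normal genomic
#' variants, and focal aberrations in the immunoglobulin / T-cell
#' receptor loci (rearrangement artefacts of the lymphocyte reference),
#' are excluded. Idempotent and order-independent.
#'
#' @param segments data.frame: `chrom`, `start`, `end` (0-based
#'   half-open, bp), `cn_total`, `cn_minor`, `is_cnloh`,
#'   `reaches_telomere`, `genes` (comma-separated labels, may be "").
#' @param cancer_genes character vector of cancer gene symbols.
#' @param normal_variant_db optional data.frame of regions (`chrom`,
#'   `start`, `end`) of known normal copy-number variants; a segment is
#'   dropped when >= 50% of it is covered by one such region.
#' @param ig_tcr_genes gene labels of the immunoglobulin / T-cell
#'   receptor loci; defaults to the bundled list.
#' @param min_cna_mb,min_cnloh_mb size thresholds in Mb (defaults 5, 10).
#' @return the kept rows of `segments`.
#' @export
filter_cna_segments <- function(segments, cancer_genes = character(),
                                normal_variant_db = NULL,
                                ig_tcr_genes = NULL,
                                min_cna_mb = 5, min_cnloh_mb = 10) {
  if (nrow(segments) == 0) return(segments)
  if (any(segments$start >= segments$end))
    .stop_invalid("malformed segment: start must be < end")
  if (is.null(ig_tcr_genes))
    ig_tcr_genes <- readLines(system.file("extdata", "ig_tcr_genes.txt",
                                          package = "cloneforest"))
  len_mb <- (segments$end - segments$start) / 1e6
  seg_genes <- strsplit(ifelse(is.na(segments$genes), "", segments$genes),
                        ",", fixed = TRUE)
  has_cancer_gene <- vapply(seg_genes, function(g)
    any(trimws(g) %in% cancer_genes), logical(1))
  is_ig_tcr <- vapply(seg_genes, function(g)
    any(trimws(g) %in% ig_tcr_genes), logical(1))

  keep <- ifelse(segments$is_cnloh,
                 len_mb > min_cnloh_mb & segments$reaches_telomere,
                 len_mb > min_cna_mb | has_cancer_gene)
  keep <- keep & !is_ig_tcr
  if (!is.null(normal_variant_db) && nrow(normal_variant_db) > 0) {
    in_db <- vapply(seq_len(nrow(segments)), function(i) {
      s <- segments[i, ]
      db <- normal_variant_db[normal_variant_db$chrom == s$chrom, ]
      if (nrow(db) == 0) return(FALSE)
      ov <- pmin(db$end, s$end) - pmax(db$start, s$start)
      any(ov >= 0.5 * (s$end - s$start))
    }, logical(1))
    keep <- keep & !in_db
  }
  segments[keep, , drop = FALSE]
}
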