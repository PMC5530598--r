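#' Copy-number state of a mutated locus
#'
#' Captures everything needed to convert a variant allele frequency (VAF)
#' into a cancer cell fraction (CCF): the tumour total copy number at the
#' locus, the number of copies carrying the mutation (multiplicity), and
#' the ploidy of the locus in normal cells (1 on the male X/Y, 2
#' elsewhere).
#'
#' @param cn_total tumour total copy number (integer >= 0).
#' @param multiplicity copies carrying the mutation (integer >= 1, and at
#'   most `max(cn_total, 1)`).
#' @param normal_ploidy 1 or 2.
#' @return an object of class `cn_state`.
#' @export
copy_number_state <- function(cn_total = 2L, multiplicity = 1L,
                              normal_ploidy = 2L) {
  if (cn_total < 0) .stop_invalid("cn_total must be >= 0")
  if (multiplicity < 1) .stop_invalid("multiplicity must be >= 1")
  if (multiplicity > max(cn_total, 1))
    .stop_invalid("multiplicity cannot exceed the tumour total copy number")
  if (!normal_ploidy %in% c(1, 2))
    .stop_invalid("normal_ploidy must be 1 or 2")
  structure(list(cn_total = as.integer(cn_total),
                 multiplicity = as.integer(multiplicity),
                 normal_ploidy = as.integer(normal_ploidy)),
            class = "cn_state")
}

#' Expected VAF of a mutation carried by a fraction of cells
#'
#' Standard two-population mixture: a fraction `ccf` of nucleated cells is
#' tumour with `cn_total` copies of the locus (of which `multiplicity`
#' carry the variant), the rest are normal cells with `normal_ploidy`
#' copies, none mutated:
#' \deqn{v = \frac{m\,c}{n_p (1 - c) + CN_t\, c}}
#' For a heterozygous mutation in a diploid region this reduces to
#' `vaf = ccf / 2`, the usual doubling rule.
#'
#' @param ccf cancer cell fraction in [0, 1] (vectorised).
#' @param state a [copy_number_state()].
#' @return expected VAF in [0, 1].
#' @export
expected_vaf <- function(ccf, state) {
  stopifnot(inherits(state, "cn_state"))
  if (any(ccf < 0 | ccf > 1)) .stop_invalid("ccf must lie in [0, 1]")
  m <- state$multiplicity; cnt <- state$cn_total; np <- state$normal_ploidy
  m * ccf / (np * (1 - ccf) + cnt * ccf)
}

#' Convert a VAF to a copy-number-corrected cancer cell fraction
#'
#' Inverts [expected_vaf()]:
#' \deqn{c = \frac{n_p\, v}{m - v (CN_t - n_p)}}
#' Raw values above 1 (sampling noise, or a mis-specified copy-number
#' state) are clipped to 1; the estimate is flagged as an overflow when
#' the raw value exceeds `1 + 3 * se`.
#'
#' @param vaf variant allele frequency in [0, 1] (vectorised).
#' @param state a [copy_number_state()].
#' @param se optional standard error(s) of the resulting CCF used for the
#'   overflow flag; default 0 (flag any raw value > 1).
#' @return a data.frame with columns `ccf`, `overflow`.
#' @export
vaf_to_ccf <- function(vaf, state, se = 0) {
  stopifnot(inherits(state, "cn_state"))
  if (any(vaf < 0 | vaf > 1)) .stop_invalid("vaf must lie in [0, 1]")
  m <- state$multiplicity; cnt <- state$cn_total; np <- state$normal_ploidy
  denom <- m - vaf * (cnt - np)
  if (any(denom <= 0))
    .stop_invalid("invalid copy-number state: non-positive denominator")
  raw <- np * vaf / denom
  data.frame(ccf = pmin(pmax(raw, 0), 1), overflow = raw > 1 + 3 * se)
}

#' Delta-method standard error of a CCF estimate
#'
#' Propagates the binomial VAF standard error `sqrt(v (1 - v) / depth)`
#' through the VAF-to-CCF map. For a heterozygous diploid locus the map is
#' linear with slope 2, so `se(ccf) = 2 * se(vaf)`.
#'
#' @param alt alternative-allele read count.
#' @param depth total read depth (> 0).
#' @param state a [copy_number_state()].
#' @param vaf_floor lower bound applied to the VAF entering the binomial
#'   variance, so that zero counts still carry the uncertainty of the
#'   detection floor rather than a deceptive zero. Default 0.002 (the
#'   deep-sequencing reporting floor).
#' @return standard error of the CCF (vectorised over `alt`/`depth`).
#' @export
ccf_se <- function(alt, depth, state, vaf_floor = 0.002) {
  stopifnot(inherits(state, "cn_state"))
  if (any(depth <= 0)) .stop_invalid("depth must be > 0")
  v <- alt / depth
  v_var <- pmin(pmax(v, vaf_floor), 1 - vaf_floor)
  se_v <- sqrt(v_var * (1 - v_var) / depth)
  m <- state$multiplicity; cnt <- state$cn_total; np <- state$normal_ploidy
  denom <- m - v * (cnt - np)
  jac <- np * m / denom^2
  abs(jac) * se_v
}

#' Assign a copy-number state to a mutation position
#'
#' Looks the (1-based) variant position up in the kept copy-number
#' segments (0-based half-open coordinates). Without an overlapping
#' segment the state defaults to diploid heterozygous, with normal ploidy
#' 1 on the X/Y of a male. In a copy-neutral LOH segment the multiplicity
#' is ambiguous (the mutation sits on the duplicated or on the lost
#' haplotype); when read counts and a candidate CCF are supplied the
#' multiplicity maximising the binomial likelihood is chosen, with ties
#' going to 2 (mutation acquired before the LOH, the common somatic
#' pattern).
#'
#' @param chrom,pos variant coordinates (1-based position).
#' @param segments data.frame of kept segments with columns `chrom`,
#'   `start`, `end`, `cn_total`, `cn_minor`, `is_cnloh` (see
#'   [filter_cna_segments()]); may be `NULL` or empty.
#' @param sex `"male"` or `"female"`.
#' @param alt,depth,candidate_ccf optional evidence for the CN-LOH
#'   multiplicity choice.
#' @return a [copy_number_state()].
#' @export
assign_cn_state <- function(chrom, pos, segments = NULL, sex = c("female", "male"),
                            alt = NULL, depth = NULL, candidate_ccf = NULL) {
  sex <- match.arg(sex)
  np <- if (sex == "male" && chrom %in% c("X", "Y", "chrX", "chrY")) 1L else 2L
  if (is.null(segments) || nrow(segments) == 0)
    return(copy_number_state(if (np == 1L) 1L else 2L, 1L, np))
  hit <- which(.point_in_segment(chrom, pos, segments))
  if (length(hit) == 0)
    return(copy_number_state(if (np == 1L) 1L else 2L, 1L, np))
  if (length(hit) > 1) {
    states <- unique(segments[hit, c("cn_total", "is_cnloh")])
    if (nrow(states) > 1)
      .stop_invalid(sprintf("contradictory copy-number segments overlap %s:%d",
                            chrom, pos))
    hit <- hit[1]
  }
  seg <- segments[hit, ]
  if (isTRUE(seg$is_cnloh)) {
    m <- .cnloh_multiplicity(alt, depth, candidate_ccf, np)
    return(copy_number_state(2L, m, np))
  }
  cnt <- as.integer(seg$cn_total)
  copy_number_state(cnt, 1L, np)
}

# Multiplicity in a CN-LOH segment: binomial likelihood of the observed
# alt count under m = 1 vs m = 2 at the candidate CCF; tie -> 2.
.cnloh_multiplicity <- function(alt, depth, candidate_ccf, np) {
  if (is.null(alt) || is.null(depth) || is.null(candidate_ccf)) return(2L)
  ll <- vapply(1:2, function(m) {
    v <- expected_vaf(candidate_ccf, copy_number_state(2L, m, np))
    v <- min(max(v, 1e-9), 1 - 1e-9)
    stats::dbinom(alt, depth, v, log = TRUE)
  }, numeric(1))
  if (ll[1] > ll[2]) 1L else 2L
}

#' Build a CCF matrix from validated read counts
#'
#' Converts per-mutation, per-sample read counts into copy-number-corrected
#' cancer cell fractions with standard errors, ordered by sampling time.
#' Entries with VAF below the 0.2% deep-sequencing reporting floor are set
#' to CCF 0 and flagged, so downstream clustering sees explicit zeros.
#'
#' @param records long data.frame with columns `mutation_id`, `sample_id`,
#'   `alt_count`, `depth`, and optionally `chrom`, `pos`.
#' @param samples sample sheet with columns `sample_id`, `time_days`;
#'   germline samples should be excluded before calling.
#' @param states named list of [copy_number_state()] per mutation id;
#'   mutations absent from the list default to diploid heterozygous.
#' @param vaf_floor detection floor on the VAF scale (default 0.002).
#' @return an object of class `ccf_matrix`: list with matrices `ccf`,
#'   `se`, `below_floor`, `vaf` (mutations x samples), the time-ordered
#'   `samples` sheet and `mutations` ids.
#' @export
build_ccf_matrix <- function(records, samples, states = list(),
                             vaf_floor = 0.002) {
  samples <- samples[order(samples$time_days), , drop = FALSE]
  muts <- sort(unique(records$mutation_id))
  sids <- samples$sample_id
  missing_sheet <- setdiff(unique(records$sample_id), sids)
  if (length(missing_sheet))
    .stop_invalid(paste("samples missing from the sample sheet:",
                        paste(missing_sheet, collapse = ", ")))
  dims <- list(muts, sids)
  empty <- matrix(NA_real_, length(muts), length(sids), dimnames = dims)
  out <- list(ccf = empty, se = empty, vaf = empty,
              below_floor = matrix(FALSE, length(muts), length(sids),
                                   dimnames = dims),
              samples = samples, mutations = muts, states = list())
  default_state <- copy_number_state(2L, 1L, 2L)
  for (mu in muts) {
    st <- if (!is.null(states[[mu]])) states[[mu]] else default_state
    out$states[[mu]] <- st
    rec <- records[records$mutation_id == mu, ]
    for (k in seq_len(nrow(rec))) {
      sid <- rec$sample_id[k]
      v <- rec$alt_count[k] / rec$depth[k]
      out$vaf[mu, sid] <- v
      se <- ccf_se(rec$alt_count[k], rec$depth[k], st, vaf_floor = vaf_floor)
      if (v < vaf_floor) {
        # censored observation: all we know is vaf < floor, so the
        # uncertainty is of the order of the floor itself, not just the
        # binomial se evaluated at the floor
        out$ccf[mu, sid] <- 0
        out$below_floor[mu, sid] <- TRUE
        se_bin <- ccf_se(vaf_floor * rec$depth[k], rec$depth[k], st,
                         vaf_floor = vaf_floor)
        ccf_floor <- vaf_to_ccf(vaf_floor, st)$ccf
        out$se[mu, sid] <- sqrt(se_bin^2 + (ccf_floor / 2)^2)
      } else {
        cc <- vaf_to_ccf(min(v, 1), st, se = se)
        out$ccf[mu, sid] <- cc$ccf
        out$se[mu, sid] <- se
      }
    }
  }
  class(out) <- "ccf_matrix"
  out
}

#' @export
print.ccf_matrix <- function(x, ...) {
  cat(sprintf("CCF matrix: %d mutations x %d samples\n",
              length(x$mutations), nrow(x$samples)))
  print(round(x$ccf, 3))
  invisible(x)
}
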