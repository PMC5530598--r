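# Clone tree / forest inference from cluster CCF trajectories, under the
# pigeonhole and sum rules, temporal precedence and single-colony
# phylogeny constraints; evolution-pattern classification and
# fishplot-ready clone fractions.

#' Genotype a single colony from its mutation VAFs
#'
#' A colony founded by one cell is heterozygous (VAF ~ 50%) for every
#' mutation its founder carries and mutation-free otherwise, so a
#' mutation is scored present above 40% VAF and absent below 5%;
#' anything between is ambiguous — the hallmark of a mixed (multi-cell)
#' colony — and such colonies are excluded from phylogenetic
#' constraints.
#'
#' @param vafs numeric vector of per-mutation VAFs in one colony.
#' @param present_min VAF above which a mutation is present (default 0.40,
#'   strict).
#' @param absent_max VAF below which it is absent (default 0.05, strict).
#' @return integer vector: 1 present, 0 absent, NA ambiguous.
#' @export
genotype_colony <- function(vafs, present_min = 0.40, absent_max = 0.05) {
  if (any(vafs < 0 | vafs > 1)) .stop_invalid("VAFs must lie in [0, 1]")
  out <- rep(NA_integer_, length(vafs))
  out[vafs > present_min] <- 1L
  out[vafs < absent_max] <- 0L
  names(out) <- names(vafs)
  out
}

#' Ternary colony-by-mutation genotype matrix
#'
#' @param colony_table long data.frame: `colony_id`, `mutation_id`, `vaf`.
#' @param ... thresholds passed to [genotype_colony()].
#' @return matrix (colonies x mutations) with entries 1/0/NA; attribute
#'   `ambiguous`: logical vector flagging colonies with any ambiguous
#'   entry (possibly mixed).
#' @export
colony_genotype_matrix <- function(colony_table, ...) {
  cols <- sort(unique(colony_table$colony_id))
  muts <- sort(unique(colony_table$mutation_id))
  m <- matrix(NA_integer_, length(cols), length(muts),
              dimnames = list(cols, muts))
  g <- genotype_colony(colony_table$vaf, ...)
  m[cbind(match(colony_table$colony_id, cols),
          match(colony_table$mutation_id, muts))] <- g
  attr(m, "ambiguous") <- apply(m, 1, anyNA)
  m
}

#' Phylogenetic constraints from colony genotypes
#'
#' Over unambiguous colonies, each mutation pair is summarised by which
#' of the co-occurrence patterns (1,0), (0,1), (1,1) it exhibits. Under a
#' perfect phylogeny, co-occurrence together with one-sided presence
#' implies an ancestor/descendant order; mutually exclusive presence
#' without co-occurrence marks the mutations as belonging to separate
#' clones; all three patterns at once violate the perfect phylogeny and
#' are reported.
#'
#' @param geno a matrix from [colony_genotype_matrix()].
#' @return list of data.frames `nested` (`ancestor`, `descendant`),
#'   `exclusive` (`a`, `b`), `violations` (`a`, `b`), plus
#'   `n_informative` (number of unambiguous colonies used).
#' @export
colony_constraints <- function(geno) {
  amb <- attr(geno, "ambiguous")
  use <- geno[!amb, , drop = FALSE]
  if (nrow(use) == 0)
    .stop_invalid("no unambiguous colony available")
  muts <- colnames(use)
  nested <- exclusive <- violations <- list()
  if (length(muts) > 1) {
    for (a in 1:(length(muts) - 1)) for (b in (a + 1):length(muts)) {
      gi <- use[, a]; gj <- use[, b]
      has11 <- any(gi == 1 & gj == 1)
      has10 <- any(gi == 1 & gj == 0)
      has01 <- any(gi == 0 & gj == 1)
      if (has11 && has10 && has01) {
        violations[[length(violations) + 1]] <- c(muts[a], muts[b])
      } else if (has11 && has10) {
        nested[[length(nested) + 1]] <- c(muts[a], muts[b])
      } else if (has11 && has01) {
        nested[[length(nested) + 1]] <- c(muts[b], muts[a])
      } else if (has10 && has01) {
        exclusive[[length(exclusive) + 1]] <- c(muts[a], muts[b])
      }
    }
  }
  as_df <- function(lst, nm) {
    if (!length(lst)) return(stats::setNames(
      data.frame(character(), character(), stringsAsFactors = FALSE), nm))
    stats::setNames(as.data.frame(do.call(rbind, lst),
                                  stringsAsFactors = FALSE), nm)
  }
  list(nested = as_df(nested, c("ancestor", "descendant")),
       exclusive = as_df(exclusive, c("a", "b")),
       violations = as_df(violations, c("a", "b")),
       n_informative = nrow(use))
}

# lift mutation-level colony constraints to cluster level
.cluster_constraints <- function(constraints, assignment) {
  if (is.null(constraints))
    return(list(nested = cbind(integer(), integer()),
                exclusive = cbind(integer(), integer())))
  map <- function(ids) unname(assignment[ids])
  nest <- unique(cbind(map(constraints$nested$ancestor),
                       map(constraints$nested$descendant)))
  excl <- unique(cbind(map(constraints$exclusive$a),
                       map(constraints$exclusive$b)))
  drop_na <- function(m) m[stats::complete.cases(m) & m[, 1] != m[, 2], ,
                           drop = FALSE]
  list(nested = drop_na(nest), exclusive = drop_na(excl))
}

.pair_eps <- function(se_i, se_j, eps_min) pmax(eps_min, 2 * sqrt(se_i^2 + se_j^2))

# ancestor matrix (k x k logical, anc[i,j]: i is a strict ancestor of j)
.ancestor_matrix <- function(parent) {
  k <- length(parent)
  anc <- matrix(FALSE, k, k)
  for (j in seq_len(k)) {
    p <- parent[j]
    while (p != 0L) { anc[p, j] <- TRUE; p <- parent[p] }
  }
  anc
}

.is_acyclic <- function(parent) {
  k <- length(parent)
  for (j in seq_len(k)) {
    p <- parent[j]; steps <- 0L
    while (p != 0L) {
      p <- parent[p]; steps <- steps + 1L
      if (steps > k) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate all admissible clone forests
#'
#' Exhaustively enumerates every assignment of a parent (or root status)
#' to each mutation cluster that satisfies, within tolerance `eps`:
#' the pigeonhole rule per edge (a child's CCF never exceeds its
#' parent's), the sum rule per node (children's CCFs cannot jointly
#' exceed their parent), the root sum rule (root CCFs cannot jointly
#' exceed 1), temporal precedence (a parent is first detected no later
#' than its child) and any colony-derived constraints (exclusive pairs
#' must not share a root path; evidenced ancestor/descendant orders must
#' not be inverted). The tolerance defaults to
#' `max(eps_min, 2 * pooled centroid se)` per comparison, scaling with
#' sequencing depth.
#'
#' @param centroid,centroid_se cluster x sample CCF matrices (from
#'   [cluster_mutations()] / [cluster_centroids()]).
#' @param first_detect integer vector: index of the first sample in which
#'   each cluster is detected (default: first sample with centroid CCF
#'   above `detect_floor`).
#' @param constraints optional output of [colony_constraints()] together
#'   with a mutation-to-cluster `assignment` (see
#'   [reconstruct_clones()]); may be NULL.
#' @param assignment named cluster assignment used to lift `constraints`
#'   to cluster level.
#' @param eps_min absolute tolerance floor (default 0.05).
#' @param detect_floor CCF detection floor (default 0.005, i.e. the 0.2%
#'   VAF reporting floor for a heterozygous diploid mutation).
#' @param max_clusters refuse to enumerate beyond this many clusters
#'   (default 12): the search is exhaustive by design, no heuristic
#'   fallback.
#' @return list of parent vectors (integer, 0 = root), each a forest.
#' @export
enumerate_forests <- function(centroid, centroid_se, first_detect = NULL,
                              constraints = NULL, assignment = NULL,
                              eps_min = 0.05, detect_floor = 0.005,
                              max_clusters = 12L) {
  k <- nrow(centroid)
  if (k > max_clusters)
    .stop_invalid(sprintf(
      "exhaustive enumeration limited to %d clusters (got %d)",
      max_clusters, k))
  if (is.null(first_detect))
    first_detect <- apply(centroid > detect_floor, 1, function(z)
      if (any(z)) which(z)[1] else ncol(centroid) + 1L)
  cc <- .cluster_constraints(constraints, assignment)

  # admissible parents per cluster: pigeonhole + temporal + direct
  # colony-order pruning (full path checks happen on complete forests)
  allowed <- lapply(seq_len(k), function(i) {
    cand <- setdiff(seq_len(k), i)
    ok <- vapply(cand, function(p) {
      eps <- .pair_eps(centroid_se[i, ], centroid_se[p, ], eps_min)
      all(centroid[i, ] <= centroid[p, ] + eps) &&
        first_detect[p] <= first_detect[i] &&
        !any(cc$nested[, 1] == i & cc$nested[, 2] == p) &&
        !any((cc$exclusive[, 1] == i & cc$exclusive[, 2] == p) |
             (cc$exclusive[, 1] == p & cc$exclusive[, 2] == i))
    }, logical(1))
    c(0L, cand[ok])
  })

  results <- list()
  parent <- integer(k)
  recurse <- function(i) {
    if (i > k) {
      if (.forest_admissible(parent, centroid, centroid_se, eps_min, cc))
        results[[length(results) + 1]] <<- parent
      return(invisible())
    }
    for (p in allowed[[i]]) {
      parent[i] <<- p
      # prune cycles early: walking up from i must terminate
      if (.partial_acyclic(parent, i)) recurse(i + 1)
    }
    parent[i] <<- 0L
  }
  recurse(1L)
  results
}

.partial_acyclic <- function(parent, i) {
  p <- parent[i]; steps <- 0L
  while (p != 0L && steps <= length(parent)) {
    if (p == i) return(FALSE)
    p <- parent[p]; steps <- steps + 1L
  }
  steps <= length(parent)
}

.forest_admissible <- function(parent, centroid, centroid_se, eps_min, cc) {
  if (!.is_acyclic(parent)) return(FALSE)
  k <- length(parent)
  # sum rule per node and for the roots
  for (p in c(0L, seq_len(k))) {
    kids <- which(parent == p)
    if (length(kids) == 0) next
    kid_sum <- colSums(centroid[kids, , drop = FALSE])
    kid_var <- colSums(centroid_se[kids, , drop = FALSE]^2)
    if (p == 0L) {
      eps <- pmax(eps_min, 2 * sqrt(kid_var))
      if (any(kid_sum > 1 + eps)) return(FALSE)
    } else {
      eps <- pmax(eps_min, 2 * sqrt(centroid_se[p, ]^2 + kid_var))
      if (any(kid_sum > centroid[p, ] + eps)) return(FALSE)
    }
  }
  # colony path constraints on the complete forest
  anc <- .ancestor_matrix(parent)
  if (nrow(cc$nested))
    for (r in seq_len(nrow(cc$nested)))
      if (anc[cc$nested[r, 2], cc$nested[r, 1]]) return(FALSE)
  if (nrow(cc$exclusive))
    for (r in seq_len(nrow(cc$exclusive))) {
      a <- cc$exclusive[r, 1]; b <- cc$exclusive[r, 2]
      if (anc[a, b] || anc[b, a]) return(FALSE)
    }
  TRUE
}

#' Score admissible forests and select the most probable one
#'
#' Parsimony score: a slack penalty (squared positive violation of the
#' sum rule in pooled-standard-error units, summed over nodes and
#' timepoints — zero for strictly admissible forests), plus `lambda` per
#' extra root and `mu` per branching node. The minimal score wins;
#' deterministic tie-breaks prefer fewer roots, then fewer branch nodes,
#' then the lexicographically smallest parent vector. When the
#' admissible set is empty, every spanning forest consistent with
#' temporal ordering is scored by its total constraint violation and the
#' least-violating forest is returned, flagged, with a violation table —
#' the method never fails silently.
#'
#' @param forests list of parent vectors from [enumerate_forests()]; may
#'   be empty.
#' @param centroid,centroid_se cluster x sample CCF matrices.
#' @param lambda penalty per root beyond the first (default 1.0).
#' @param mu penalty per node with >= 2 children (default 0.25).
#' @param eps_min tolerance floor used in the violation report.
#' @param constraints,assignment,first_detect,detect_floor used only in
#'   the empty-set fallback, to keep the hard (colony, temporal)
#'   constraints satisfied while relaxing the CCF rules.
#' @return object of class `clone_forest_estimate`: list with `parent`,
#'   `ccf` (= centroid), `se`, `score`, `admissible`, `n_admissible`,
#'   `violations` (data.frame, empty when admissible).
#' @export
score_and_select <- function(forests, centroid, centroid_se,
                             lambda = 1.0, mu = 0.25, eps_min = 0.05,
                             constraints = NULL, assignment = NULL,
                             first_detect = NULL, detect_floor = 0.005) {
  k <- nrow(centroid)
  admissible <- length(forests) > 0
  if (!admissible) {
    # relax the CCF rules but keep colony evidence and temporal order:
    # the all-roots forest always qualifies, so the set is never empty
    cc <- .cluster_constraints(constraints, assignment)
    if (is.null(first_detect))
      first_detect <- apply(centroid > detect_floor, 1, function(z)
        if (any(z)) which(z)[1] else ncol(centroid) + 1L)
    forests <- Filter(function(parent)
      .hard_constraints_ok(parent, cc, first_detect),
      .all_acyclic_parent_vectors(k))
  }
  scored <- lapply(forests, function(parent) {
    sl <- .slack_penalty(parent, centroid, centroid_se,
                         edges = !admissible)
    n_roots <- sum(parent == 0L)
    n_branch <- sum(tabulate(parent[parent != 0L], nbins = k) >= 2)
    list(parent = parent,
         score = sl + lambda * (n_roots - 1) + mu * n_branch,
         n_roots = n_roots, n_branch = n_branch)
  })
  ord <- order(vapply(scored, `[[`, numeric(1), "score"),
               vapply(scored, `[[`, numeric(1), "n_roots"),
               vapply(scored, `[[`, numeric(1), "n_branch"),
               vapply(scored, function(s)
                 paste(sprintf("%02d", s$parent), collapse = ""),
                 character(1)))
  best <- scored[[ord[1]]]
  structure(list(parent = best$parent, ccf = centroid, se = centroid_se,
                 score = best$score, admissible = admissible,
                 n_admissible = if (admissible) length(forests) else 0L,
                 violations = .violation_table(best$parent, centroid,
                                               centroid_se, eps_min)),
            class = "clone_forest_estimate")
}

.hard_constraints_ok <- function(parent, cc, first_detect) {
  for (i in seq_along(parent)) {
    p <- parent[i]
    if (p != 0L && first_detect[p] > first_detect[i]) return(FALSE)
  }
  anc <- .ancestor_matrix(parent)
  if (nrow(cc$nested))
    for (r in seq_len(nrow(cc$nested)))
      if (anc[cc$nested[r, 2], cc$nested[r, 1]]) return(FALSE)
  if (nrow(cc$exclusive))
    for (r in seq_len(nrow(cc$exclusive))) {
      a <- cc$exclusive[r, 1]; b <- cc$exclusive[r, 2]
      if (a == b || anc[a, b] || anc[b, a]) return(FALSE)
    }
  TRUE
}

.slack_penalty <- function(parent, centroid, centroid_se, edges = FALSE) {
  k <- length(parent)
  total <- 0
  for (p in c(0L, seq_len(k))) {
    kids <- which(parent == p)
    if (!length(kids)) next
    kid_sum <- colSums(centroid[kids, , drop = FALSE])
    kid_var <- colSums(centroid_se[kids, , drop = FALSE]^2)
    if (p == 0L) {
      slack <- pmax(0, kid_sum - 1)
      total <- total + sum(slack^2 / kid_var)
    } else {
      slack <- pmax(0, kid_sum - centroid[p, ])
      total <- total + sum(slack^2 / (centroid_se[p, ]^2 + kid_var))
    }
  }
  if (edges) {  # fallback scoring also penalises per-edge pigeonhole excess
    for (i in seq_len(k)) {
      p <- parent[i]
      if (p == 0L) next
      excess <- pmax(0, centroid[i, ] - centroid[p, ])
      total <- total +
        sum(excess^2 / (centroid_se[i, ]^2 + centroid_se[p, ]^2))
    }
  }
  total
}

.violation_table <- function(parent, centroid, centroid_se, eps_min) {
  out <- list()
  k <- length(parent)
  for (p in c(0L, seq_len(k))) {
    kids <- which(parent == p)
    if (!length(kids)) next
    kid_sum <- colSums(centroid[kids, , drop = FALSE])
    kid_var <- colSums(centroid_se[kids, , drop = FALSE]^2)
    bound <- if (p == 0L) rep(1, ncol(centroid)) else centroid[p, ]
    var_tot <- if (p == 0L) kid_var else centroid_se[p, ]^2 + kid_var
    eps <- pmax(eps_min, 2 * sqrt(var_tot))
    bad <- which(kid_sum > bound + eps)
    for (t in bad)
      out[[length(out) + 1]] <- data.frame(
        type = "sum_rule", node = p, timepoint = t,
        value = kid_sum[t], bound = bound[t],
        excess = kid_sum[t] - bound[t])
  }
  for (i in seq_len(k)) {
    p <- parent[i]
    if (p == 0L) next
    eps <- .pair_eps(centroid_se[i, ], centroid_se[p, ], eps_min)
    bad <- which(centroid[i, ] > centroid[p, ] + eps)
    for (t in bad)
      out[[length(out) + 1]] <- data.frame(
        type = "pigeonhole", node = i, timepoint = t,
        value = centroid[i, t], bound = centroid[p, t],
        excess = centroid[i, t] - centroid[p, t])
  }
  if (!length(out))
    return(data.frame(type = character(), node = integer(),
                      timepoint = integer(), value = numeric(),
                      bound = numeric(), excess = numeric()))
  do.call(rbind, out)
}

.all_acyclic_parent_vectors <- function(k) {
  if (k == 1) return(list(0L))
  grid <- vector("list", k)
  for (i in seq_len(k)) grid[[i]] <- setdiff(0:k, i)
  combos <- do.call(expand.grid, grid)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    parent <- as.integer(combos[r, ])
    if (.is_acyclic(parent)) out[[length(out) + 1]] <- parent
  }
  out
}

#' Label non-primary roots as unrelated clones, with evidence grade
#'
#' The primary root is the one with the highest mean CCF. Every other
#' root is an unrelated clone; its evidence is graded `colony_proven`
#' (an exclusive mutation pair straddles the two trees), `pigeonhole`
#' (the two root CCFs sum above 1 at some timepoint, so the clones
#' cannot be nested), or `topology_only` (it merely could not be
#' attached).
#'
#' @param estimate a `clone_forest_estimate`.
#' @param constraints optional [colony_constraints()] output.
#' @param assignment mutation-to-cluster assignment (needed with
#'   `constraints`).
#' @param eps_min tolerance floor (default 0.05).
#' @return data.frame `root`, `evidence` (empty when the forest has a
#'   single root).
#' @export
detect_unrelated_clones <- function(estimate, constraints = NULL,
                                    assignment = NULL, eps_min = 0.05) {
  parent <- estimate$parent
  roots <- which(parent == 0L)
  if (length(roots) < 2)
    return(data.frame(root = integer(), evidence = character()))
  primary <- roots[which.max(rowMeans(estimate$ccf[roots, , drop = FALSE]))]
  anc <- .ancestor_matrix(parent)
  tree_of <- function(r) c(r, which(anc[r, ]))
  cc <- .cluster_constraints(constraints, assignment)
  primary_tree <- tree_of(primary)
  out <- lapply(setdiff(roots, primary), function(r) {
    this_tree <- tree_of(r)
    colony_proof <- nrow(cc$exclusive) > 0 &&
      any((cc$exclusive[, 1] %in% this_tree &
           cc$exclusive[, 2] %in% primary_tree) |
          (cc$exclusive[, 2] %in% this_tree &
           cc$exclusive[, 1] %in% primary_tree))
    eps <- .pair_eps(estimate$se[r, ], estimate$se[primary, ], eps_min)
    pigeon <- any(estimate$ccf[r, ] + estimate$ccf[primary, ] > 1 + eps)
    data.frame(root = r,
               evidence = if (colony_proof) "colony_proven"
                          else if (pigeon) "pigeonhole"
                          else "topology_only",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify the evolution pattern of a selected forest
#'
#' `single_clone` when the forest is one tree with one node; `branching`
#' when any node of the primary tree has two or more children; `linear`
#' otherwise. The unrelated-clones flag is set when the forest has
#' multiple roots.
#'
#' @param estimate a `clone_forest_estimate`.
#' @return list with `pattern` and `unrelated_clones`.
#' @export
classify_pattern <- function(estimate) {
  parent <- estimate$parent
  k <- length(parent)
  roots <- which(parent == 0L)
  if (k == 1)
    return(list(pattern = "single_clone", unrelated_clones = FALSE))
  primary <- roots[which.max(rowMeans(estimate$ccf[roots, , drop = FALSE]))]
  anc <- .ancestor_matrix(parent)
  primary_tree <- c(primary, which(anc[primary, ]))
  n_children <- tabulate(parent[parent != 0L], nbins = k)
  branching <- any(n_children[primary_tree] >= 2)
  pattern <- if (length(roots) == 1 && length(primary_tree) == 1)
    "single_clone" else if (branching) "branching" else "linear"
  list(pattern = pattern, unrelated_clones = length(roots) >= 2)
}

#' Exclusive clone fractions over time (fishplot-ready)
#'
#' The fraction of cells belonging to a clone but to none of its
#' children: `fraction(c, t) = CCF(c, t) - sum(children CCF)`, clipped at
#' zero; a `normal` row holds the residual non-tumour fraction. Per
#' tree, the fractions telescope back to the root CCF.
#'
#' @param estimate a `clone_forest_estimate`.
#' @return matrix (clusters + `"normal"`) x samples.
#' @export
clone_fractions <- function(estimate) {
  parent <- estimate$parent
  cc <- estimate$ccf
  k <- length(parent)
  frac <- matrix(0, k + 1, ncol(cc),
                 dimnames = list(c(rownames(cc) %||% paste0("clone", 1:k),
                                   "normal"), colnames(cc)))
  for (i in seq_len(k)) {
    kids <- which(parent == i)
    kid_sum <- if (length(kids)) colSums(cc[kids, , drop = FALSE]) else 0
    frac[i, ] <- pmax(cc[i, ] - kid_sum, 0)
  }
  roots <- which(parent == 0L)
  frac[k + 1, ] <- pmax(1 - colSums(cc[roots, , drop = FALSE]), 0)
  frac
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full clonal reconstruction of one patient
#'
#' Pipeline wrapper: copy-number state assignment, CCF matrix, trajectory
#' clustering, colony constraints, exhaustive forest enumeration,
#' selection, unrelated-clone detection, pattern classification and
#' clone fractions.
#'
#' @param counts long read-count table (columns `mutation_id`,
#'   `sample_id`, `alt_count`, `depth`, optionally `chrom`, `pos`).
#' @param samples sample sheet (`sample_id`, `tissue`, `time_days`);
#'   germline control rows are identified by `germline_tissues`.
#' @param segments kept copy-number segments (may be NULL / empty).
#' @param colonies optional long colony VAF table (`colony_id`,
#'   `mutation_id`, `vaf`).
#' @param sex `"female"` or `"male"` (sets normal ploidy on X/Y).
#' @param germline_tissues tissues regarded as germline controls.
#' @param z_threshold clustering threshold (default 3).
#' @param eps_min forest tolerance floor (default 0.05).
#' @param lambda,mu parsimony penalties (defaults 1.0, 0.25).
#' @param validate drop mutations failing the 5-percentage-point
#'   tumour-minus-germline validation rule first (default TRUE when a
#'   germline sample is present).
#' @return object of class `clone_reconstruction`.
#' @export
reconstruct_clones <- function(counts, samples, segments = NULL,
                               colonies = NULL, sex = "female",
                               germline_tissues = c("T_cells", "MSC"),
                               z_threshold = 3.0, eps_min = 0.05,
                               lambda = 1.0, mu = 0.25,
                               validate = TRUE) {
  gl_ids <- samples$sample_id[samples$tissue %in% germline_tissues]
  tumour_sheet <- samples[!samples$sample_id %in% gl_ids, , drop = FALSE]
  tumour <- counts[!counts$sample_id %in% gl_ids, , drop = FALSE]
  germline <- counts[counts$sample_id %in% gl_ids, , drop = FALSE]

  if (validate && nrow(germline) > 0) {
    keep <- vapply(unique(tumour$mutation_id), function(mu_id) {
      tv <- tumour[tumour$mutation_id == mu_id, ]
      gv <- germline[germline$mutation_id == mu_id, ][1, ]
      any(validate_mutation(tv$alt_count / tv$depth,
                            gv$alt_count / gv$depth))
    }, logical(1))
    tumour <- tumour[tumour$mutation_id %in%
                       unique(tumour$mutation_id)[keep], , drop = FALSE]
  }
  if (nrow(tumour) == 0) .stop_invalid("no validated mutations to reconstruct")

  has_pos <- all(c("chrom", "pos") %in% names(tumour))
  muts <- unique(tumour$mutation_id)
  states <- lapply(muts, function(mu_id) {
    if (!has_pos || is.null(segments) || nrow(segments) == 0)
      return(copy_number_state())
    rec <- tumour[tumour$mutation_id == mu_id, ][1, ]
    assign_cn_state(rec$chrom, rec$pos, segments, sex = sex)
  })
  names(states) <- muts

  ccfm <- build_ccf_matrix(tumour, tumour_sheet, states)
  clusters <- cluster_mutations(ccfm, z_threshold = z_threshold)

  constraints <- NULL
  if (!is.null(colonies) && nrow(colonies) > 0) {
    geno <- colony_genotype_matrix(
      colonies[colonies$mutation_id %in% muts, , drop = FALSE])
    if (any(!attr(geno, "ambiguous")))
      constraints <- colony_constraints(geno)
  }

  forests <- enumerate_forests(clusters$centroid, clusters$centroid_se,
                               constraints = constraints,
                               assignment = clusters$assignment,
                               eps_min = eps_min)
  estimate <- score_and_select(forests, clusters$centroid,
                               clusters$centroid_se, lambda = lambda,
                               mu = mu, eps_min = eps_min,
                               constraints = constraints,
                               assignment = clusters$assignment)
  unrelated <- detect_unrelated_clones(estimate, constraints,
                                       clusters$assignment,
                                       eps_min = eps_min)
  pattern <- classify_pattern(estimate)
  fractions <- clone_fractions(estimate)
  structure(list(ccf_matrix = ccfm, clusters = clusters,
                 constraints = constraints, estimate = estimate,
                 unrelated = unrelated, pattern = pattern,
                 fractions = fractions, samples = tumour_sheet),
            class = "clone_reconstruction")
}

#' @export
print.clone_reconstruction <- function(x, ...) {
  k <- length(x$estimate$parent)
  cat(sprintf("Clonal reconstruction: %d cluster(s), pattern '%s'%s\n", k,
              x$pattern$pattern,
              if (x$pattern$unrelated_clones) " + unrelated clone(s)" else ""))
  cat("parent vector:", paste(x$estimate$parent, collapse = " "), "\n")
  if (!x$estimate$admissible)
    cat("NOTE: no fully admissible forest; least-violating forest shown\n")
  invisible(x)
}
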