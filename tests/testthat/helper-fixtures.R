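# In-code fixtures shared across test files.

# Wrap bare CCF / SE matrices into the object build_ccf_matrix() returns,
# for tests that target clustering and forest inference directly.
make_ccfm <- function(ccf, se = NULL) {
  if (is.null(rownames(ccf)))
    rownames(ccf) <- sprintf("M%02d", seq_len(nrow(ccf)))
  if (is.null(colnames(ccf)))
    colnames(ccf) <- sprintf("S%02d", seq_len(ncol(ccf)))
  if (is.null(se)) se <- matrix(0.01, nrow(ccf), ncol(ccf))
  dimnames(se) <- dimnames(ccf)
  structure(list(ccf = ccf, se = se, vaf = ccf / 2,
                 below_floor = ccf == 0,
                 samples = data.frame(sample_id = colnames(ccf),
                                      time_days = seq_len(ncol(ccf))),
                 mutations = rownames(ccf)),
            class = "ccf_matrix")
}

# Base-count vector for the deep-sequencing caller.
base_counts <- function(A = 0, C = 0, G = 0, T = 0) {
  c(A = A, C = C, G = G, T = T)
}

# True evolution pattern of a simulated forest. The primary tree is the
# one whose root has the highest mean CCF (same convention as
# classify_pattern); pass the true trajectory matrix when the forest has
# several roots.
truth_pattern <- function(forest, ccf = NULL) {
  nodes <- forest$nodes
  roots <- nodes$clone_id[is.na(nodes$parent_id)]
  if (nrow(nodes) == 1) return("single_clone")
  primary_tree <- if (length(roots) > 1 && !is.null(ccf))
    roots[which.max(rowMeans(ccf[roots, , drop = FALSE]))] else roots[1]
  repeat {
    kids <- nodes$clone_id[!is.na(nodes$parent_id) &
                             nodes$parent_id %in% primary_tree]
    kids <- setdiff(kids, primary_tree)
    if (!length(kids)) break
    primary_tree <- c(primary_tree, kids)
  }
  n_children <- table(nodes$parent_id[nodes$parent_id %in% primary_tree])
  if (length(n_children) && any(n_children >= 2)) "branching" else "linear"
}

# Map inferred clusters to true clones by majority vote; returns NULL
# unless the mapping is a bijection (a prerequisite for an exact
# topology comparison).
cluster_to_clone_map <- function(assignment, truth_clone) {
  k <- max(assignment)
  map <- character(k)
  for (cl in seq_len(k)) {
    tc <- truth_clone[names(assignment)[assignment == cl]]
    map[cl] <- names(sort(table(tc), decreasing = TRUE))[1]
  }
  if (anyDuplicated(map)) return(NULL)
  map
}

# Restrict a simulated forest to the clones visible to the pipeline
# (those with at least one mutation among `mutation_ids`, i.e. surviving
# validation); children of dropped clones are re-attached to the nearest
# surviving ancestor. Clones whose mutations never clear the validation
# threshold are undiscoverable by construction, so they cannot count
# against topology recovery.
visible_forest <- function(forest, mutation_ids) {
  seen <- unique(forest$mutations$clone_id[
    forest$mutations$mutation_id %in% mutation_ids])
  nodes <- forest$nodes[forest$nodes$clone_id %in% seen, , drop = FALSE]
  lookup <- stats::setNames(forest$nodes$parent_id, forest$nodes$clone_id)
  nodes$parent_id <- vapply(nodes$parent_id, function(p) {
    while (!is.na(p) && !p %in% seen) p <- lookup[[p]]
    p
  }, character(1))
  list(nodes = nodes,
       mutations = forest$mutations[
         forest$mutations$mutation_id %in% mutation_ids, , drop = FALSE])
}

# TRUE when the inferred parent vector reproduces the simulated tree.
topology_matches <- function(estimate, assignment, forest) {
  forest <- visible_forest(forest, names(assignment))
  map <- cluster_to_clone_map(assignment, stats::setNames(
    forest$mutations$clone_id, forest$mutations$mutation_id))
  if (is.null(map) || length(map) != nrow(forest$nodes)) return(FALSE)
  nodes <- forest$nodes
  for (cl in seq_along(map)) {
    true_parent <- nodes$parent_id[nodes$clone_id == map[cl]]
    est_parent <- estimate$parent[cl]
    est_parent_clone <- if (est_parent == 0L) NA_character_
                        else map[est_parent]
    if (!identical(is.na(true_parent), is.na(est_parent_clone))) return(FALSE)
    if (!is.na(true_parent) && true_parent != est_parent_clone) return(FALSE)
  }
  TRUE
}

.read_tsv_for_test <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
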