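# Independent oracles used to cross-check the implementation. These
# deliberately share no code with the package internals.

# One-sided Fisher p by direct enumeration over all 2x2 tables with the
# observed margins, using only choose().
oracle_fisher_greater <- function(alt_t, ref_t, alt_c, ref_c) {
  n_t <- alt_t + ref_t
  n_c <- alt_c + ref_c
  k <- alt_t + alt_c
  xs <- max(0, k - n_c):min(k, n_t)
  probs <- choose(n_t, xs) * choose(n_c, k - xs) / choose(n_t + n_c, k)
  sum(probs[xs >= alt_t])
}

# Brute-force enumeration of admissible clone forests: try every parent
# vector directly (0 = root) and test all rules from first principles.
oracle_enumerate_forests <- function(centroid, se, eps_min = 0.05,
                                     detect_floor = 0.005) {
  k <- nrow(centroid)
  first_det <- apply(centroid > detect_floor, 1, function(z)
    if (any(z)) which(z)[1] else ncol(centroid) + 1L)
  options <- lapply(seq_len(k), function(i) setdiff(0:k, i))
  combos <- as.matrix(do.call(expand.grid, options))
  keep <- list()
  for (r in seq_len(nrow(combos))) {
    parent <- as.integer(combos[r, ])
    # acyclicity: repeatedly strip leaves
    remaining <- seq_len(k)
    repeat {
      leaves <- remaining[!remaining %in% parent[remaining]]
      if (!length(leaves)) break
      remaining <- setdiff(remaining, leaves)
    }
    if (length(remaining)) next   # a cycle survived leaf stripping
    ok <- TRUE
    for (i in seq_len(k)) {
      p <- parent[i]
      if (p == 0L) next
      eps <- pmax(eps_min, 2 * sqrt(se[i, ]^2 + se[p, ]^2))
      if (any(centroid[i, ] > centroid[p, ] + eps) ||
          first_det[p] > first_det[i]) { ok <- FALSE; break }
    }
    if (ok) for (p in 0:k) {
      kids <- which(parent == p)
      if (length(kids) == 0) next
      ksum <- colSums(centroid[kids, , drop = FALSE])
      kvar <- colSums(se[kids, , drop = FALSE]^2)
      if (p == 0L) {
        if (any(ksum > 1 + pmax(eps_min, 2 * sqrt(kvar)))) {
          ok <- FALSE; break
        }
      } else if (any(ksum > centroid[p, ] +
                     pmax(eps_min, 2 * sqrt(se[p, ]^2 + kvar)))) {
        ok <- FALSE; break
      }
    }
    if (ok) keep[[length(keep) + 1]] <- parent
  }
  keep
}

canonical_forest_set <- function(forests) {
  sort(vapply(forests, paste, character(1), collapse = ","))
}
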