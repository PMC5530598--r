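# Clustering of ploidy-corrected VAF (CCF) trajectories across serial
# samples: mutations whose trajectories are statistically
# indistinguishable at every timepoint are assigned to one clone.

#' Worst-sample z distance between two mutation trajectories
#'
#' The maximum, over samples where both mutations have finite estimates,
#' of the absolute CCF difference in units of its pooled standard error:
#' \deqn{d_{ij} = \max_t |c_{it} - c_{jt}| / \sqrt{se_{it}^2 + se_{jt}^2}}
#' Two mutations belong to the same clone only if their corrected VAFs
#' agree at every timepoint, so the distance is driven by the single most
#' discordant sample.
#'
#' @param i,j mutation ids (rownames of the matrix).
#' @param ccf_matrix a `ccf_matrix` from [build_ccf_matrix()].
#' @return non-negative scalar.
#' @export
trajectory_distance <- function(i, j, ccf_matrix) {
  ci <- ccf_matrix$ccf[i, ]; cj <- ccf_matrix$ccf[j, ]
  si <- ccf_matrix$se[i, ]; sj <- ccf_matrix$se[j, ]
  ok <- is.finite(ci) & is.finite(cj)
  if (!any(ok)) .stop_invalid("mutations share no sample with estimates")
  max(abs(ci[ok] - cj[ok]) / sqrt(si[ok]^2 + sj[ok]^2))
}

.distance_matrix <- function(ccf_matrix) {
  ids <- ccf_matrix$mutations
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1)
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      d[a, b] <- d[b, a] <- trajectory_distance(ids[a], ids[b], ccf_matrix)
  d
}

#' Cluster mutations by their CCF trajectories
#'
#' Average-linkage agglomerative clustering on the worst-sample z
#' distance. Merging stops when the smallest inter-cluster linkage
#' reaches `z_threshold` (default 3 pooled standard errors, the
#' conventional bound for "statistically indistinguishable"). A
#' consolidation pass then merges any clusters whose precision-weighted
#' centroid trajectories are still within `z_threshold` of each other:
#' with several samples and many mutation pairs, a single >3-sigma
#' fluctuation of one mutation at one timepoint is expected by chance
#' and would otherwise strand that mutation in its own cluster, whereas
#' the centroid — the actual estimate of the clone trajectory — averages
#' such noise out. Fully deterministic: mutations are processed in
#' sorted id order and linkage ties are broken towards the pair
#' containing the smallest mutation id. Output clusters are ordered by
#' descending mean centroid CCF, so cluster 1 is the putative founding
#' clone.
#'
#' @param ccf_matrix a `ccf_matrix`.
#' @param z_threshold stop merging at this linkage (default 3).
#' @return object of class `mutation_clusters`: list with `assignment`
#'   (named integer vector mutation -> cluster), `members` (list),
#'   `centroid`, `centroid_se` (cluster x sample matrices).
#' @export
cluster_mutations <- function(ccf_matrix, z_threshold = 3.0) {
  ids <- sort(ccf_matrix$mutations)
  n <- length(ids)
  if (n == 0) .stop_invalid("no mutations to cluster")
  d <- .distance_matrix(ccf_matrix)[ids, ids, drop = FALSE]
  groups <- as.list(ids)
  repeat {
    g <- length(groups)
    if (g == 1) break
    best <- NULL; best_link <- Inf
    for (a in 1:(g - 1)) for (b in (a + 1):g) {
      link <- mean(d[groups[[a]], groups[[b]]])
      better <- link < best_link - 1e-12 ||
        (abs(link - best_link) <= 1e-12 && !is.null(best) &&
         .tie_rank(groups, a, b) < .tie_rank(groups, best[1], best[2]))
      if (is.null(best) || better) { best <- c(a, b); best_link <- link }
    }
    if (best_link >= z_threshold) break
    groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    groups[[best[2]]] <- NULL
  }

  # consolidation: merge clusters with indistinguishable centroids
  repeat {
    g <- length(groups)
    if (g == 1) break
    cents <- cluster_centroids(list(members = groups), ccf_matrix)
    best <- NULL; best_d <- Inf
    for (a in 1:(g - 1)) for (b in (a + 1):g) {
      dd <- max(abs(cents$centroid[a, ] - cents$centroid[b, ]) /
                  sqrt(cents$centroid_se[a, ]^2 + cents$centroid_se[b, ]^2))
      better <- dd < best_d - 1e-12 ||
        (abs(dd - best_d) <= 1e-12 && !is.null(best) &&
         .tie_rank(groups, a, b) < .tie_rank(groups, best[1], best[2]))
      if (is.null(best) || better) { best <- c(a, b); best_d <- dd }
    }
    if (best_d >= z_threshold) break
    groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    groups[[best[2]]] <- NULL
  }
  cl <- structure(list(members = groups), class = "mutation_clusters")
  cents <- cluster_centroids(cl, ccf_matrix)
  ord <- order(-rowMeans(cents$centroid, na.rm = TRUE),
               vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  assignment <- integer(n); names(assignment) <- ids
  for (k in seq_along(groups)) assignment[groups[[k]]] <- k
  structure(list(assignment = assignment, members = groups,
                 centroid = cents$centroid[ord, , drop = FALSE],
                 centroid_se = cents$centroid_se[ord, , drop = FALSE]),
            class = "mutation_clusters")
}

.tie_rank <- function(groups, a, b) min(c(groups[[a]], groups[[b]]))

#' Precision-weighted cluster centroid trajectories
#'
#' Per cluster and sample, the inverse-variance-weighted mean of the
#' member CCFs and the corresponding combined standard error
#' `1 / sqrt(sum(1 / se^2))`. A singleton's centroid equals the member;
#' with equal standard errors the centroid is the arithmetic mean; the
#' combined standard error never exceeds the smallest member error.
#'
#' @param clusters a `mutation_clusters` (only `members` is used).
#' @param ccf_matrix a `ccf_matrix`.
#' @return list with matrices `centroid` and `centroid_se`
#'   (cluster x sample).
#' @export
cluster_centroids <- function(clusters, ccf_matrix) {
  groups <- clusters$members
  ns <- ncol(ccf_matrix$ccf)
  centroid <- matrix(NA_real_, length(groups), ns,
                     dimnames = list(NULL, colnames(ccf_matrix$ccf)))
  centroid_se <- centroid
  for (k in seq_along(groups)) {
    cc <- ccf_matrix$ccf[groups[[k]], , drop = FALSE]
    se <- ccf_matrix$se[groups[[k]], , drop = FALSE]
    w <- 1 / se^2
    centroid[k, ] <- colSums(cc * w, na.rm = TRUE) /
      colSums(w, na.rm = TRUE)
    centroid_se[k, ] <- 1 / sqrt(colSums(w, na.rm = TRUE))
  }
  list(centroid = centroid, centroid_se = centroid_se)
}

#' @export
print.mutation_clusters <- function(x, ...) {
  cat(sprintf("%d mutation cluster(s):\n", length(x$members)))
  for (k in seq_along(x$members))
    cat(sprintf("  cluster %d (%d mutations): %s\n", k,
                length(x$members[[k]]),
                paste(x$members[[k]], collapse = ", ")))
  invisible(x)
}
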