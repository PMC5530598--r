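#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items,
#' used throughout the test-suite to compare inferred mutation clusters
#' with simulated ground truth. 1 means identical partitions (up to label
#' permutation), 0 is the expectation under random labelling.
#'
#' @param a,b vectors of cluster labels (any atomic type), same length.
#' @return a single numeric value in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# 1-based point vs 0-based half-open segment overlap
.point_in_segment <- function(chrom, pos, seg) {
  seg$chrom == chrom & seg$start < pos & pos <= seg$end
}

.stop_invalid <- function(msg) stop(msg, call. = FALSE)

# deterministic TSV writer: fixed column order, no quoting surprises
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
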