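test_that("colony genotyping applies the >40% / <5% rules", {
  g <- genotype_colony(c(a = 0.45, b = 0.04, c = 0.20, d = 0.40, e = 0.05))
  expect_equal(g[["a"]], 1L)
  expect_equal(g[["b"]], 0L)
  expect_true(is.na(g[["c"]]))   # possibly mixed: excluded
  expect_true(is.na(g[["d"]]))   # 40% is not > 40%
  expect_true(is.na(g[["e"]]))   # 5% is not < 5%
})

test_that("colony constraints read nesting, exclusivity and violations", {
  tab <- function(geno) {
    # geno: colonies x mutations 0/1 matrix -> long VAF table
    df <- expand.grid(colony_id = rownames(geno),
                      mutation_id = colnames(geno),
                      stringsAsFactors = FALSE)
    df$vaf <- ifelse(geno[cbind(df$colony_id, df$mutation_id)] == 1,
                     0.5, 0)
    df
  }
  # containment: {11, 10} => i ancestral to j
  g <- colony_genotype_matrix(tab(matrix(c(1, 1, 1, 0), 2, 2,
    dimnames = list(c("c1", "c2"), c("mi", "mj")))))
  cc <- colony_constraints(g)
  expect_equal(cc$nested$ancestor, "mi")
  expect_equal(cc$nested$descendant, "mj")
  expect_equal(nrow(cc$exclusive), 0)

  # {10, 01} => exclusive (separate clones)
  g <- colony_genotype_matrix(tab(matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("c1", "c2"), c("mi", "mj")))))
  cc <- colony_constraints(g)
  expect_equal(nrow(cc$exclusive), 1)
  expect_equal(nrow(cc$nested), 0)

  # all three patterns => perfect-phylogeny violation, exhaustively
  for (rows in list(c(1, 1, 0, 1, 0, 1), c(0, 1, 1, 1, 1, 0))) {
    g <- colony_genotype_matrix(tab(matrix(rows, 3, 2,
      dimnames = list(c("c1", "c2", "c3"), c("mi", "mj")))))
    cc <- colony_constraints(g)
    expect_equal(nrow(cc$violations), 1)
    expect_equal(nrow(cc$nested) + nrow(cc$exclusive), 0)
  }

  # ambiguous colonies are excluded from the evidence
  df <- tab(matrix(c(1, 1, 1, 0), 2, 2,
    dimnames = list(c("c1", "c2"), c("mi", "mj"))))
  df$vaf[df$colony_id == "c2"] <- 0.2
  cc <- colony_constraints(colony_genotype_matrix(df))
  expect_equal(cc$n_informative, 1)
  expect_equal(nrow(cc$nested), 0)
})

test_that("forest enumeration matches the stated worked examples", {
  # one cluster: exactly one forest, a single root
  f <- enumerate_forests(matrix(0.5, 1, 2), matrix(0.01, 1, 2))
  expect_equal(f, list(0L))

  # A=[.9,.9], B=[.5,.2], C=[.3,.6], eps floor .05: unique forest A->(B,C)
  cen <- rbind(c(0.9, 0.9), c(0.5, 0.2), c(0.3, 0.6))
  se <- matrix(0.001, 3, 2)
  f <- enumerate_forests(cen, se, eps_min = 0.05)
  expect_equal(f, list(c(0L, 1L, 1L)))

  # one-sample chain: admissible set equals the brute-force oracle
  cen <- matrix(c(0.8, 0.5, 0.4), 3, 1)
  se <- matrix(0.001, 3, 1)
  expect_setequal(
    canonical_forest_set(enumerate_forests(cen, se, eps_min = 0)),
    canonical_forest_set(oracle_enumerate_forests(cen, se, eps_min = 0)))

  expect_error(enumerate_forests(matrix(0.1, 13, 1), matrix(0.01, 13, 1)),
               "12 clusters")
})

test_that("forest enumeration equals the oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    k <- sample(1:5, 1)
    ns <- sample(2:4, 1)
    cen <- matrix(runif(k * ns), k, ns)
    se <- matrix(runif(k * ns, 0.002, 0.03), k, ns)
    expect_identical(
      canonical_forest_set(enumerate_forests(cen, se)),
      canonical_forest_set(oracle_enumerate_forests(cen, se)))
  }
})

test_that("forest selection is parsimonious with deterministic tie-breaks", {
  # unique admissible forest is returned unchanged
  cen <- rbind(c(0.9, 0.9), c(0.5, 0.2), c(0.3, 0.6))
  se <- matrix(0.001, 3, 2)
  est <- score_and_select(enumerate_forests(cen, se), cen, se)
  expect_equal(est$parent, c(0L, 1L, 1L))
  expect_true(est$admissible)
  expect_equal(nrow(est$violations), 0)

  # chain and branch both slack-free: the linear chain wins (mu > 0)
  cen <- rbind(c(0.9), c(0.5), c(0.2))
  se <- matrix(0.01, 3, 1)
  forests <- enumerate_forests(cen, se)
  expect_true(all(c("0,1,2", "0,1,1") %in% canonical_forest_set(forests)))
  est <- score_and_select(forests, cen, se)
  expect_equal(est$parent, c(0L, 1L, 2L))

  # no admissible forest: least-violating forest returned, flagged
  cen2 <- rbind(c(0.9), c(0.8))
  se2 <- matrix(0.001, 2, 1)
  # force emptiness with colony exclusivity between the two clusters
  constraints <- list(
    nested = data.frame(ancestor = character(), descendant = character()),
    exclusive = data.frame(a = "M01", b = "M02"),
    violations = data.frame(a = character(), b = character()))
  asg <- c(M01 = 1L, M02 = 2L)
  forests <- enumerate_forests(cen2, se2, constraints = constraints,
                               assignment = asg)
  expect_equal(length(forests), 0)
  est <- score_and_select(forests, cen2, se2, constraints = constraints,
                          assignment = asg)
  expect_false(est$admissible)
  expect_gt(nrow(est$violations), 0)   # two "roots" summing to 1.7
})

test_that("simulated branching patient is reconstructed exactly", {
  cfg <- simulation_config(seed = 2, n_clones = 4, topology = "branching")
  b <- simulate_patient(cfg, min_separation = 0.2)
  rec <- reconstruct_clones(b$counts, b$samples, b$segments)
  expect_true(topology_matches(rec$estimate, rec$clusters$assignment,
                               b$forest))
  expect_equal(rec$pattern$pattern, "branching")
})

test_that("unrelated clones are detected and graded", {
  # crossing trajectories that sum above 1 at the middle timepoint:
  # neither clone can nest in the other, and the sum rule forbids two
  # admissible roots, so the least-violating two-root forest is chosen
  # and the overlap is graded as pigeonhole exclusivity
  cen <- rbind(c(0.70, 0.60, 0.05), c(0.004, 0.55, 0.70))
  se <- matrix(0.01, 2, 3)
  forests <- enumerate_forests(cen, se)
  expect_equal(length(forests), 0)
  est <- score_and_select(forests, cen, se)
  expect_equal(sum(est$parent == 0L), 2)
  un <- detect_unrelated_clones(est)
  expect_equal(un$evidence, "pigeonhole")

  # colony-proven exclusivity outranks the pigeonhole grade
  constraints <- list(
    nested = data.frame(ancestor = character(), descendant = character()),
    exclusive = data.frame(a = "M01", b = "M02"),
    violations = data.frame(a = character(), b = character()))
  un <- detect_unrelated_clones(est, constraints,
                                assignment = c(M01 = 1L, M02 = 2L))
  expect_equal(un$evidence, "colony_proven")

  # single root: nothing to report
  cen1 <- matrix(c(0.8, 0.4), 1, 2)
  est1 <- score_and_select(list(0L), cen1, matrix(0.01, 1, 2))
  expect_equal(nrow(detect_unrelated_clones(est1)), 0)
})

test_that("pattern classification covers all shapes", {
  mk <- function(parent, ccf) structure(
    list(parent = parent, ccf = ccf,
         se = matrix(0.01, nrow(ccf), ncol(ccf))),
    class = "clone_forest_estimate")
  expect_equal(classify_pattern(mk(0L, matrix(0.5, 1, 2)))$pattern,
               "single_clone")
  expect_equal(classify_pattern(
    mk(c(0L, 1L, 2L), matrix(c(0.9, 0.5, 0.2), 3, 2)))$pattern, "linear")
  p <- classify_pattern(mk(c(0L, 1L, 1L), matrix(c(0.9, 0.4, 0.4), 3, 2)))
  expect_equal(p$pattern, "branching")
  expect_false(p$unrelated_clones)
  p <- classify_pattern(mk(c(0L, 1L, 0L), matrix(c(0.7, 0.4, 0.2), 3, 2)))
  expect_equal(p$pattern, "linear")
  expect_true(p$unrelated_clones)
})

test_that("clone fractions telescope to the root CCF", {
  cen <- rbind(c(0.8, 0.9), c(0.5, 0.3), c(0.2, 0.4))
  se <- matrix(0.005, 3, 2)
  est <- score_and_select(enumerate_forests(cen, se), cen, se)
  frac <- clone_fractions(est)
  expect_true(all(frac >= 0))
  # root-exclusive fraction is root CCF minus its children's CCFs
  kids <- which(est$parent == 1L)
  expect_equal(unname(frac[1, ]),
               unname(cen[1, ] - colSums(cen[kids, , drop = FALSE])))
  # per-tree telescoping: fractions sum back to the root CCF
  roots <- which(est$parent == 0L)
  expect_equal(unname(colSums(frac[seq_len(3), , drop = FALSE])),
               unname(colSums(cen[roots, , drop = FALSE])))
  # childless clone keeps its full CCF
  leaf <- setdiff(seq_len(3), est$parent)
  for (l in leaf) expect_equal(frac[l, ], cen[l, ])

  # property over random admissible instances
  set.seed(123)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    cen <- matrix(sort(runif(k), decreasing = TRUE), k, 1)
    se <- matrix(0.01, k, 1)
    forests <- enumerate_forests(cen, se)
    est <- score_and_select(forests, cen, se)
    frac <- clone_fractions(est)
    roots <- which(est$parent == 0L)
    expect_true(all(frac >= -1e-12))
    expect_equal(unname(colSums(frac[seq_len(k), , drop = FALSE])),
                 unname(colSums(cen[roots, , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("colony constraints from unmixed colonies match the truth", {
  cfg <- simulation_config(seed = 17, n_clones = 3, topology = "linear",
                           p_unrelated = 1)
  b <- simulate_patient(cfg, n_colonies = 60, min_separation = 0.15)
  geno <- colony_genotype_matrix(b$colonies)
  cc <- colony_constraints(geno)
  truth <- b$truth$mutation_clone
  nodes <- b$forest$nodes
  anc_clone <- function(id) {  # clone and its ancestors
    path <- id
    while (!is.na(nodes$parent_id[nodes$clone_id == id])) {
      id <- nodes$parent_id[nodes$clone_id == id]
      path <- c(path, id)
    }
    path
  }
  expect_equal(nrow(cc$violations), 0)
  if (nrow(cc$nested)) for (r in seq_len(nrow(cc$nested))) {
    ca <- truth[[cc$nested$ancestor[r]]]
    cd <- truth[[cc$nested$descendant[r]]]
    expect_true(ca %in% anc_clone(cd))
  }
  if (nrow(cc$exclusive)) for (r in seq_len(nrow(cc$exclusive))) {
    ca <- truth[[cc$exclusive$a[r]]]
    cb <- truth[[cc$exclusive$b[r]]]
    expect_false(ca %in% anc_clone(cb) || cb %in% anc_clone(ca))
  }
})
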