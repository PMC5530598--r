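test_that("one-sided Fisher test matches direct hypergeometric enumeration", {
  expect_equal(fisher_exact_one_sided(0, 100, 0, 100), 1.0)
  expect_equal(fisher_exact_one_sided(10, 90, 0, 100),
               oracle_fisher_greater(10, 90, 0, 100), tolerance = 1e-12)
  p <- fisher_exact_one_sided(1, 99, 1, 99)
  expect_equal(p, oracle_fisher_greater(1, 99, 1, 99), tolerance = 1e-12)
  expect_gt(p, 0.001)

  # sweep over random tables; also agree with stats::fisher.test
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    mine <- fisher_exact_one_sided(a, n1 - a, c, n2 - c)
    expect_equal(mine, oracle_fisher_greater(a, n1 - a, c, n2 - c),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, n1 - a, c, n2 - c), 2,
                                    byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(mine, ft, tolerance = 1e-9)
  }
  expect_error(fisher_exact_one_sided(0, 0, 1, 5), "zero depth")
})

test_that("WES candidate filter applies every selection rule", {
  rec <- function(vaf, conseq = "nonsynonymous SNV", gene = "GENE1",
                  depth = 1000) {
    data.frame(mutation_id = "M1", sample_id = "S1",
               alt_count = round(vaf * depth), depth = depth,
               consequence = conseq, gene = gene, chrom = "1",
               pos = 100L, ref = "C", alt = "T",
               stringsAsFactors = FALSE)
  }
  gl_clean <- data.frame(mutation_id = "M1", alt_count = 0, depth = 1000)

  # strong signal but VAF below the 0.07 floor
  d <- wes_candidate_filter(rec(0.06), gl_clean)
  expect_false(d$passed); expect_equal(d$rule, "vaf_floor")

  # synonymous SNV fails regardless of signal strength
  d <- wes_candidate_filter(rec(0.4, conseq = "synonymous SNV"), gl_clean)
  expect_false(d$passed); expect_equal(d$rule, "synonymous")

  # boundary: VAF exactly 0.07 and p exactly at the cutoff both pass
  d <- wes_candidate_filter(rec(0.07), gl_clean)
  expect_true(d$passed)
  expect_lte(d$p_value, 0.001)

  # SNP-database hit and incomplete-ORF gene are excluded
  snp <- data.frame(chrom = "1", pos = 100L, ref = "C", alt = "T")
  d <- wes_candidate_filter(rec(0.4), gl_clean, snp_dbs = list(snp))
  expect_equal(d$rule, "snp_database")
  d <- wes_candidate_filter(rec(0.4), gl_clean,
                            incomplete_orf_genes = "GENE1")
  expect_equal(d$rule, "incomplete_orf")

  # a variant equally present in the germline fails the Fisher rule
  gl_hot <- data.frame(mutation_id = "M1", alt_count = 400, depth = 1000)
  d <- wes_candidate_filter(rec(0.4), gl_hot)
  expect_equal(d$rule, "fisher_p")

  expect_error(wes_candidate_filter(rec(0.4),
                                    data.frame(mutation_id = "M9",
                                               alt_count = 0, depth = 10)),
               "germline")
})

test_that("deep-sequencing caller enforces cutoff and base ranking", {
  # 20/10,000 reads is exactly the 0.2% cutoff
  r <- deep_seq_call(base_counts(A = 9975, C = 20, G = 3, T = 2),
                     ref_base = "A", alt_base = "C")
  expect_true(r$called)
  expect_equal(r$vaf, 0.002)

  # zero alt reads are never called
  r <- deep_seq_call(base_counts(A = 10000, C = 0, G = 0, T = 0), "A", "C")
  expect_false(r$called)

  # alt third-highest: rejected despite VAF at the cutoff
  r <- deep_seq_call(base_counts(A = 9940, G = 25, C = 20, T = 15),
                     "A", "C")
  expect_false(r$called)
  expect_equal(r$rule, "not_second_highest")

  # tie with another non-reference base still counts as second-highest
  r <- deep_seq_call(base_counts(A = 9950, C = 25, G = 25, T = 0),
                     "A", "C")
  expect_true(r$called)
  expect_true(r$tie)

  expect_error(deep_seq_call(base_counts(A = 1), "A", "A"), "alt base")

  # monotone in alt count: once called, more alt reads never un-call
  called <- vapply(0:60, function(alt)
    deep_seq_call(base_counts(A = 9950 - alt, C = alt, G = 22, T = 14),
                  "A", "C")$called, logical(1))
  expect_true(all(diff(called) >= 0))
})

test_that("validation rule requires a 5-percentage-point VAF difference", {
  expect_true(validate_mutation(0.30, 0.00))
  expect_false(validate_mutation(0.24, 0.20))
  expect_true(validate_mutation(0.25, 0.20))  # boundary inclusive
  expect_error(validate_mutation(1.2, 0), "VAFs")
})

test_that("FISH cutoff is mean + 3 sample standard deviations", {
  expect_equal(fish_cutoff(c(0, 0, 0)), 0)
  expect_equal(fish_cutoff(c(0.01, 0.02, 0.03)), 0.05)
  expect_equal(fish_cutoff(rep(0.04, 5)), 0.04)
  expect_error(fish_cutoff(0.01), "control values")
})

test_that("copy-number segment filter implements the size and gene rules", {
  seg <- function(mb, genes = "", cnloh = FALSE, telo = FALSE, chrom = "1") {
    data.frame(chrom = chrom, start = 10e6, end = 10e6 + mb * 1e6,
               cn_total = if (cnloh) 2L else 1L,
               cn_minor = 0L, is_cnloh = cnloh, reaches_telomere = telo,
               genes = genes, stringsAsFactors = FALSE)
  }
  # > 5 Mb kept regardless of gene content
  expect_equal(nrow(filter_cna_segments(seg(6))), 1)
  # <= 5 Mb dropped without a cancer gene, kept with one
  expect_equal(nrow(filter_cna_segments(seg(3))), 0)
  expect_equal(nrow(filter_cna_segments(seg(3, genes = "TP53"),
                                        cancer_genes = "TP53")), 1)
  # CN-LOH: > 10 Mb AND telomeric
  expect_equal(nrow(filter_cna_segments(seg(12, cnloh = TRUE, telo = TRUE))), 1)
  expect_equal(nrow(filter_cna_segments(seg(8, cnloh = TRUE, telo = TRUE))), 0)
  expect_equal(nrow(filter_cna_segments(seg(12, cnloh = TRUE, telo = FALSE))), 0)
  # IG/TCR focal artefacts dropped even when large
  expect_equal(nrow(filter_cna_segments(seg(7, genes = "IGH"))), 0)
  # normal-variant database match dropped
  db <- data.frame(chrom = "1", start = 9e6, end = 20e6)
  expect_equal(nrow(filter_cna_segments(seg(6), normal_variant_db = db)), 0)

  # idempotent and order-independent
  all_segs <- rbind(seg(6), seg(3, genes = "TP53"), seg(12, cnloh = TRUE,
                                                        telo = TRUE),
                    seg(3), seg(7, genes = "IGH"))
  kept <- filter_cna_segments(all_segs, cancer_genes = "TP53")
  expect_equal(filter_cna_segments(kept, cancer_genes = "TP53"), kept)
  shuffled <- all_segs[c(4, 2, 5, 1, 3), ]
  kept2 <- filter_cna_segments(shuffled, cancer_genes = "TP53")
  expect_setequal(
    do.call(paste, kept[c("start", "end", "genes")]),
    do.call(paste, kept2[c("start", "end", "genes")]))

  expect_error(filter_cna_segments(
    data.frame(chrom = "1", start = 5, end = 5, cn_total = 1,
               cn_minor = 0, is_cnloh = FALSE, reaches_telomere = FALSE,
               genes = "")), "malformed")
})
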