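make_records <- function(fpkm_bait, fpkm_control, counts = NULL,
                         rna_type = "protein_coding") {
  n <- nrow(fpkm_bait)
  df <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                   rna_type = rep_len(rna_type, n),
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(fpkm_bait)))
    df[[paste0("fpkm_bait_", i)]] <- fpkm_bait[, i]
  for (i in seq_len(ncol(fpkm_control)))
    df[[paste0("fpkm_control_", i)]] <- fpkm_control[, i]
  counts <- counts %||% round(fpkm_bait * 10)
  for (i in seq_len(ncol(counts)))
    df[[paste0("count_bait_", i)]] <- counts[, i]
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("contaminant RNA classes are excluded, everything else kept", {
  df <- data.frame(gene_id = c("a", "b", "c", "d"),
                   rna_type = c("rRNA", "protein_coding", "mitochondrial",
                                "snRNA"))
  out <- exclude_contaminant_classes(df)
  expect_identical(out$gene_id, c("b", "d"))
  empty <- df[0, ]
  expect_identical(nrow(exclude_contaminant_classes(empty)), 0L)
})

test_that("pseudocount enrichment formula gives the documented values", {
  expect_equal(fold_enrichment(0, 0), 1)
  expect_equal(fold_enrichment(18, 8), 2)
  expect_equal(fold_enrichment(0, 198), 0.01)
  expect_error(fold_enrichment(-1, 5))
})

test_that("enrichment is monotone in bait signal and swap-consistent", {
  f1 <- fold_enrichment(seq(0, 50, by = 5), 10)
  expect_true(all(diff(f1) > 0))
  f <- fold_enrichment(18, 8); g <- fold_enrichment(8, 18)
  expect_equal(f, 2); expect_equal(g, 0.5)
  # swapped form is computed from the swapped pseudocount ratio, and is the
  # exact reciprocal only because both means appear with the same pseudocount
  expect_equal(g, (8 + 2) / (18 + 2))
})

test_that("differential test: null genes get p = 1, strong genes tiny fdr", {
  b <- matrix(c(8, 8, 8), 1, 3); c0 <- matrix(c(8, 8, 8), 1, 3)
  df <- make_records(rbind(b, 2^matrix(10, 1, 3)),
                     rbind(c0, 2^matrix(2, 1, 3) - 2))
  # add slight jitter so variances are nonzero for the strong gene
  df$fpkm_bait_1[2] <- df$fpkm_bait_1[2] * 1.01
  df$fpkm_control_1[2] <- df$fpkm_control_1[2] + 0.01
  out <- differential_test(df)
  expect_equal(out$p[1], 1)
  expect_lt(out$fdr[2], 0.01)
  expect_error(differential_test(make_records(matrix(1, 2, 1),
                                              matrix(1, 2, 1))),
               "at least 2 replicates")
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  df <- make_records(matrix(runif(9, 5, 10), 3, 3),
                     matrix(runif(9, 5, 10), 3, 3))
  out <- differential_test(df)
  # the implementation must agree with p.adjust on its own p-values
  expect_equal(out$fdr, p.adjust(out$p, "BH"))
  expect_equal(oracle_bh(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH"), c(0.003, 0.03, 0.9))
})

test_that("BH step-up equals the brute-force oracle on random vectors", {
  set.seed(33)
  for (m in c(1, 7, 100, 1000)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("permutation alternative to the t-test works for 4+ replicates", {
  set.seed(8)
  df <- make_records(matrix(runif(20, 5, 10), 5, 4),
                     matrix(runif(20, 5, 10), 5, 4))
  out <- differential_test(df, method = "permutation")
  expect_true(all(out$p >= 1 / choose(8, 4)))
  expect_true(all(out$p <= 1))
  df3 <- make_records(matrix(1, 2, 3), matrix(1, 2, 3))
  expect_error(differential_test(df3, method = "permutation"),
               "at least 4 replicates")
})

test_that("all three enrichment thresholds are strict and individually binding", {
  base <- make_records(matrix(18, 4, 3), matrix(8, 4, 3),
                       counts = matrix(50, 4, 3))
  base$fdr <- 0.001; base$p <- 0.0001
  # gene 1: fold exactly 2 fails; others get fold 4
  base[2:4, grep("fpkm_bait", names(base))] <- 38
  base$fdr[3] <- 0.01                     # exactly at the fdr bound: fails
  base$count_bait_1[4] <- 9               # min count below 10: fails
  out <- classify_enriched(base)
  expect_identical(out$enriched, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$fold_enrichment[1], 2)
  # sum-based count rule rescues gene 4 (9 + 50 + 50 >= 10)
  out2 <- classify_enriched(base, count_rule = "sum")
  expect_true(out2$enriched[4])
})

test_that("category breakdown and preference calls behave as documented", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  rna_type = c("snRNA", "protein_coding", "protein_coding"),
                  enriched = c(TRUE, TRUE, FALSE),
                  fold_enrichment = c(8, 4, 1))
  b <- data.frame(gene_id = c("g1", "g2", "g3"),
                  rna_type = c("snRNA", "protein_coding", "protein_coding"),
                  enriched = c(FALSE, TRUE, TRUE),
                  fold_enrichment = c(2, 8, 4))
  bd <- breakdown_and_preference(a, b)
  g <- bd$genes
  expect_identical(g$category, c("NCBP2-only", "both", "NCBP3-only"))
  # g2: preference ratio exactly 2 -> not preferential (strict)
  expect_equal(g$preference_ratio[2], 2)
  expect_false(g$preferential[2])
  expect_true(g$preferential[3])  # ratio 4 > 2
  # percentages within a category sum to 100
  for (cat in unique(bd$breakdown$category))
    expect_equal(sum(bd$breakdown$percent[bd$breakdown$category == cat]), 100)
  only_b <- bd$breakdown[bd$breakdown$category == "NCBP3-only", ]
  expect_identical(only_b$rna_type, "protein_coding")
  expect_equal(only_b$percent, 100)
  bad <- a; bad$gene_id <- c("x1", "x2", "x3")
  expect_error(breakdown_and_preference(bad, b), "disjoint")
})

test_that("classification is threshold-monotone", {
  set.seed(10)
  sim <- gen_ripseq(n_genes_per_type = 25, seed = 10)
  rec <- differential_test(exclude_contaminant_classes(sim$NCBP2))
  loose <- classify_enriched(rec, min_fold = 1.5, max_fdr = 0.05,
                             min_reads = 5)
  tight1 <- classify_enriched(rec, min_fold = 3, max_fdr = 0.05,
                              min_reads = 5)
  tight2 <- classify_enriched(rec, min_fold = 1.5, max_fdr = 0.001,
                              min_reads = 5)
  tight3 <- classify_enriched(rec, min_fold = 1.5, max_fdr = 0.05,
                              min_reads = 100)
  for (t in list(tight1, tight2, tight3))
    expect_true(all(which(t$enriched) %in% which(loose$enriched)))
})

test_that("generated type structure is recovered at strong enrichment", {
  sim <- gen_ripseq(n_genes_per_type = 30, dispersion = 0.1, seed = 77)
  cls <- function(df)
    classify_enriched(differential_test(exclude_contaminant_classes(df)))
  bd <- breakdown_and_preference(cls(sim$NCBP2), cls(sim$NCBP3))
  g <- bd$genes
  expected <- ifelse(g$rna_type %in% c("snRNA", "lincRNA", "antisense"),
                     "NCBP2-only", "both")
  expect_identical(ifelse(is.na(g$category), "none", g$category), expected)
  # scatter table covers the shared universe with finite log-enrichments
  sc <- enrichment_scatter(cls(sim$NCBP2), cls(sim$NCBP3))
  expect_identical(nrow(sc), nrow(g))
  expect_true(all(is.finite(sc$log2_enrichment_a)))
})

test_that("a null design yields (almost) no enriched calls", {
  sim <- gen_ripseq(types_with_enrichment = list(
    protein_coding = c(NCBP2 = 1, NCBP3 = 1)),
    n_genes_per_type = 200, seed = 19)
  cls <- classify_enriched(differential_test(
    exclude_contaminant_classes(sim$NCBP2)))
  expect_lt(mean(cls$enriched), 0.02)
})

test_that("the generator is a pure function of its seed", {
  a <- gen_ripseq(n_genes_per_type = 10, seed = 5)
  b <- gen_ripseq(n_genes_per_type = 10, seed = 5)
  c <- gen_ripseq(n_genes_per_type = 10, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$NCBP2, c$NCBP2))
})
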