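test_that("probability-weighted aggregation evaluates the stated formula", {
  f <- rbind(c(1, 0), c(3, 0))
  expect_equal(aggregate_patient(f, c(0.5, 0.5)), c(2, 0))
  expect_equal(aggregate_patient(f, c(1, 0)), c(1, 0))
  expect_equal(aggregate_patient(f, c(0.25, 0.75)), c(2.5, 0))
  ## order and probability-scale invariance
  set.seed(4)
  F <- matrix(rnorm(40), 8, 5)
  p <- runif(8)
  base <- aggregate_patient(F, p)
  perm <- sample(8)
  expect_equal(aggregate_patient(F[perm, ], p[perm]), base)
  expect_equal(aggregate_patient(F, 3.7 * p), base)
  ## convex combination: inside the per-coordinate range
  expect_true(all(base >= apply(F, 2, min) - 1e-12 &
                    base <= apply(F, 2, max) + 1e-12))
  expect_warning(out <- aggregate_patient(F, rep(0, 8)), "unweighted mean")
  expect_equal(out, colMeans(F))
  expect_error(aggregate_patient(F[0, , drop = FALSE], numeric(0)), "no patches")
})

make_reps <- function(n = 30, f = 8, seed = 5) {
  set.seed(seed)
  matrix(rnorm(n * f, 5, 2), n, f,
         dimnames = list(sprintf("S%02d", 1:n), NULL))
}

test_that("the gene screen recovers planted pairs and de-duplicates cleanly", {
  reps <- make_reps(40)
  planted <- list(list(gene_id = "geneA", feature_index = 5, target_r = 0.9))
  expr <- generate_expression(reps, 100, planted, seed = 3)
  screen <- correlate_gene_features(expr, reps)
  expect_equal(nrow(screen), 100 * 8)
  hit <- screen[screen$entity == "geneA" & screen$feature == 5, ]
  expect_gt(hit$r, 0.7)
  expect_lt(hit$q, 0.05)
  pairs <- filter_pairs(screen)
  expect_true("geneA" %in% pairs$entity)
  ## a duplicated gene gets identical statistics
  expr2 <- rbind(expr, dup_gene = expr["geneA", ])
  s2 <- correlate_gene_features(expr2, reps)
  a <- s2[s2$entity == "geneA", c("r", "p")]
  b <- s2[s2$entity == "dup_gene", c("r", "p")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  ## subject mismatch names the offenders
  colnames(expr)[1] <- "nobody"
  expect_error(correlate_gene_features(expr, reps), "nobody")
})

test_that("pair filtering applies strict thresholds", {
  res <- data.frame(entity = c("a", "b"), feature = 1:2,
                    r = c(0.71, 0.70), p = c(1e-5, 1e-5),
                    q = c(0.01, 0.01), n = 40)
  kept <- filter_pairs(res)
  expect_equal(kept$entity, "a")
})

test_that("genes are ranked by distinct correlated features", {
  pairs <- data.frame(entity = c("g1", "g1", "g1", "g1", "g2"),
                      feature = c(1, 2, 2, 7, 3))
  rk <- genes_by_feature_count(pairs)
  expect_equal(rk$n_features[rk$entity == "g1"], 3)
  expect_equal(rk$entity[1], "g1")
  expect_equal(nrow(genes_by_feature_count(pairs[0, ])), 0)
  ## lexicographic tie-break
  tie <- data.frame(entity = c("zz", "aa"), feature = c(1, 2))
  expect_equal(genes_by_feature_count(tie)$entity, c("aa", "zz"))
})

test_that("biomarker screen flags planted associations and skips degenerate columns", {
  reps <- make_reps(40)
  clin <- generate_clinical_table(
    40, planted_assoc = list(
      biomarker = list(name = "CRP", feature_index = 2, target_r = 0.8)),
    seed = 6, reps = reps)
  res <- correlate_biomarkers(clin$biomarkers, reps)
  expect_true(res$flagged[res$entity == "CRP" & res$feature == 2])
  expect_true(all(res$n <= 40))
  bio2 <- clin$biomarkers
  bio2$flatline <- 1
  expect_warning(res2 <- correlate_biomarkers(bio2, reps), "constant")
  expect_false("flatline" %in% res2$entity)
  resq <- correlate_biomarkers(clin$biomarkers, reps, adjust = TRUE)
  expect_true("q" %in% names(resq))
  expect_equal(resq$q, benjamini_hochberg(resq$p))
})

test_that("the TAC screen reproduces the exact Mann-Whitney conventions", {
  reps <- matrix(c(4, 5, 6, 1, 2, 3), 6, 1,
                 dimnames = list(sprintf("S%d", 1:6), NULL))
  tac <- data.frame(marker = c(1, 1, 1, 0, 0, 0),
                    row.names = rownames(reps))
  res <- compare_tac(tac, reps, p_max = 0.05)
  expect_equal(res$U, 9)
  expect_equal(res$p, 0.1)
  expect_false(res$flagged)
  single <- data.frame(allpos = rep(1, 6), row.names = rownames(reps))
  expect_warning(res2 <- compare_tac(single, reps), "single class")
  expect_equal(nrow(res2), 0)
})

test_that("null screens are calibrated near their nominal rates", {
  reps <- make_reps(40, f = 30, seed = 9)
  expr <- generate_expression(reps, 400, list(), seed = 10)
  screen <- correlate_gene_features(expr, reps)
  expect_lt(nrow(filter_pairs(screen)) / nrow(screen), 0.001)
  ## raw p<0.01 flags about 1% of null biomarker tests
  set.seed(12)
  null_bio <- as.data.frame(matrix(rnorm(40 * 20), 40,
                                   dimnames = list(rownames(reps),
                                                   paste0("b", 1:20))))
  res <- correlate_biomarkers(null_bio, reps)
  expect_lt(mean(res$flagged), 0.05)
})
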