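test_that("generators are pure functions of their seed", {
  reps <- matrix(rnorm(80, 5, 2), 20, 4,
                 dimnames = list(sprintf("S%d", 1:20), NULL))
  e1 <- generate_expression(reps, 50, seed = 3)
  e2 <- generate_expression(reps, 50, seed = 3)
  expect_identical(e1, e2)
  l1 <- generate_lipidomics(5, seed = 4)
  l2 <- generate_lipidomics(5, seed = 4)
  expect_identical(l1, l2)
  net <- generate_toy_network("parallel_pathways")
  t1 <- generate_transcript_abundances(net, 3, seed = 5)
  t2 <- generate_transcript_abundances(net, 3, seed = 5)
  expect_identical(t1, t2)
  c1 <- generate_clinical_table(6, seed = 6)
  c2 <- generate_clinical_table(6, seed = 6)
  expect_identical(c1, c2)
})

test_that("expression columns are TPM-like and planting is calibrated", {
  set.seed(1)
  reps <- matrix(rnorm(40 * 6, 5, 2), 40, 6,
                 dimnames = list(sprintf("S%02d", 1:40), NULL))
  planted <- list(list(gene_id = "gA", feature_index = 2, target_r = 0.9))
  rs <- vapply(1:20, function(s) {
    M <- generate_expression(reps, 60, planted, seed = s)
    cor(M["gA", ], reps[, 2])
  }, 0)
  expect_true(all(rs > 0.8 & rs < 0.97))
  M <- generate_expression(reps, 60, planted, seed = 1)
  expect_true(all(M >= 0))
  expect_equal(unname(colSums(M)), rep(1e6, 40), tolerance = 1e-6)
  expect_equal(attr(M, "planted")$gene_id, "gA")
  ## near-noiseless limit: correlation approaches 1
  p99 <- list(list(gene_id = "gA", feature_index = 2, target_r = 0.999))
  M2 <- generate_expression(reps, 60, p99, seed = 2)
  expect_gt(cor(M2["gA", ], reps[, 2]), 0.99)
  expect_error(generate_expression(reps, 60,
                                   list(list(gene_id = "g", feature_index = 2,
                                             target_r = 1.2))), "target_r")
  expect_error(generate_expression(reps, 60,
                                   list(list(gene_id = "g", feature_index = 9,
                                             target_r = 0.5))), "feature_index")
})

test_that("transcript abundances encode the planted group directions", {
  net <- generate_toy_network("parallel_pathways")
  pl <- list(list(reaction_id = "R2", group_mean_shift = 4,
                  direction = "up_in_disease"))
  ta <- generate_transcript_abundances(net, 5, pl, noise_cv = 0.2, seed = 2)
  g2 <- c("g2a", "g2b")
  expect_gt(mean(ta$abundances[g2, ta$groups == "disease"]),
            mean(ta$abundances[g2, ta$groups == "control"]))
  expect_true(all(ta$abundances > 0))
  ## zero noise collapses within-group variation
  ta0 <- generate_transcript_abundances(net, 4, pl, noise_cv = 0, seed = 2)
  expect_equal(apply(ta0$abundances[, ta0$groups == "disease"], 1, sd),
               stats::setNames(rep(0, 4), rownames(ta0$abundances)))
  expect_error(generate_transcript_abundances(
    net, 3, list(list(reaction_id = "EX_A", group_mean_shift = 2,
                      direction = "up_in_disease"))), "no gene rule")
  expect_error(generate_transcript_abundances(
    net, 3, list(list(reaction_id = "nope", group_mean_shift = 2,
                      direction = "up_in_disease"))), "not in network")
})

test_that("lipidomics generator plants class shifts with a parsable grammar", {
  lip <- generate_lipidomics(8, planted_shifts = c(PC = 1), seed = 3)
  cls <- parse_lipid_names(rownames(lip$intensities))$lipid_class
  expect_false(any(cls == "unknown"))
  pc <- cls == "PC"
  lm <- log2(lip$intensities)
  expect_gt(mean(lm[pc, lip$groups == "disease"]) -
              mean(lm[pc, lip$groups == "control"]), 0.5)
  ## unshifted classes stay centered
  tg <- cls == "TG"
  expect_lt(abs(mean(lm[tg, lip$groups == "disease"]) -
                  mean(lm[tg, lip$groups == "control"])), 0.5)
  expect_error(generate_lipidomics(5, class_spec = c(PC = 0)), "species")
  expect_error(generate_lipidomics(5, planted_shifts = c(XX = 1)), "unknown class")
})

test_that("clinical tables have the requested shape and guarded TAC columns", {
  ct <- generate_clinical_table(4, seed = 9)
  expect_equal(nrow(ct$biomarkers), 4)
  expect_equal(nrow(ct$tac), 4)
  expect_true(all(unlist(ct$tac) %in% c(0, 1)))
  for (j in seq_len(ncol(ct$tac)))
    expect_gt(length(unique(ct$tac[[j]])), 1)
  expect_error(generate_clinical_table(3), "n")
})
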