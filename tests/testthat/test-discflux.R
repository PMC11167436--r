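fake_samples <- function(subject, group, M) {
  m <- as.matrix(M)
  attr(m, "subject") <- subject
  attr(m, "group") <- group
  class(m) <- c("flux_sample_matrix", class(m))
  m
}

test_that("dataset assembly excludes similar-flow and constant reactions", {
  set.seed(1)
  mk <- function(subject, group, shift) {
    M <- cbind(planted = rnorm(30, shift), noisy = rnorm(30),
               const = rep(2, 30))
    fake_samples(subject, group, M)
  }
  ds <- assemble_dataset(list(mk("d1", "disease", 5), mk("d2", "disease", 5),
                              mk("c1", "control", 0), mk("c2", "control", 0)))
  expect_true("planted" %in% colnames(ds$matrix))
  expect_true("const" %in% ds$excluded$reaction)
  expect_equal(ds$excluded$reason[ds$excluded$reaction == "const"], "constant")
  ## identical multiset case
  v <- rnorm(10)
  same <- function(subject, group)
    fake_samples(subject, group, cbind(mirror = v, keepme = rnorm(10, ifelse(group == "disease", 3, 0))))
  ds2 <- assemble_dataset(list(same("d1", "disease"), same("c1", "control"),
                               same("d2", "disease"), same("c2", "control")))
  expect_true("mirror" %in% ds2$excluded$reaction)
  ## disjoint reaction sets fail loudly
  a <- fake_samples("d1", "disease", cbind(x = rnorm(5)))
  b <- fake_samples("c1", "control", cbind(y = rnorm(5)))
  c2 <- fake_samples("d2", "disease", cbind(x = rnorm(5)))
  d2 <- fake_samples("c2", "control", cbind(y = rnorm(5)))
  expect_error(assemble_dataset(list(a, c2, b, d2)), "intersection")
})

test_that("planted group differences are recovered by the RF procedure", {
  net <- generate_toy_network("coupled_pathways", list(n_units = 3))
  ta <- generate_transcript_abundances(net, 4, coupled_planted(), noise_cv = 0.2,
                                       seed = 31)
  mats <- sample_cohort_fluxes(net, ta, n_samples = 50, seed = 31)
  ds <- assemble_dataset(mats)
  rep <- rf_classify_splits(ds, n_splits = 40, seed = 8)
  expect_gte(median(rep$splits$accuracy), 0.9)
  top <- extract_top_reactions(rep)
  expect_true(all(sprintf("R%d_hi", 1:3) %in% top$reaction))
  ## determinism of the split procedure
  rep2 <- rf_classify_splits(ds, n_splits = 40, seed = 8)
  expect_identical(rep$splits, rep2$splits)
})

test_that("permuted labels give chance-level accuracy", {
  net <- generate_toy_network("coupled_pathways", list(n_units = 3))
  ta <- generate_transcript_abundances(net, 4, coupled_planted(), noise_cv = 0.2,
                                       seed = 32)
  mats <- sample_cohort_fluxes(net, ta, n_samples = 50, seed = 32)
  ds <- assemble_dataset(mats)
  set.seed(77)
  ds$labels$group <- sample(ds$labels$group)
  rep <- rf_classify_splits(ds, n_splits = 30, seed = 9)
  med <- median(rep$splits$accuracy)
  n_test <- round(0.2 * nrow(ds$matrix))
  ci_half <- 1.96 * sqrt(0.25 / n_test)
  expect_gt(med, 0.5 - ci_half - 0.05)
  expect_lt(med, 0.5 + ci_half + 0.05)
})

test_that("top-reaction aggregation honors the accuracy gate and tie rules", {
  mk_rep <- function(acc, tops) {
    structure(list(
      splits = data.frame(split = seq_along(acc), accuracy = acc),
      top = lapply(tops, function(t)
        data.frame(reaction = t, importance = rev(seq_along(t)),
                   rank = seq_along(t))),
      top_k = 3), class = "discriminative_report")
  }
  ## all splits below the gate: empty with a warning
  r1 <- mk_rep(c(0.55, 0.55), list(c("a", "b", "c"), c("a", "b", "c")))
  expect_warning(out1 <- extract_top_reactions(r1), "threshold")
  expect_equal(nrow(out1), 0)
  ## strict inequality at the boundary
  r2 <- mk_rep(c(0.60, 0.9), list(c("a", "b", "c"), c("x", "y", "z")))
  out2 <- extract_top_reactions(r2)
  expect_setequal(out2$reaction, c("x", "y", "z"))
  ## equal counts broken by median rank, then id
  r3 <- mk_rep(c(0.9, 0.9), list(c("a", "b", "c"), c("b", "a", "c")))
  out3 <- extract_top_reactions(r3, top_k = 3)
  expect_equal(out3$reaction[1:2], c("a", "b"))
  ## invariance to split ordering
  r4 <- mk_rep(c(0.9, 0.55), list(c("a", "b", "c"), c("x", "y", "z")))
  r5 <- mk_rep(c(0.55, 0.9), list(c("x", "y", "z"), c("a", "b", "c")))
  expect_equal(extract_top_reactions(r4), extract_top_reactions(r5))
})

test_that("group comparison reports exact p-values and medians", {
  M <- rbind(matrix(c(4, 5, 6), 3, 1), matrix(c(1, 2, 3), 3, 1))
  colnames(M) <- "rx"
  ds <- list(matrix = M,
             labels = data.frame(subject = c("d1", "d1", "d2", "c1", "c1", "c2"),
                                 group = rep(c("disease", "control"), each = 3)))
  class(ds) <- "flux_dataset"
  cg <- compare_groups(ds, "rx")
  expect_equal(cg$p, 0.1)
  expect_equal(unname(cg$medians), c(5, 2))
  expect_error(compare_groups(ds, "nope"), "not in the dataset")
})

test_that("subsystem grouping applies the fallback labels", {
  net <- generate_toy_network("coupled_pathways", list(n_units = 3))
  fams <- group_by_subsystem(c("R1_hi", "R1_lo", "EX_P", "ghost"), net)
  expect_equal(sum(fams$family == "pathway_1"), 2)
  expect_equal(fams$family[fams$reaction == "EX_P"], "exchange/demand")
  expect_equal(fams$family[fams$reaction == "ghost"], "unannotated")
})
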