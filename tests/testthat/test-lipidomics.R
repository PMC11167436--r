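test_that("lipid name parsing follows the grammar with a safe fallback", {
  p <- parse_lipid_name("PC(34:2)")
  expect_equal(p$lipid_class, "PC")
  expect_equal(p$total_carbons, 34)
  expect_equal(p$total_double_bonds, 2)
  expect_false(p$ether_linked)
  p2 <- parse_lipid_name("LPC(O-18:1)")
  expect_true(p2$ether_linked)
  expect_equal(p2$lipid_class, "LPC")
  expect_equal(p2$total_carbons, 18)
  p3 <- parse_lipid_name("SM 34:1")
  expect_equal(p3$lipid_class, "SM")
  expect_warning(p4 <- parse_lipid_name("glycocholic acid"), "unparseable")
  expect_equal(p4$lipid_class, "unknown")
})

test_that("normalization removes global per-sample scale factors", {
  set.seed(2)
  base <- matrix(rlnorm(40, log(1e4), 1), 10, 4,
                 dimnames = list(paste0("sp", 1:10), paste0("s", 1:4)))
  doubled <- base
  doubled[, 2] <- base[, 2] * 2
  n1 <- normalize_intensities(base)
  n2 <- normalize_intensities(doubled)
  ## a global 2x factor is absorbed by median centering (up to the
  ## pseudocount, negligible at these intensities)
  expect_equal(n1[, 2], n2[, 2], tolerance = 1e-3)
  ## constant table centers to zero
  const <- matrix(100, 4, 3, dimnames = list(paste0("sp", 1:4), paste0("s", 1:3)))
  expect_equal(unname(normalize_intensities(const)),
               matrix(0, 4, 3), ignore_attr = TRUE)
  ## pseudocount maps zero intensity to zero log
  z <- matrix(c(0, 7), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(log2(z + 1))[1], 0)
  expect_error(normalize_intensities(
    matrix(0, 2, 1, dimnames = list(c("a", "b"), "bad_sample"))), "bad_sample")
})

test_that("fold changes are antisymmetric and rank the planted class first", {
  lip <- generate_lipidomics(10, planted_shifts = c(PC = 1), seed = 6)
  norm <- normalize_intensities(lip$intensities)
  fc <- fold_changes(norm, lip$groups)
  cls <- parse_lipid_names(fc$species)$lipid_class
  expect_equal(mean(fc$logFC[cls == "PC"]), 1, tolerance = 0.35)
  swapped <- ifelse(lip$groups == "disease", "control", "disease")
  names(swapped) <- names(lip$groups)
  fc2 <- fold_changes(norm, swapped)
  m <- match(fc$species, fc2$species)
  expect_equal(fc2$logFC[m], -fc$logFC, tolerance = 1e-12)
  expect_equal(fc2$p[m], fc$p, tolerance = 1e-12)
})

test_that("LSEA detects the planted class and respects the p floor", {
  lip <- generate_lipidomics(10, planted_shifts = c(PC = 1), seed = 7)
  fc <- fold_changes(normalize_intensities(lip$intensities), lip$groups)
  enr <- lsea(fc, n_permutations = 500, seed = 1)
  pc <- enr[enr$lipid_class == "PC", ]
  expect_equal(pc$direction, "up")
  expect_lt(pc$p_permutation, 0.05)
  expect_true(all(enr$p_permutation >= 1 / 501))
  expect_true(all((enr$enrichment_score >= 0) == (enr$direction == "up")))
})

test_that("LSEA is invariant to monotone rescaling of the fold changes", {
  lip <- generate_lipidomics(8, planted_shifts = c(SM = -1), seed = 8)
  fc <- fold_changes(normalize_intensities(lip$intensities), lip$groups)
  e1 <- lsea(fc, n_permutations = 200, seed = 5)
  fc2 <- fc
  fc2$logFC <- fc2$logFC * 3.5
  e2 <- lsea(fc2, n_permutations = 200, seed = 5)
  expect_equal(e1$p_permutation, e2$p_permutation)
  expect_equal(e1$enrichment_score, e2$enrichment_score, tolerance = 1e-12)
  expect_equal(e1$direction, e2$direction)
})

test_that("the enrichment score matches the fgsea statistic", {
  skip_if_not_installed("fgsea")
  set.seed(9)
  n <- 60
  lfc <- sort(rnorm(n), decreasing = TRUE)
  member <- seq_len(n) %in% sample(n, 12)
  got <- eedomics:::es_score(abs(lfc), member)
  ## fgsea ranks by decreasing stat with weights |stat|^1
  ref <- fgsea::calcGseaStat(lfc, selectedStats = which(member),
                             gseaParam = 1, scoreType = "std")
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("small or all-covering classes are handled explicitly", {
  fc <- data.frame(species = sprintf("PC(%d:0)", 30:39),
                   logFC = rnorm(10), p = runif(10))
  fc <- fc[order(-fc$logFC), ]
  expect_warning(out <- lsea(fc, class_sets = list(tiny = fc$species[1:2]),
                             n_permutations = 50, seed = 1), "fewer than 3")
  expect_equal(nrow(out), 0)
  expect_error(lsea(fc, class_sets = list(all = fc$species),
                    n_permutations = 50, seed = 1), "entire ranked list")
})

test_that("PCA explained variance matches the covariance eigenvalues", {
  set.seed(10)
  X <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(paste0("sp", 1:15), paste0("s", 1:8)))
  pc <- lipid_pca(X)
  ev <- eigen(cov(t(X)), symmetric = TRUE)$values
  expect_equal(pc$explained_variance, ev[seq_along(pc$explained_variance)] / sum(ev),
               tolerance = 1e-10)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  ## rank-1 structure: first component explains everything
  prof <- rnorm(15)
  R1 <- outer(prof, 1:6) + 5
  rownames(R1) <- paste0("sp", 1:15); colnames(R1) <- paste0("s", 1:6)
  expect_gte(lipid_pca(R1)$explained_variance[1], 0.999)
  ## rotating the species axes leaves the explained-variance spectrum alone
  Q <- qr.Q(qr(matrix(rnorm(225), 15, 15)))
  XQ <- Q %*% X
  dimnames(XQ) <- dimnames(X)
  expect_equal(lipid_pca(XQ)$explained_variance, pc$explained_variance,
               tolerance = 1e-8)
})
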