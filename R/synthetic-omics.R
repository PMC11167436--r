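## Synthetic omics generators with planted, machine-readable ground truth.
## Every generator is a pure function of (arguments, seed); per-stream
## seeds are derived with substream_seed() so streams stay uncoupled.

#' Generate a TPM-like expression matrix with planted feature correlations
#'
#' Planted genes are linear functions of one patient-level tissue feature
#' plus Gaussian noise calibrated analytically so the expected sample
#' correlation equals `target_r` (noise sd `= sd(x) * sqrt(1/r^2 - 1)`).
#' Non-planted genes are independent noise. Each gene is shifted so its
#' minimum is zero (a location shift, which leaves correlations intact),
#' negatives are clipped, and columns are renormalized to sum to
#' `tpm_total`.
#'
#' @param patient_reps numeric matrix, patients x N features, rownames =
#'   subject ids.
#' @param n_genes total number of genes (>= number of planted genes).
#' @param planted list of planted correlations, each a list with
#'   `gene_id`, `feature_index` (1-based), `target_r` in (-1, 1).
#' @param noise_sd sd of the non-planted background genes.
#' @param seed integer seed.
#' @param tpm_total the per-sample total (default 1e6).
#' @return genes x patients matrix with attribute `planted` (a data.frame
#'   of the planted ground truth).
#' @export
generate_expression <- function(patient_reps, n_genes, planted = list(),
                                noise_sd = 1, seed = 1, tpm_total = 1e6) {
  n_genes <- check_count(n_genes, "n_genes")
  if (noise_sd <= 0) stop_invalid("noise_sd must be positive")
  n_sub <- nrow(patient_reps)
  nfeat <- ncol(patient_reps)
  for (p in planted) {
    if (abs(p$target_r) >= 1 || p$target_r == 0)
      stop_invalid("target_r must be in (-1, 1) and nonzero (gene %s)", p$gene_id)
    if (p$feature_index < 1 || p$feature_index > nfeat)
      stop_invalid("feature_index %d out of range [1, %d]", p$feature_index, nfeat)
  }
  if (length(planted) > n_genes)
    stop_invalid("n_genes smaller than the number of planted genes")
  planted_ids <- vapply(planted, function(p) p$gene_id, "")
  if (anyDuplicated(planted_ids)) stop_invalid("duplicate planted gene ids")
  gene_ids <- c(planted_ids,
                sprintf("gene%05d", seq_len(n_genes - length(planted))))
  with_seed(substream_seed(seed, 1L), {
    M <- matrix(stats::rnorm(n_genes * n_sub, mean = 5, sd = noise_sd),
                n_genes, n_sub, dimnames = list(gene_ids, rownames(patient_reps)))
    for (k in seq_along(planted)) {
      p <- planted[[k]]
      x <- patient_reps[, p$feature_index]
      sx <- stats::sd(x)
      if (sx == 0) stop_invalid("feature %d has zero variance", p$feature_index)
      a <- sign(p$target_r)
      sn <- sx * sqrt(1 / p$target_r^2 - 1)
      M[k, ] <- a * x + stats::rnorm(n_sub, 0, sn)
    }
    M <- M - apply(M, 1, min)        # per-gene shift to zero minimum
    M[M < 0] <- 0
    cs <- colSums(M)
    if (any(cs == 0)) stop_invalid("degenerate sample with zero total expression")
    M <- sweep(M, 2, cs, "/") * tpm_total
    attr(M, "planted") <- if (length(planted)) data.frame(
      gene_id = planted_ids,
      feature_index = vapply(planted, function(p) as.integer(p$feature_index), 1L),
      target_r = vapply(planted, function(p) p$target_r, 0),
      stringsAsFactors = FALSE) else
        data.frame(gene_id = character(0), feature_index = integer(0),
                   target_r = numeric(0))
    M
  })
}

#' Generate per-subject transcript abundances for a metabolic network
#'
#' Produces log-normal gene abundances for every gene in the network's
#' GPR rules, with the genes of planted reactions shifted between groups
#' in the stated direction: `group_mean_shift` acts as a fold change
#' applied symmetrically (for `up_in_disease` the disease group mean is
#' multiplied by it and the control group mean divided by it;
#' `down_in_disease` reverses the roles), so the stated group contrast is
#' the square of the shift.
#'
#' @param network a `metabolic_network`.
#' @param n_per_group subjects per group.
#' @param planted list of planted flux differences, each a list with
#'   `reaction_id`, `group_mean_shift` (> 1), and `direction`
#'   (`"up_in_disease"` or `"down_in_disease"`).
#' @param noise_cv coefficient of variation of the log-normal noise
#'   (0 gives identical within-group abundances).
#' @param seed integer seed.
#' @param base_mean baseline mean abundance (TPM-like), default 10.
#' @return list with `abundances` (genes x subjects matrix), `groups`
#'   (named character vector), and `planted` (data.frame ground truth).
#' @export
generate_transcript_abundances <- function(network, n_per_group, planted = list(),
                                           noise_cv = 0.2, seed = 1,
                                           base_mean = 10) {
  n_per_group <- check_count(n_per_group, "n_per_group")
  if (noise_cv < 0) stop_invalid("noise_cv must be >= 0")
  genes <- network_genes(network)
  if (length(genes) == 0L) stop_invalid("network has no gene associations")
  rx <- network$reactions
  for (p in planted) {
    if (!p$reaction_id %in% rx$id)
      stop_invalid("planted reaction %s not in network", p$reaction_id)
    g <- rx$gpr[rx$id == p$reaction_id]
    if (!nzchar(g))
      stop_invalid("planted reaction %s has no gene rule", p$reaction_id)
    if (is.null(p$group_mean_shift) || p$group_mean_shift <= 1)
      stop_invalid("group_mean_shift must exceed 1 (reaction %s)", p$reaction_id)
    if (!p$direction %in% c("up_in_disease", "down_in_disease"))
      stop_invalid("unknown direction '%s'", p$direction)
  }
  subjects <- c(sprintf("D%02d", seq_len(n_per_group)),
                sprintf("C%02d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("disease", "control"), each = n_per_group),
                            subjects)
  mean_mat <- matrix(base_mean, length(genes), length(subjects),
                     dimnames = list(genes, subjects))
  for (p in planted) {
    pg <- gpr_genes(gpr_parse(rx$gpr[rx$id == p$reaction_id]))
    fac <- if (p$direction == "up_in_disease") p$group_mean_shift else
      1 / p$group_mean_shift
    mean_mat[pg, groups == "disease"] <- base_mean * fac
    mean_mat[pg, groups == "control"] <- base_mean / fac
  }
  with_seed(substream_seed(seed, 2L), {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      ab <- mean_mat * matrix(
        stats::rlnorm(length(mean_mat), meanlog = -sdlog^2 / 2, sdlog = sdlog),
        nrow(mean_mat))
      dimnames(ab) <- dimnames(mean_mat)
    } else ab <- mean_mat
    list(abundances = ab, groups = groups,
         planted = if (length(planted)) data.frame(
           reaction_id = vapply(planted, function(p) p$reaction_id, ""),
           group_mean_shift = vapply(planted, function(p) p$group_mean_shift, 0),
           direction = vapply(planted, function(p) p$direction, ""),
           stringsAsFactors = FALSE) else
             data.frame(reaction_id = character(0),
                        group_mean_shift = numeric(0), direction = character(0)))
  })
}

#' Generate a synthetic lipidomics intensity table
#'
#' Log-normal species intensities with optional planted per-class log2
#' fold changes in the disease group. Species names follow the
#' `CLASS(C:D)` grammar (with `O-`/`P-` ether prefixes for a fraction of
#' the glycerophospholipids) parsed by [parse_lipid_name()].
#'
#' @param n_per_group samples per group.
#' @param class_spec named integer vector: lipid class -> species count.
#' @param planted_shifts named numeric vector: class -> log2 fold change
#'   applied to the disease group.
#' @param seed integer seed.
#' @param cv log-normal coefficient of variation (default 0.4).
#' @return list with `intensities` (species x samples matrix), `groups`
#'   (named character), `species` (parsed species table), and
#'   `planted_shifts`.
#' @export
generate_lipidomics <- function(n_per_group = 10,
                                class_spec = c(PC = 12, LPC = 8, PE = 10,
                                               TG = 12, SM = 8, CE = 6),
                                planted_shifts = c(), seed = 1, cv = 0.4) {
  n_per_group <- check_count(n_per_group, "n_per_group")
  if (any(class_spec < 1)) stop_invalid("every lipid class needs >= 1 species")
  bad <- setdiff(names(planted_shifts), names(class_spec))
  if (length(bad)) stop_invalid("planted shift for unknown class: %s",
                                paste(bad, collapse = ", "))
  ether_classes <- c("PC", "LPC", "PE", "PI", "PS")
  with_seed(substream_seed(seed, 3L), {
    species <- character(0)
    for (cl in names(class_spec)) {
      k <- class_spec[[cl]]
      carbons <- if (cl %in% c("TG")) sample(44:58, k, replace = TRUE) else
        if (cl %in% c("LPC")) sample(14:22, k, replace = TRUE) else
          sample(30:40, k, replace = TRUE)
      dbs <- sample(0:6, k, replace = TRUE)
      ether <- (cl %in% ether_classes) & (stats::runif(k) < 0.2)
      nm <- ifelse(ether,
                   sprintf("%s(O-%d:%d)", cl, carbons, dbs),
                   sprintf("%s(%d:%d)", cl, carbons, dbs))
      ## de-duplicate within class
      while (anyDuplicated(nm)) {
        d <- duplicated(nm)
        carbons[d] <- carbons[d] + 1L
        nm <- ifelse(ether, sprintf("%s(O-%d:%d)", cl, carbons, dbs),
                     sprintf("%s(%d:%d)", cl, carbons, dbs))
      }
      species <- c(species, nm)
    }
    classes <- rep(names(class_spec), class_spec)
    samples <- c(sprintf("D%02d", seq_len(n_per_group)),
                 sprintf("C%02d", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("disease", "control"), each = n_per_group),
                              samples)
    base <- stats::rlnorm(length(species), meanlog = log(1e5), sdlog = 0.8)
    sdlog <- sqrt(log(1 + cv^2))
    M <- base * matrix(stats::rlnorm(length(species) * length(samples),
                                     meanlog = -sdlog^2 / 2, sdlog = sdlog),
                       length(species), length(samples))
    dimnames(M) <- list(species, samples)
    for (cl in names(planted_shifts))
      M[classes == cl, groups == "disease"] <-
        M[classes == cl, groups == "disease"] * 2^planted_shifts[[cl]]
    list(intensities = M, groups = groups,
         species = data.frame(name = species, lipid_class = classes,
                              stringsAsFactors = FALSE),
         planted_shifts = planted_shifts)
  })
}

#' Generate synthetic clinical biomarker and stool TAC tables
#'
#' Continuous biomarker columns (log-normal, loosely modeled on systemic
#' inflammation panels) with an optional planted correlation to a
#' designated tissue feature, and binary enteropathogen-card (TAC)
#' columns with an optional planted separation along a feature.
#'
#' @param n number of subjects (>= 4).
#' @param planted_assoc optional list with elements `biomarker`
#'   (list(name, feature_index, target_r)) and/or `tac`
#'   (list(name, feature_index, flip_rate)).
#' @param seed integer seed.
#' @param reps optional patients x N feature matrix required when
#'   planting associations.
#' @param missing_rate fraction of biomarker entries set missing
#'   (default 0.05), emulating variable per-assay availability.
#' @return list with `biomarkers` (data.frame, subjects x assays),
#'   `tac` (data.frame of 0/1), `groups` = NULL, and `planted`.
#' @export
generate_clinical_table <- function(n, planted_assoc = NULL, seed = 1,
                                    reps = NULL, missing_rate = 0.05) {
  n <- check_count(n, "n", min = 4L)
  if (!is.null(planted_assoc) && is.null(reps))
    stop_invalid("planting clinical associations requires `reps`")
  if (!is.null(reps) && nrow(reps) != n)
    stop_invalid("`reps` must have %d rows", n)
  assays <- c("CRP", "AGP", "LPS", "ferritin", "hemoglobin", "albumin")
  pathogens <- c("EAEC", "Giardia", "Campylobacter", "Norovirus")
  with_seed(substream_seed(seed, 4L), {
    B <- sapply(assays, function(a) stats::rlnorm(n, log(10), 0.5))
    rownames(B) <- if (!is.null(reps)) rownames(reps) else sprintf("S%02d", seq_len(n))
    if (!is.null(planted_assoc$biomarker)) {
      pb <- planted_assoc$biomarker
      x <- reps[, pb$feature_index]
      sn <- stats::sd(x) * sqrt(1 / pb$target_r^2 - 1)
      B[, pb$name] <- sign(pb$target_r) * x + stats::rnorm(n, 0, sn)
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(length(B)) < missing_rate, nrow(B))
      ## never blank out a full column
      for (j in seq_len(ncol(B))) if (sum(!miss[, j]) < 3) miss[, j] <- FALSE
      B[miss] <- NA
    }
    TAC <- sapply(pathogens, function(p) as.integer(stats::runif(n) < 0.35))
    rownames(TAC) <- rownames(B)
    if (!is.null(planted_assoc$tac)) {
      pt <- planted_assoc$tac
      x <- reps[, pt$feature_index]
      pos <- as.integer(x > stats::median(x))
      flip <- stats::runif(n) < (pt$flip_rate %||% 0.1)
      TAC[, pt$name] <- ifelse(flip, 1L - pos, pos)
    }
    ## guarantee both classes present in every TAC column
    for (j in seq_len(ncol(TAC))) {
      if (all(TAC[, j] == TAC[1, j])) TAC[sample.int(n, 1), j] <- 1L - TAC[1, j]
    }
    list(biomarkers = as.data.frame(B), tac = as.data.frame(TAC),
         planted = planted_assoc)
  })
}
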