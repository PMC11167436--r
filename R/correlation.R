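## Patient-level feature aggregation and the feature x gene /
## feature x biomarker / feature x TAC screens.

#' Probability-weighted aggregation of patch features
#'
#' `vector = sum(p_i * f_i) / sum(p_i)` with `p_i` the disease-class
#' probability of patch i, emphasizing the most severely scored patches.
#' If all probabilities are zero the unweighted mean is used with a
#' warning. The result is a convex combination of the patch vectors and
#' is invariant to patch order and to uniform positive scaling of the
#' probabilities.
#'
#' @param features list of per-patch feature vectors (equal length), or a
#'   patches x N matrix.
#' @param probabilities numeric vector of disease probabilities, one per
#'   patch.
#' @return the aggregated feature vector.
#' @export
aggregate_patient <- function(features, probabilities) {
  if (is.list(features)) features <- do.call(rbind, features)
  if (nrow(features) == 0L) stop_invalid("no patches to aggregate")
  if (length(probabilities) != nrow(features))
    stop_invalid("one probability per patch required")
  if (any(!is.finite(probabilities)) || any(probabilities < 0))
    stop_invalid("probabilities must be finite and >= 0")
  tot <- sum(probabilities)
  if (tot == 0) {
    warning("all disease probabilities zero; falling back to unweighted mean")
    return(colMeans(features))
  }
  as.numeric(crossprod(features, probabilities) / tot)
}

#' Patient-level tissue feature representations for a cohort
#'
#' Runs the trained model over every retained patch of every slide,
#' aggregates patches to each slide by disease-probability weighting, and
#' slides to the patient by unweighted mean.
#'
#' @param model a trained `histo_model`.
#' @param slides list of `slide_image`s.
#' @param patch_size,tissue_threshold passed to [extract_patches()].
#' @return subjects x F matrix of patient representations, with an
#'   attribute `n_patches` (named count per subject).
#' @export
patient_representations <- function(model, slides, patch_size = 64,
                                    tissue_threshold = 0.5) {
  per_slide <- list(); slide_subject <- character(0)
  for (s in slides) {
    patches <- extract_patches(s, patch_size, tissue_threshold)
    if (length(patches) == 0L) next
    fs <- lapply(patches, function(p) extract_features(model, p$pixels))
    F <- do.call(rbind, lapply(fs, function(f) f$vector))
    pr <- vapply(fs, function(f) f$disease_probability, 0)
    per_slide[[length(per_slide) + 1L]] <- aggregate_patient(F, pr)
    slide_subject <- c(slide_subject, s$subject_id)
    attr(per_slide[[length(per_slide)]], "n") <- length(patches)
  }
  subjects <- unique(slide_subject)
  reps <- t(vapply(subjects, function(sj) {
    colMeans(do.call(rbind, per_slide[slide_subject == sj]))
  }, numeric(length(per_slide[[1]]))))
  rownames(reps) <- subjects
  attr(reps, "n_patches") <- stats::setNames(
    vapply(subjects, function(sj)
      sum(vapply(per_slide[slide_subject == sj],
                 function(x) attr(x, "n"), 0L)), 0L), subjects)
  reps
}

#' Genome-wide feature-gene correlation screen
#'
#' Pearson correlation of every gene against every patient-level feature;
#' q-values are Benjamini-Hochberg over the full gene x feature family.
#'
#' @param expression genes x patients matrix (TPM-like), colnames =
#'   subject ids.
#' @param reps patients x N representation matrix, rownames = subject ids.
#' @return data.frame (entity, feature, r, p, q, n), one row per pair.
#' @export
correlate_gene_features <- function(expression, reps) {
  if (is.null(colnames(expression)) || is.null(rownames(reps)))
    stop_invalid("expression columns and reps rows must carry subject ids")
  if (!setequal(colnames(expression), rownames(reps)))
    stop_invalid("subject mismatch; offenders: %s",
                 paste(union(setdiff(colnames(expression), rownames(reps)),
                             setdiff(rownames(reps), colnames(expression))),
                       collapse = ", "))
  expression <- expression[, rownames(reps), drop = FALSE]
  if (nrow(reps) < 3L) stop_invalid("need >= 3 subjects")
  res <- pearson_matrix(t(expression), reps)
  genes <- rownames(expression) %||% sprintf("gene%d", seq_len(nrow(expression)))
  out <- data.frame(
    entity = rep(genes, times = ncol(reps)),
    feature = rep(seq_len(ncol(reps)), each = nrow(expression)),
    r = as.numeric(res$r), p = as.numeric(res$p), n = res$n,
    stringsAsFactors = FALSE)
  ## constant genes (possible after TPM clipping) yield NA r: drop with note
  bad <- is.na(out$r)
  if (any(bad)) out <- out[!bad, , drop = FALSE]
  out$q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out[, c("entity", "feature", "r", "p", "q", "n")]
}

#' Filter screen results to significant pairs
#'
#' Keeps pairs with `r > r_min` AND `q < q_max` (both strict).
#'
#' @param results data.frame from [correlate_gene_features()].
#' @param r_min correlation threshold (default 0.7).
#' @param q_max FDR threshold (default 0.05).
#' @return the filtered data.frame.
#' @export
filter_pairs <- function(results, r_min = 0.7, q_max = 0.05) {
  out <- results[results$r > r_min & results$q < q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by the number of features they correlate with
#'
#' @param pairs filtered pairs from [filter_pairs()].
#' @return data.frame (entity, n_features) sorted by descending count,
#'   ties broken lexicographically by gene id.
#' @export
genes_by_feature_count <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(entity = character(0), n_features = integer(0)))
  counts <- tapply(pairs$feature, pairs$entity, function(f) length(unique(f)))
  out <- data.frame(entity = names(counts), n_features = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_features, out$entity), ]
  rownames(out) <- NULL
  out
}

#' Feature-biomarker correlation screen
#'
#' Pearson correlation of every continuous biomarker against every
#' feature, with pairwise deletion of missing values and per-test n.
#' Pairs with `p < p_max` are flagged. Constant or all-missing columns
#' are skipped with a warning.
#'
#' @param biomarkers data.frame or matrix, subjects x assays (may contain
#'   NA), rownames = subject ids.
#' @param reps patients x N representation matrix.
#' @param p_max flagging threshold (default 0.01, applied to raw p).
#' @param adjust if TRUE, additionally report Benjamini-Hochberg
#'   q-values over all biomarker x feature tests (the screen is defined
#'   on raw p; the adjustment is informational).
#' @return data.frame (entity, feature, r, p, n, flagged; plus q when
#'   `adjust`).
#' @export
correlate_biomarkers <- function(biomarkers, reps, p_max = 0.01,
                                 adjust = FALSE) {
  biomarkers <- as.matrix(biomarkers)
  if (!is.null(rownames(biomarkers)) && !is.null(rownames(reps)))
    biomarkers <- biomarkers[rownames(reps), , drop = FALSE]
  out <- list()
  for (a in colnames(biomarkers)) {
    x <- biomarkers[, a]
    ok <- is.finite(x)
    if (sum(ok) < 3L) { warning(sprintf("biomarker %s: < 3 values, skipped", a)); next }
    if (stats::sd(x[ok]) == 0) { warning(sprintf("biomarker %s: constant, skipped", a)); next }
    for (f in seq_len(ncol(reps))) {
      y <- reps[, f]
      use <- ok & is.finite(y)
      if (sum(use) < 3L || stats::sd(y[use]) == 0) next
      pe <- pearson(x[use], y[use])
      out[[length(out) + 1L]] <- data.frame(
        entity = a, feature = f, r = pe$r, p = pe$p, n = pe$n,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(entity = character(0), feature = integer(0), r = numeric(0),
               p = numeric(0), n = integer(0))
  res$flagged <- res$p < p_max
  if (adjust && nrow(res)) res$q <- benjamini_hochberg(res$p)
  rownames(res) <- NULL
  res
}

#' Feature-TAC comparison screen (Mann-Whitney)
#'
#' For each binary enteropathogen marker, compares every feature's values
#' between positive and negative subjects by the two-sided Mann-Whitney U
#' test; `U` counts (positive, negative) pairs where the positive
#' subject's feature value is larger. Markers without both classes are
#' skipped with a warning.
#'
#' @param tac data.frame or matrix of 0/1, subjects x markers.
#' @param reps patients x N representation matrix.
#' @param p_max flagging threshold (default 0.05).
#' @return data.frame (entity, feature, U, p, n, flagged).
#' @export
compare_tac <- function(tac, reps, p_max = 0.05) {
  tac <- as.matrix(tac)
  if (!is.null(rownames(tac)) && !is.null(rownames(reps)))
    tac <- tac[rownames(reps), , drop = FALSE]
  out <- list()
  for (a in colnames(tac)) {
    g <- tac[, a]
    if (length(unique(g[is.finite(g)])) < 2L) {
      warning(sprintf("TAC marker %s: single class, skipped", a)); next
    }
    for (f in seq_len(ncol(reps))) {
      y <- reps[, f]
      mw <- mann_whitney(y[g == 1], y[g == 0])
      out[[length(out) + 1L]] <- data.frame(
        entity = a, feature = f, U = mw$U, p = mw$p, n = mw$n1 + mw$n2,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(entity = character(0), feature = integer(0), U = numeric(0),
               p = numeric(0), n = integer(0))
  res$flagged <- res$p < p_max
  rownames(res) <- NULL
  res
}
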