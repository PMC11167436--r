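## Lipidomics: species-name parsing, normalization, per-species fold
## changes, permutation-based lipid set enrichment (GSEA-style weighted
## Kolmogorov-Smirnov statistic), and PCA.

#' Parse a lipid species name
#'
#' Recognizes `CLASS(C:D)` and `CLASS C:D`, with optional ether prefixes
#' `O-`/`P-` before the carbon count (e.g. `"LPC(O-18:1)"`). Names
#' outside the grammar yield class `"unknown"` with a warning; the
#' function never fails.
#'
#' @param name species name text.
#' @return list with `raw_name`, `lipid_class`, `ether_linked`,
#'   `total_carbons`, `total_double_bonds` (the last two NA when
#'   unparsed).
#' @export
parse_lipid_name <- function(name) {
  m <- regmatches(name, regexec(
    "^([A-Za-z][A-Za-z0-9]*)[ (]+([OP]-)?([0-9]+):([0-9]+)\\)?$", name))[[1]]
  if (length(m) == 0L) {
    warning(sprintf("unparseable lipid name '%s'", name))
    return(list(raw_name = name, lipid_class = "unknown", ether_linked = FALSE,
                total_carbons = NA_integer_, total_double_bonds = NA_integer_))
  }
  list(raw_name = name, lipid_class = m[2], ether_linked = nzchar(m[3]),
       total_carbons = as.integer(m[4]), total_double_bonds = as.integer(m[5]))
}

#' Parse many lipid names into a species table
#' @param names character vector of species names.
#' @return data.frame (raw_name, lipid_class, ether_linked,
#'   total_carbons, total_double_bonds).
#' @export
parse_lipid_names <- function(names) {
  rows <- lapply(names, parse_lipid_name)
  data.frame(raw_name = vapply(rows, `[[`, "", "raw_name"),
             lipid_class = vapply(rows, `[[`, "", "lipid_class"),
             ether_linked = vapply(rows, `[[`, TRUE, "ether_linked"),
             total_carbons = vapply(rows, `[[`, 1L, "total_carbons"),
             total_double_bonds = vapply(rows, `[[`, 1L, "total_double_bonds"),
             stringsAsFactors = FALSE)
}

#' Normalize a lipid intensity table
#'
#' `log2(x + 1)` followed by per-sample median centering. Zero-variance
#' species are flagged in the `"flat_species"` attribute; an all-zero
#' sample is an error.
#'
#' @param intensities species x samples matrix of nonnegative raw
#'   intensities.
#' @param pseudocount added before the log (default 1).
#' @return normalized species x samples matrix (log2 scale, median 0 per
#'   sample).
#' @export
normalize_intensities <- function(intensities, pseudocount = 1) {
  if (any(intensities < 0)) stop_invalid("intensities must be >= 0")
  zero_samp <- colSums(intensities) == 0
  if (any(zero_samp))
    stop_invalid("all-zero sample(s): %s",
                 paste(colnames(intensities)[zero_samp], collapse = ", "))
  L <- log2(intensities + pseudocount)
  L <- sweep(L, 2, apply(L, 2, stats::median), "-")
  flat <- rownames(L)[apply(L, 1, function(r) max(r) - min(r) == 0)]
  attr(L, "flat_species") <- flat
  L
}

#' Per-species log fold changes between groups
#'
#' `logFC = mean(disease) - mean(control)` on the normalized log scale,
#' with a two-sided Welch t p-value; the result is ranked by descending
#' logFC. Groups with a single sample get `p = NA`.
#'
#' @param normalized normalized species x samples matrix.
#' @param groups named character vector (sample -> "disease"/"control"),
#'   or unnamed in column order.
#' @return data.frame (species, logFC, p), ranked by logFC descending.
#' @export
fold_changes <- function(normalized, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(normalized)]
  if (length(groups) != ncol(normalized))
    stop_invalid("one group label per sample required")
  di <- groups == "disease"; co <- groups == "control"
  if (!any(di) || !any(co)) stop_invalid("both groups must be present")
  lfc <- rowMeans(normalized[, di, drop = FALSE]) -
    rowMeans(normalized[, co, drop = FALSE])
  p <- vapply(seq_len(nrow(normalized)), function(i) {
    if (sum(di) < 2L || sum(co) < 2L) return(NA_real_)
    x <- normalized[i, di]; y <- normalized[i, co]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y)$p.value
  }, 0)
  out <- data.frame(species = rownames(normalized), logFC = unname(lfc),
                    p = p, stringsAsFactors = FALSE)
  out <- out[order(-out$logFC, out$species), ]
  rownames(out) <- NULL
  out
}

## GSEA-style weighted KS enrichment score for one set over a ranked list.
## weights: |logFC|^exponent in ranked order; member: logical in ranked order.
es_score <- function(weights, member) {
  n <- length(member)
  nh <- sum(member)
  wsum <- sum(weights[member])
  step <- numeric(n)
  step[member] <- if (wsum > 0) weights[member] / wsum else 1 / nh
  step[!member] <- -1 / (n - nh)
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Lipid set enrichment analysis (permutation-based)
#'
#' Species are ranked by fold change; each lipid class is scored with the
#' GSEA-style weighted Kolmogorov-Smirnov running-sum statistic (weight
#' `|logFC|^exponent`, exponent 1 by default). Significance comes from
#' permuting species labels: `p = (1 + #{|ES_null| >= |ES|}) /
#' (n_permutations + 1)`, so p is never below `1/(n_permutations + 1)`;
#' the normalized score is `ES / mean(|ES_null|)`.
#'
#' @param ranked data.frame from [fold_changes()] (species, logFC),
#'   already ranked.
#' @param class_sets named list: lipid class -> character vector of
#'   member species (or NULL to derive classes by [parse_lipid_names()]).
#' @param n_permutations permutation count (default 1000).
#' @param seed integer seed.
#' @param exponent weight exponent on |logFC| (default 1).
#' @return data.frame (lipid_class, set_size, enrichment_score,
#'   normalized_score, p_permutation, direction). Classes with fewer than
#'   3 members present are skipped with a warning; a class spanning the
#'   whole list is an error.
#' @export
lsea <- function(ranked, class_sets = NULL, n_permutations = 1000, seed = 1,
                 exponent = 1) {
  if (is.null(class_sets)) {
    cls <- parse_lipid_names(ranked$species)$lipid_class
    class_sets <- split(ranked$species, cls)
    class_sets <- class_sets[names(class_sets) != "unknown"]
  }
  n <- nrow(ranked)
  w <- abs(ranked$logFC)^exponent
  out <- list()
  with_seed(substream_seed(seed, 5L), {
    perm_members <- NULL   # reuse permutation index draws across classes
    for (cl in names(class_sets)) {
      member <- ranked$species %in% class_sets[[cl]]
      nh <- sum(member)
      if (nh < 3L) {
        warning(sprintf("class %s: fewer than 3 members present, skipped", cl))
        next
      }
      if (nh == n)
        stop_invalid("class %s covers the entire ranked list: score undefined", cl)
      es <- es_score(w, member)
      null_es <- vapply(seq_len(n_permutations), function(b) {
        es_score(w, seq_len(n) %in% sample.int(n, nh))
      }, 0)
      p <- (1 + sum(abs(null_es) >= abs(es))) / (n_permutations + 1)
      nes <- es / mean(abs(null_es))
      out[[cl]] <- data.frame(
        lipid_class = cl, set_size = nh, enrichment_score = es,
        normalized_score = nes, p_permutation = p,
        direction = if (es >= 0) "up" else "down", stringsAsFactors = FALSE)
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(lipid_class = character(0), set_size = integer(0),
               enrichment_score = numeric(0), normalized_score = numeric(0),
               p_permutation = numeric(0), direction = character(0))
  rownames(res) <- NULL
  res
}

#' PCA of a normalized lipid table
#'
#' Samples are observations; species are mean-centered before the
#' decomposition. Explained-variance fractions are the normalized
#' eigenvalues of the sample covariance and are nonincreasing.
#'
#' @param normalized species x samples matrix.
#' @return list with `scores` (samples x components), `loadings`
#'   (species x components), `explained_variance` (fractions).
#' @export
lipid_pca <- function(normalized) {
  if (ncol(normalized) < 2L || nrow(normalized) < 2L)
    stop_invalid("PCA needs >= 2 samples and >= 2 species")
  X <- t(normalized)
  if (all(apply(X, 2, stats::sd) == 0)) stop_invalid("constant table")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}
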