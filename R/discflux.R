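## Discriminative-reaction extraction: pool per-subject flux samples into
## a labeled dataset, drop reactions with similar flow between groups,
## run repeated stratified 80/20 random-forest splits, and aggregate the
## top-ranked reactions from the splits that classify well.

#' Assemble a labeled flux dataset from per-subject sample matrices
#'
#' Columns are the intersection of the reactions present in every
#' subject's contextualized model. Reactions whose pooled flux
#' distributions are similar between the groups are excluded (they are
#' taken to reflect shared core function): a reaction is excluded when it
#' is constant across all samples, when the two groups' pooled values are
#' identical as multisets, or when a two-sided Mann-Whitney test gives
#' `p >= similarity_p` (default 0.99, i.e. near-total overlap).
#'
#' @param sample_matrices list of `flux_sample_matrix` objects (each with
#'   `subject` and `group` attributes).
#' @param similarity_p Mann-Whitney p-value above which a reaction counts
#'   as "similar flow" (default 0.99).
#' @return object of class `flux_dataset`: list with `matrix` (samples x
#'   kept reactions), `labels` (data.frame subject/group per row), and
#'   `excluded` (data.frame reaction/reason).
#' @export
assemble_dataset <- function(sample_matrices, similarity_p = 0.99) {
  groups <- vapply(sample_matrices, function(m) attr(m, "group") %||% NA_character_, "")
  subjects <- vapply(sample_matrices, function(m) attr(m, "subject") %||% NA_character_, "")
  if (anyNA(groups) || anyNA(subjects))
    stop_invalid("every sample matrix needs subject and group attributes")
  if (length(unique(groups)) < 2L)
    stop_invalid("need samples from both groups")
  for (g in unique(groups))
    if (length(unique(subjects[groups == g])) < 2L)
      stop_invalid("need >= 2 subjects per group (group %s)", g)
  shared <- Reduce(intersect, lapply(sample_matrices, colnames))
  if (length(shared) == 0L)
    stop_invalid("empty reaction intersection across subjects")
  M <- do.call(rbind, lapply(sample_matrices, function(m)
    unclass(m)[, shared, drop = FALSE]))
  labels <- data.frame(
    subject = rep(subjects, vapply(sample_matrices, nrow, 1L)),
    group = rep(groups, vapply(sample_matrices, nrow, 1L)),
    stringsAsFactors = FALSE)
  dis <- labels$group == unique(groups)[1]
  excluded <- data.frame(reaction = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- logical(length(shared))
  for (k in seq_along(shared)) {
    v <- M[, k]
    if (max(v) - min(v) <= 1e-12) {
      excluded <- rbind(excluded, data.frame(reaction = shared[k],
                                             reason = "constant"))
    } else if (identical(sort(v[dis]), sort(v[!dis])) &&
               sum(dis) == sum(!dis)) {
      excluded <- rbind(excluded, data.frame(reaction = shared[k],
                                             reason = "identical distributions"))
    } else {
      p <- mann_whitney(v[dis], v[!dis], exact = FALSE)$p
      if (p >= similarity_p) {
        excluded <- rbind(excluded, data.frame(reaction = shared[k],
                                               reason = "similar flow"))
      } else keep[k] <- TRUE
    }
  }
  if (!any(keep)) stop_invalid("all reactions excluded as similar flow")
  structure(list(matrix = M[, keep, drop = FALSE], labels = labels,
                 excluded = excluded),
            class = "flux_dataset")
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat(sprintf("flux_dataset: %d samples x %d reactions (%d excluded), groups: %s\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$excluded),
              paste(unique(x$labels$group), collapse = "/")))
  invisible(x)
}

#' Repeated random-forest train/test splits on flux samples
#'
#' Runs `n_splits` stratified 80/20 row splits; on each, fits a random
#' forest (100 trees, sqrt-features per node, impurity importance) on the
#' training rows and records test accuracy and the `top_k` reactions by
#' importance. Test rows never appear in training rows within a split.
#' With `split_by = "subject"` whole subjects are assigned to one side
#' (avoiding subject leakage); the default splits sample rows, matching
#' the flux-point independence convention.
#'
#' @param dataset a `flux_dataset`.
#' @param n_splits number of train/test splits (default 100).
#' @param train_fraction training fraction (default 0.8).
#' @param top_k reactions recorded per split (default 10).
#' @param seed integer seed; results are deterministic given it.
#' @param n_trees forest size (default 100).
#' @param split_by `"sample"` (default) or `"subject"`.
#' @return object of class `discriminative_report`: list with `splits`
#'   (data.frame split/accuracy), `top` (list of per-split data.frames
#'   reaction/importance/rank), and the call parameters.
#' @export
rf_classify_splits <- function(dataset, n_splits = 100, train_fraction = 0.8,
                               top_k = 10, seed = 1, n_trees = 100,
                               split_by = c("sample", "subject")) {
  split_by <- match.arg(split_by)
  n_splits <- check_count(n_splits, "n_splits")
  check_fraction(train_fraction, "train_fraction", 0.05, 0.95)
  M <- dataset$matrix
  y <- factor(dataset$labels$group)
  top_k <- min(top_k, ncol(M))
  acc <- numeric(n_splits)
  top <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(substream_seed(seed, 30L + s))
    tr <- logical(nrow(M))
    if (split_by == "sample") {
      for (g in levels(y)) {
        rows <- which(y == g)
        tr[sample(rows, round(train_fraction * length(rows)))] <- TRUE
      }
    } else {
      for (g in levels(y)) {
        subs <- unique(dataset$labels$subject[y == g])
        n_tr <- max(1L, round(train_fraction * length(subs)))
        chosen <- sample(subs, n_tr)
        tr[dataset$labels$subject %in% chosen & y == g] <- TRUE
      }
    }
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop_invalid("degenerate split %d: a side lost a class", s)
    fit <- randomForest::randomForest(
      x = M[tr, , drop = FALSE], y = y[tr], ntree = n_trees)
    pred <- stats::predict(fit, M[!tr, , drop = FALSE])
    acc[s] <- mean(pred == y[!tr])
    imp <- randomForest::importance(fit)[, 1]
    ord <- order(-imp, names(imp))
    top[[s]] <- data.frame(reaction = names(imp)[ord][seq_len(top_k)],
                           importance = unname(imp[ord][seq_len(top_k)]),
                           rank = seq_len(top_k), stringsAsFactors = FALSE)
  }
  structure(list(splits = data.frame(split = seq_len(n_splits), accuracy = acc),
                 top = top, top_k = top_k, train_fraction = train_fraction,
                 split_by = split_by, seed = seed),
            class = "discriminative_report")
}

#' @export
print.discriminative_report <- function(x, ...) {
  cat(sprintf("discriminative_report: %d splits, median accuracy %.3f\n",
              nrow(x$splits), stats::median(x$splits$accuracy)))
  invisible(x)
}

#' Aggregate the top reactions over well-classifying splits
#'
#' Counts how often each reaction enters a split's top-`top_k` importance
#' list, over the splits with accuracy strictly greater than
#' `accuracy_min`. Ranking is by selection count (descending), ties
#' broken by median importance rank (ascending) then reaction id.
#'
#' @param report a `discriminative_report`.
#' @param accuracy_min qualifying-split threshold (default 0.60, strict).
#' @param top_k number of aggregated reactions returned (default 10).
#' @return data.frame (reaction, n_selected, median_rank,
#'   n_qualifying_splits); zero rows with a warning when no split
#'   qualifies.
#' @export
extract_top_reactions <- function(report, accuracy_min = 0.60, top_k = 10) {
  qual <- which(report$splits$accuracy > accuracy_min)
  if (length(qual) == 0L) {
    warning("no split exceeded the accuracy threshold")
    return(data.frame(reaction = character(0), n_selected = integer(0),
                      median_rank = numeric(0), n_qualifying_splits = integer(0)))
  }
  tops <- do.call(rbind, report$top[qual])
  counts <- tapply(tops$rank, tops$reaction, length)
  med_rank <- tapply(tops$rank, tops$reaction, stats::median)
  out <- data.frame(reaction = names(counts),
                    n_selected = as.integer(counts),
                    median_rank = as.numeric(med_rank),
                    n_qualifying_splits = length(qual),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_selected, out$median_rank, out$reaction), ]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Compare one reaction's flux between groups
#'
#' Two-sided Mann-Whitney on the pooled per-sample fluxes, with group
#' medians.
#'
#' @param dataset a `flux_dataset`.
#' @param reaction reaction id (must be a retained column).
#' @return list with `U`, `p`, and `medians` (named by group).
#' @export
compare_groups <- function(dataset, reaction) {
  if (!reaction %in% colnames(dataset$matrix))
    stop_invalid("reaction %s not in the dataset", reaction)
  v <- dataset$matrix[, reaction]
  gs <- unique(dataset$labels$group)
  x <- v[dataset$labels$group == gs[1]]
  y <- v[dataset$labels$group == gs[2]]
  mw <- mann_whitney(x, y)
  list(U = mw$U, p = mw$p,
       medians = stats::setNames(c(stats::median(x), stats::median(y)), gs))
}

#' Group ranked reactions into subsystem families
#'
#' @param reactions character vector of reaction ids (e.g. the aggregated
#'   top list).
#' @param network the `metabolic_network` carrying subsystem labels.
#' @return data.frame (reaction, family); unlabeled exchange reactions
#'   fall under "exchange/demand", other unlabeled ones under
#'   "unannotated".
#' @export
group_by_subsystem <- function(reactions, network) {
  rx <- network$reactions
  fam <- vapply(reactions, function(rid) {
    i <- match(rid, rx$id)
    if (is.na(i)) return("unannotated")
    if (nzchar(rx$subsystem[i])) rx$subsystem[i]
    else if (rx$is_exchange[i]) "exchange/demand"
    else "unannotated"
  }, "")
  out <- data.frame(reaction = reactions, family = unname(fam),
                    stringsAsFactors = FALSE)
  out[order(out$family, out$reaction), , drop = FALSE]
}
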