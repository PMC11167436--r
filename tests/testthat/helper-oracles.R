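# Independent oracles used across test files. These deliberately use
# different algorithms from the package implementations they check.

# Brute-force Benjamini-Hochberg step-up: sort, apply p*(m/i), running
# minimum from the largest rank down, map back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Exact Mann-Whitney two-sided p by enumerating all group assignments,
# computing U by direct pairwise comparison counts (not rank sums).
mw_bruteforce <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  U_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- U_of(x, y)
  mid <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1, simplify = FALSE)
  devs <- vapply(combs, function(ix)
    abs(U_of(pooled[ix], pooled[-ix]) - mid), 0)
  list(U = U_obs, p = mean(devs >= abs(U_obs - mid) - 1e-9))
}

# Random small metabolic network with bounds containing zero (always
# feasible) for LP oracle comparisons.
rand_toy_network <- function(seed, n_rxn = NULL, n_met = NULL) {
  set.seed(seed)
  n <- n_rxn %||% sample(3:6, 1)
  m <- n_met %||% sample(1:3, 1)
  mets <- paste0("m", seq_len(m))
  repeat {
    st <- lapply(seq_len(n), function(j) {
      k <- sample(1:min(2, m), 1)
      stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE),
                      sample(mets, k))
    })
    if (length(unique(unlist(lapply(st, names)))) == m) break
  }
  names(st) <- paste0("r", seq_len(n))
  lb <- ifelse(stats::runif(n) < 0.5, 0, -round(stats::runif(n, 1, 10), 1))
  ub <- round(stats::runif(n, 1, 10), 1)
  rx <- data.frame(id = names(st), lb = lb, ub = ub, gpr = "",
                   subsystem = "", is_exchange = vapply(st, length, 1L) == 1L,
                   stringsAsFactors = FALSE)
  metabolic_network(
    data.frame(id = mets, compartment = "c", stringsAsFactors = FALSE),
    rx, st, objective_id = names(st)[n])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vertex-enumeration LP oracle for max c'v over {S v = 0, lb <= v <= ub}:
# fix n - rank(S) variables at a bound (all 2^k sign patterns over all
# subsets), solve for the rest, keep feasible points, return the best
# objective. Exact for bounded polytopes with few reactions.
vertex_optimum <- function(network, obj_id = network$objective_id) {
  S <- stoichiometric_matrix(network)
  lb <- network$reactions$lb; ub <- network$reactions$ub
  cc <- as.numeric(network$reactions$id == obj_id)
  n <- ncol(S)
  r <- qr(S)$rank
  free <- n - r
  best <- -Inf
  subsets <- if (free == 0) list(integer(0)) else
    utils::combn(n, free, simplify = FALSE)
  for (F in subsets) {
    B <- setdiff(seq_len(n), F)
    SB <- S[, B, drop = FALSE]
    if (length(B) && qr(SB)$rank < length(B)) next
    n_pat <- if (length(F)) 2^length(F) else 1
    for (maskv in seq_len(n_pat) - 1) {
      bits <- as.logical(bitwAnd(maskv, 2^(seq_along(F) - 1)))
      vF <- ifelse(bits, ub[F], lb[F])
      v <- numeric(n)
      v[F] <- vF
      if (length(B)) {
        rhs <- if (length(F)) -S[, F, drop = FALSE] %*% vF else
          matrix(0, nrow(S), 1)
        vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
        if (is.null(vB)) next
        v[B] <- vB
      }
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      best <- max(best, sum(cc * v))
    }
  }
  best
}

# Convenience: planted differential-flux design on the coupled template.
coupled_planted <- function(n_units = 3, shift = 4) {
  unlist(lapply(seq_len(n_units), function(k) list(
    list(reaction_id = sprintf("R%d_hi", k), group_mean_shift = shift,
         direction = "up_in_disease"),
    list(reaction_id = sprintf("R%d_lo", k), group_mean_shift = shift,
         direction = "down_in_disease"))), recursive = FALSE)
}

# Per-subject flux sample matrices for a transcript-abundance set.
sample_cohort_fluxes <- function(net, ta, n_samples = 50, seed = 1,
                                 fraction = 1.0) {
  lapply(colnames(ta$abundances), function(s) {
    ab <- map_abundance_to_reactions(net, ta$abundances[, s])
    cm <- contextualize(net, ab, fraction,
                        provenance = list(subject = s, group = ta$groups[[s]]))
    suppressWarnings(sample_fluxes(
      cm, n_samples, seed = substream_seed(seed, match(s, colnames(ta$abundances)))))
  })
}

# Shared small trained model for feature/saliency tests (built once per
# test run).
.test_cache <- new.env(parent = emptyenv())
get_test_cohort <- function() {
  if (is.null(.test_cache$cohort))
    .test_cache$cohort <- generate_wsi_cohort(6, 6, image_size = 256, seed = 1)
  .test_cache$cohort
}
get_test_patches <- function() {
  if (is.null(.test_cache$patches))
    .test_cache$patches <- unlist(lapply(get_test_cohort(), extract_patches,
                                         patch_size = 64), recursive = FALSE)
  .test_cache$patches
}
get_test_model <- function() {
  if (is.null(.test_cache$model))
    .test_cache$model <- train_classifier(
      get_test_patches(), cnn_config(feature_width = 16, seed = 3))
  .test_cache$model
}
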