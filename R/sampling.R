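## Steady-state flux sampling by artificial-centering hit-and-run (ACHR)
## in the null space of the stoichiometric matrix. Every sample satisfies
## S v = 0 by construction (v = v0 + N t with N an orthonormal null-space
## basis) and the bounds/objective constraints through the line-segment
## computation.

#' Sample steady-state flux vectors from a contextualized model
#'
#' Draws near-uniform samples from the polytope
#' `{v : S v = 0, lb <= v <= ub, objective >= fraction * optimum}` of the
#' model's pruned network using artificial-centering hit-and-run with
#' warm-up and thinning. If the polytope is a single point (all fluxes
#' forced), the unique vector is replicated with a warning.
#'
#' @param model a `contextualized_model` (or a bare `metabolic_network`,
#'   in which case `fraction` defaults to 1).
#' @param n_samples number of samples; the conventional range is 50-500
#'   and values outside it trigger a warning.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param n_warmup hit-and-run warm-up steps before recording (default 100).
#' @param thinning record every `thinning`-th step (default 10).
#' @return a `flux_sample_matrix`: numeric matrix `n_samples x n_reactions`
#'   with reaction ids as column names and attributes `subject` and
#'   `group` copied from the model's provenance when present.
#' @export
sample_fluxes <- function(model, n_samples = 200, seed = 1,
                          n_warmup = 100, thinning = 10) {
  n_samples <- check_count(n_samples, "n_samples")
  if (n_samples < 50 || n_samples > 500)
    warning("n_samples outside the conventional 50-500 range")
  if (inherits(model, "contextualized_model")) {
    network <- model$network
    fraction <- model$objective_fraction
    prov <- model$provenance
  } else if (inherits(model, "metabolic_network")) {
    network <- model; fraction <- 1; prov <- NULL
  } else stop_invalid("model must be a contextualized_model or metabolic_network")

  rx <- network$reactions
  n <- nrow(rx)
  S <- stoichiometric_matrix(network)
  lb <- cap_bounds(rx$lb); ub <- cap_bounds(rx$ub)
  opt <- fba(network)$value
  cobj <- as.numeric(rx$id == network$objective_id)
  min_obj <- fraction * opt - FEAS_TOL

  ## orthonormal null-space basis of S
  sv <- svd(S, nu = 0, nv = n)
  tolr <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tolr)
  N <- if (rank < n) sv$v[, (rank + 1):n, drop = FALSE] else matrix(0, n, 0)

  ## inequalities G t <= h around a feasible interior-ish point v0
  ranges <- fva(network, fraction = fraction)
  widths <- ranges$max - ranges$min
  degenerate <- ncol(N) == 0L || all(widths <= 1e-9)
  v0 <- fba(network)$fluxes
  if (degenerate) {
    warning("flux polytope has zero volume: returning replicated unique solution")
    out <- matrix(rep(as.numeric(v0), each = n_samples), n_samples, n,
                  dimnames = list(NULL, rx$id))
    return(new_flux_sample_matrix(out, prov))
  }
  G <- rbind(N, -N, matrix(-cobj %*% N, nrow = 1))
  h <- c(ub - v0, v0 - lb, sum(cobj * v0) - min_obj)

  ## warm-up point set from flux-variability vertices
  pts <- list()
  Aobj <- matrix(-cobj, nrow = 1); bobj <- -min_obj
  for (k in seq_len(n)) {
    for (dir in c(TRUE, FALSE)) {
      sol <- solve_lp(as.numeric(rx$id == rx$id[k]), S, rep(0, nrow(S)),
                      lb, ub, Ale = Aobj, ble = bobj, maximize = dir)
      if (sol$status == "optimal")
        pts[[length(pts) + 1L]] <- as.numeric(crossprod(N, sol$v - v0))
    }
  }
  P <- unique(do.call(rbind, pts))
  if (is.null(P) || nrow(P) < 2L)
    P <- rbind(rep(0, ncol(N)), rep(0, ncol(N)))

  with_seed(substream_seed(seed, 0L), {
    d <- ncol(N)
    ## pull warm-up points slightly toward their centroid so the chain
    ## starts strictly inside the polytope
    ctr0 <- colMeans(P)
    P <- sweep(sweep(P, 2, ctr0, "-") * 0.95, 2, ctr0, "+")
    center <- colMeans(P)
    t_cur <- P[sample.int(nrow(P), 1L), ]
    n_store <- nrow(P)
    samples <- matrix(NA_real_, n_samples, d)
    got <- 0L; step <- 0L
    total <- n_warmup + n_samples * thinning
    while (got < n_samples && step < 50L * total) {
      step <- step + 1L
      dir_pt <- P[sample.int(nrow(P), 1L), ]
      dvec <- dir_pt - center
      nrm <- sqrt(sum(dvec^2))
      if (nrm < 1e-12) { dvec <- stats::rnorm(d); nrm <- sqrt(sum(dvec^2)) }
      dvec <- dvec / nrm
      gd <- as.numeric(G %*% dvec)
      slack <- h - as.numeric(G %*% t_cur)
      slack <- pmax(slack, 0)
      amax <- suppressWarnings(min(slack[gd > 1e-12] / gd[gd > 1e-12]))
      amin <- suppressWarnings(max(-slack[gd < -1e-12] / (-gd[gd < -1e-12])))
      if (!is.finite(amax)) amax <- 0
      if (!is.finite(amin)) amin <- 0
      if (amax - amin < 1e-12) next
      alpha <- stats::runif(1, amin, amax)
      t_cur <- t_cur + alpha * dvec
      ## artificial centering: fold the new point into the running center
      n_store <- n_store + 1L
      center <- center + (t_cur - center) / n_store
      if (step > n_warmup && ((step - n_warmup) %% thinning == 0L)) {
        got <- got + 1L
        samples[got, ] <- t_cur
      }
    }
    if (got < n_samples)
      stop_invalid("flux sampler failed to mix (%d/%d samples)", got, n_samples)
    V <- sweep(samples %*% t(N), 2, as.numeric(v0), "+")
    ## snap residual numerical overshoot onto the box
    V <- pmin(pmax(V, matrix(lb, n_samples, n, byrow = TRUE)),
              matrix(ub, n_samples, n, byrow = TRUE))
    colnames(V) <- rx$id
    new_flux_sample_matrix(V, prov)
  })
}

#' Write flux samples as TSV with a JSON provenance sidecar
#'
#' @param samples a `flux_sample_matrix`.
#' @param path TSV output path (rows = samples, columns = reaction ids);
#'   `<path>.json` receives subject/group provenance.
#' @return `path`, invisibly.
#' @export
write_flux_samples <- function(samples, path) {
  utils::write.table(unclass(samples), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(subject = attr(samples, "subject"), group = attr(samples, "group"),
         n_samples = nrow(samples), reactions = colnames(samples)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

new_flux_sample_matrix <- function(m, prov) {
  attr(m, "subject") <- if (is.list(prov)) prov$subject else prov
  attr(m, "group") <- if (is.list(prov)) prov$group else NULL
  class(m) <- c("flux_sample_matrix", class(m))
  m
}
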