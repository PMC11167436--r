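## Flux balance analysis and flux variability analysis.
##
## LPs are solved with the two-phase simplex in the recommended `boot`
## package. Variables are shifted by their lower bounds so the solver's
## x >= 0 convention applies; infinite bounds are capped at +/- 1000
## (the usual genome-scale convention) so every problem is bounded.

BOUND_CAP <- 1000
FEAS_TOL <- 1e-6
BLOCKED_TOL <- 1e-9

cap_bounds <- function(b) pmin(pmax(b, -BOUND_CAP), BOUND_CAP)

## Solve: optimize obj'v  s.t.  Aeq v = beq, lb <= v <= ub, Ale v <= ble.
## Returns list(status = "optimal"|"infeasible"|"unsolved", value, v).
solve_lp <- function(obj, Aeq, beq, lb, ub, Ale = NULL, ble = NULL,
                     maximize = TRUE) {
  lb <- cap_bounds(lb); ub <- cap_bounds(ub)
  n <- length(obj)
  ## shift x = v - lb >= 0
  ub_x <- ub - lb
  b3 <- beq - as.numeric(Aeq %*% lb)
  A3 <- Aeq
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3[neg] <- -b3[neg]
  A1 <- diag(n); b1 <- ub_x
  A2 <- NULL; b2 <- NULL
  if (!is.null(Ale)) {
    bs <- ble - as.numeric(Ale %*% lb)
    pos <- bs >= 0
    if (any(pos)) { A1 <- rbind(A1, Ale[pos, , drop = FALSE]); b1 <- c(b1, bs[pos]) }
    if (any(!pos)) {
      A2 <- -Ale[!pos, , drop = FALSE]; b2 <- -bs[!pos]
    }
  }
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = maximize,
                  n.iter = 50 * (n + nrow(A3)), eps = 1e-10),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) {
    ## rare degenerate pivots abort boot::simplex; retry with the
    ## package's Bland-rule two-phase implementation
    res <- simplex_two_phase(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                             A3 = A3, b3 = b3, maxi = maximize)
  }
  if (res$solved < 0)
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  if (res$solved == 0)
    return(list(status = "unsolved", value = NA_real_, v = NULL))
  v <- as.numeric(res$soln) + lb
  list(status = "optimal", value = sum(obj * v), v = v)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through the network's objective
#' reaction subject to steady state (`S v = 0`) and the reaction bounds.
#'
#' @param network a `metabolic_network`.
#' @param maximize logical; maximize the objective (default TRUE).
#' @return list with `value` (optimal objective flux) and `fluxes`
#'   (a named optimal flux vector).
#' @export
fba <- function(network, maximize = TRUE) {
  S <- stoichiometric_matrix(network)
  rx <- network$reactions
  obj <- as.numeric(rx$id == network$objective_id)
  sol <- solve_lp(obj, S, rep(0, nrow(S)), rx$lb, rx$ub, maximize = maximize)
  if (sol$status == "infeasible")
    stop_invalid("FBA infeasible: no steady-state flux distribution satisfies the bounds")
  if (sol$status == "unsolved")
    stop_invalid("FBA failed: simplex did not converge")
  fl <- stats::setNames(sol$v, rx$id)
  list(value = sol$value, fluxes = fl)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum achievable flux under steady state,
#' bounds, optionally a minimum objective requirement, and optional extra
#' linear constraints.
#'
#' @param network a `metabolic_network`.
#' @param reactions reaction ids to analyse (default all).
#' @param fraction if non-NULL, require objective flux >=
#'   `fraction * FBA optimum`.
#' @return data.frame with columns `id`, `min`, `max`.
#' @export
fva <- function(network, reactions = NULL, fraction = NULL) {
  S <- stoichiometric_matrix(network)
  rx <- network$reactions
  reactions <- reactions %||% rx$id
  Ale <- NULL; ble <- NULL
  if (!is.null(fraction)) {
    opt <- fba(network)$value
    cobj <- as.numeric(rx$id == network$objective_id)
    Ale <- matrix(-cobj, nrow = 1)
    ble <- -fraction * opt + FEAS_TOL
  }
  out <- data.frame(id = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    obj <- as.numeric(rx$id == reactions[k])
    for (dir in c(FALSE, TRUE)) {
      sol <- solve_lp(obj, S, rep(0, nrow(S)), rx$lb, rx$ub,
                      Ale = Ale, ble = ble, maximize = dir)
      if (sol$status != "optimal")
        stop_invalid("FVA subproblem for %s %s", reactions[k], sol$status)
      out[k, if (dir) "max" else "min"] <- sol$value
    }
  }
  out
}

## Keep only the named reactions; drop metabolites no longer referenced.
subset_network <- function(network, keep_ids) {
  keep_ids <- intersect(network$reactions$id, keep_ids)
  rx <- network$reactions[network$reactions$id %in% keep_ids, , drop = FALSE]
  st <- network$stoichiometry[rx$id]
  used <- unique(unlist(lapply(st, names)))
  mets <- network$metabolites[network$metabolites$id %in% used, , drop = FALSE]
  rownames(rx) <- NULL; rownames(mets) <- NULL
  metabolic_network(mets, rx, st, network$objective_id)
}

#' Remove blocked (inactive) reactions
#'
#' A reaction is removed iff its flux-variability range is `[0, 0]`
#' (within 1e-9): it can carry no steady-state flux. The objective
#' reaction is always retained. Removal preserves the FBA optimum.
#'
#' @param network a `metabolic_network`.
#' @return the pruned `metabolic_network`, with attribute
#'   `"removed_reactions"` listing what was dropped.
#' @export
remove_inactive <- function(network) {
  ranges <- fva(network)
  blocked <- ranges$id[abs(ranges$min) <= BLOCKED_TOL & abs(ranges$max) <= BLOCKED_TOL]
  blocked <- setdiff(blocked, network$objective_id)
  out <- subset_network(network, setdiff(network$reactions$id, blocked))
  attr(out, "removed_reactions") <- blocked
  out
}
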