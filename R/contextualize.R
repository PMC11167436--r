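## Transcript-guided contextualization: restrict a network to measured
## genes, map gene abundances onto reactions through the GPR rules, then
## prune the network to the reactions used by a transcript-weighted
## parsimonious flux distribution while holding the objective at a stated
## fraction of its optimum.

#' Restrict GPR rules to a measured gene set
#'
#' Genes absent from `measured_gene_ids` are deleted from every GPR tree:
#' an absent leaf inside an OR is dropped (an isozyme not observed), an
#' absent leaf inside an AND invalidates the conjunct (an enzyme complex
#' missing a subunit). Reactions whose rule becomes empty are retained
#' but carry no gene evidence.
#'
#' @param network a `metabolic_network`.
#' @param measured_gene_ids character vector of measured genes.
#' @return the network with rewritten GPR rules.
#' @export
restrict_to_measured_genes <- function(network, measured_gene_ids) {
  rx <- network$reactions
  rx$gpr <- vapply(rx$gpr, function(s) {
    if (!nzchar(s)) return("")
    gpr_deparse(gpr_restrict_tree(gpr_parse(s), measured_gene_ids))
  }, "", USE.NAMES = FALSE)
  network$reactions <- rx
  network
}

#' Map gene abundances onto reactions
#'
#' Each GPR tree is evaluated with AND as `min` and OR as `max` over the
#' gene abundances. Reactions without a gene rule receive the median
#' abundance of the gene-bearing reactions.
#'
#' @param network a `metabolic_network`.
#' @param abundances named numeric vector, gene id -> abundance (>= 0,
#'   TPM-like).
#' @return named numeric vector, reaction id -> abundance.
#' @export
map_abundance_to_reactions <- function(network, abundances) {
  if (any(abundances < 0)) stop_invalid("abundances must be >= 0")
  rx <- network$reactions
  vals <- vapply(rx$gpr, function(s) {
    if (!nzchar(s)) return(NA_real_)
    gpr_eval(gpr_parse(s), abundances, default = 0)
  }, 0, USE.NAMES = FALSE)
  has_gene <- !is.na(vals)
  if (any(!has_gene)) {
    fill <- if (any(has_gene)) stats::median(vals[has_gene]) else 0
    vals[!has_gene] <- fill
  }
  stats::setNames(vals, rx$id)
}

## Weighted-parsimony LP in flux-split space: v = vf - vb, vf, vb >= 0.
## minimize sum(w * (vf + vb)) s.t. S vf - S vb = 0, split bounds,
## objective flux >= frac * opt. Returns list(value, vf, vb).
solve_weighted_parsimony <- function(S, lb, ub, w, cobj, min_obj,
                                     extra_obj = NULL, budget = NULL,
                                     maximize_extra = TRUE) {
  n <- ncol(S)
  lb <- cap_bounds(lb); ub <- cap_bounds(ub)
  lbf <- pmax(0, lb); ubf <- pmax(0, ub)
  lbb <- pmax(0, -ub); ubb <- pmax(0, -lb)
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  ## objective-flux floor: -cobj (vf - vb) <= -min_obj
  Ale <- matrix(c(-cobj, cobj), nrow = 1)
  ble <- -min_obj + FEAS_TOL
  if (!is.null(budget)) {
    Ale <- rbind(Ale, c(w, w))
    ble <- c(ble, budget)
  }
  obj <- if (is.null(extra_obj)) c(w, w) else c(extra_obj, -extra_obj)
  sol <- solve_lp(obj, Aeq, beq, c(lbf, lbb), c(ubf, ubb),
                  Ale = Ale, ble = ble,
                  maximize = if (is.null(extra_obj)) FALSE else maximize_extra)
  if (sol$status != "optimal") return(sol)
  vf <- sol$v[seq_len(n)]; vb <- sol$v[n + seq_len(n)]
  list(status = "optimal", value = sol$value, v = vf - vb)
}

#' Contextualize a metabolic network with reaction abundances
#'
#' Implements transcript-guided parsimonious pruning: reaction weights
#' `w_r = 1 - a_r / max(a)` penalize flux through lowly expressed
#' reactions; the total weighted flux `sum w_r |v_r|` is minimized
#' subject to steady state, bounds, and an objective flux of at least
#' `objective_fraction` times the FBA optimum; flux variability is then
#' computed under the additional constraint that the weighted total stays
#' at its minimum, and reactions whose constrained range is `[0, 0]` are
#' pruned. The absolute-value objective is linearized by splitting each
#' flux into irreversible forward/backward parts.
#'
#' The retained internal reactions then receive contextualized bounds:
#' the flux range each attains when the weighted total is allowed
#' `budget_relax` (default 1%) above its minimum, so the permissible flux
#' ranges of the model reflect the transcript evidence. Exchange
#' reactions keep the input model's bounds (no medium edits).
#'
#' @param network a `metabolic_network`.
#' @param reaction_abundances named numeric vector from
#'   [map_abundance_to_reactions()] covering every reaction.
#' @param objective_fraction minimum fraction of the parent optimum the
#'   pruned model must retain (default 1.0).
#' @param budget_relax fractional slack on the parsimony minimum used
#'   when deriving the contextualized flux bounds (default 0.01).
#' @param provenance optional free-form tag (e.g. subject id, or a list
#'   with `subject` and `group`).
#' @return an object of class `contextualized_model`: list with
#'   `network` (pruned, with contextualized bounds), `reaction_weights`,
#'   `objective_fraction`, `parent_optimum`, `parsimony_minimum`,
#'   `pruned_reactions`, `provenance`.
#' @export
contextualize <- function(network, reaction_abundances, objective_fraction = 1.0,
                          budget_relax = 0.01, provenance = NULL) {
  if (!(objective_fraction > 0 && objective_fraction <= 1))
    stop_invalid("objective_fraction must be in (0, 1]")
  rx <- network$reactions
  a <- reaction_abundances[rx$id]
  if (anyNA(a))
    stop_invalid("reaction_abundances must cover every reaction; missing: %s",
                 paste(rx$id[is.na(a)], collapse = ", "))
  amax <- max(a)
  w_raw <- if (amax > 0) 1 - a / amax else rep(0, length(a))
  ## a small uniform tie-break keeps the parsimony objective strictly
  ## positive, so with uniform abundances the procedure reduces to plain
  ## parsimonious FBA support
  eps_tie <- 1e-3
  w <- w_raw * (1 - eps_tie) + eps_tie
  S <- stoichiometric_matrix(network)
  cobj <- as.numeric(rx$id == network$objective_id)
  opt <- fba(network)$value
  min_obj <- objective_fraction * opt
  base <- solve_weighted_parsimony(S, rx$lb, rx$ub, w, cobj, min_obj)
  if (base$status != "optimal")
    stop_invalid(paste0("contextualization infeasible at objective_fraction=%g; ",
                        "try a lower fraction"), objective_fraction)
  slack <- 1e-9 * max(1, abs(base$value))
  budget <- base$value + slack
  ## constrained flux variability per reaction; the prune threshold is
  ## per-reaction: flux beyond slack / w_r is impossible within the
  ## budget, so a range within that radius is slack-enabled noise
  keep <- logical(nrow(rx))
  for (k in seq_len(nrow(rx))) {
    er <- as.numeric(rx$id == rx$id[k])
    hi <- solve_weighted_parsimony(S, rx$lb, rx$ub, w, cobj, min_obj,
                                   extra_obj = er, budget = budget,
                                   maximize_extra = TRUE)
    lo <- solve_weighted_parsimony(S, rx$lb, rx$ub, w, cobj, min_obj,
                                   extra_obj = er, budget = budget,
                                   maximize_extra = FALSE)
    if (hi$status != "optimal" || lo$status != "optimal")
      stop_invalid("constrained FVA failed for reaction %s", rx$id[k])
    tol_k <- max(BLOCKED_TOL, 10 * slack / w[k])
    keep[k] <- abs(hi$value) > tol_k || abs(lo$value) > tol_k
  }
  keep[rx$id == network$objective_id] <- TRUE
  pruned_ids <- rx$id[!keep]
  pruned <- subset_network(network, rx$id[keep])
  ## contextualized bounds for retained internal reactions: flux ranges
  ## under the relaxed parsimony budget (exchanges keep input bounds)
  relaxed <- base$value * (1 + budget_relax) + FEAS_TOL
  prx <- pruned$reactions
  for (k in seq_len(nrow(prx))) {
    if (prx$is_exchange[k]) next
    er <- as.numeric(rx$id == prx$id[k])
    hi <- solve_weighted_parsimony(S, rx$lb, rx$ub, w, cobj, min_obj,
                                   extra_obj = er, budget = relaxed,
                                   maximize_extra = TRUE)
    lo <- solve_weighted_parsimony(S, rx$lb, rx$ub, w, cobj, min_obj,
                                   extra_obj = er, budget = relaxed,
                                   maximize_extra = FALSE)
    if (hi$status == "optimal" && lo$status == "optimal" &&
        lo$value <= hi$value) {
      prx$lb[k] <- max(prx$lb[k], lo$value)
      prx$ub[k] <- min(prx$ub[k], hi$value)
    }
  }
  pruned$reactions <- prx
  new_opt <- fba(pruned)$value
  if (new_opt < min_obj - FEAS_TOL)
    stop_invalid("internal error: pruned model lost the objective (%.6g < %.6g)",
                 new_opt, min_obj)
  structure(list(network = pruned,
                 reaction_weights = stats::setNames(w, rx$id),
                 objective_fraction = objective_fraction,
                 parent_optimum = opt,
                 parsimony_minimum = base$value,
                 pruned_reactions = pruned_ids,
                 provenance = provenance),
            class = "contextualized_model")
}

#' @export
print.contextualized_model <- function(x, ...) {
  cat(sprintf("contextualized_model (%s): %d/%d reactions retained, objective fraction %.2f\n",
              x$provenance %||% "unnamed",
              nrow(x$network$reactions),
              nrow(x$network$reactions) + length(x$pruned_reactions),
              x$objective_fraction))
  invisible(x)
}
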