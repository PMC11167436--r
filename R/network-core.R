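## Metabolic network data model.
##
## A `metabolic_network` is a plain list:
##   metabolites    data.frame(id, compartment)
##   reactions      data.frame(id, lb, ub, gpr, subsystem, is_exchange)
##   stoichiometry  named list: reaction id -> named numeric vector
##                  (metabolite id -> coefficient; negative = consumed)
##   objective_id   id of the objective reaction
## Exchange reactions touch exactly one metabolite; the COBRA sign
## convention is used (stoichiometry -1 on the exchanged metabolite,
## negative lower bound = uptake).

#' Construct a metabolic network
#'
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`
#'   (boolean gene rule as text, "" for none), `subsystem`, `is_exchange`.
#' @param stoichiometry named list mapping each reaction id to a named
#'   numeric vector of metabolite coefficients.
#' @param objective_id id of the objective reaction.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry, objective_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  if (anyDuplicated(reactions$id))
    stop_invalid("duplicate reaction ids: %s",
                 paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stop_invalid("duplicate metabolite ids")
  if (!objective_id %in% reactions$id)
    stop_invalid("objective reaction '%s' not in network", objective_id)
  if (any(reactions$lb > reactions$ub))
    stop_invalid("lower bound exceeds upper bound for: %s",
                 paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))
  missing_st <- setdiff(reactions$id, names(stoichiometry))
  if (length(missing_st))
    stop_invalid("reactions without stoichiometry: %s", paste(missing_st, collapse = ", "))
  stoichiometry <- stoichiometry[reactions$id]
  for (rid in reactions$id) {
    st <- stoichiometry[[rid]]
    bad <- setdiff(names(st), metabolites$id)
    if (length(bad))
      stop_invalid("reaction %s references unknown metabolites: %s",
                   rid, paste(bad, collapse = ", "))
  }
  nx <- reactions$id[reactions$is_exchange &
                       vapply(stoichiometry[reactions$id], length, 1L) != 1L]
  if (length(nx))
    stop_invalid("exchange reactions must touch exactly one metabolite: %s",
                 paste(nx, collapse = ", "))
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = stoichiometry, objective_id = objective_id),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites, %d reactions (objective: %s)\n",
              nrow(x$metabolites), nrow(x$reactions), x$objective_id))
  cat(sprintf("  exchanges: %d; gene-associated: %d; subsystems: %d\n",
              sum(x$reactions$is_exchange),
              sum(nzchar(x$reactions$gpr)),
              length(unique(x$reactions$subsystem[nzchar(x$reactions$subsystem)]))))
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param network a `metabolic_network`.
#' @return dense numeric matrix, rows = metabolites, columns = reactions.
#' @export
stoichiometric_matrix <- function(network) {
  mets <- network$metabolites$id
  rxns <- network$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- network$stoichiometry[[rxns[j]]]
    S[names(st), j] <- st
  }
  S
}

#' All gene ids appearing in a network's GPR rules
#' @param network a `metabolic_network`.
#' @return character vector of gene ids.
#' @export
network_genes <- function(network) {
  g <- unlist(lapply(network$reactions$gpr, function(s)
    if (nzchar(s)) gpr_genes(gpr_parse(s)) else character(0)))
  sort(unique(g))
}

## ---------------------------------------------------------------------------
## GPR boolean expressions: recursive-descent parser over
##   expr := term ("or" term)* ; term := factor ("and" factor)* ;
##   factor := gene | "(" expr ")"
## Tree nodes are list(op = "and"|"or", args = list(...)) or
## list(gene = "id"). NULL denotes an empty rule.

gpr_tokenize <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-protein-reaction rule
#'
#' Accepts `and`/`or` (case-insensitive, also `&`/`|`) and parentheses.
#'
#' @param s rule text; "" yields NULL (no gene association).
#' @return an expression tree of nested `list(op=, args=)` /
#'   `list(gene=)` nodes, or NULL.
#' @export
gpr_parse <- function(s) {
  if (is.null(s) || !nzchar(trimws(s))) return(NULL)
  toks <- gpr_tokenize(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) %in% kw
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), c("or", "|"))) { advance(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), c("and", "&"))) { advance(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop_invalid("malformed GPR '%s': unexpected end", s)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop_invalid("malformed GPR '%s': missing ')'", s)
      advance()
      return(e)
    }
    if (t == ")" || is_kw(t, c("and", "or", "&", "|")))
      stop_invalid("malformed GPR '%s': unexpected '%s'", s, t)
    advance()
    list(gene = t)
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop_invalid("malformed GPR '%s': trailing tokens", s)
  out
}

#' Genes referenced by a GPR tree
#' @param tree result of [gpr_parse()].
#' @return character vector.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree against gene values
#'
#' AND maps to `min` (enzyme complex limited by scarcest subunit), OR to
#' `max` (isozymes). Genes missing from `values` evaluate to `default`.
#'
#' @param tree result of [gpr_parse()].
#' @param values named numeric vector of gene abundances.
#' @param default value for genes absent from `values`.
#' @return a scalar, or NA_real_ for a NULL tree.
#' @export
gpr_eval <- function(tree, values, default = 0) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    v <- values[tree$gene]
    return(if (is.na(v)) default else unname(v))
  }
  vals <- vapply(tree$args, gpr_eval, 0, values = values, default = default)
  if (tree$op == "and") min(vals) else max(vals)
}

## Restrict a tree to a measured gene set: an unmeasured leaf inside an OR
## is dropped; inside an AND it invalidates the whole conjunction.
gpr_restrict_tree <- function(tree, measured) {
  if (is.null(tree)) return(NULL)
  if (!is.null(tree$gene)) return(if (tree$gene %in% measured) tree else NULL)
  kept <- lapply(tree$args, gpr_restrict_tree, measured = measured)
  if (tree$op == "and") {
    if (any(vapply(kept, is.null, TRUE))) return(NULL)
  } else {
    kept <- kept[!vapply(kept, is.null, TRUE)]
    if (length(kept) == 0L) return(NULL)
  }
  if (length(kept) == 1L) kept[[1L]] else list(op = tree$op, args = kept)
}

#' Render a GPR tree back to rule text
#' @param tree result of [gpr_parse()], or NULL.
#' @return a character scalar ("" for NULL).
#' @export
gpr_deparse <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(node, parent_op) {
    if (!is.null(node$gene)) return(node$gene)
    parts <- vapply(node$args, rec, "", parent_op = node$op)
    s <- paste(parts, collapse = sprintf(" %s ", node$op))
    if (!is.null(parent_op) && parent_op != node$op) sprintf("(%s)", s) else s
  }
  rec(tree, NULL)
}

## ---------------------------------------------------------------------------
## Toy network templates

#' Generate a toy metabolic network
#'
#' Three desk-scale templates standing in for a genome-scale
#' reconstruction:
#' * `linear_chain`: one uptake, `n - 1` internal conversions over `n`
#'   chain metabolites, one export (the objective).
#' * `parallel_pathways`: two internal routes with distinct gene sets
#'   between the same metabolite pair; route capacities and the uptake
#'   bound are configurable.
#' * `branched_biomass`: two substrates feeding a branched precursor set
#'   combined by a biomass reaction (the objective).
#'
#' A fourth template, `coupled_pathways`, chains `n_units` independent
#' two-route units into one biomass product, with route capacities below
#' the unit demand so both routes of every unit must carry flux; it is
#' the test bed for group-differential flux analysis (transcript weights
#' decide how each unit's demand is split across its routes).
#'
#' @param template one of `"linear_chain"`, `"parallel_pathways"`,
#'   `"branched_biomass"`, `"coupled_pathways"`.
#' @param size_params list of template parameters: `n` (chain length,
#'   default 3), `capacities` (two route upper bounds, default c(10, 10)),
#'   `uptake` (uptake magnitude, default 10), `n_units` and `route_cap`
#'   (coupled_pathways; defaults 3 and 8).
#' @return a `metabolic_network`.
#' @export
generate_toy_network <- function(template = c("linear_chain", "parallel_pathways",
                                              "branched_biomass", "coupled_pathways"),
                                 size_params = list()) {
  if (length(template) != 1L || !template %in%
      c("linear_chain", "parallel_pathways", "branched_biomass",
        "coupled_pathways"))
    stop_invalid("unknown toy network template '%s'", paste(template, collapse = ","))
  up <- size_params$uptake %||% 10
  switch(template,
    linear_chain = {
      n <- size_params$n %||% 3L
      n <- check_count(n, "n", min = 2L)
      mets <- paste0("M", seq_len(n))
      rx <- list()
      st <- list()
      rx[["EX_M1"]] <- list(lb = -up, ub = 0, gpr = "", subsystem = "", ex = TRUE)
      st[["EX_M1"]] <- c(M1 = -1)
      for (i in seq_len(n - 1L)) {
        id <- paste0("R", i)
        rx[[id]] <- list(lb = 0, ub = 1000, gpr = paste0("g", i),
                         subsystem = "chain", ex = FALSE)
        sti <- c(-1, 1); names(sti) <- mets[c(i, i + 1L)]
        st[[id]] <- sti
      }
      exid <- paste0("EX_M", n)
      rx[[exid]] <- list(lb = 0, ub = 1000, gpr = "", subsystem = "", ex = TRUE)
      st[[exid]] <- stats::setNames(-1, mets[n])
      build_toy(mets, rx, st, objective = exid)
    },
    parallel_pathways = {
      caps <- size_params$capacities %||% c(10, 10)
      mets <- c("A", "B")
      rx <- list(
        EX_A = list(lb = -up, ub = 0, gpr = "", subsystem = "", ex = TRUE),
        R1   = list(lb = 0, ub = caps[1], gpr = "g1a and g1b",
                    subsystem = "route1", ex = FALSE),
        R2   = list(lb = 0, ub = caps[2], gpr = "g2a and g2b",
                    subsystem = "route2", ex = FALSE),
        EX_B = list(lb = 0, ub = 1000, gpr = "", subsystem = "", ex = TRUE))
      st <- list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                 R2 = c(A = -1, B = 1), EX_B = c(B = -1))
      build_toy(mets, rx, st, objective = "EX_B")
    },
    branched_biomass = {
      mets <- c("A", "B", "C", "D", "P")
      rx <- list(
        EX_A = list(lb = -up, ub = 0, gpr = "", subsystem = "", ex = TRUE),
        EX_B = list(lb = -up, ub = 0, gpr = "", subsystem = "", ex = TRUE),
        R1 = list(lb = 0, ub = 1000, gpr = "gA1 or gA2", subsystem = "branchA", ex = FALSE),
        R2 = list(lb = 0, ub = 1000, gpr = "gB1 and gB2", subsystem = "branchB", ex = FALSE),
        BIOMASS = list(lb = 0, ub = 1000, gpr = "gbio", subsystem = "biomass", ex = FALSE),
        EX_P = list(lb = 0, ub = 1000, gpr = "", subsystem = "", ex = TRUE))
      st <- list(EX_A = c(A = -1), EX_B = c(B = -1),
                 R1 = c(A = -1, C = 1), R2 = c(B = -1, D = 1),
                 BIOMASS = c(C = -0.5, D = -0.5, P = 1), EX_P = c(P = -1))
      build_toy(mets, rx, st, objective = "EX_P")
    },
    coupled_pathways = {
      n_units <- check_count(size_params$n_units %||% 3L, "n_units")
      cap <- size_params$route_cap %||% 8
      if (2 * cap <= up) stop_invalid("route_cap too small: units infeasible")
      mets <- c(paste0("A", seq_len(n_units)), paste0("B", seq_len(n_units)), "P")
      rx <- list(); st <- list()
      for (k in seq_len(n_units)) {
        exid <- sprintf("EX_A%d", k)
        rx[[exid]] <- list(lb = -up, ub = 0, gpr = "", subsystem = "", ex = TRUE)
        st[[exid]] <- stats::setNames(-1, sprintf("A%d", k))
        hi <- sprintf("R%d_hi", k); lo <- sprintf("R%d_lo", k)
        rx[[hi]] <- list(lb = 0, ub = cap,
                         gpr = sprintf("ghi%d_1 and ghi%d_2", k, k),
                         subsystem = sprintf("pathway_%d", k), ex = FALSE)
        rx[[lo]] <- list(lb = 0, ub = cap,
                         gpr = sprintf("glo%d_1 and glo%d_2", k, k),
                         subsystem = sprintf("pathway_%d", k), ex = FALSE)
        sti <- stats::setNames(c(-1, 1), c(sprintf("A%d", k), sprintf("B%d", k)))
        st[[hi]] <- sti; st[[lo]] <- sti
        cid <- sprintf("C%d", k)
        rx[[cid]] <- list(lb = 0, ub = 1000, gpr = sprintf("gc%d", k),
                          subsystem = sprintf("pathway_%d", k), ex = FALSE)
        st[[cid]] <- stats::setNames(c(-1, 1), c(sprintf("B%d", k), "P"))
      }
      rx[["EX_P"]] <- list(lb = 0, ub = 1000, gpr = "", subsystem = "", ex = TRUE)
      st[["EX_P"]] <- c(P = -1)
      build_toy(mets, rx, st, objective = "EX_P")
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_toy <- function(mets, rx, st, objective) {
  metabolic_network(
    metabolites = data.frame(id = mets, compartment = "c", stringsAsFactors = FALSE),
    reactions = data.frame(
      id = names(rx),
      lb = vapply(rx, function(x) x$lb, 0),
      ub = vapply(rx, function(x) x$ub, 0),
      gpr = vapply(rx, function(x) x$gpr, ""),
      subsystem = vapply(rx, function(x) x$subsystem, ""),
      is_exchange = vapply(rx, function(x) x$ex, TRUE),
      stringsAsFactors = FALSE),
    stoichiometry = st,
    objective_id = objective)
}
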