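## Network serialization: a documented JSON dialect and a minimal SBML
## Level 3 + FBC (version 2) subset. Both round-trip every field of the
## in-memory model (stoichiometry, bounds, GPR, subsystem, exchange flag,
## objective).
##
## JSON dialect:
## {
##   "metabolites": [{"id": ..., "compartment": ...}, ...],
##   "reactions":   [{"id": ..., "stoichiometry": {met: coef, ...},
##                    "lower_bound": ..., "upper_bound": ..., "gpr": ...,
##                    "subsystem": ..., "is_exchange": ...}, ...],
##   "objective": reaction id
## }

#' Write a metabolic network to disk
#'
#' @param network a `metabolic_network`.
#' @param path output file path.
#' @param format `"json"` (the package's dialect) or `"sbml"`
#'   (SBML Level 3 with the FBC package for bounds, GPR and objective).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") write_network_json(network, path) else
    write_network_sbml(network, path)
  invisible(path)
}

#' Read a metabolic network from disk
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return a `metabolic_network`.
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  format <- match.arg(format, c("json", "sbml"))
  if (format == "json") read_network_json(path) else read_network_sbml(path)
}

write_network_json <- function(network, path) {
  rx <- network$reactions
  obj <- list(
    metabolites = lapply(seq_len(nrow(network$metabolites)), function(i)
      list(id = network$metabolites$id[i],
           compartment = network$metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(rx)), function(i)
      list(id = rx$id[i],
           stoichiometry = as.list(network$stoichiometry[[rx$id[i]]]),
           lower_bound = rx$lb[i], upper_bound = rx$ub[i],
           gpr = rx$gpr[i], subsystem = rx$subsystem[i],
           is_exchange = rx$is_exchange[i])),
    objective = network$objective_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_network_json <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$objective)) stop_invalid("network JSON is missing the objective")
  mets <- data.frame(
    id = vapply(x$metabolites, function(m) m$id, ""),
    compartment = vapply(x$metabolites, function(m) m$compartment %||% "c", ""),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = vapply(x$reactions, function(r) r$id, ""),
    lb = vapply(x$reactions, function(r) as.numeric(r$lower_bound), 0),
    ub = vapply(x$reactions, function(r) as.numeric(r$upper_bound), 0),
    gpr = vapply(x$reactions, function(r) r$gpr %||% "", ""),
    subsystem = vapply(x$reactions, function(r) r$subsystem %||% "", ""),
    is_exchange = vapply(x$reactions, function(r) isTRUE(r$is_exchange), TRUE),
    stringsAsFactors = FALSE)
  st <- lapply(x$reactions, function(r) {
    v <- unlist(r$stoichiometry)
    stats::setNames(as.numeric(v), names(v))
  })
  names(st) <- rx$id
  for (i in seq_len(nrow(rx))) {
    if (nzchar(rx$gpr[i]))
      tryCatch(gpr_parse(rx$gpr[i]), error = function(e)
        stop_invalid("reaction %s: %s", rx$id[i], conditionMessage(e)))
  }
  metabolic_network(mets, rx, st, x$objective)
}

## --- SBML -------------------------------------------------------------------

SBML_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_network_sbml <- function(network, path) {
  rx <- network$reactions
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  genes <- network_genes(network)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE, SBML_FBC),
    '<model id="model" fbc:strict="true">',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>',
            unique(sanitize_sid(network$metabolites$compartment))),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    lines <- c(lines, sprintf(
      '<species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      sanitize_sid(m$id), esc(m$id), sanitize_sid(m$compartment)))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  bvals <- sort(unique(c(rx$lb, rx$ub)))
  bid <- function(v) sprintf("bnd_%d", match(v, bvals))
  lines <- c(lines, sprintf(
    '<parameter id="%s" value="%s" constant="true"/>',
    bid(bvals), format(bvals, digits = 17)), "</listOfParameters>",
    "<listOfReactions>")
  for (i in seq_len(nrow(rx))) {
    st <- network$stoichiometry[[rx$id[i]]]
    head <- sprintf(
      '<reaction id="R_%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      sanitize_sid(rx$id[i]), esc(rx$id[i]),
      tolower(rx$lb[i] < 0), bid(rx$lb[i]), bid(rx$ub[i]))
    notes <- sprintf(
      '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p><p>EXCHANGE: %s</p></body></notes>',
      esc(rx$subsystem[i]), tolower(rx$is_exchange[i]))
    reac <- st[st < 0]; prod <- st[st > 0]
    body <- character(0)
    if (length(reac))
      body <- c(body, "<listOfReactants>", sprintf(
        '<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
        sanitize_sid(names(reac)), format(-as.numeric(reac), digits = 17)),
        "</listOfReactants>")
    if (length(prod))
      body <- c(body, "<listOfProducts>", sprintf(
        '<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
        sanitize_sid(names(prod)), format(as.numeric(prod), digits = 17)),
        "</listOfProducts>")
    gpa <- ""
    if (nzchar(rx$gpr[i])) {
      gpa <- sprintf("<fbc:geneProductAssociation>%s</fbc:geneProductAssociation>",
                     gpr_to_fbc(gpr_parse(rx$gpr[i])))
    }
    lines <- c(lines, head, notes, body, gpa, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            sanitize_sid(network$objective_id)),
    "</fbc:listOfFluxObjectives>", "</fbc:objective>", "</fbc:listOfObjectives>")
  if (length(genes)) {
    lines <- c(lines, "<fbc:listOfGeneProducts>", sprintf(
      '<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
      sanitize_sid(genes), esc(genes)), "</fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
}

gpr_to_fbc <- function(tree) {
  if (!is.null(tree$gene))
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   sanitize_sid(tree$gene)))
  tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
  sprintf("<%s>%s</%s>", tag,
          paste(vapply(tree$args, gpr_to_fbc, ""), collapse = ""), tag)
}

read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ## resolve gene product id -> label first
  ns <- xml2::xml_ns(doc)
  gp <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gene_label <- stats::setNames(
    xml2::xml_attr(gp, "label"),
    xml2::xml_attr(gp, "id"))
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_name[is.na(sp_name)] <- sub("^M_", "", sp_id[is.na(sp_name)])
  met_of <- stats::setNames(sp_name, sp_id)
  mets <- data.frame(id = sp_name,
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rnodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  n <- length(rnodes)
  ids <- character(n); lb <- ub <- numeric(n)
  gprs <- subs <- character(n); isx <- logical(n)
  st <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rnodes[[i]]
    rid <- xml2::xml_attr(r, "id")
    nm <- xml2::xml_attr(r, "name")
    ids[i] <- if (!is.na(nm)) nm else sub("^R_", "", rid)
    lb[i] <- parval[[xml2::xml_attr(r, "lowerFluxBound")]]
    ub[i] <- parval[[xml2::xml_attr(r, "upperFluxBound")]]
    notes <- xml2::xml_text(xml2::xml_find_all(r, ".//*[local-name()='p']"))
    subs[i] <- sub("^SUBSYSTEM: ?", "", grep("^SUBSYSTEM:", notes, value = TRUE)[1] %|NA|% "SUBSYSTEM:")
    isx[i] <- identical(sub("^EXCHANGE: ?", "",
                            grep("^EXCHANGE:", notes, value = TRUE)[1] %|NA|% ""), "true")
    coefs <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (length(refs)) {
        v <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        if (side == "listOfReactants") v <- -v
        coefs <- c(coefs, stats::setNames(v, met_of[xml2::xml_attr(refs, "species")]))
      }
    }
    st[[i]] <- coefs
    gpa <- xml2::xml_find_first(r, ".//*[local-name()='geneProductAssociation']")
    gprs[i] <- if (inherits(gpa, "xml_missing")) "" else {
      tree <- fbc_to_gpr(xml2::xml_children(gpa)[[1]], gene_label)
      gpr_deparse(tree)
    }
  }
  names(st) <- ids
  fo <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing")) stop_invalid("SBML file has no flux objective")
  obj_rid <- xml2::xml_attr(fo, "reaction")
  obj_idx <- match(obj_rid, paste0("R_", sanitize_sid(ids)))
  if (is.na(obj_idx)) stop_invalid("objective reaction %s not found", obj_rid)
  metabolic_network(
    mets,
    data.frame(id = ids, lb = lb, ub = ub, gpr = gprs, subsystem = subs,
               is_exchange = isx, stringsAsFactors = FALSE),
    st, ids[obj_idx])
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

fbc_to_gpr <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lbl <- gene_label[gid]
    return(list(gene = if (is.na(lbl)) sub("^G_", "", gid) else unname(lbl)))
  }
  if (!nm %in% c("and", "or")) stop_invalid("malformed GPR element <%s>", nm)
  list(op = nm,
       args = lapply(xml2::xml_children(node), fbc_to_gpr, gene_label = gene_label))
}
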