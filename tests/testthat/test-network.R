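test_that("GPR parser builds the expected trees and round-trips", {
  t1 <- gpr_parse("(g1 and g2) or g3")
  expect_equal(t1$op, "or")
  expect_equal(t1$args[[1]]$op, "and")
  expect_equal(sort(gpr_genes(t1)), c("g1", "g2", "g3"))
  expect_equal(gpr_deparse(t1), "(g1 and g2) or g3")
  expect_null(gpr_parse(""))
  expect_error(gpr_parse("g1 and"), "malformed")
  expect_error(gpr_parse("(g1 or g2"), "malformed")
  expect_error(gpr_parse("g1 g2"), "malformed")
})

test_that("GPR evaluation agrees with R boolean/min-max semantics", {
  # enumerate the truth table of a nested rule against direct evaluation
  rule <- "(g1 and g2) or (g3 and (g4 or g5))"
  tree <- gpr_parse(rule)
  vals_grid <- expand.grid(g1 = 0:1, g2 = 0:1, g3 = 0:1, g4 = 0:1, g5 = 0:1)
  for (i in seq_len(nrow(vals_grid))) {
    v <- unlist(vals_grid[i, ])
    direct <- max(min(v["g1"], v["g2"]),
                  min(v["g3"], max(v["g4"], v["g5"])))
    expect_equal(gpr_eval(tree, v), unname(direct))
  }
  expect_equal(gpr_eval(gpr_parse("g1 and g2"), c(g1 = 10, g2 = 4)), 4)
  expect_equal(gpr_eval(gpr_parse("g1 or g2"), c(g1 = 10, g2 = 4)), 10)
})

test_that("restriction to measured genes follows the OR-drop/AND-kill rule", {
  net <- generate_toy_network("branched_biomass")
  r1 <- function(n) n$reactions$gpr[n$reactions$id == "R1"]
  r2 <- function(n) n$reactions$gpr[n$reactions$id == "R2"]
  expect_equal(r1(restrict_to_measured_genes(net, "gA1")), "gA1")
  expect_equal(r2(restrict_to_measured_genes(net, c("gB1", "gA1"))), "")
  all_g <- network_genes(net)
  expect_identical(restrict_to_measured_genes(net, all_g)$reactions,
                   net$reactions)
})

test_that("abundance mapping fills empty rules with the median", {
  net <- generate_toy_network("linear_chain", list(n = 4))
  ab <- map_abundance_to_reactions(net, c(g1 = 2, g2 = 4, g3 = 9))
  expect_equal(unname(ab[c("R1", "R2", "R3")]), c(2, 4, 9))
  expect_equal(unname(ab["EX_M1"]), 4)   # median of gene-bearing reactions
  expect_error(map_abundance_to_reactions(net, c(g1 = -1)), ">= 0")
})

test_that("toy network templates satisfy their constructive contracts", {
  lc <- generate_toy_network("linear_chain", list(n = 3))
  expect_equal(nrow(lc$reactions), 4)
  expect_equal(sum(lc$reactions$is_exchange), 2)
  expect_equal(lc$objective_id, "EX_M3")
  pp <- generate_toy_network("parallel_pathways")
  g1 <- gpr_genes(gpr_parse(pp$reactions$gpr[pp$reactions$id == "R1"]))
  g2 <- gpr_genes(gpr_parse(pp$reactions$gpr[pp$reactions$id == "R2"]))
  expect_length(intersect(g1, g2), 0)
  expect_error(generate_toy_network("nope"), "unknown")
})

test_that("JSON and SBML round-trips preserve the whole model", {
  for (tpl in c("linear_chain", "parallel_pathways", "branched_biomass",
                "coupled_pathways")) {
    net <- generate_toy_network(tpl)
    fj <- withr::local_tempfile(fileext = ".json")
    fx <- withr::local_tempfile(fileext = ".xml")
    write_network(net, fj, "json")
    write_network(net, fx, "sbml")
    expect_equal(unclass(read_network(fj)), unclass(net))
    expect_equal(unclass(read_network(fx)), unclass(net))
  }
})

test_that("malformed network files produce informative errors", {
  f <- withr::local_tempfile(fileext = ".json")
  net <- generate_toy_network("linear_chain")
  obj <- jsonlite::read_json({ write_network(net, f, "json"); f })
  obj$objective <- NULL
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(read_network(f), "objective")
  obj2 <- jsonlite::read_json({ write_network(net, f, "json"); f })
  obj2$reactions[[2]]$gpr <- "g1 and"
  jsonlite::write_json(obj2, f, auto_unbox = TRUE)
  expect_error(read_network(f), "R1")
})

test_that("network constructor enforces its invariants", {
  net <- generate_toy_network("linear_chain")
  bad <- net$reactions; bad$lb[2] <- 5; bad$ub[2] <- 1
  expect_error(metabolic_network(net$metabolites, bad, net$stoichiometry,
                                 net$objective_id), "lower bound")
  expect_error(metabolic_network(net$metabolites, net$reactions,
                                 net$stoichiometry, "missing"), "objective")
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(3, 4))
  expect_equal(unname(S["M1", "R1"]), -1)
})
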