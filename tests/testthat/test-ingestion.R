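test_that("reaction strings parse into role lists", {
  r <- parse_reaction_string("CCO.CC(=O)O>>CCOC(C)=O")
  expect_identical(r$reactants, c("CCO", "CC(=O)O"))
  expect_identical(r$agents, character(0))
  expect_identical(r$products, "CCOC(C)=O")

  r <- parse_reaction_string("CCO>O>CC=O")
  expect_identical(r$agents, "O")

  expect_error(parse_reaction_string("CCO>CC=O"), "parse error")
  expect_error(parse_reaction_string("CCO>>"), "parse error")
  expect_error(parse_reaction_string(">>CCO"), "parse error")
  expect_error(parse_reaction_string("A>B>C>D"), "parse error")
})

test_that("canonicalization maps equivalent SMILES together and is a fixed point", {
  expect_identical(canonicalize_molecule("OCC"), canonicalize_molecule("CCO"))
  can <- canonicalize_molecule("CC(=O)O")
  expect_identical(canonicalize_molecule(can), can)
  expect_error(canonicalize_molecule("C("), "validation error.*C\\(")
  expect_error(canonicalize_molecule(""), "validation error")
  # atom maps are stripped before canonicalization
  expect_identical(canonicalize_molecule("[CH3:1][OH:2]"), canonicalize_molecule("CO"))
})

test_that("role reassignment moves pass-through species to agents", {
  roles <- reaction_roles(c("CCO", "O"), character(0), c("CC=O", "O"))
  out <- assign_roles(roles)
  expect_identical(out$reactants, "CCO")
  expect_identical(out$agents, "O")
  expect_identical(out$products, "CC=O")

  roles <- reaction_roles("CCO", character(0), "CC=O")
  expect_identical(assign_roles(roles), roles)

  expect_error(assign_roles(reaction_roles("O", character(0), "O")),
               "degenerate")
})

test_that("canonical reaction strings are order-invariant", {
  a <- canonical_reaction_string(reaction_roles(c("CC(=O)O", "CCO"),
                                                character(0), "CCOC(C)=O"))
  b <- canonical_reaction_string(reaction_roles(c("CCO", "CC(=O)O"),
                                                character(0), "CCOC(C)=O"))
  expect_identical(a, "CC(=O)O.CCO>>CCOC(C)=O")
  expect_identical(a, b)
})

test_that("graph elements follow set semantics", {
  roles <- parse_reaction_string("CCO.CC(=O)O>>CCOC(C)=O")
  roles$reactants <- canonicalize_molecule(roles$reactants)
  roles$products <- canonicalize_molecule(roles$products)
  el <- build_graph_elements(assign_roles(roles))
  kinds <- vapply(el$nodes, `[[`, "", "kind")
  expect_identical(sum(kinds == "molecule"), 3L)
  expect_identical(sum(kinds == "reaction"), 1L)
  ek <- vapply(el$edges, `[[`, "", "kind")
  expect_identical(sum(ek == "REACTANT"), 2L)
  expect_identical(sum(ek == "PRODUCT"), 1L)

  # duplicate reactant species deduplicate
  el2 <- build_graph_elements(reaction_roles(c("C", "C"), character(0), "CC"))
  expect_identical(sum(vapply(el2$edges, `[[`, "", "kind") == "REACTANT"), 1L)
})

test_that("ingestion merges duplicates by canonical identifier", {
  rows <- c("OCC.CC(=O)O>>CCOC(C)=O",
            "CC(=O)O.CCO>>CCOC(C)=O",   # same reaction, species reordered/rewritten
            "CCO>>CC=O")
  res <- ingest(rows)
  expect_identical(res$report$n_failed, 0L)
  expect_identical(res$report$n_unique_reactions, 2L)
  st <- noc_stats(res$graph)
  expect_identical(st$n_reactions, 2L)
})

test_that("without validation, deduplication is by the reaction string as written", {
  rows <- c("OCC.CC(=O)O>>CCOC(C)=O",
            "OCC.CC(=O)O>>CCOC(C)=O",   # exact duplicate collapses
            "CC(=O)O.OCC>>CCOC(C)=O")   # reordered: distinct without validation
  res <- ingest(rows, validate = FALSE)
  expect_identical(res$report$n_unique_reactions, 2L)
  res_v <- ingest(rows, validate = TRUE)
  expect_identical(res_v$report$n_unique_reactions, 1L)
  # validation monotonicity
  expect_lte(res_v$report$n_unique_reactions, res$report$n_unique_reactions)
})

test_that("ingestion is chunking- and order-invariant", {
  rows <- c("OCC>>CC=O", "CC=O>>CC(=O)O", "CCO.CC(=O)O>>CCOC(C)=O",
            "OCC>>CC=O", "C=C>>CC")
  g1 <- ingest(rows, chunk_size = 1L)$graph
  g2 <- ingest(rows, chunk_size = 5L)$graph
  g3 <- ingest(rev(rows), chunk_size = 2L)$graph
  expect_true(noc_equal(g1, g2))
  expect_true(noc_equal(g1, g3))
  # dedup soundness: X union X ingests to the same graph as X
  g4 <- ingest(c(rows, rows))$graph
  expect_true(noc_equal(g1, g4))
})

test_that("failed rows are skipped and logged, or abort under fail_fast", {
  rows <- c("CCO>>CC=O", "not a reaction", "O>>O")
  res <- ingest(rows)
  expect_identical(res$report$n_failed, 2L)
  expect_identical(res$report$failures$row, c(2L, 3L))
  expect_match(res$report$failures$reason[2], "degenerate")
  expect_identical(res$report$n_unique_reactions, 1L)
  expect_error(ingest(rows, on_error = "fail_fast"), "row 2")
})

test_that("tabular input requires the configured reaction column", {
  tab <- data.frame(rxn = c("CCO>>CC=O"), stringsAsFactors = FALSE)
  expect_error(ingest(tab, reaction_column = "reaction"), "configuration error")
  res <- ingest(tab, reaction_column = "rxn")
  expect_identical(res$report$n_unique_reactions, 1L)
})

test_that("agents are excluded from the graph but kept as a reaction property", {
  res <- ingest("CCO>[Na+]>CC=O")
  g <- res$graph
  st <- noc_stats(g)
  expect_identical(st$n_molecules, 2L)
  rn <- get(ls(g$rxn), envir = g$rxn)
  expect_match(rn$properties$agents, "Na")
})
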