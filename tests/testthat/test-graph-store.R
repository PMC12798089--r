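test_that("neighborhood accessors follow the bipartite edge semantics", {
  fx <- g_or()
  expect_identical(producers(fx$graph, fx$mol[["m3"]]),
                   sort(unname(fx$rxn), method = "radix"))
  expect_identical(producers(fx$graph, fx$mol[["m1"]]), character(0))
  expect_identical(consumers(fx$graph, fx$mol[["m1"]]), unname(fx$rxn[["r1"]]))
  expect_error(producers(fx$graph, "M-nope"), "lookup error")

  res <- ingest("CCO.CC(=O)O>>CCOC(C)=O")
  r <- ls(res$graph$rxn)
  expect_identical(reactants_of(res$graph, r),
                   sort(compute_uid("molecule", c("CCO", "CC(=O)O")), method = "radix"))
  expect_length(products_of(res$graph, r), 1L)
})

test_that("OR nodes are exactly the molecules with two or more producers", {
  expect_identical(or_nodes(g_or()$graph), unname(g_or()$mol[["m3"]]))
  expect_identical(or_nodes(g_lin()$graph), character(0))
  fx <- g_prod()
  expect_identical(or_nodes(fx$graph),
                   sort(unname(fx$mol[c("a", "b")]), method = "radix"))
})

test_that("network statistics match hand counts on the branching fixture", {
  st <- noc_stats(g_prod()$graph)
  expect_identical(st$n_molecules, 8L)
  expect_identical(st$n_reactions, 6L)
  expect_identical(st$n_reactant_edges, 7L)
  expect_identical(st$n_product_edges, 6L)
  expect_equal(st$avg_reactants_per_reaction, 7 / 6)
  expect_equal(st$avg_products_per_reaction, 1)
  expect_identical(st$n_roots, 1L)
  expect_identical(st$n_leaves, 5L)
  expect_identical(st$n_or_nodes, 2L)
})

test_that("edge totals equal per-reaction sums and empty graphs yield undefined averages", {
  fx <- benchmark27()
  st <- noc_stats(fx$graph)
  expect_identical(st$n_reactant_edges,
                   sum(lengths(lapply(reaction_uids(fx$graph), reactants_of,
                                      graph = fx$graph))))
  expect_identical(st$n_product_edges,
                   sum(lengths(lapply(reaction_uids(fx$graph), products_of,
                                      graph = fx$graph))))
  expect_lte(st$n_roots + st$n_leaves, st$n_molecules)

  st0 <- noc_stats(noc_graph())
  expect_identical(st0$n_molecules, 0L)
  expect_true(is.na(st0$avg_reactants_per_reaction))
})

test_that("predicate selection returns matching nodes and induced edges", {
  fx <- g_prod()
  res <- noc_select(fx$graph, node_predicate = function(n, g)
    n$kind == "molecule" && length(producers(g, n$uid)) >= 2L)
  expect_identical(res$records[[1]]$nodes,
                   sort(unname(fx$mol[c("a", "b")]), method = "radix"))
  expect_identical(nrow(res$records[[1]]$edges), 0L)

  # always-true predicates return the whole graph
  all_res <- noc_select(fx$graph)
  expect_identical(all_res$records[[1]]$nodes,
                   sort(c(unname(fx$mol), unname(fx$rxn)), method = "radix"))
  expect_identical(nrow(all_res$records[[1]]$edges), 13L)  # 7 REACTANT + 6 PRODUCT

  # reactions with >= 2 reactants: exactly the root reaction
  res2 <- noc_select(fx$graph, node_predicate = function(n, g)
    n$kind == "reaction" && length(reactants_of(g, n$uid)) >= 2L)
  expect_identical(res2$records[[1]]$nodes, unname(fx$rxn[["r0"]]))
})

test_that("synthetic trees are bounded backward closures that may contain cycles", {
  fx <- g_lin()
  tr <- synthetic_tree(fx$graph, fx$mol[["m3"]])
  expect_identical(sort(ls(tr$subgraph$mol)), sort(unname(fx$mol)))
  tr1 <- synthetic_tree(fx$graph, fx$mol[["m3"]],
                        route_bounds(max_number_reactions = 1))
  expect_identical(ls(tr1$subgraph$rxn), unname(fx$rxn[["r2"]]))
  expect_identical(sort(ls(tr1$subgraph$mol)),
                   sort(unname(fx$mol[c("m2", "m3")])))

  # cyclic region is included without hanging
  cy <- g_cyc()
  trc <- synthetic_tree(cy$graph, cy$mol[["b"]])
  expect_identical(sort(ls(trc$subgraph$rxn)), sort(unname(cy$rxn)))
  expect_identical(unname(trc$or_alternatives), 2L)  # a has two producers

  expect_error(synthetic_tree(fx$graph, "M-nope"), "lookup error")
})

test_that("an unbounded synthetic tree equals the union of all mined routes", {
  for (fx in list(g_prod(), benchmark27())) {
    t <- fx$targets[1] %||% "t"
    tuid <- fx$mol[[if (is.null(fx$targets)) "t" else fx$targets[1]]]
    tr <- synthetic_tree(fx$graph, tuid)
    res <- mine_routes(fx$graph, tuid)
    union_nodes <- sort(unique(unlist(lapply(res$records, `[[`, "nodes"))),
                        method = "radix")
    tree_nodes <- sort(c(ls(tr$subgraph$mol), ls(tr$subgraph$rxn)), method = "radix")
    expect_true(all(union_nodes %in% tree_nodes))
    union_edges <- unique(do.call(rbind, lapply(res$records, `[[`, "edges")))
    for (i in seq_len(nrow(union_edges))) {
      key <- paste(union_edges$kind[i], union_edges$source[i],
                   union_edges$target[i], sep = "|")
      expect_true(exists(key, envir = tr$subgraph$edge, inherits = FALSE))
    }
  }
})
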