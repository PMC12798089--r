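test_that("the benchmark graph has exactly 27 nodes and the advertised features", {
  fx <- benchmark27()
  st <- noc_stats(fx$graph)
  expect_identical(st$n_molecules + st$n_reactions, 27L)
  # all five challenge phenomena present
  expect_gte(st$n_or_nodes, 3L)                          # OR decision points
  multi_prod <- Filter(function(r) length(products_of(fx$graph, r)) >= 2L,
                       reaction_uids(fx$graph))
  expect_gte(length(multi_prod), 1L)                     # multiple products
  common <- Filter(function(m) length(consumers(fx$graph, m)) >= 2L,
                   molecule_uids(fx$graph))
  expect_gte(length(common), 2L)                         # common intermediates
  # a cycle: some molecule is an ancestor of itself through PRODUCT/REACTANT
  tr <- synthetic_tree(fx$graph, fx$mol[["E"]])
  expect_true(fx$mol[["E"]] %in% ls(tr$subgraph$mol))    # E reachable from E region
})

test_that("frozen benchmark answers regenerate identically from the oracle", {
  fx <- benchmark27()
  frozen <- jsonlite::fromJSON(system.file("extdata", "benchmark27_answers.json",
                                           package = "rxnmine"),
                               simplifyVector = TRUE)
  expect_identical(sort(names(frozen)), sort(fx$targets))
  for (t in fx$targets) {
    oracle <- as.character(enumerate_routes_bruteforce(fx$graph, fx$mol[[t]]))
    expect_identical(oracle, as.character(frozen[[t]]))
    mined <- result_identities(mine_routes(fx$graph, t))
    expect_identical(mined, oracle)
  }
})

test_that("frozen scenario answers regenerate identically from the oracle", {
  frozen <- jsonlite::fromJSON(system.file("extdata", "scenario_answers.json",
                                           package = "rxnmine"),
                               simplifyVector = TRUE)
  for (nm in names(frozen)) {
    fx <- scenario(nm)
    for (t in fx$targets) {
      oracle <- as.character(enumerate_routes_bruteforce(fx$graph, fx$mol[[t]]))
      expect_identical(oracle, as.character(frozen[[nm]][[t]]))
    }
  }
  expect_error(scenario("no_such_case"), "lookup error")
})

test_that("scenario graphs have their defining structure", {
  # common intermediate: one route, molecule c feeds two reactions
  fx <- scenario("common_intermediates")
  res <- mine_routes(fx$graph, "t")
  expect_length(res$records, 1L)
  rt <- res$records[[1]]$route
  expect_identical(sort(rt$reactions), sort(unname(fx$rxn)))
  c_uid <- unname(fx$mol[["c"]])
  expect_identical(sum(rt$edges$source == c_uid & rt$edges$kind == "REACTANT"), 2L)

  # multiple products: the reaction appears once, one PRODUCT edge per product
  fm <- scenario("multiple_products")
  rtm <- mine_routes(fm$graph, "t")$records[[1]]$route
  r1 <- unname(fm$rxn[["r1"]])
  expect_identical(sum(rtm$reactions == r1), 1L)
  expect_identical(sum(rtm$edges$source == r1 & rtm$edges$kind == "PRODUCT"), 2L)
  expect_identical(unname(rtm$provenance[unname(fm$mol[c("p", "q")])]),
                   c(r1, r1))

  # cycles: exactly one route that enters the cycle region once
  expect_length(mine_routes(scenario("cycles")$graph, "b")$records, 1L)
})

test_that("the random generator is seed-deterministic and respects its dials", {
  a <- random_noc(12, 9, 0.3, 0.1, 3, seed = 7)
  b <- random_noc(12, 9, 0.3, 0.1, 3, seed = 7)
  expect_true(noc_equal(a$graph, b$graph))
  c <- random_noc(12, 9, 0.3, 0.1, 3, seed = 8)
  expect_false(noc_equal(a$graph, c$graph))

  # no OR nodes and no cycles: every molecule has at most one producer
  d <- random_noc(12, 9, or_density = 0, cycle_rate = 0, seed = 3)
  expect_identical(or_nodes(d$graph), character(0))
  for (t in names(d$mol)) {
    if (!length(producers(d$graph, d$mol[[t]]))) next
    expect_lte(length(mine_routes(d$graph, t)$records), 1L)
  }

  # arity constraints hold for every generated reaction
  e <- random_noc(14, 10, 0.4, 0.2, max_arity = 2, seed = 11)
  for (r in reaction_uids(e$graph)) {
    expect_gte(length(reactants_of(e$graph, r)), 1L)
    expect_lte(length(reactants_of(e$graph, r)), 2L)
    expect_gte(length(products_of(e$graph, r)), 1L)
  }
  expect_error(random_noc(2, 1), "generation error")
  expect_error(random_noc(10, 5, or_density = 1.5), "generation error")
})

test_that("the OR-density dial is calibrated over many seeds", {
  fracs <- vapply(1:100, function(s) {
    fx <- random_noc(12, 11, or_density = 0.3, cycle_rate = 0, seed = s)
    st <- noc_stats(fx$graph)
    st$n_or_nodes / st$n_molecules
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.3), 0.1)
})

test_that("generated graphs always satisfy the structural invariants", {
  for (s in 1:25) {
    fx <- random_noc(10 + s %% 5, 7 + s %% 4, or_density = 0.3,
                     cycle_rate = 0.2, seed = s)
    g <- fx$graph
    edges <- noc_edges(g)
    for (i in seq_len(nrow(edges))) {
      if (edges$kind[i] == "PRODUCT") {
        expect_true(exists(edges$source[i], envir = g$rxn, inherits = FALSE))
        expect_true(exists(edges$target[i], envir = g$mol, inherits = FALSE))
      } else {
        expect_true(exists(edges$source[i], envir = g$mol, inherits = FALSE))
        expect_true(exists(edges$target[i], envir = g$rxn, inherits = FALSE))
      }
    }
  }
})
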