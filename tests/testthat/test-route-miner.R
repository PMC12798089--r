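test_that("linear chains yield exactly one fully forced route", {
  fx <- g_lin()
  res <- mine_routes(fx$graph, "m3")
  expect_length(res$records, 1L)
  m <- res$records[[1]]$metrics
  expect_identical(m$n_steps, 2L)
  expect_identical(m$longest_sequence, 2L)
  expect_identical(m$n_branches, 0L)
  rt <- res$records[[1]]$route
  expect_identical(unname(rt$leaves), "DEAD_END")
  expect_identical(names(rt$leaves), unname(fx$mol[["m1"]]))
})

test_that("each producing alternative of an OR target yields its own route", {
  expect_identical(length(mine_routes(g_or()$graph, "m3")$records), 2L)
})

test_that("the bound truncates routes and marks cut molecules as BOUND leaves", {
  fx <- g_lin3()
  res <- mine_routes(fx$graph, "m4", route_bounds(max_number_reactions = 2))
  expect_length(res$records, 1L)
  rt <- res$records[[1]]$route
  expect_identical(rt$leaves[[unname(fx$mol[["m2"]])]], "BOUND")
  expect_identical(res$records[[1]]$metrics$longest_sequence, 2L)
  expect_oracle_equiv(fx, "m4", route_bounds(max_number_reactions = 2))
  # bound 1 keeps only the last reaction
  res1 <- mine_routes(fx$graph, "m4", route_bounds(max_number_reactions = 1))
  expect_identical(res1$records[[1]]$metrics$n_steps, 1L)
})

test_that("stop-marked molecules terminate routes as STOP leaves", {
  # both OR-branch source molecules stop-marked: routes end there with 1 step
  fx <- g_or(stop_marks = c("m1", "m2"))
  bounds <- route_bounds(stop_property = "startingMaterial")
  res <- mine_routes(fx$graph, "m3", bounds)
  expect_length(res$records, 2L)
  for (rec in res$records) expect_identical(rec$metrics$n_steps, 1L)
  expect_oracle_equiv(fx, "m3", bounds)

  # a stop mark on a *producible* molecule halts expansion with a STOP leaf
  fx2 <- abstract_network(list(
    r0 = list(reactants = "mid", products = "t"),
    r1 = list(reactants = "raw", products = "mid")
  ), stop_materials = "mid")
  res2 <- mine_routes(fx2$graph, "t", bounds)
  expect_length(res2$records, 1L)
  rt <- res2$records[[1]]$route
  expect_identical(rt$leaves[[unname(fx2$mol[["mid"]])]], "STOP")
  expect_identical(res2$records[[1]]$metrics$n_steps, 1L)
  expect_oracle_equiv(fx2, "t", bounds)

  # without naming the stop property the marks are inert
  expect_identical(length(mine_routes(fx2$graph, "t")$records[[1]]$route$reactions),
                   2L)
})

test_that("subroute extraction collapses forced segments and flags decision points", {
  fx <- g_lin()
  sub <- extract_subroutes(fx$graph, fx$mol[["m3"]])
  expect_identical(names(sub), unname(fx$mol[["m3"]]))
  s <- sub[[1]][[1]]
  expect_identical(s$leaves, setNames("DEAD_END", unname(fx$mol[["m1"]])))
  expect_length(s$fragment, 2L)  # whole chain absorbed

  fo <- g_or()
  sub2 <- extract_subroutes(fo$graph, fo$mol[["m3"]])
  expect_length(sub2[[unname(fo$mol[["m3"]])]], 2L)  # one per choice

  # cycle: the cycling alternative carries a CYCLE_BLOCKED leaf
  cy <- g_cyc()
  sub3 <- extract_subroutes(cy$graph, cy$mol[["b"]])
  a_uid <- unname(cy$mol[["a"]])
  expect_true(a_uid %in% names(sub3))
  reasons <- unlist(lapply(sub3[[a_uid]], function(s) unname(s$leaves)))
  expect_true("CYCLE_BLOCKED" %in% reasons)
  expect_true("DEAD_END" %in% reasons)
})

test_that("route validation rejects broken routes for the right reason", {
  fx <- g_lin()
  res <- mine_routes(fx$graph, "m3")
  rt <- res$records[[1]]$route
  expect_true(validate_route(fx$graph, rt)$valid)

  # missing producing reaction below the bound: maximality violation
  partial <- make_route(fx$graph, fx$mol[["m3"]],
                        setNames(fx$rxn[["r2"]], fx$mol[["m3"]]))
  chk <- validate_route(fx$graph, partial)
  expect_false(chk$valid)
  expect_match(paste(chk$violations, collapse = "; "), "maximality")

  # two in-route reactions producing one molecule: provenance uniqueness
  fo <- g_or()
  bad <- make_route(fo$graph, fo$mol[["m3"]],
                    setNames(fo$rxn[["r1"]], fo$mol[["m3"]]))
  bad$edges <- rbind(bad$edges,
                     data.frame(kind = "PRODUCT", source = unname(fo$rxn[["r2"]]),
                                target = unname(fo$mol[["m3"]])))
  bad$reactions <- sort(unname(fo$rxn), method = "radix")
  chk2 <- validate_route(fo$graph, bad)
  expect_false(chk2$valid)
  expect_match(paste(chk2$violations, collapse = "; "),
               "more than one incoming PRODUCT|reactant set")

  # a bound-respecting route passes with the bound it was mined under
  fx3 <- g_lin3()
  res3 <- mine_routes(fx3$graph, "m4", route_bounds(2))
  expect_true(validate_route(fx3$graph, res3$records[[1]]$route,
                             route_bounds(2))$valid)
  # ... and fails maximality when judged unbounded
  expect_false(validate_route(fx3$graph, res3$records[[1]]$route)$valid)
})

test_that("route metrics on the branching fixture match the hand trace", {
  res <- mine_routes(g_prod()$graph, "t")
  for (rec in res$records) {
    m <- rec$metrics
    expect_identical(m$n_steps, 3L)
    expect_identical(m$longest_sequence, 2L)
    expect_identical(m$n_leaves, 2L)
    expect_identical(m$n_branches, 1L)
  }
})

test_that("mined routes are sound, deduplicated and deterministically ordered", {
  fx <- benchmark27()
  res <- mine_routes(fx$graph, "T")
  ids <- result_identities(res)
  expect_identical(anyDuplicated(ids), 0L)
  for (rec in res$records) {
    expect_true(validate_route(fx$graph, rec$route)$valid)
  }
  res2 <- mine_routes(fx$graph, "T")
  expect_identical(result_identities(res2), ids)
  steps <- vapply(res$records, function(r) r$metrics$n_steps, integer(1))
  expect_true(all(diff(steps) >= 0))
})

test_that("unknown targets and tight budgets raise the documented conditions", {
  fx <- g_lin()
  expect_error(mine_routes(fx$graph, "no such target"), "lookup error")
  fxp <- g_prod()
  err <- tryCatch(mine_routes(fxp$graph, "t", budget = 2L), error = identity)
  expect_s3_class(err, "rxnmine_budget_error")
  expect_gte(length(err$routes), 3L)  # partial results attached
})

test_that("oracle refuses oversized graphs", {
  fx <- benchmark27()
  expect_error(enumerate_routes_bruteforce(fx$graph, fx$mol[["T"]],
                                           node_limit = 5L),
               "size guard")
})

test_that("bound monotonicity holds on the benchmark graph", {
  fx <- benchmark27()
  n_prev <- 0L
  for (d in 1:5) {
    n <- length(mine_routes(fx$graph, "T", route_bounds(d))$records)
    expect_gte(n, 0L)
    n_prev <- n
  }
  # every unbounded route with longest sequence <= 5 appears at bound 5
  unb <- mine_routes(fx$graph, "T")
  ids5 <- result_identities(mine_routes(fx$graph, "T", route_bounds(5)))
  for (rec in unb$records) {
    if (rec$metrics$longest_sequence <= 5L) {
      expect_true(rec$route$identity %in% ids5)
    }
  }
})
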