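# Shared fixture builders. All graphs are abstract (labels, no chemistry).

g_lin <- function() {
  abstract_network(list(
    r1 = list(reactants = "m1", products = "m2"),
    r2 = list(reactants = "m2", products = "m3")
  ))
}

g_lin3 <- function() {
  abstract_network(list(
    r1 = list(reactants = "m1", products = "m2"),
    r2 = list(reactants = "m2", products = "m3"),
    r3 = list(reactants = "m3", products = "m4")
  ))
}

g_or <- function(stop_marks = character(0)) {
  abstract_network(list(
    r1 = list(reactants = "m1", products = "m3"),
    r2 = list(reactants = "m2", products = "m3")
  ), stop_materials = stop_marks)
}

# t <- r0 <- {a, b}; a has 2 producers, b has 3, all from distinct leaves
g_prod <- function() scenario("concurrent_branching")

g_cyc <- function() scenario("cycles")

g_common <- function() scenario("common_intermediates")

# miner and oracle agreement on one (graph, target, bounds) case
expect_oracle_equiv <- function(fx, target_label, bounds = route_bounds()) {
  oracle <- enumerate_routes_bruteforce(fx$graph, fx$mol[[target_label]], bounds)
  mined <- result_identities(mine_routes(fx$graph, target_label, bounds))
  expect_identical(mined, as.character(oracle))
  invisible(length(oracle))
}

# stamp stop marks onto a copy of a fixture graph
with_stop_marks <- function(fx, labels) {
  g <- clone_graph(fx$graph)
  for (lab in labels) {
    merge_node(g, molecule_node(lab, properties = list(startingMaterial = TRUE)))
  }
  fx$graph <- g
  fx
}
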