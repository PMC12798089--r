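#' Brute-force reference enumeration of synthetic routes
#'
#' Independent correctness oracle for [mine_routes()]: recursively explores
#' every producing-reaction choice (or leaf decision) at every molecule
#' reachable from the target, then keeps exactly the assignments that pass
#' [validate_route()], deduplicated by [route_identity()]. The state space is
#' exponential, so the enumerator refuses graphs whose backward closure
#' exceeds `node_limit` nodes and aborts after `max_states` recursion states.
#'
#' Termination is unconditional even on cyclic graphs: each molecule receives
#' at most one decision per explored assignment, and cyclic provenance is
#' rejected by the validator.
#'
#' @param graph A [noc_graph()].
#' @param target_uid Target molecule uid.
#' @param bounds A [route_bounds()].
#' @param node_limit Refuse if the unbounded backward closure from the target
#'   has more than this many nodes.
#' @param max_states Hard cap on explored recursion states.
#' @return Sorted character vector of route identities; the corresponding
#'   `noc_route` objects are attached as the `"routes"` attribute (in the
#'   same order).
#' @export
enumerate_routes_bruteforce <- function(graph, target_uid,
                                        bounds = route_bounds(),
                                        node_limit = 400L, max_states = 2e6) {
  assert_mol(graph, target_uid)
  tree <- synthetic_tree(graph, target_uid, route_bounds())
  n_nodes <- length(ls(tree$subgraph$mol)) + length(ls(tree$subgraph$rxn))
  if (n_nodes > node_limit) {
    stop("size guard: backward closure has ", n_nodes, " nodes (limit ",
         node_limit, "); brute-force enumeration refused", call. = FALSE)
  }

  found <- new.env(parent = emptyenv())
  order_keys <- character(0)
  states <- 0L

  D <- bound_depth(bounds)

  recurse <- function(assign) {
    states <<- states + 1L
    if (states > max_states) {
      stop("size guard: brute-force enumeration exceeded ", max_states,
           " states", call. = FALSE)
    }
    prov <- assign[nzchar(assign)]
    cl <- route_closure(graph, target_uid, prov)
    dp <- route_depths(graph, target_uid, prov, cl)
    # sound pruning: assignments only ever grow, so cyclic provenance and
    # depths already past the bound can never become valid
    if (dp$cyclic) return(invisible(NULL))
    if (is.finite(D) && max(dp$depth) > D) return(invisible(NULL))
    pend <- setdiff(cl$mols, names(assign))
    pend <- pend[vapply(pend, function(m) length(producers(graph, m)) > 0L,
                        logical(1))]
    if (!length(pend)) {
      if (!length(prov)) return(invisible(NULL))
      route <- make_route(graph, target_uid, prov, bounds)
      chk <- validate_route(graph, route, bounds)
      if (chk$valid && !exists(route$identity, envir = found, inherits = FALSE)) {
        assign(route$identity, route, envir = found)
        order_keys <<- c(order_keys, route$identity)
      }
      return(invisible(NULL))
    }
    m <- sort_c(pend)[1L]
    choices <- if (m != target_uid && is_stop_marked(graph, m, bounds)) {
      ""  # stop-marked molecules are never expanded
    } else if (!is.finite(D)) {
      producers(graph, m)  # unbounded: a producible molecule must expand
    } else if (dp$depth[[m]] >= D) {
      ""  # at the bound: expansion would exceed it
    } else {
      c(producers(graph, m), "")
    }
    for (ch in choices) {
      a2 <- assign
      a2[m] <- ch
      recurse(a2)
    }
    invisible(NULL)
  }

  recurse(setNames(character(0), character(0)))
  ids <- sort_c(order_keys)
  routes <- lapply(ids, function(k) get(k, envir = found))
  attr(ids, "routes") <- routes
  ids
}
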