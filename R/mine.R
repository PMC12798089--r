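## Two-phase route mining: (1) subroute extraction collapses contiguous
## forced segments (molecules with a single producing reaction) into
## provenance fragments rooted at the target or at an (OR node, producing
## reaction) choice; (2) route assembly stitches fragments together over the
## OR decision points, re-normalizing depths and truncating at the bound
## after every stitch, until no expandable molecule is pending. Every
## completed route is checked against the declarative contract
## (validate_route) and deduplicated by route_identity.

# Fragment extraction for one (root molecule, producing reaction) choice.
# A fragment is a provenance map covering the root and every molecule of the
# forced segment below it. `local_limit` truncates absorption at a depth
# (reactions from the root); leaves record why absorption stopped.
subroute_fragment <- function(graph, root, choice, bounds, local_limit = Inf) {
  frag <- setNames(choice, root)
  leaves <- character(0)

  absorb <- function(x, path, ld) {
    if (x %in% path) {
      leaves[x] <<- "CYCLE_BLOCKED"
      return(invisible(NULL))
    }
    if (x %in% names(frag)) return(invisible(NULL))  # convergent re-entry
    pr <- producers(graph, x)
    if (!length(pr)) {
      if (!x %in% names(leaves)) leaves[x] <<- "DEAD_END"
      return(invisible(NULL))
    }
    if (is_stop_marked(graph, x, bounds)) {
      if (!x %in% names(leaves)) leaves[x] <<- "STOP"
      return(invisible(NULL))
    }
    if (length(pr) >= 2L) {
      if (!x %in% names(leaves)) leaves[x] <<- "OR_NODE"
      return(invisible(NULL))
    }
    if (ld >= local_limit) {
      if (!x %in% names(leaves)) leaves[x] <<- "BOUND"
      return(invisible(NULL))
    }
    frag[x] <<- pr
    if (x %in% names(leaves)) leaves <<- leaves[names(leaves) != x]
    for (y in reactants_of(graph, pr)) absorb(y, c(path, x), ld + 1)
    invisible(NULL)
  }

  for (y in reactants_of(graph, choice)) absorb(y, root, 1)
  list(root = root, choice = choice, fragment = frag, leaves = leaves)
}

fragment_to_subroute <- function(graph, fr) {
  prov <- fr$fragment
  rxns <- sort_c(unique(prov))
  mols <- unique(c(names(prov), unlist(lapply(rxns, reactants_of, graph = graph))))
  edges <- list()
  for (r in rxns) {
    for (x in reactants_of(graph, r)) edges[[length(edges) + 1L]] <- c("REACTANT", x, r)
  }
  for (m in names(prov)) edges[[length(edges) + 1L]] <- c("PRODUCT", prov[[m]], m)
  df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(df) <- c("kind", "source", "target")
  df <- df[order(df$kind, df$source, df$target, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(
    root = fr$root,
    choice = fr$choice,
    nodes = sort_c(c(mols, rxns)),
    edges = df,
    leaves = fr$leaves[sort_c(names(fr$leaves))],
    fragment = prov
  ), class = "noc_subroute")
}

#' @export
print.noc_subroute <- function(x, ...) {
  cat(sprintf("<noc_subroute> root %s via %s: %d provenance entries, leaves: %s\n",
              x$root, x$choice, length(x$fragment),
              if (length(x$leaves)) paste(names(x$leaves), x$leaves, sep = "=",
                                          collapse = ", ") else "none"))
  invisible(x)
}

# all (choice) fragments for a molecule, lexicographic by reaction uid.
# absorb = FALSE returns minimal one-entry fragments: under a finite bound,
# collapsing forced chains is lossy (every absorbed molecule could instead be
# the BOUND leaf), so each forced molecule must stay an explicit decision.
fragments_for <- function(graph, m, bounds, local_limit, cache = NULL,
                          absorb = TRUE) {
  if (!is.null(cache) && exists(m, envir = cache, inherits = FALSE)) {
    return(get(m, envir = cache))
  }
  frs <- if (absorb) {
    lapply(producers(graph, m), function(r)
      subroute_fragment(graph, m, r, bounds, local_limit))
  } else {
    lapply(producers(graph, m), function(r)
      list(root = m, choice = r, fragment = setNames(r, m),
           leaves = character(0)))
  }
  if (!is.null(cache)) assign(m, frs, envir = cache)
  frs
}

#' Extract subroutes below a target molecule
#'
#' Phase one of route mining: a backward breadth-first traversal from the
#' target collapses contiguous segments where only one producing reaction is
#' possible into *subroutes*. A subroute is opened at the target and at every
#' (OR node, producing reaction) pair reachable under the bounds; its leaves
#' are OR nodes (the next decision points), dead ends (no producers),
#' stop-marked molecules, bound cutoffs, or cycle blocks (a forced expansion
#' that would re-traverse the current expansion path).
#'
#' @param graph A [noc_graph()].
#' @param target_uid Target molecule uid.
#' @param bounds A [route_bounds()].
#' @return Named list: for the target and each reachable OR node, a list of
#'   `noc_subroute` objects (one per producing-reaction choice, in
#'   lexicographic uid order).
#' @export
extract_subroutes <- function(graph, target_uid, bounds = route_bounds()) {
  assert_mol(graph, target_uid)
  D <- bound_depth(bounds)
  tree <- synthetic_tree(graph, target_uid, bounds)
  # minimum depth of each molecule inside the bounded tree
  mind <- setNames(0, target_uid)
  queue <- target_uid
  sub <- tree$subgraph
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    for (r in idx_get(sub$producers_idx, m)) {
      for (x in idx_get(sub$reactants_idx, r)) {
        if (!x %in% names(mind) || mind[[x]] > mind[[m]] + 1) {
          mind[x] <- mind[[m]] + 1
          queue <- c(queue, x)
        }
      }
    }
  }
  roots <- union(target_uid,
                 intersect(names(tree$or_alternatives), names(mind)))
  roots <- c(target_uid, sort_c(setdiff(roots, target_uid)))
  out <- lapply(roots, function(m) {
    lim <- if (is.finite(D)) D - mind[[m]] else Inf
    if (lim <= 0) return(list())
    lapply(fragments_for(graph, m, bounds, lim),
           function(fr) fragment_to_subroute(graph, fr))
  })
  names(out) <- roots
  out
}

## ---- assembly --------------------------------------------------------------

# Restrict a partial provenance map to the closure of the target and compute
# molecule depths. Under a finite bound, `over` lists the provenance
# molecules whose (max) depth has reached the bound: every valid completion
# must cut at least one of them, and all molecules a valid completion cuts
# are always in the current over-set (cutting only removes paths, so depths
# only shrink) -- the assembly therefore branches over single cuts.
normalize_prov <- function(graph, target, prov, D) {
  cl <- route_closure(graph, target, prov)
  prov <- prov[names(prov) %in% cl$mols]
  dp <- route_depths(graph, target, prov, cl)
  over <- if (is.finite(D)) {
    names(prov)[dp$depth[names(prov)] >= D]
  } else character(0)
  discard <- dp$cyclic && !length(over)  # cycle nothing can cut: dead end
  list(discard = discard, prov = prov, depth = dp$depth, closure = cl,
       over = sort_c(over), cyclic = dp$cyclic)
}

pending_molecules <- function(graph, target, prov, closure, depth, D, bounds) {
  cand <- setdiff(closure$mols, names(prov))
  keep <- vapply(cand, function(m) {
    if (!length(producers(graph, m))) return(FALSE)
    if (m != target && is_stop_marked(graph, m, bounds)) return(FALSE)
    depth[[m]] < D
  }, logical(1))
  cand[keep]
}

budget_condition <- function(msg, routes) {
  structure(class = c("rxnmine_budget_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), routes = routes))
}

#' Assemble complete routes from subroutes
#'
#' Phase two of route mining: starting from the target's subroute
#' alternatives, partial routes are iteratively extended by stitching a
#' subroute fragment onto the pending decision point of minimum depth, one
#' partial route per alternative. After every stitch the partial provenance is
#' re-normalized: depths are recomputed (max reactions from the target),
#' molecules whose depth reaches the bound lose their provenance and become
#' `BOUND` leaves, and cyclic provenance discards the partial route (an
#' intermediate only reachable through a cycle is not purchasable). Completed
#' routes pass [validate_route()] and are deduplicated by [route_identity()].
#'
#' @param graph A [noc_graph()].
#' @param subroute_map Output of [extract_subroutes()]; may be `NULL`, in
#'   which case fragments are computed on demand.
#' @param target_uid Target molecule uid.
#' @param bounds A [route_bounds()].
#' @param budget Maximum number of routes (and a proportional cap on
#'   exploration work); exceeding it raises a partial-result error of class
#'   `rxnmine_budget_error` carrying the routes found so far.
#' @return List of `noc_route` objects sorted by (number of steps, identity).
#' @export
assemble_routes <- function(graph, subroute_map = NULL, target_uid,
                            bounds = route_bounds(), budget = 100000L) {
  assert_mol(graph, target_uid)
  D <- bound_depth(bounds)
  cache <- new.env(parent = emptyenv())
  use_absorption <- !is.finite(D)
  if (!is.null(subroute_map) && use_absorption) {
    for (m in names(subroute_map)) {
      frs <- lapply(subroute_map[[m]], function(s)
        list(root = s$root, choice = s$choice, fragment = s$fragment,
             leaves = s$leaves))
      assign(m, frs, envir = cache)
    }
  }
  local_limit <- if (is.finite(D)) D else Inf

  ## Assembly state: a named character map over molecules -- a reaction uid
  ## (chosen provenance) or "" (decided leaf: a bound cut). Under a finite
  ## bound, whether a molecule is expanded or left as a BOUND leaf interacts
  ## with the depths induced by every other decision (multiple consistent
  ## fixpoints exist), so both alternatives are branched explicitly and the
  ## declarative validator arbitrates.
  routes <- list()
  seen_routes <- new.env(parent = emptyenv())
  seen_states <- new.env(parent = emptyenv())
  worklist <- list(setNames(character(0), character(0)))
  steps <- 0L
  step_cap <- max(10000L, 50L * as.integer(min(budget, 1e6)))

  while (length(worklist)) {
    steps <- steps + 1L
    if (steps > step_cap) {
      stop(budget_condition(sprintf(
        "route assembly exceeded its work budget (%d steps); partial results attached",
        step_cap), routes))
    }
    assign_map <- worklist[[length(worklist)]]
    worklist[[length(worklist)]] <- NULL

    prov <- assign_map[nzchar(assign_map)]
    norm <- normalize_prov(graph, target_uid, prov, D)
    if (norm$discard) next
    assign_map <- assign_map[names(assign_map) %in% norm$closure$mols]
    state_key <- if (length(assign_map)) {
      paste(names(assign_map), assign_map, sep = "=", collapse = ";")
    } else "<empty>"
    if (exists(state_key, envir = seen_states, inherits = FALSE)) next
    assign(state_key, TRUE, envir = seen_states)

    if (length(norm$over)) {
      # the bound was hit: branch over which molecule becomes the BOUND leaf
      for (m in norm$over) {
        a2 <- assign_map
        a2[m] <- ""
        worklist[[length(worklist) + 1L]] <- a2
      }
      next
    }
    if (norm$cyclic) next

    pend <- setdiff(
      pending_molecules(graph, target_uid, norm$prov, norm$closure, norm$depth,
                        D, bounds),
      names(assign_map))
    if (!length(pend)) {
      if (!length(norm$prov)) next  # target not producible: no route
      route <- make_route(graph, target_uid, norm$prov, bounds)
      chk <- validate_route(graph, route, bounds)
      if (chk$valid && !exists(route$identity, envir = seen_routes, inherits = FALSE)) {
        assign(route$identity, TRUE, envir = seen_routes)
        routes[[length(routes) + 1L]] <- route
        if (length(routes) > budget) {
          stop(budget_condition(sprintf(
            "route count exceeded budget (%d); partial results attached",
            as.integer(budget)), routes))
        }
      }
      next
    }
    ord <- order(norm$depth[pend], pend, method = "radix")
    m <- pend[ord[1L]]
    if (is.finite(D)) {
      # tentative BOUND leaf: later stitches may raise m's depth to the bound
      a2 <- assign_map
      a2[m] <- ""
      worklist[[length(worklist) + 1L]] <- a2
    }
    frs <- fragments_for(graph, m, bounds, local_limit, cache,
                         absorb = use_absorption)
    # push in reverse so alternatives are explored in lexicographic uid order
    for (fr in rev(frs)) {
      add <- fr$fragment[!names(fr$fragment) %in% names(assign_map)]
      a2 <- c(assign_map, add)
      worklist[[length(worklist) + 1L]] <- a2
    }
  }

  ord <- order(vapply(routes, function(r) length(r$reactions), integer(1)),
               vapply(routes, function(r) r$identity, character(1)),
               method = "radix")
  routes[ord]
}

#' Mine all synthetic routes to a target molecule
#'
#' Exhaustively enumerates every valid synthetic route from starting
#' materials to the target under the given bounds, using the two-phase
#' algorithm (subroute extraction, route assembly). With no bounds the
#' expansion continues until true leaves; see [route_bounds()] for the
#' mitigation options when enumeration explodes combinatorially.
#'
#' @param graph A [noc_graph()].
#' @param target A molecule uid present in the graph, or a SMILES string
#'   (canonicalized, then looked up).
#' @param bounds A [route_bounds()].
#' @param budget Route-count budget; exceeding it raises a partial-result
#'   error of class `rxnmine_budget_error` carrying the routes found so far.
#' @return A [noc_results()] object; each record holds one route's nodes and
#'   edges plus the `noc_route` object and its [route_metrics()].
#' @examples
#' \dontrun{
#' res <- mine_routes(graph, "CC(=O)Nc1ccc(O)cc1",
#'                    route_bounds(max_number_reactions = 4))
#' length(res)
#' }
#' @export
mine_routes <- function(graph, target, bounds = route_bounds(), budget = 100000L) {
  stopifnot(is.character(target), length(target) == 1L)
  uid <- target
  if (!exists(uid, envir = graph$mol, inherits = FALSE)) {
    # exact structure string (covers abstract benchmark labels), then
    # chemical canonicalization
    uid <- compute_uid("molecule", target)
    if (!exists(uid, envir = graph$mol, inherits = FALSE)) {
      can <- tryCatch(canonicalize_molecule(target), error = function(e) NULL)
      uid <- if (!is.null(can)) compute_uid("molecule", can) else NA_character_
      if (is.na(uid) || !exists(uid, envir = graph$mol, inherits = FALSE)) {
        stop("lookup error: target \"", target, "\" not found in graph", call. = FALSE)
      }
    }
  }
  submap <- extract_subroutes(graph, uid, bounds)
  routes <- assemble_routes(graph, submap, uid, bounds, budget)
  noc_results(
    records = lapply(routes, function(rt) {
      list(nodes = rt$nodes, edges = rt$edges, route = rt,
           metrics = route_metrics(rt))
    }),
    query = "mine_routes",
    params = list(target = uid,
                  max_number_reactions = bounds$max_number_reactions,
                  stop_property = bounds$stop_property),
    graph = graph
  )
}

#' Route identities of a mining result
#'
#' @param result A [noc_results()] from [mine_routes()].
#' @return Sorted character vector of route identities.
#' @export
result_identities <- function(result) {
  sort_c(vapply(result$records, function(rec) rec$route$identity, character(1)))
}
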