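#' Bounds for route mining
#'
#' Route enumeration in a dense network explodes combinatorially, so mining
#' accepts two user-defined bounds. `max_number_reactions` caps the *longest
#' linear sequence* of a route -- the maximum number of reactions on any
#' starting-material-to-target path -- not the total step count; a molecule
#' sitting exactly at that depth becomes a `BOUND` leaf. `stop_property`
#' names a node property (e.g. `"startingMaterial"`) whose truthy value halts
#' expansion at that molecule, which then terminates routes as a `STOP` leaf.
#' With no bounds, expansion continues until true leaves (molecules with no
#' incoming `PRODUCT` relationship).
#'
#' @param max_number_reactions Optional positive integer.
#' @param stop_property Optional property name (character scalar).
#' @return An object of class `route_bounds`.
#' @export
route_bounds <- function(max_number_reactions = NULL, stop_property = NULL) {
  if (!is.null(max_number_reactions)) {
    max_number_reactions <- as.integer(max_number_reactions)
    if (length(max_number_reactions) != 1L || is.na(max_number_reactions) ||
        max_number_reactions < 1L) {
      stop("max_number_reactions must be a positive integer", call. = FALSE)
    }
  }
  if (!is.null(stop_property)) {
    stopifnot(is.character(stop_property), length(stop_property) == 1L,
              nzchar(stop_property))
  }
  structure(list(max_number_reactions = max_number_reactions,
                 stop_property = stop_property),
            class = "route_bounds")
}

bound_depth <- function(bounds) bounds$max_number_reactions %||% Inf

## ---- route construction -------------------------------------------------

# Molecules/reactions reachable from the target under a provenance map.
# prov: named character, molecule uid -> producing reaction uid.
route_closure <- function(graph, target, prov) {
  mols <- target
  rxns <- character(0)
  queue <- target
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    r <- if (m %in% names(prov)) prov[[m]] else NA_character_
    if (is.na(r) || r %in% rxns) next
    rxns <- c(rxns, r)
    for (x in reactants_of(graph, r)) {
      if (!x %in% mols) {
        mols <- c(mols, x)
        queue <- c(queue, x)
      }
    }
  }
  list(mols = sort_c(mols), rxns = sort_c(rxns))
}

# Longest-path molecule depths (number of reactions from the target, max over
# paths). Returns cyclic = TRUE when relaxation fails to converge, which on a
# finite graph can only happen if the provenance subgraph contains a cycle.
route_depths <- function(graph, target, prov, closure) {
  mols <- closure$mols
  rxns <- closure$rxns
  depth <- setNames(rep(0, length(mols)), mols)
  if (!length(rxns)) return(list(depth = depth, cyclic = FALSE))
  prods_by_rxn <- split(names(prov), prov)
  reacts_by_rxn <- lapply(setNames(rxns, rxns), function(r)
    intersect(reactants_of(graph, r), mols))
  cyclic <- FALSE
  for (round in seq_len(length(mols) + length(rxns) + 1L)) {
    changed <- FALSE
    for (r in rxns) {
      pp <- prods_by_rxn[[r]]
      if (is.null(pp)) next  # reaction with no provenance product (invalid route)
      dprod <- max(depth[pp])
      dr <- dprod + 1
      xs <- reacts_by_rxn[[r]]
      lower <- xs[depth[xs] < dr]
      if (length(lower)) {
        depth[lower] <- dr
        changed <- TRUE
      }
    }
    if (!changed) break
    if (round == length(mols) + length(rxns) + 1L) cyclic <- TRUE
  }
  list(depth = depth, cyclic = cyclic)
}

#' Construct a synthetic route from a provenance map
#'
#' A route is fully determined by its target and provenance map (the unique
#' producing reaction chosen for each non-starting molecule): its molecule set
#' is the backward closure of the target under the map, its reactions the
#' provenance values, and its edges follow the byproduct rule -- every
#' reaction contributes `REACTANT` edges for its full reactant set (AND
#' semantics) but a `PRODUCT` edge only toward molecules whose provenance maps
#' to it, preserving the one-incoming-`PRODUCT` invariant when a reaction has
#' several products.
#'
#' @param graph A [noc_graph()].
#' @param target Target molecule uid.
#' @param provenance Named character vector, molecule uid -> reaction uid.
#' @param bounds A [route_bounds()] (used to classify leaf termination
#'   reasons).
#' @return An object of class `noc_route` with fields `target`, `provenance`,
#'   `reactions`, `nodes`, `edges`, `leaves` (named vector of termination
#'   reasons: `DEAD_END`, `STOP` or `BOUND`), `depths` and `identity`.
#' @seealso [validate_route()], [route_metrics()], [route_identity()]
#' @export
make_route <- function(graph, target, provenance, bounds = route_bounds()) {
  provenance <- provenance[sort_c(names(provenance))]
  cl <- route_closure(graph, target, provenance)
  provenance <- provenance[names(provenance) %in% cl$mols]
  dp <- route_depths(graph, target, provenance, cl)

  edges <- list()
  for (r in cl$rxns) {
    for (x in reactants_of(graph, r)) {
      edges[[length(edges) + 1L]] <- c("REACTANT", x, r)
    }
  }
  for (m in names(provenance)) {
    edges[[length(edges) + 1L]] <- c("PRODUCT", provenance[[m]], m)
  }
  edges <- if (length(edges)) {
    df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    names(df) <- c("kind", "source", "target")
    df[order(df$kind, df$source, df$target, method = "radix"), , drop = FALSE]
  } else {
    data.frame(kind = character(0), source = character(0), target = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL

  leaf_mols <- setdiff(cl$mols, names(provenance))
  reasons <- vapply(leaf_mols, function(m) {
    if (!length(producers(graph, m))) "DEAD_END"
    else if (m != target && is_stop_marked(graph, m, bounds)) "STOP"
    else "BOUND"
  }, character(1))
  route <- list(
    target = target,
    provenance = provenance,
    reactions = cl$rxns,
    nodes = sort_c(c(cl$mols, cl$rxns)),
    edges = edges,
    leaves = setNames(reasons, leaf_mols),
    depths = dp$depth,
    cyclic = dp$cyclic
  )
  route$identity <- route_identity(route)
  structure(route, class = "noc_route")
}

#' @export
print.noc_route <- function(x, ...) {
  m <- route_metrics(x)
  cat(sprintf("<noc_route> target %s: %d reactions, longest sequence %d, %d leaves\n",
              x$target, m$n_steps, m$longest_sequence, m$n_leaves))
  invisible(x)
}

## ---- declarative validity ------------------------------------------------

#' Check a route against the declarative validity contract
#'
#' A valid synthetic route is a single-rooted subgraph oriented toward its
#' target in which: the target is the only root (no outgoing `REACTANT` edge
#' inside the route); every reaction's full network reactant set is present
#' (AND semantics); every molecule has at most one incoming `PRODUCT` edge
#' (unique provenance); the subgraph is acyclic; every node has a directed
#' path to the target; every leaf is legal (a true dead end with no producers
#' in the network, a stop-marked molecule, or a cut at exactly
#' `max_number_reactions` depth); no expandable molecule is left unexpanded
#' (maximality); and the longest linear sequence does not exceed the bound.
#'
#' Both the two-phase miner and the brute-force reference enumerator are
#' required to emit only routes that pass this check, which pins down the
#' algorithm's semantics independently of its implementation.
#'
#' @param graph A [noc_graph()].
#' @param route A `noc_route` (see [make_route()]).
#' @param bounds A [route_bounds()].
#' @return A list with `valid` (logical) and `violations` (character vector).
#' @export
validate_route <- function(graph, route, bounds = route_bounds()) {
  v <- character(0)
  target <- route$target
  prov <- route$provenance
  D <- bound_depth(bounds)
  edges <- route$edges

  if (!length(route$reactions)) {
    return(list(valid = FALSE, violations = "empty route: no reactions"))
  }
  if (!setequal(route$reactions, unique(prov))) {
    v <- c(v, "reactions set does not equal the set of provenance reactions")
  }

  ## single root
  if (!target %in% route$nodes) v <- c(v, "target not in route")
  out_react <- edges$source[edges$kind == "REACTANT"]
  if (target %in% out_react) {
    v <- c(v, "target has an outgoing REACTANT edge inside the route")
  }

  ## AND-completeness
  react_edges <- edges[edges$kind == "REACTANT", , drop = FALSE]
  for (r in route$reactions) {
    need <- reactants_of(graph, r)
    have <- react_edges$source[react_edges$target == r]
    if (!all(need %in% have) || !all(need %in% route$nodes)) {
      v <- c(v, paste0("AND-completeness: reaction ", r,
                       " is missing part of its reactant set"))
    }
  }

  ## unique provenance
  prod_edges <- edges[edges$kind == "PRODUCT", , drop = FALSE]
  if (anyDuplicated(prod_edges$target)) {
    v <- c(v, "a molecule has more than one incoming PRODUCT edge")
  }
  exp_prod <- sort_c(paste(prov, names(prov), sep = "->"))
  got_prod <- sort_c(paste(prod_edges$source, prod_edges$target, sep = "->"))
  if (!identical(exp_prod, got_prod)) {
    v <- c(v, "PRODUCT edges do not match the provenance map (byproduct rule)")
  }

  ## acyclicity + depths
  cl <- list(mols = sort_c(setdiff(route$nodes, route$reactions)),
             rxns = sort_c(route$reactions))
  dp <- route_depths(graph, target, prov, cl)
  if (dp$cyclic) v <- c(v, "route subgraph is cyclic")

  ## connectivity: every node reaches the target following route edges
  if (!dp$cyclic) {
    reach <- target
    queue <- target
    while (length(queue)) {
      n <- queue[[1L]]; queue <- queue[-1L]
      prev <- edges$source[edges$target == n]
      new <- setdiff(prev, reach)
      reach <- c(reach, new)
      queue <- c(queue, new)
    }
    if (!all(route$nodes %in% reach)) {
      v <- c(v, "route contains nodes with no directed path to the target")
    }
  }

  ## stop semantics: a stop-marked molecule halts expansion entirely
  expanded_stops <- names(prov)[vapply(names(prov), function(m)
    m != target && is_stop_marked(graph, m, bounds), logical(1))]
  if (length(expanded_stops)) {
    v <- c(v, paste0("stop-marked molecule expanded: ",
                     paste(expanded_stops, collapse = ", ")))
  }

  ## leaves: legality and maximality
  if (!dp$cyclic) {
    depth <- dp$depth
    mols <- cl$mols
    leaf_mols <- setdiff(mols, names(prov))
    for (m in leaf_mols) {
      has_prod <- length(producers(graph, m)) > 0L
      stop_ok <- m != target && is_stop_marked(graph, m, bounds)
      bound_ok <- is.finite(D) && depth[[m]] == D
      if (has_prod && !stop_ok && !bound_ok) {
        v <- c(v, paste0("maximality: molecule ", m,
                         " has producers but was left unexpanded"))
      }
    }
    longest <- if (length(depth)) max(depth) else 0
    if (longest > D) {
      v <- c(v, sprintf("longest sequence %d exceeds bound %d",
                        as.integer(longest), as.integer(D)))
    }
  }

  list(valid = length(v) == 0L, violations = v)
}

## ---- metrics --------------------------------------------------------------

#' Metrics of a synthetic route
#'
#' `n_steps` is the number of reactions in the route; `longest_sequence` the
#' maximum number of reactions on any starting-material-to-target path (the
#' quantity capped by `max_number_reactions`); `n_leaves` the number of
#' starting materials; `n_branches = max(n_leaves - 1, 0)` counts the
#' convergent branch points implied by multiple starting materials.
#'
#' @param route A `noc_route`.
#' @return A list of class `route_metrics`.
#' @export
route_metrics <- function(route) {
  stopifnot(inherits(route, "noc_route"))
  n_leaves <- length(route$leaves)
  structure(list(
    n_steps = length(route$reactions),
    longest_sequence = as.integer(if (length(route$depths)) max(route$depths) else 0),
    n_branches = max(n_leaves - 1L, 0L),
    n_leaves = n_leaves
  ), class = "route_metrics")
}

#' @export
print.route_metrics <- function(x, ...) {
  cat(sprintf("steps %d | longest sequence %d | branches %d | leaves %d\n",
              x$n_steps, x$longest_sequence, x$n_branches, x$n_leaves))
  invisible(x)
}
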