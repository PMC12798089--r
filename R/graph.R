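#' Create an empty reaction-molecule network
#'
#' A `noc_graph` is a bipartite directed multistructure: molecule nodes and
#' reaction nodes connected by `REACTANT` edges (molecule -> reaction) and
#' `PRODUCT` edges (reaction -> molecule). Nodes are keyed by content-derived
#' identifiers (see [compute_uid()]) and merging an existing identifier is
#' idempotent: node properties merge last-write-wins, edges have set
#' semantics. Duplicate reactions therefore collapse at merge time.
#'
#' The object is backed by environments and has *reference semantics*: merge
#' operations mutate the graph in place and return it invisibly (the same
#' convention as `data.table`). Use [clone_graph()] for an independent copy.
#'
#' @return An empty `noc_graph`.
#' @seealso [merge_node()], [merge_edge()], [ingest()], [noc_stats()]
#' @export
noc_graph <- function() {
  g <- list(
    mol = new.env(parent = emptyenv()),  # uid -> list(uid, smiles, properties)
    rxn = new.env(parent = emptyenv()),  # uid -> list(uid, rxn_smiles, properties)
    edge = new.env(parent = emptyenv()), # "KIND|source|target" -> edge list
    producers_idx = new.env(parent = emptyenv()), # mol uid -> rxn uids producing it
    consumers_idx = new.env(parent = emptyenv()), # mol uid -> rxn uids consuming it
    reactants_idx = new.env(parent = emptyenv()), # rxn uid -> reactant mol uids
    products_idx  = new.env(parent = emptyenv())  # rxn uid -> product mol uids
  )
  structure(g, class = "noc_graph")
}

#' Deep-copy a reaction network
#'
#' @param graph A `noc_graph`.
#' @return An independent `noc_graph` with identical content.
#' @export
clone_graph <- function(graph) {
  stopifnot(inherits(graph, "noc_graph"))
  g2 <- noc_graph()
  for (slot in names(unclass(graph))) {
    e1 <- graph[[slot]]
    e2 <- g2[[slot]]
    for (k in ls(e1, all.names = TRUE)) assign(k, get(k, envir = e1), envir = e2)
  }
  g2
}

## ---- node constructors ------------------------------------------------

#' Construct graph nodes
#'
#' `molecule_node()` and `reaction_node()` build validated node records whose
#' uid is derived from the canonical string. Properties are free-form scalar
#' maps (character/numeric/logical), e.g. a `startingMaterial` stop flag.
#'
#' @param smiles Canonical SMILES of the molecule (any non-empty string for
#'   abstract benchmark graphs).
#' @param rxn_smiles Canonical two-sided reaction SMILES
#'   (`"reactants>>products"`, dot-separated species).
#' @param properties Named list of scalar properties.
#' @return A node record (list with `uid`, structure string, `properties`).
#' @export
molecule_node <- function(smiles, properties = list()) {
  check_properties(properties)
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("molecule_node(): smiles must be a non-empty string", call. = FALSE)
  }
  list(uid = compute_uid("molecule", smiles), kind = "molecule",
       smiles = smiles, properties = properties)
}

#' @rdname molecule_node
#' @export
reaction_node <- function(rxn_smiles, properties = list()) {
  check_properties(properties)
  if (!is.character(rxn_smiles) || length(rxn_smiles) != 1L || is.na(rxn_smiles) ||
      !nzchar(rxn_smiles)) {
    stop("reaction_node(): rxn_smiles must be a non-empty string", call. = FALSE)
  }
  sides <- strsplit(rxn_smiles, ">>", fixed = TRUE)[[1L]]
  if (length(sides) != 2L || !nzchar(sides[1L]) || !nzchar(sides[2L]) ||
      length(gregexpr(">>", rxn_smiles, fixed = TRUE)[[1L]]) != 1L) {
    stop("reaction_node(): rxn_smiles must have exactly one '>>' and non-empty sides",
         call. = FALSE)
  }
  list(uid = compute_uid("reaction", rxn_smiles), kind = "reaction",
       rxn_smiles = rxn_smiles, properties = properties)
}

check_properties <- function(properties) {
  if (!is.list(properties)) stop("properties must be a named list", call. = FALSE)
  if (length(properties)) {
    nm <- names(properties)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("property keys must be non-empty strings", call. = FALSE)
    }
    ok <- vapply(properties, function(v)
      length(v) == 1L && (is.character(v) || is.numeric(v) || is.logical(v)),
      logical(1))
    if (!all(ok)) stop("property values must be scalar character/numeric/logical",
                       call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an edge record
#'
#' `PRODUCT` edges run reaction -> molecule, `REACTANT` edges run
#' molecule -> reaction; any other orientation is rejected at merge time.
#'
#' @param kind `"PRODUCT"` or `"REACTANT"`.
#' @param source,target Node uids.
#' @export
noc_edge <- function(kind, source, target) {
  kind <- match.arg(kind, c("PRODUCT", "REACTANT"))
  list(kind = kind, source = source, target = target)
}

edge_key <- function(e) paste(e$kind, e$source, e$target, sep = "|")

## ---- merge ------------------------------------------------------------

idx_add <- function(env, key, value) {
  cur <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else character(0)
  if (!value %in% cur) assign(key, c(cur, value), envir = env)
  invisible(NULL)
}

idx_get <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else character(0)
}

#' Merge nodes and edges into a network
#'
#' Merging is idempotent by uid: inserting a node that already exists leaves
#' the node count unchanged and merges its properties last-write-wins;
#' inserting an existing edge is a no-op (edge set semantics). Edges are
#' validated against the bipartite direction law and both endpoints must
#' already be present.
#'
#' @param graph A [noc_graph()]. Mutated in place (reference semantics).
#' @param node A node record from [molecule_node()] or [reaction_node()].
#' @param edge An edge record from [noc_edge()].
#' @return The graph, invisibly.
#' @export
merge_node <- function(graph, node) {
  stopifnot(inherits(graph, "noc_graph"))
  env <- if (identical(node$kind, "molecule")) graph$mol else graph$rxn
  if (exists(node$uid, envir = env, inherits = FALSE)) {
    old <- get(node$uid, envir = env)
    if (length(node$properties)) {
      old$properties <- modifyList(old$properties, node$properties)
      assign(node$uid, old, envir = env)
    }
  } else {
    assign(node$uid, node, envir = env)
  }
  invisible(graph)
}

#' @rdname merge_node
#' @export
merge_edge <- function(graph, edge) {
  stopifnot(inherits(graph, "noc_graph"))
  src <- edge$source; tgt <- edge$target
  if (identical(edge$kind, "PRODUCT")) {
    ok <- exists(src, envir = graph$rxn, inherits = FALSE) &&
      exists(tgt, envir = graph$mol, inherits = FALSE)
    if (!ok) stop("integrity error: PRODUCT edge must run reaction -> molecule, ",
                  "with both endpoints present", call. = FALSE)
  } else if (identical(edge$kind, "REACTANT")) {
    ok <- exists(src, envir = graph$mol, inherits = FALSE) &&
      exists(tgt, envir = graph$rxn, inherits = FALSE)
    if (!ok) stop("integrity error: REACTANT edge must run molecule -> reaction, ",
                  "with both endpoints present", call. = FALSE)
  } else {
    stop("integrity error: unknown edge kind ", edge$kind, call. = FALSE)
  }
  key <- edge_key(edge)
  if (!exists(key, envir = graph$edge, inherits = FALSE)) {
    assign(key, edge, envir = graph$edge)
    if (edge$kind == "PRODUCT") {
      idx_add(graph$producers_idx, tgt, src)
      idx_add(graph$products_idx, src, tgt)
    } else {
      idx_add(graph$consumers_idx, src, tgt)
      idx_add(graph$reactants_idx, tgt, src)
    }
  }
  invisible(graph)
}

## ---- accessors --------------------------------------------------------

assert_mol <- function(graph, uid) {
  if (!exists(uid, envir = graph$mol, inherits = FALSE)) {
    stop("lookup error: unknown molecule uid ", uid, call. = FALSE)
  }
}

assert_rxn <- function(graph, uid) {
  if (!exists(uid, envir = graph$rxn, inherits = FALSE)) {
    stop("lookup error: unknown reaction uid ", uid, call. = FALSE)
  }
}

#' Neighborhood accessors
#'
#' `producers()` returns the reactions with a `PRODUCT` edge into a molecule;
#' `consumers()` the reactions consuming it via `REACTANT` edges;
#' `reactants_of()` / `products_of()` the molecule sets of a reaction. All
#' results are sorted for determinism. Unknown uids raise a lookup error.
#'
#' @param graph A [noc_graph()].
#' @param uid A molecule uid (for `producers`/`consumers`) or reaction uid.
#' @return Character vector of uids (possibly empty).
#' @export
producers <- function(graph, uid) {
  assert_mol(graph, uid)
  sort_c(idx_get(graph$producers_idx, uid))
}

#' @rdname producers
#' @export
consumers <- function(graph, uid) {
  assert_mol(graph, uid)
  sort_c(idx_get(graph$consumers_idx, uid))
}

#' @rdname producers
#' @export
reactants_of <- function(graph, uid) {
  assert_rxn(graph, uid)
  sort_c(idx_get(graph$reactants_idx, uid))
}

#' @rdname producers
#' @export
products_of <- function(graph, uid) {
  assert_rxn(graph, uid)
  sort_c(idx_get(graph$products_idx, uid))
}

molecule_uids <- function(graph) sort_c(ls(graph$mol, all.names = TRUE))
reaction_uids <- function(graph) sort_c(ls(graph$rxn, all.names = TRUE))
edge_keys <- function(graph) sort_c(ls(graph$edge, all.names = TRUE))

get_mol <- function(graph, uid) get(uid, envir = graph$mol)
get_rxn <- function(graph, uid) get(uid, envir = graph$rxn)

get_node <- function(graph, uid) {
  if (exists(uid, envir = graph$mol, inherits = FALSE)) return(get(uid, envir = graph$mol))
  if (exists(uid, envir = graph$rxn, inherits = FALSE)) return(get(uid, envir = graph$rxn))
  stop("lookup error: unknown uid ", uid, call. = FALSE)
}

#' Edges of a network as a data frame
#'
#' @param graph A [noc_graph()].
#' @return A data frame with columns `kind`, `source`, `target`, ordered by
#'   (kind, source, target).
#' @export
noc_edges <- function(graph) {
  keys <- edge_keys(graph)
  if (!length(keys)) {
    return(data.frame(kind = character(0), source = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    kind = vapply(parts, `[[`, "", 1L),
    source = vapply(parts, `[[`, "", 2L),
    target = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' Molecules with multiple producing reactions (OR nodes)
#'
#' An OR node is a molecule with at least two incoming `PRODUCT` edges. Each
#' producing reaction is an alternative provenance; a synthetic route may use
#' at most one of them, so OR nodes are exactly the decision points of route
#' mining.
#'
#' @param graph A [noc_graph()].
#' @return Sorted character vector of molecule uids.
#' @export
or_nodes <- function(graph) {
  mols <- ls(graph$producers_idx, all.names = TRUE)
  hits <- mols[vapply(mols, function(m) length(idx_get(graph$producers_idx, m)) >= 2L,
                      logical(1))]
  sort_c(hits)
}

## ---- stats ------------------------------------------------------------

#' Network statistics
#'
#' Summary counts over the bipartite network: node and edge totals, root
#' molecules (produced by at least one reaction, consumed by none), leaf
#' molecules (consumed but never produced, i.e. starting materials), OR nodes,
#' and the average number of reactant/product edges per reaction. Molecules
#' with neither producers nor consumers are counted in `n_molecules` only.
#'
#' @param graph A [noc_graph()].
#' @return An object of class `noc_stats` (a named list).
#' @export
noc_stats <- function(graph) {
  mols <- molecule_uids(graph)
  n_mol <- length(mols)
  n_rxn <- length(reaction_uids(graph))
  n_prod_in <- vapply(mols, function(m) length(idx_get(graph$producers_idx, m)), integer(1))
  n_cons_out <- vapply(mols, function(m) length(idx_get(graph$consumers_idx, m)), integer(1))
  if (!n_mol) {
    n_prod_in <- integer(0); n_cons_out <- integer(0)
  }
  n_product_edges <- sum(n_prod_in)
  n_reactant_edges <- sum(n_cons_out)
  structure(list(
    n_molecules = n_mol,
    n_reactions = n_rxn,
    n_product_edges = n_product_edges,
    n_reactant_edges = n_reactant_edges,
    n_roots = sum(n_prod_in >= 1L & n_cons_out == 0L),
    n_leaves = sum(n_prod_in == 0L & n_cons_out >= 1L),
    n_or_nodes = sum(n_prod_in >= 2L),
    avg_reactants_per_reaction = if (n_rxn > 0L) n_reactant_edges / n_rxn else NA_real_,
    avg_products_per_reaction = if (n_rxn > 0L) n_product_edges / n_rxn else NA_real_
  ), class = "noc_stats")
}

#' @export
print.noc_stats <- function(x, ...) {
  cat("Reaction network statistics\n")
  fmt <- function(v) if (is.na(v)) "undefined" else format(v, digits = 6)
  cat(sprintf("  molecules:        %d\n", x$n_molecules))
  cat(sprintf("  reactions:        %d\n", x$n_reactions))
  cat(sprintf("  PRODUCT edges:    %d\n", x$n_product_edges))
  cat(sprintf("  REACTANT edges:   %d\n", x$n_reactant_edges))
  cat(sprintf("  root molecules:   %d\n", x$n_roots))
  cat(sprintf("  leaf molecules:   %d\n", x$n_leaves))
  cat(sprintf("  OR nodes:         %d\n", x$n_or_nodes))
  cat(sprintf("  avg reactants/reaction: %s\n", fmt(x$avg_reactants_per_reaction)))
  cat(sprintf("  avg products/reaction:  %s\n", fmt(x$avg_products_per_reaction)))
  invisible(x)
}

#' @export
print.noc_graph <- function(x, ...) {
  cat(sprintf("<noc_graph> %d molecules, %d reactions, %d edges\n",
              length(ls(x$mol)), length(ls(x$rxn)), length(ls(x$edge))))
  invisible(x)
}

#' Compare two networks for content equality
#'
#' Labeled-graph equality: same node uids, same node payloads (including
#' properties, order-insensitive) and same edge set.
#'
#' @param g1,g2 [noc_graph()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
noc_equal <- function(g1, g2) {
  if (!identical(molecule_uids(g1), molecule_uids(g2))) return(FALSE)
  if (!identical(reaction_uids(g1), reaction_uids(g2))) return(FALSE)
  if (!identical(edge_keys(g1), edge_keys(g2))) return(FALSE)
  same_node <- function(a, b) {
    pa <- a$properties[sort_c(names(a$properties))]
    pb <- b$properties[sort_c(names(b$properties))]
    identical(a[setdiff(names(a), "properties")], b[setdiff(names(b), "properties")]) &&
      identical(pa, pb)
  }
  for (u in molecule_uids(g1)) if (!same_node(get_mol(g1, u), get_mol(g2, u))) return(FALSE)
  for (u in reaction_uids(g1)) if (!same_node(get_rxn(g1, u), get_rxn(g2, u))) return(FALSE)
  TRUE
}

## ---- predicate selection ----------------------------------------------

#' Select a subgraph by node and edge predicates
#'
#' A declarative replacement for database pattern queries: keeps nodes for
#' which `node_predicate` is `TRUE` and edges for which both endpoints were
#' kept *and* `edge_predicate` is `TRUE`. Returns a one-record [result
#' set][noc_results].
#'
#' @param graph A [noc_graph()].
#' @param node_predicate `function(node, graph)` returning a scalar logical;
#'   the node record carries `uid`, `kind`, `smiles`/`rxn_smiles` and
#'   `properties`. Defaults to all nodes.
#' @param edge_predicate `function(edge, graph)` returning a scalar logical.
#'   Defaults to all edges.
#' @return A `noc_results` object with a single record.
#' @export
noc_select <- function(graph, node_predicate = NULL, edge_predicate = NULL) {
  keep_node <- function(n) is.null(node_predicate) || isTRUE(node_predicate(n, graph))
  keep_edge <- function(e) is.null(edge_predicate) || isTRUE(edge_predicate(e, graph))
  mols <- Filter(function(u) keep_node(get_mol(graph, u)), molecule_uids(graph))
  rxns <- Filter(function(u) keep_node(get_rxn(graph, u)), reaction_uids(graph))
  kept <- c(mols, rxns)
  edges <- noc_edges(graph)
  if (nrow(edges)) {
    in_kept <- edges$source %in% kept & edges$target %in% kept
    edges <- edges[in_kept, , drop = FALSE]
    if (nrow(edges)) {
      keep <- vapply(seq_len(nrow(edges)), function(i)
        keep_edge(as.list(edges[i, ])), logical(1))
      edges <- edges[keep, , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  noc_results(
    records = list(list(nodes = sort_c(kept), edges = edges)),
    query = "select",
    params = list()
  )
}

## ---- result sets -------------------------------------------------------

#' Query result container
#'
#' An ordered collection of records, each holding a set of node uids and an
#' edge table, plus provenance metadata (query name and parameters). Route
#' queries attach the route object and its metrics to each record.
#'
#' @param records List of records; each record is a list with at least
#'   `nodes` (character vector of uids) and `edges` (data frame with
#'   `kind`/`source`/`target`).
#' @param query Query name.
#' @param params Named list of query parameters.
#' @param graph Optionally, the graph the records refer to (used by
#'   exporters to resolve node payloads).
#' @return An object of class `noc_results`.
#' @export
noc_results <- function(records, query = "", params = list(), graph = NULL) {
  structure(list(records = records, query = query, params = params, graph = graph),
            class = "noc_results")
}

#' @export
print.noc_results <- function(x, ...) {
  cat(sprintf("<noc_results> query '%s': %d record(s)\n", x$query, length(x$records)))
  invisible(x)
}

#' @export
length.noc_results <- function(x) length(x$records)

## ---- synthetic tree ----------------------------------------------------

#' Extract the synthetic tree of a target molecule
#'
#' The synthetic tree aggregates every synthetic route converging on the
#' target: it is the backward-reachable closure from the target, alternating
#' incoming `PRODUCT` edges (molecule to its producers) and incoming
#' `REACTANT` edges (reaction to its reactants), honouring the same bounds as
#' route mining. Expansion stops at stop-marked molecules and at
#' `max_number_reactions` reaction layers (a molecule's depth being the
#' minimum number of reactions from the target). Despite the name, the result
#' may contain cycles.
#'
#' @param graph A [noc_graph()].
#' @param target_uid Molecule uid of the target.
#' @param bounds A [route_bounds()] object.
#' @return A list of class `noc_tree`: `target`, `subgraph` (a `noc_graph`
#'   fragment), and `or_alternatives` (named integer vector of
#'   producing-alternative counts for the tree's OR nodes).
#' @export
synthetic_tree <- function(graph, target_uid, bounds = route_bounds()) {
  assert_mol(graph, target_uid)
  d_max <- bounds$max_number_reactions %||% Inf
  sub <- noc_graph()
  merge_node(sub, get_mol(graph, target_uid))
  depth <- setNames(0, target_uid)
  queue <- target_uid
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    d <- depth[[m]]
    if (d >= d_max) next
    if (m != target_uid && is_stop_marked(graph, m, bounds)) next
    for (r in producers(graph, m)) {
      merge_node(sub, get_rxn(graph, r))
      merge_edge(sub, noc_edge("PRODUCT", r, m))
      for (x in reactants_of(graph, r)) {
        merge_node(sub, get_mol(graph, x))
        merge_edge(sub, noc_edge("REACTANT", x, r))
        if (!x %in% names(depth) || depth[[x]] > d + 1) {
          depth[x] <- d + 1  # minimum-depth semantics; re-relax if improved
          queue <- c(queue, x)
        }
      }
    }
  }
  alt <- vapply(molecule_uids(sub), function(m) length(idx_get(sub$producers_idx, m)),
                integer(1))
  alt <- alt[alt >= 2L]
  structure(list(target = target_uid, subgraph = sub,
                 or_alternatives = alt[sort_c(names(alt))]),
            class = "noc_tree")
}

#' @export
print.noc_tree <- function(x, ...) {
  cat(sprintf("<noc_tree> target %s: %d molecules, %d reactions, %d OR nodes\n",
              x$target, length(ls(x$subgraph$mol)), length(ls(x$subgraph$rxn)),
              length(x$or_alternatives)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_stop_marked <- function(graph, mol_uid, bounds) {
  sp <- bounds$stop_property
  if (is.null(sp)) return(FALSE)
  props <- get_mol(graph, mol_uid)$properties
  isTRUE(as.logical(props[[sp]]))
}
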