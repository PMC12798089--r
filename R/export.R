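node_payload_string <- function(node) {
  if (node$kind == "molecule") node$smiles else node$rxn_smiles
}

props_json <- function(props) {
  if (!length(props)) return("{}")
  props <- props[sort_c(names(props))]
  as.character(jsonlite::toJSON(props, auto_unbox = TRUE, digits = NA))
}

#' Export a result set as node and edge tables
#'
#' Flattens a [noc_results()] into two data frames. The node table has
#' columns `record_id` (iff `with_records_id`), `uid`, `kind`, `smiles` (the
#' molecule SMILES or the reaction SMILES) and `properties` (a JSON string);
#' the edge table has `record_id` (iff flag), `kind`, `source`, `target`.
#' Rows are ordered by record then uid (edges by kind, source, target). With
#' `with_records_id = FALSE` the records are merged and duplicate rows
#' collapsed.
#'
#' @param result A [noc_results()].
#' @param with_records_id Keep the per-record separation? Default `TRUE`;
#'   record ids are zero-based.
#' @param graph Graph used to resolve node payloads; defaults to the graph
#'   attached to the result.
#' @return A list with data frames `nodes` and `edges`.
#' @export
write_tables <- function(result, with_records_id = TRUE, graph = NULL) {
  stopifnot(inherits(result, "noc_results"))
  graph <- graph %||% result$graph
  if (is.null(graph)) stop("write_tables(): no graph available to resolve nodes",
                           call. = FALSE)
  nrows <- list(); erows <- list()
  for (i in seq_along(result$records)) {
    rec <- result$records[[i]]
    for (u in sort_c(rec$nodes)) {
      nd <- get_node(graph, u)
      nrows[[length(nrows) + 1L]] <- data.frame(
        record_id = i - 1L, uid = u, kind = nd$kind,
        smiles = node_payload_string(nd),
        properties = props_json(nd$properties),
        stringsAsFactors = FALSE)
    }
    e <- rec$edges
    if (nrow(e)) {
      e <- e[order(e$kind, e$source, e$target, method = "radix"), , drop = FALSE]
      e <- cbind(record_id = i - 1L, e)
      erows[[length(erows) + 1L]] <- e
    }
  }
  nodes <- if (length(nrows)) do.call(rbind, nrows) else
    data.frame(record_id = integer(0), uid = character(0), kind = character(0),
               smiles = character(0), properties = character(0),
               stringsAsFactors = FALSE)
  edges <- if (length(erows)) do.call(rbind, erows) else
    data.frame(record_id = integer(0), kind = character(0), source = character(0),
               target = character(0), stringsAsFactors = FALSE)
  if (!with_records_id) {
    nodes$record_id <- NULL
    edges$record_id <- NULL
    nodes <- unique(nodes)
    edges <- unique(edges)
    nodes <- nodes[order(nodes$uid, method = "radix"), , drop = FALSE]
    if (nrow(edges)) {
      edges <- edges[order(edges$kind, edges$source, edges$target,
                           method = "radix"), , drop = FALSE]
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

## ---- canonical graph JSON ----------------------------------------------------

GRAPH_JSON_SCHEMA <- "noc-graph-json"
GRAPH_JSON_VERSION <- 1L

node_to_list <- function(nd) {
  out <- list(uid = nd$uid)
  if (nd$kind == "molecule") out$smiles <- nd$smiles else out$rxn_smiles <- nd$rxn_smiles
  out$properties <- if (length(nd$properties)) {
    nd$properties[sort_c(names(nd$properties))]
  } else structure(list(), names = character(0))
  out
}

edges_to_list <- function(edges_df) {
  lapply(seq_len(nrow(edges_df)), function(i)
    list(kind = edges_df$kind[i], source = edges_df$source[i],
         target = edges_df$target[i]))
}

#' Canonical graph JSON persistence
#'
#' The package's lossless on-disk format for graphs and query results: a
#' versioned, deterministically ordered JSON document (nodes sorted by uid,
#' edges by kind/source/target), so identical objects always serialize to
#' byte-identical files. `read_graph_json()` restores a [noc_graph()] or, for
#' result documents, a [noc_results()] whose records (node uid sets and edge
#' tables) round-trip exactly; a catalog of node payloads accompanies result
#' records and is restored as the attached graph fragment.
#'
#' @param x A [noc_graph()] or [noc_results()].
#' @param path Output file.
#' @return `write_graph_json()` returns `path` invisibly; `read_graph_json()`
#'   the restored object.
#' @export
write_graph_json <- function(x, path) {
  if (inherits(x, "noc_graph")) {
    doc <- list(
      schema = GRAPH_JSON_SCHEMA, version = GRAPH_JSON_VERSION, kind = "graph",
      molecules = lapply(molecule_uids(x), function(u) node_to_list(get_mol(x, u))),
      reactions = lapply(reaction_uids(x), function(u) node_to_list(get_rxn(x, u))),
      edges = edges_to_list(noc_edges(x))
    )
  } else if (inherits(x, "noc_results")) {
    g <- x$graph
    if (is.null(g)) stop("write_graph_json(): result set has no attached graph",
                         call. = FALSE)
    all_uids <- sort_c(unique(unlist(lapply(x$records, `[[`, "nodes"))))
    mols <- all_uids[vapply(all_uids, function(u)
      exists(u, envir = g$mol, inherits = FALSE), logical(1))]
    rxns <- setdiff(all_uids, mols)
    doc <- list(
      schema = GRAPH_JSON_SCHEMA, version = GRAPH_JSON_VERSION, kind = "results",
      query = x$query,
      params = x$params[!vapply(x$params, is.null, logical(1))],
      catalog = list(
        molecules = lapply(mols, function(u) node_to_list(get_mol(g, u))),
        reactions = lapply(rxns, function(u) node_to_list(get_rxn(g, u)))
      ),
      records = lapply(x$records, function(rec)
        list(nodes = as.list(sort_c(rec$nodes)), edges = edges_to_list(rec$edges)))
    )
  } else {
    stop("write_graph_json(): x must be a noc_graph or noc_results", call. = FALSE)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

restore_props <- function(p) {
  if (!length(p)) return(list())
  p[sort_c(names(p))]
}

edges_from_list <- function(lst) {
  if (!length(lst)) {
    return(data.frame(kind = character(0), source = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    kind = vapply(lst, `[[`, "", "kind"),
    source = vapply(lst, `[[`, "", "source"),
    target = vapply(lst, `[[`, "", "target"),
    stringsAsFactors = FALSE)
  df <- df[order(df$kind, df$source, df$target, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

load_catalog_graph <- function(mol_list, rxn_list, edge_df) {
  g <- noc_graph()
  for (nd in mol_list) {
    merge_node(g, molecule_node(nd$smiles, properties = restore_props(nd$properties)))
  }
  for (nd in rxn_list) {
    merge_node(g, reaction_node(nd$rxn_smiles, properties = restore_props(nd$properties)))
  }
  if (nrow(edge_df)) {
    for (i in seq_len(nrow(edge_df))) {
      merge_edge(g, noc_edge(edge_df$kind[i], edge_df$source[i], edge_df$target[i]))
    }
  }
  g
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("format error: cannot parse ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!identical(doc$schema, GRAPH_JSON_SCHEMA)) {
    stop("format error: not a ", GRAPH_JSON_SCHEMA, " document", call. = FALSE)
  }
  if (!identical(as.integer(doc$version), GRAPH_JSON_VERSION)) {
    stop("format error: unsupported version ", doc$version,
         " (this build reads version ", GRAPH_JSON_VERSION, ")", call. = FALSE)
  }
  if (identical(doc$kind, "graph")) {
    load_catalog_graph(doc$molecules, doc$reactions, edges_from_list(doc$edges))
  } else if (identical(doc$kind, "results")) {
    records <- lapply(doc$records, function(rec)
      list(nodes = sort_c(unlist(rec$nodes)), edges = edges_from_list(rec$edges)))
    all_edges <- do.call(rbind, c(
      list(data.frame(kind = character(0), source = character(0),
                      target = character(0), stringsAsFactors = FALSE)),
      lapply(records, `[[`, "edges")))
    g <- load_catalog_graph(doc$catalog$molecules, doc$catalog$reactions,
                            unique(all_edges))
    noc_results(records = records, query = doc$query %||% "",
                params = doc$params %||% list(), graph = g)
  } else {
    stop("format error: unknown document kind ", doc$kind, call. = FALSE)
  }
}

## ---- GraphML ------------------------------------------------------------------

#' Export a graph to GraphML
#'
#' Standard GraphML 1.0 with node attributes `kind` and `smiles` and edge
#' attribute `kind`, importable by mainstream graph tools.
#'
#' @param graph A [noc_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "noc_graph"))
  uids <- c(molecule_uids(graph), reaction_uids(graph))
  if (length(uids)) {
    vertices <- data.frame(
      name = uids,
      kind = c(rep("molecule", length(molecule_uids(graph))),
               rep("reaction", length(reaction_uids(graph)))),
      smiles = vapply(uids, function(u) node_payload_string(get_node(graph, u)), ""),
      stringsAsFactors = FALSE)
    e <- noc_edges(graph)
    ig <- igraph::graph_from_data_frame(
      d = data.frame(from = e$source, to = e$target, kind = e$kind,
                     stringsAsFactors = FALSE),
      directed = TRUE, vertices = vertices)
  } else {
    ig <- igraph::make_empty_graph(directed = TRUE)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

## ---- routes as reaction strings ------------------------------------------------

#' Convert mined routes to reaction-string lists
#'
#' For each record, emits the route's reaction SMILES in deterministic
#' topological order: reactions closest to the starting materials first, the
#' target-producing reaction last (ties broken by uid). With
#' `with_records_id = FALSE` the per-record lists are flattened into a single
#' deduplicated list (first-occurrence order).
#'
#' @param result A [noc_results()] from [mine_routes()].
#' @param with_records_id Keep one list per record? Default `TRUE`.
#' @param graph Graph to resolve reaction strings; defaults to the attached
#'   graph.
#' @return A list of character vectors, or a single character vector when
#'   `with_records_id = FALSE`.
#' @export
routes_to_reaction_strings <- function(result, with_records_id = TRUE,
                                       graph = NULL) {
  stopifnot(inherits(result, "noc_results"))
  graph <- graph %||% result$graph
  if (is.null(graph)) stop("routes_to_reaction_strings(): no graph available",
                           call. = FALSE)
  one <- function(rec) {
    rxns <- if (!is.null(rec$route)) rec$route$reactions else
      rec$nodes[vapply(rec$nodes, function(u)
        exists(u, envir = graph$rxn, inherits = FALSE), logical(1))]
    if (!length(rxns)) return(character(0))
    if (!is.null(rec$route)) {
      rt <- rec$route
      # reaction depth: one more than the max depth of the molecules it
      # produces within the route
      rdepth <- vapply(rxns, function(r) {
        prods <- names(rt$provenance)[rt$provenance == r]
        max(rt$depths[prods]) + 1
      }, numeric(1))
      rxns <- rxns[order(-rdepth, rxns, method = "radix")]
    } else {
      rxns <- sort_c(rxns)
    }
    vapply(rxns, function(r) get_rxn(graph, r)$rxn_smiles, "", USE.NAMES = FALSE)
  }
  out <- lapply(result$records, one)
  if (with_records_id) return(out)
  flat <- unlist(out, use.names = FALSE)
  if (is.null(flat)) character(0) else flat[!duplicated(flat)]
}
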