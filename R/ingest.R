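#' Ingest reaction strings into a reaction network
#'
#' Parses, optionally validates (canonicalization + role reassignment), and
#' merges a batch of reaction SMILES strings into a bipartite
#' reaction-molecule network. Duplicate reactions collapse by content-derived
#' identifier: with `validate = TRUE` two reactions are duplicates when their
#' canonical reaction strings coincide; with `validate = FALSE` duplicate
#' detection falls back to the reaction string as written (no
#' canonicalization, original species order preserved).
#'
#' Rows are processed in chunks of `chunk_size`. Because node and edge merging
#' is commutative, associative and idempotent, the resulting graph is
#' identical for any chunk size, worker count or row order; `n_workers` is
#' accepted for configuration compatibility but execution is sequential.
#'
#' @param x Character vector of reaction SMILES, or a data frame with a
#'   reaction-string column.
#' @param reaction_column Column holding reaction strings when `x` is a data
#'   frame.
#' @param validate Apply standardization (SMILES canonicalization, within-role
#'   deduplication, both-sides role reassignment)? Default `TRUE`.
#' @param chunk_size Rows per processing chunk (>= 1).
#' @param n_workers Accepted for configuration compatibility; must be >= 1.
#' @param on_error `"skip_and_log"` (default): failed rows are skipped and
#'   recorded in the report; `"fail_fast"`: stop at the first failure.
#' @param graph An existing [noc_graph()] to merge into; a fresh graph by
#'   default.
#' @return A list with `graph` (the merged [noc_graph()]) and `report` (an
#'   `ingestion_report`: input/failed row counts, distinct reaction and
#'   molecule counts touched by this ingestion, and per-row failures).
#' @examples
#' \dontrun{
#' res <- ingest(c("CCO.CC(=O)O>>CCOC(C)=O", "OCC.CC(=O)O>>CCOC(C)=O"))
#' res$report$n_unique_reactions  # 1: same reaction written two ways
#' }
#' @export
ingest <- function(x, reaction_column = "reaction", validate = TRUE,
                   chunk_size = 1000L, n_workers = 1L,
                   on_error = c("skip_and_log", "fail_fast"),
                   graph = NULL) {
  on_error <- match.arg(on_error)
  chunk_size <- as.integer(chunk_size)
  n_workers <- as.integer(n_workers)
  if (is.na(chunk_size) || chunk_size < 1L) stop("chunk_size must be >= 1", call. = FALSE)
  if (is.na(n_workers) || n_workers < 1L) stop("n_workers must be >= 1", call. = FALSE)
  if (is.data.frame(x)) {
    if (!reaction_column %in% names(x)) {
      stop("configuration error: column \"", reaction_column,
           "\" not found in input table", call. = FALSE)
    }
    rows <- as.character(x[[reaction_column]])
  } else if (is.character(x)) {
    rows <- x
  } else {
    stop("configuration error: input must be a character vector or data frame",
         call. = FALSE)
  }
  if (is.null(graph)) graph <- noc_graph()
  stopifnot(inherits(graph, "noc_graph"))

  failures_row <- integer(0)
  failures_reason <- character(0)
  touched_rxn <- character(0)
  touched_mol <- character(0)

  n <- length(rows)
  chunk_starts <- seq(1L, max(n, 1L), by = chunk_size)
  for (cs in chunk_starts) {
    if (n == 0L) break
    idx <- cs:min(cs + chunk_size - 1L, n)
    chunk <- rows[idx]
    parsed <- vector("list", length(chunk))
    for (k in seq_along(chunk)) {
      parsed[[k]] <- tryCatch(parse_reaction_string(chunk[[k]]),
                              error = function(e) conditionMessage(e))
    }
    if (validate) {
      # canonicalize all species of the chunk in one pass
      species <- unlist(lapply(parsed, function(p)
        if (inherits(p, "reaction_roles")) unlist(p, use.names = FALSE)))
      if (length(species)) canon_many(unique(species))
    }
    for (k in seq_along(chunk)) {
      row_i <- idx[k]
      p <- parsed[[k]]
      if (!inherits(p, "reaction_roles")) {
        if (on_error == "fail_fast") stop("row ", row_i, ": ", p, call. = FALSE)
        failures_row <- c(failures_row, row_i)
        failures_reason <- c(failures_reason, p)
        next
      }
      res <- tryCatch({
        if (validate) {
          p$reactants <- canonicalize_molecule(p$reactants)
          if (length(p$agents)) p$agents <- canonicalize_molecule(p$agents)
          p$products <- canonicalize_molecule(p$products)
          p <- assign_roles(p)
          build_graph_elements(p)
        } else {
          raw_string <- paste0(paste(p$reactants, collapse = "."), ">>",
                               paste(p$products, collapse = "."))
          props <- if (length(p$agents)) {
            list(agents = paste(p$agents, collapse = "."))
          } else list()
          rnode <- reaction_node(raw_string, properties = props)
          mols <- sort_c(unique(c(p$reactants, p$products)))
          list(
            nodes = c(list(rnode), lapply(mols, molecule_node)),
            edges = c(
              lapply(sort_c(unique(p$reactants)), function(m)
                noc_edge("REACTANT", compute_uid("molecule", m), rnode$uid)),
              lapply(sort_c(unique(p$products)), function(m)
                noc_edge("PRODUCT", rnode$uid, compute_uid("molecule", m)))
            )
          )
        }
      }, error = function(e) conditionMessage(e))
      if (!is.list(res)) {
        if (on_error == "fail_fast") stop("row ", row_i, ": ", res, call. = FALSE)
        failures_row <- c(failures_row, row_i)
        failures_reason <- c(failures_reason, res)
        next
      }
      for (nd in res$nodes) {
        merge_node(graph, nd)
        if (nd$kind == "reaction") touched_rxn <- c(touched_rxn, nd$uid)
        else touched_mol <- c(touched_mol, nd$uid)
      }
      for (ed in res$edges) merge_edge(graph, ed)
    }
  }

  report <- structure(list(
    n_input_rows = n,
    n_failed = length(failures_row),
    n_unique_reactions = length(unique(touched_rxn)),
    n_unique_molecules = length(unique(touched_mol)),
    failures = data.frame(row = failures_row, reason = failures_reason,
                          stringsAsFactors = FALSE)
  ), class = "ingestion_report")
  list(graph = graph, report = report)
}

#' @export
print.ingestion_report <- function(x, ...) {
  cat(sprintf("Ingestion: %d rows, %d failed, %d distinct reactions, %d distinct molecules\n",
              x$n_input_rows, x$n_failed, x$n_unique_reactions, x$n_unique_molecules))
  if (nrow(x$failures)) {
    cat("Failures:\n")
    for (i in seq_len(min(nrow(x$failures), 10L))) {
      cat(sprintf("  row %d: %s\n", x$failures$row[i], x$failures$reason[i]))
    }
    if (nrow(x$failures) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Read reaction strings from a delimited table or plain-text file
#'
#' CSV files (UTF-8, header row required) are read with the designated
#' reaction-string column; any other file is treated as one reaction string
#' per line (blank lines skipped).
#'
#' @param path File path.
#' @param reaction_column Reaction-string column for CSV input.
#' @return Character vector of reaction strings.
#' @export
read_reactions <- function(path, reaction_column = "reaction") {
  if (!file.exists(path)) stop("cannot read input file: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!reaction_column %in% names(tab)) {
      stop("configuration error: column \"", reaction_column, "\" not found in ",
           path, call. = FALSE)
    }
    tab[[reaction_column]]
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines[nzchar(trimws(lines))]
  }
}
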