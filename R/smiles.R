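#' Parse a reaction SMILES string into role lists
#'
#' Reaction SMILES use the three-role form `"reactants>agents>products"` with
#' dot-separated species per role; the agents role may be empty
#' (`"A>>B"`). Surrounding whitespace is stripped from every species.
#'
#' @param s A reaction SMILES string.
#' @return A `reaction_roles` list with character vectors `reactants`,
#'   `agents`, `products`.
#' @examples
#' parse_reaction_string("CCO.CC(=O)O>>CCOC(C)=O")
#' parse_reaction_string("CCO>O>CC=O")
#' @export
parse_reaction_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop("parse error: reaction string must be a single string", call. = FALSE)
  }
  s <- trimws(s)
  seps <- gregexpr(">", s, fixed = TRUE)[[1L]]
  n_sep <- if (seps[1L] == -1L) 0L else length(seps)
  if (n_sep != 2L) {
    stop("parse error: expected exactly two '>' role separators, found ", n_sep,
         " in \"", s, "\"", call. = FALSE)
  }
  role_str <- c(substr(s, 1L, seps[1L] - 1L),
                substr(s, seps[1L] + 1L, seps[2L] - 1L),
                substr(s, seps[2L] + 1L, nchar(s)))
  split_role <- function(str, role) {
    str <- trimws(str)
    if (!nzchar(str)) return(character(0))
    sp <- trimws(strsplit(str, ".", fixed = TRUE)[[1L]])
    if (any(!nzchar(sp))) {
      stop("parse error: empty species in ", role, " role of \"", s, "\"",
           call. = FALSE)
    }
    sp
  }
  roles <- reaction_roles(
    reactants = split_role(role_str[1L], "reactant"),
    agents = split_role(role_str[2L], "agent"),
    products = split_role(role_str[3L], "product")
  )
  if (!length(roles$reactants)) {
    stop("parse error: empty reactant role in \"", s, "\"", call. = FALSE)
  }
  if (!length(roles$products)) {
    stop("parse error: empty product role in \"", s, "\"", call. = FALSE)
  }
  roles
}

#' @rdname parse_reaction_string
#' @param reactants,agents,products Character vectors of SMILES.
#' @export
reaction_roles <- function(reactants = character(0), agents = character(0),
                           products = character(0)) {
  structure(list(reactants = as.character(reactants),
                 agents = as.character(agents),
                 products = as.character(products)),
            class = "reaction_roles")
}

## ---- canonicalization ----------------------------------------------------

# memoization cache for canonical SMILES (canonicalization is pure)
.canon_cache <- new.env(parent = emptyenv())

# light syntactic screen: OpenBabel silently "repairs" some malformed SMILES,
# so reject obvious garbage before handing over
smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (!grepl("^[]A-Za-z0-9@+().=#$%:/\\\\*~[-]+$", s)) return(FALSE)
  chars <- strsplit(s, "")[[1L]]
  depth_p <- 0L; depth_b <- 0L
  for (ch in chars) {
    if (ch == "(") depth_p <- depth_p + 1L
    else if (ch == ")") depth_p <- depth_p - 1L
    else if (ch == "[") depth_b <- depth_b + 1L
    else if (ch == "]") depth_b <- depth_b - 1L
    if (depth_p < 0L || depth_b < 0L) return(FALSE)
  }
  depth_p == 0L && depth_b == 0L
}

strip_atom_maps <- function(s) gsub(":[0-9]+\\]", "]", s)

# vectorized canonicalization; returns NA for species OpenBabel cannot
# convert instead of raising, so callers can attribute failures per row
canon_many <- function(smiles) {
  uniq <- unique(smiles)
  uniq <- uniq[!is.na(uniq) & nzchar(uniq)]
  vals <- setNames(rep(NA_character_, length(uniq)), uniq)
  if (!length(uniq)) {
    return(setNames(rep(NA_character_, length(smiles)), smiles))
  }
  cached <- uniq[vapply(uniq, exists, logical(1),
                        envir = .canon_cache, inherits = FALSE)]
  if (length(cached)) {
    vals[cached] <- vapply(cached, get, character(1), envir = .canon_cache)
  }
  todo <- uniq[is.na(vals)]
  ok <- todo[vapply(todo, smiles_syntax_ok, logical(1))]
  if (length(ok)) {
    stripped <- strip_atom_maps(ok)
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste(stripped, collapse = "\n")),
      error = function(e) NULL)
    lines <- if (is.null(res)) character(0) else {
      sub("\t.*$", "", strsplit(res, "\n", fixed = TRUE)[[1L]])
    }
    if (length(lines) == length(ok) && all(nzchar(lines)) && !anyNA(lines)) {
      vals[ok] <- lines
    } else {
      # batch misaligned (a species was dropped): fall back to one-by-one
      vals[ok] <- vapply(stripped, function(s) {
        r <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                      error = function(e) "")
        r <- sub("\t.*$", "", strsplit(r, "\n", fixed = TRUE)[[1L]][1L])
        if (length(r) != 1L || is.na(r) || !nzchar(r)) NA_character_ else r
      }, character(1), USE.NAMES = FALSE)
    }
    done <- ok[!is.na(vals[ok])]
    for (s in done) assign(s, vals[[s]], envir = .canon_cache)
  }
  setNames(vals[smiles], smiles)
}

#' Canonicalize molecule SMILES
#'
#' Standardizes SMILES to the OpenBabel canonical form, so that chemically
#' identical inputs written differently (`"OCC"` vs `"CCO"`) map to the same
#' string. Canonicalization is a fixed point: applying it to an already
#' canonical string returns it unchanged. Atom-map annotations (`[CH3:1]`)
#' are stripped before canonicalization -- they are bookkeeping that would
#' break deduplication -- while stereo descriptors are preserved.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @examples
#' \dontrun{
#' canonicalize_molecule("OCC")  # "CCO"
#' }
#' @export
canonicalize_molecule <- function(smiles) {
  if (!is.character(smiles)) stop("smiles must be character", call. = FALSE)
  if (!length(smiles)) return(character(0))
  out <- canon_many(smiles)
  if (anyNA(out)) {
    bad <- smiles[is.na(out)][1L]
    stop("validation error: unparseable SMILES \"", bad, "\"", call. = FALSE)
  }
  unname(out)
}

## ---- role reassignment -----------------------------------------------------

#' Reassign reaction roles after canonicalization
#'
#' Species are deduplicated within each role, and any species whose canonical
#' SMILES appears on both the reactant and the product side is moved to the
#' agents role (it passes through the reaction unchanged, e.g. a solvent
#' recorded on both sides). A reaction left with an empty reactant or product
#' side after reassignment is degenerate and rejected.
#'
#' @param roles A [reaction_roles()] object with per-molecule canonical
#'   SMILES.
#' @return A corrected `reaction_roles` object.
#' @examples
#' assign_roles(reaction_roles(c("CCO", "O"), character(0), c("CC=O", "O")))
#' @export
assign_roles <- function(roles) {
  stopifnot(inherits(roles, "reaction_roles"))
  r <- unique(roles$reactants)
  p <- unique(roles$products)
  a <- unique(roles$agents)
  common <- intersect(r, p)
  r <- setdiff(r, common)
  p <- setdiff(p, common)
  a <- unique(c(a, common))
  if (!length(r) || !length(p)) {
    stop("validation error: degenerate reaction (empty ",
         if (!length(r)) "reactant" else "product",
         " side after role reassignment)", call. = FALSE)
  }
  reaction_roles(reactants = r, agents = a, products = p)
}

#' Canonical two-sided reaction string
#'
#' Joins the reactant and product lists -- each sorted lexicographically by
#' canonical SMILES -- with `"."`, separated by `">>"`. Agents are excluded.
#' Two reactions are duplicates exactly when their canonical reaction strings
#' are identical, so this string is the deduplication key and the input to
#' the reaction node identifier.
#'
#' @param roles A validated [reaction_roles()] object.
#' @return A reaction SMILES string of the form `"reactants>>products"`.
#' @export
canonical_reaction_string <- function(roles) {
  stopifnot(inherits(roles, "reaction_roles"))
  paste0(paste(sort_c(unique(roles$reactants)), collapse = "."),
         ">>",
         paste(sort_c(unique(roles$products)), collapse = "."))
}

#' Expand validated reaction roles into graph elements
#'
#' Produces one reaction node, one molecule node per distinct reactant or
#' product, one `REACTANT` edge per distinct reactant and one `PRODUCT` edge
#' per distinct product (set semantics: `"C.C>>CC"` yields a single reactant
#' edge). Agents are excluded from the core bipartite graph and recorded as
#' an `agents` property on the reaction node.
#'
#' @param roles A validated [reaction_roles()] object.
#' @return A list with `nodes` (list of node records) and `edges` (list of
#'   edge records).
#' @export
build_graph_elements <- function(roles) {
  stopifnot(inherits(roles, "reaction_roles"))
  rs <- unique(roles$reactants)
  ps <- unique(roles$products)
  if (!length(rs) || !length(ps)) {
    stop("validation error: reactant and product lists must be non-empty",
         call. = FALSE)
  }
  canon <- canonical_reaction_string(roles)
  props <- if (length(roles$agents)) {
    list(agents = paste(sort_c(unique(roles$agents)), collapse = "."))
  } else list()
  rnode <- reaction_node(canon, properties = props)
  mnodes <- lapply(sort_c(unique(c(rs, ps))), molecule_node)
  edges <- c(
    lapply(sort_c(rs), function(x)
      noc_edge("REACTANT", compute_uid("molecule", x), rnode$uid)),
    lapply(sort_c(ps), function(x)
      noc_edge("PRODUCT", rnode$uid, compute_uid("molecule", x)))
  )
  list(nodes = c(list(rnode), mnodes), edges = edges)
}
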