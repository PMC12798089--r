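#' Content-derived node identifiers
#'
#' Every node in a reaction-molecule network is keyed by a deterministic
#' identifier computed from its canonical string representation: the canonical
#' SMILES for a molecule, the canonical two-sided reaction SMILES for a
#' reaction. Identifiers are a fixed-length 128-bit hexadecimal digest with a
#' kind-specific prefix (`"M-"` for molecules, `"C-"` for reactions, after the
#' chemical-equation terminology), so the two kinds can never collide.
#'
#' @param kind `"molecule"` or `"reaction"`.
#' @param canonical_string Character vector of non-empty canonical strings.
#' @return Character vector of identifiers, same length as `canonical_string`.
#' @examples
#' compute_uid("molecule", "CCO")
#' compute_uid("reaction", "CC(=O)O.CCO>>CCOC(C)=O")
#' @export
compute_uid <- function(kind, canonical_string) {
  kind <- match.arg(kind, c("molecule", "reaction"))
  if (length(canonical_string) == 0L) return(character(0))
  if (!is.character(canonical_string) || anyNA(canonical_string) ||
      any(!nzchar(canonical_string))) {
    stop("compute_uid(): canonical_string must be non-empty character values",
         call. = FALSE)
  }
  prefix <- if (kind == "molecule") "M-" else "C-"
  paste0(prefix, fnv1a128_hex(canonical_string))
}

uid_is_molecule <- function(uid) startsWith(uid, "M-")
uid_is_reaction <- function(uid) startsWith(uid, "C-")

# C-locale sort, independent of the session locale
sort_c <- function(x) {
  if (is.null(x) || !length(x)) return(character(0))
  sort(x, method = "radix")
}

#' Canonical identity of a synthetic route
#'
#' Two routes are the same route exactly when they use the same reaction set
#' *and* assign the same producing reaction (provenance) to every molecule.
#' The identity is a single canonical string, stable under any reordering of
#' the route's internal containers, suitable for set membership and
#' distinct-route counting.
#'
#' @param route A route object as returned by [mine_routes()] /
#'   [assemble_routes()], or any list with `reactions` and `provenance`
#'   fields.
#' @return A character scalar.
#' @seealso [mine_routes()], [enumerate_routes_bruteforce()]
#' @export
route_identity <- function(route) {
  prov <- route$provenance
  prov <- prov[sort_c(names(prov))]
  paste0(
    "rxns{", paste(sort_c(unique(route$reactions)), collapse = ","), "}",
    "|prov{", paste(names(prov), prov, sep = "=", collapse = ","), "}"
  )
}
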