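#' Build an abstract reaction network from labeled reactions
#'
#' Benchmark and test graphs abstract away all chemistry: molecules are plain
#' labels (`"A"`, `"M1"`, ...) used verbatim as structure strings, and each
#' reaction is given as its reactant and product label sets. Stop-marked
#' molecules receive a truthy `startingMaterial` property.
#'
#' @param reactions Named list; each element is a list with character vectors
#'   `reactants` and `products` of molecule labels.
#' @param stop_materials Labels to mark with `startingMaterial = TRUE`.
#' @return A list of class `noc_fixture` with `graph` (a [noc_graph()]),
#'   `mol` (named map label -> molecule uid) and `rxn` (named map reaction
#'   name -> reaction uid).
#' @examples
#' fx <- abstract_network(list(
#'   r1 = list(reactants = "M1", products = "M2"),
#'   r2 = list(reactants = "M2", products = "M3")
#' ))
#' producers(fx$graph, fx$mol[["M3"]])
#' @export
abstract_network <- function(reactions, stop_materials = character(0)) {
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  if (is.null(names(reactions)) || any(!nzchar(names(reactions)))) {
    stop("reactions must be a named list", call. = FALSE)
  }
  g <- noc_graph()
  mol_uid <- character(0)
  rxn_uid <- character(0)
  labels <- unique(unlist(lapply(reactions, function(r) c(r$reactants, r$products))))
  for (lab in labels) {
    props <- if (lab %in% stop_materials) list(startingMaterial = TRUE) else list()
    nd <- molecule_node(lab, properties = props)
    merge_node(g, nd)
    mol_uid[lab] <- nd$uid
  }
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    if (!length(r$reactants) || !length(r$products)) {
      stop("reaction ", nm, " must have reactants and products", call. = FALSE)
    }
    rs <- paste0(paste(r$reactants, collapse = "."), ">>",
                 paste(r$products, collapse = "."))
    nd <- reaction_node(rs)
    merge_node(g, nd)
    rxn_uid[nm] <- nd$uid
    for (x in unique(r$reactants)) merge_edge(g, noc_edge("REACTANT", mol_uid[[x]], nd$uid))
    for (x in unique(r$products)) merge_edge(g, noc_edge("PRODUCT", nd$uid, mol_uid[[x]]))
  }
  structure(list(graph = g, mol = mol_uid, rxn = rxn_uid), class = "noc_fixture")
}

#' @export
print.noc_fixture <- function(x, ...) {
  cat(sprintf("<noc_fixture> %d molecules, %d reactions\n",
              length(x$mol), length(x$rxn)))
  invisible(x)
}

## ---- named challenge scenarios ----------------------------------------------

scenario_defs <- function() {
  list(
    cycles = list(
      reactions = list(
        r3 = list(reactants = "l", products = "a"),
        r1 = list(reactants = "a", products = "b"),
        r2 = list(reactants = "b", products = "a")
      ),
      targets = "b"
    ),
    multiple_products = list(
      # one reaction contributes two products, both consumed downstream of
      # the same target (double addition / byproduct reuse)
      reactions = list(
        r1 = list(reactants = "x", products = c("p", "q")),
        r2 = list(reactants = c("p", "q"), products = "t")
      ),
      targets = "t"
    ),
    common_intermediates = list(
      reactions = list(
        r0 = list(reactants = c("a", "b"), products = "t"),
        r1 = list(reactants = "c", products = "a"),
        r2 = list(reactants = "c", products = "b")
      ),
      targets = "t"
    ),
    branch_in_cycle = list(
      # cycle a -> r2 -> b -> r3 -> c -> r4 -> a with an OR entry point at a
      reactions = list(
        r1 = list(reactants = "l1", products = "a"),
        r2 = list(reactants = "a", products = "b"),
        r3 = list(reactants = c("b", "l2"), products = "c"),
        r4 = list(reactants = "c", products = "a")
      ),
      targets = "c"
    ),
    concurrent_branching = list(
      # two independent OR branches under one root: 2 x 3 = 6 routes
      reactions = list(
        r0 = list(reactants = c("a", "b"), products = "t"),
        ra1 = list(reactants = "l1", products = "a"),
        ra2 = list(reactants = "l2", products = "a"),
        rb1 = list(reactants = "l3", products = "b"),
        rb2 = list(reactants = "l4", products = "b"),
        rb3 = list(reactants = "l5", products = "b")
      ),
      targets = "t"
    )
  )
}

#' Minimal challenge scenario graphs
#'
#' Five minimal graphs, each exhibiting exactly one of the phenomena that
#' make route mining hard on real reaction networks: `"cycles"`,
#' `"multiple_products"` (double additions / byproduct reuse),
#' `"common_intermediates"`, `"branch_in_cycle"` and
#' `"concurrent_branching"`. Expected route-identity answers, computed once
#' with [enumerate_routes_bruteforce()], are shipped with the package
#' (`system.file("extdata", "scenario_answers.json", package = "rxnmine")`)
#' and regenerated from the oracle by the test suite.
#'
#' @param name Scenario name.
#' @return A `noc_fixture` (see [abstract_network()]) with an additional
#'   `targets` element: the molecule labels to mine from.
#' @export
scenario <- function(name) {
  defs <- scenario_defs()
  if (!name %in% names(defs)) {
    stop("lookup error: unknown scenario \"", name, "\"; available: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  d <- defs[[name]]
  fx <- abstract_network(d$reactions)
  fx$targets <- d$targets
  fx
}

#' The 27-node benchmark graph
#'
#' A deterministic abstract validation graph of 27 nodes (14 molecules, 13
#' reactions) that combines, in one connected network, all five challenge
#' scenarios: a cycle (`E <- R08 <- I <- R10 <- E`), branching within that
#' cycle (`I` is an OR node inside it), a multi-product reaction (`R03`
#' produces both `A` and the byproduct `H`, each consumed on a different
#' pathway), common intermediates (`L1` feeds `R06` and `R13`; `L2` feeds
#' `R07` and `R12`), and concurrent branching from the root (`R01` consumes
#' two OR molecules `A` and `B`). Mining is intended both from the true root
#' `T` and from non-root molecules (e.g. `B`, `E`) so that cyclic regions are
#' entered directly. Expected route identities are shipped under
#' `inst/extdata/benchmark27_answers.json` and regenerated from the
#' brute-force oracle by the test suite.
#'
#' @return A `noc_fixture` with `targets = c("T", "B", "E")`.
#' @export
benchmark27 <- function() {
  fx <- abstract_network(list(
    R01 = list(reactants = c("A", "B"), products = "T"),
    R02 = list(reactants = "C", products = "A"),
    R03 = list(reactants = "D", products = c("A", "H")),
    R04 = list(reactants = "E", products = "B"),
    R05 = list(reactants = c("G", "H"), products = "B"),
    R06 = list(reactants = "L1", products = "C"),
    R07 = list(reactants = "L2", products = "D"),
    R08 = list(reactants = "I", products = "E"),
    R09 = list(reactants = "K", products = "I"),
    R10 = list(reactants = "E", products = "I"),
    R11 = list(reactants = c("L3", "L4"), products = "K"),
    R12 = list(reactants = "L2", products = "G"),
    R13 = list(reactants = "L1", products = "K")
  ))
  fx$targets <- c("T", "B", "E")
  fx
}

## ---- random AND/OR network generator ----------------------------------------

#' Random AND/OR reaction network generator
#'
#' Generates a seeded random bipartite reaction network for property-based
#' testing: a layered acyclic base in which every produced molecule has one
#' producing reaction, extra producing reactions added to random molecules
#' until the OR-node fraction approaches `or_density`, and back-edge
#' reactions injected at rate `cycle_rate` (product earlier than reactant in
#' the layer order, creating potential cycles). Base reactions gain a second
#' product with probability 0.15, emulating byproducts. All reactions have
#' 1..`max_arity` reactants and at least one product. The output is
#' deterministic for a fixed seed; the caller's random-number state is left
#' untouched.
#'
#' @param n_molecules Number of molecules (>= 3).
#' @param n_reactions Number of base reactions (>= 1).
#' @param or_density Target fraction of molecules with >= 2 producers.
#' @param cycle_rate Back-edge reactions per base reaction.
#' @param max_arity Maximum reactants per reaction.
#' @param seed Integer seed.
#' @return A `noc_fixture`; molecules are labeled `"N01"`, `"N02"`, ... in
#'   layer order, so high-numbered molecules are the natural mining targets.
#' @export
random_noc <- function(n_molecules, n_reactions, or_density = 0.2,
                       cycle_rate = 0.1, max_arity = 3L, seed = 1L) {
  if (n_molecules < 3L || n_reactions < 1L || max_arity < 1L) {
    stop("generation error: need n_molecules >= 3, n_reactions >= 1, max_arity >= 1",
         call. = FALSE)
  }
  if (or_density < 0 || or_density > 1 || cycle_rate < 0 || cycle_rate > 1) {
    stop("generation error: or_density and cycle_rate must be in [0, 1]",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  labels <- sprintf("N%02d", seq_len(n_molecules))
  n_base <- min(n_reactions, n_molecules - 1L)
  produced_pos <- (n_molecules - n_base + 1L):n_molecules
  rxns <- list()
  add_rxn <- function(reactants, products) {
    nm <- sprintf("X%03d", length(rxns) + 1L)
    rxns[[nm]] <<- list(reactants = labels[reactants], products = labels[products])
  }
  sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

  produced_done <- logical(n_molecules)
  for (p in produced_pos) {
    if (produced_done[p]) next  # already produced as a byproduct
    a <- sample1(seq_len(min(max_arity, p - 1L)))
    reac <- sort(sample(seq_len(p - 1L), a))
    prods <- p
    # occasional second product: a later molecule that has no producer yet,
    # whose own base reaction is then skipped (keeps single-producer counts)
    later <- setdiff(produced_pos, c(reac, p))
    later <- later[later > max(c(reac, p)) & !produced_done[later]]
    if (length(later) && stats::runif(1) < 0.15) {
      q <- sample1(later)
      prods <- c(p, q)
      produced_done[q] <- TRUE
    }
    produced_done[p] <- TRUE
    add_rxn(reac, prods)
  }

  # extra producers until the OR fraction approaches or_density
  n_producers <- integer(n_molecules)
  for (r in rxns) for (lab in r$products) {
    i <- match(lab, labels); n_producers[i] <- n_producers[i] + 1L
  }
  target_or <- min(round(or_density * n_molecules), length(produced_pos))
  attempts <- 0L
  while (sum(n_producers >= 2L) < target_or && attempts < 20L * n_molecules) {
    attempts <- attempts + 1L
    p <- sample1(produced_pos)
    a <- sample1(seq_len(min(max_arity, p - 1L)))
    reac <- sort(sample(seq_len(p - 1L), a))
    add_rxn(reac, p)
    n_producers[p] <- n_producers[p] + 1L
  }

  # back edges: consume a late molecule, produce an early one
  n_cyc <- round(cycle_rate * n_base)
  for (k in seq_len(n_cyc)) {
    hi <- sample1(3L:n_molecules)
    lo <- sample1(seq_len(hi - 1L))
    extra <- setdiff(seq_len(hi - 1L), lo)
    reac <- hi
    if (length(extra) && max_arity > 1L && stats::runif(1) < 0.5) {
      reac <- sort(c(hi, sample1(extra)))
    }
    add_rxn(reac, lo)
  }

  abstract_network(rxns)
}
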