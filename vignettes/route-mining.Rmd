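---
title: "Reaction networks and exhaustive synthetic route mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction networks and exhaustive synthetic route mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnmine)
```

## The data model

`rxnmine` represents a reaction corpus as a bipartite directed graph: molecule
nodes and reaction nodes, connected by `REACTANT` edges (molecule to reaction)
and `PRODUCT` edges (reaction to molecule). The model deliberately carries no
chemistry beyond the structure strings themselves — yields, conditions and
reagent roles are out of scope; agents are retained only as a property on the
reaction node. Nodes are keyed by a content-derived identifier: a fixed-length
128-bit digest of the canonical SMILES (molecules, prefix `M-`) or of the
canonical two-sided reaction SMILES (reactions, prefix `C-`). Identifier-based
merging makes graph construction commutative, associative and idempotent,
which is the whole ingestion contract: any chunking, ordering or repetition of
the input rows yields the same graph.

Ingestion validation (`validate = TRUE`) does exactly three things: per-species
canonicalization (OpenBabel canonical SMILES, with atom-map annotations
stripped first and stereo descriptors preserved), within-role deduplication,
and both-sides role reassignment (a species occurring among both reactants and
products is moved to the agents role; a reaction left without reactants or
products is rejected as degenerate). Deeper curation — tautomer or salt
normalization, charge balancing — is intentionally not attempted. With
`validate = FALSE`, duplicate detection degrades to the reaction string as
written. Canonicalization details determine how many distinct reaction nodes a
large corpus collapses to, so counts obtained with a different toolkit or
version will differ slightly.

## Routes, AND/OR semantics and bounds

A reaction has AND semantics: a route using it must contain its entire
reactant set. A molecule with several producing reactions is an OR node; a
route uses at most one of the alternatives. A *synthetic route* to a target is
a single-rooted acyclic subgraph oriented toward the target in which every
non-starting molecule has exactly one producing reaction. Its identity — used
for distinct-route counting — is the pair (reaction set, provenance map);
two routes sharing reactions but differing in which reaction produces a
multiply-produced molecule are distinct. When a reaction in a route has
several products, only the products actually traced by the provenance map get
a `PRODUCT` edge inside the route; this preserves the one-incoming-`PRODUCT`
invariant for double additions and multi-product reactions.

Two bounds control combinatorial explosion. `max_number_reactions` caps the
*longest linear sequence* — the maximum number of reactions on any
starting-material-to-target path, not the total step count; a molecule cut by
the cap becomes a `BOUND` leaf and is legal exactly when its depth equals the
bound. `stop_property` names a node property whose truthy value freezes a
molecule as a purchasable starting material (`STOP` leaf); stop-marked
molecules are never expanded, and the mark is ignored on the mining target
itself (mining a stop-marked target would otherwise be vacuous). With no
bounds, expansion continues to true leaves, and maximality is enforced: a
route may never stop early at a molecule that still has producers.

## The two-phase algorithm

Phase one (`extract_subroutes()`) walks backward from the target and collapses
*forced* segments — chains of molecules with a single producer — into
subroutes rooted at the target and at each (OR node, alternative) pair. A
subroute's leaves record why collapsing stopped: `OR_NODE` (next decision
point), `DEAD_END`, `STOP`, `BOUND`, or `CYCLE_BLOCKED` when a forced
expansion would re-enter the current expansion path.

Phase two (`assemble_routes()`) stitches subroutes over the decision points.
A partial route is a provenance assignment; at each step the pending molecule
of minimum depth is expanded by every alternative. After every stitch the
assignment is re-normalized: the closure from the target is recomputed, depths
(max reactions from the target) are relaxed, and, under a finite bound, the
set of molecules whose depth has reached the bound is identified. Three
subtleties matter, all discovered by oracle testing and all handled
explicitly:

* **Cyclic provenance** can never complete into a valid route (routes are
  acyclic, and assignments only grow), so it discards the partial route —
  unless a finite bound is active, in which case cutting a provenance entry at
  the bound may break the cycle.
* **Which entry to cut is a choice.** When the bound is hit, any molecule of
  the over-depth set may be the one that becomes the `BOUND` leaf, and
  different cuts yield different valid routes. The assembly branches over
  single cuts rather than cutting wholesale; since cutting only removes paths,
  every molecule a valid completion cuts remains in the over-set until its
  turn, which makes single-cut branching complete.
* **Forced-chain collapsing is lossy under a bound.** Any absorbed molecule
  could, in some other valid route, be the `BOUND` leaf instead, and
  expand-versus-cut configurations admit multiple consistent fixpoints (one
  molecule's expansion can be what raises another to the bound). Under a
  finite bound the assembly therefore works with one-entry fragments and an
  explicit tentative-leaf branch per decision; with no bound, full subroute
  absorption is lossless (maximality forces every expansion) and is kept as
  the fast path.

Every completed assignment passes the declarative validator
(`validate_route()`), which checks: single root, AND-completeness, unique
provenance, acyclicity, connectivity to the target, leaf legality, stop
semantics, maximality, and the bound. Routes are deduplicated by identity and
ordered by (steps, identity). Exceeding the route budget (default 100,000)
raises a condition of class `rxnmine_budget_error` carrying the routes found
so far.

`enumerate_routes_bruteforce()` is the independent semantic oracle: it
recursively enumerates every producing-reaction-or-leaf decision at every
reachable molecule and keeps exactly the assignments the validator accepts. It
is exponential and guarded by a node limit, but on small graphs it *defines*
correctness; the miner is required to reproduce its identity sets exactly.

## Fixtures and the synthetic-data generator

`benchmark27()` builds a deterministic 27-node abstract graph (14 molecules,
13 reactions — the molecule/reaction split is this package's own choice) that
contains all five hard phenomena in one connected network: a cycle, branching
inside the cycle, a multi-product reaction whose byproduct is consumed on a
different pathway, common intermediates, and concurrent branching from the
root. Expected route-identity sets for the root target `T` (6 routes) and
two non-root targets `B` (3) and `E` (2, entering the cyclic region) were
computed once with the oracle and ship under `inst/extdata/`; the test suite
regenerates them from the oracle and requires byte-identical agreement.
`scenario()` exposes each phenomenon as a minimal separate graph with frozen
answers.

`random_noc()` generates property-test inputs: a layered acyclic base where
each produced molecule has one producer, extra producing reactions until the
OR fraction approaches `or_density`, and back-edge reactions at rate
`cycle_rate`. Base reactions gain a second product with probability 0.15 (the
byproduct then *replaces* the target molecule's own base reaction, so
`or_density = 0` still guarantees single producers). Defaults in the
acceptance battery — 8–14 molecules, 5–10 base reactions, OR density up to
0.5, cycle rate up to 0.3, arity up to 3 — keep graphs at or below ~40 nodes,
where the brute-force oracle is exact and fast; the suite checks
miner-oracle equality on 200 such graphs under no bound, bounds 1–3, and
random stop marks (over a thousand cases, a few seconds total). What these
graphs do **not** emulate: realistic molecule size distributions, the heavy
tail of reaction reuse in literature corpora, or chemical plausibility — so
passing tests certify the *graph semantics* of mining, not chemical validity
of routes on real data.

## Numerical and design choices

* Identifiers use a 128-bit FNV-1a digest (two independent 64-bit lanes,
  implemented in C++): deterministic across platforms, collision probability
  ~1e-20 at a million nodes. The digest choice is invisible to the API.
* All orderings (species within a canonical reaction string, route output,
  table rows, JSON keys) use C-locale radix sorting, so outputs are
  byte-identical across sessions and locales.
* The graph container is environment-backed with reference semantics —
  `merge_node()`/`merge_edge()` mutate in place and return the graph
  invisibly (the `data.table` convention); use `clone_graph()` for a copy.
* `n_branches = max(n_leaves - 1, 0)`: a route with one starting material is
  linear; each additional starting material implies one convergent branch
  point. This is a documented convention, not a measured quantity.
* Empty networks report undefined (`NA`) average reactants/products per
  reaction rather than dividing by zero; isolated molecules (injected
  manually; ingestion cannot create them) count as neither roots nor leaves.
* `ingest()` accepts `n_workers` for configuration compatibility but runs
  sequentially; the chunked contract (identical result for any chunking or
  ordering) is what parallel execution would rely on, and is what the tests
  pin down.

## Known limitations

Exhaustive enumeration is exponential in the number of OR decisions; the
budget turns runaway queries into a partial-result condition rather than a
hang, but choosing informative bounds remains the user's job. Reagent/agent
nodes, route scoring and similarity clustering of routes are out of scope.
Full-corpus node/edge counts depend on the canonicalization toolkit;
reproducing counts published for a specific corpus requires the same
canonicalizer the publisher used.
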