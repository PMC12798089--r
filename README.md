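# rxnmine

Reaction networks for synthesis planning in R: build a bipartite
reaction–molecule graph (a *network of organic chemistry*, NOC) from reaction
SMILES strings, query its connectivity, and exhaustively enumerate every
valid synthetic route to a target molecule under user-defined bounds.

## The problem and the model

Reaction databases are usually tables of isolated reaction strings, but
chemistry is a network: the product of one reaction is the reactant of
another. `rxnmine` represents a reaction corpus as a directed bipartite
graph with two node kinds and two edge kinds:

```
molecule --REACTANT--> reaction --PRODUCT--> molecule
```

Every node is keyed by a content-derived identifier (a fixed-length digest
of its canonical SMILES / canonical reaction SMILES), so ingesting the same
reaction twice — however it is written — merges into a single node.
Validation canonicalizes each species (OpenBabel canonical SMILES via
ChemmineOB), deduplicates species within a role, and moves species appearing
on both sides of a reaction to the agents role.

On this graph, AND/OR semantics drive route mining. A reaction is an AND
node: if a route uses it, all of its reactants must be in the route. A
molecule with two or more producing reactions is an **OR node**: each
incoming PRODUCT edge is an alternative provenance, and a route may use at
most one. A **synthetic route** to a target is a single-rooted acyclic
subgraph, oriented toward the target, in which every non-starting molecule
has exactly one producing reaction, every reaction carries its full reactant
set, and every leaf is legal: a true dead end (no producers in the network),
a stop-marked molecule (e.g. `startingMaterial`), or a cut at exactly
`max_number_reactions` depth — the cap on the longest linear sequence.

Mining proceeds in two phases: backward traversal from the target collapses
forced segments (molecules with a single producer) into *subroutes* rooted
at the target and at each (OR node, producing reaction) pair; assembly then
stitches subroutes across the OR decision points, discarding cyclic
provenance and truncating at the bound, until no expandable molecule
remains. Every emitted route passes a declarative validator
(`validate_route()`), and a brute-force reference enumerator
(`enumerate_routes_bruteforce()`) serves as an independent correctness
oracle in the test suite.

## Worked example

```r
library(rxnmine)

## build a network from reaction SMILES (two spellings of one esterification)
res <- ingest(c("OCC.CC(=O)O>>CCOC(C)=O",
                "CC(=O)O.CCO>>CCOC(C)=O",
                "CCO>>CC=O",
                "CC=O>>CC(=O)O"))
res$report
#> Ingestion: 4 rows, 0 failed, 3 distinct reactions, 4 distinct molecules

## mine every route to ethyl acetate
routes <- mine_routes(res$graph, "CCOC(C)=O")
routes
#> <noc_results> query 'mine_routes': 1 record(s)
routes_to_reaction_strings(routes)[[1]]
#> [1] "CCO>>CC=O"              "CC=O>>CC(=O)O"          "CC(=O)O.CCO>>CCOC(=O)C"
```

The single route chains the oxidation steps into the esterification: acetic
acid is itself producible from ethanol in this small corpus, and maximal
expansion continues until true starting materials.

On the packaged 27-node benchmark graph (14 molecules, 13 reactions,
covering cycles, multi-product reactions, common intermediates, branching
inside a cycle and concurrent branching from the root):

```r
fx <- benchmark27()
noc_stats(fx$graph)
#> Reaction network statistics
#>   molecules:        14
#>   reactions:        13
#>   ...
#>   OR nodes:         4
length(mine_routes(fx$graph, "T")$records)   # routes to the root target
#> [1] 6
```

## Command-line tool

A thin executable over the same functions is installed at `exec/rxnmine`:

```sh
rxnmine build   --input reactions.csv --column reaction --out graph.json
rxnmine stats   --graph graph.json
rxnmine mine    --graph graph.json --target-smiles "CC(=O)Nc1ccc(O)cc1" \
                --max-reactions 4 --format smiles --out routes.json
rxnmine fixture --name benchmark27 --out b27.json
```

Exit codes: 0 success, 2 usage error, 3 data error, 4 budget-partial
(enumeration stopped at the route budget; partial results are written).

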