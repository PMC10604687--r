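---
title: "Normalizing, augmenting and querying cross-species orthology data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing, augmenting and querying cross-species orthology data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthonorm)
```

## The problem

Harmonized orthology calls for the canonical model organisms are distributed
as a combined-orthology TSV: one line per *directed* gene pair, carrying the
two genes' prefixed accessions, symbols, taxa and species names, the list of
prediction algorithms that called the pair, how many algorithms agreed out
of how many could compare the species pair, and two tri-state best-score
flags (`Yes`/`No`/`Yes_Adjusted`, forward and reverse). That flat file
answers few questions directly, and the distribution has no mechanism for
adding species beyond the canonical nine. `orthonorm` normalizes the file
into a relational model, extends it with externally mapped species, rebuilds
homology clusters from the pairwise data, and exposes the result as a fixed
catalog of parameterized JSON queries.

## The relational model

An `ortho_db` holds ten tables. The core five mirror the file's content in
normal form:

* `species` (`sp_id`, binomial name, NCBI taxon, provenance
  `canonical`/`added`),
* `genes` (`gn_id`, prefixed accession, namespace prefix, symbol, species),
* `algorithms` (label registry),
* `orthologs` (directed pair with decoded best flags, match counts and an
  `ort_source` provenance label),
* `ortholog_algorithms` (pair-to-algorithm links).

Both directions of a relationship are stored as distinct rows. The file
dialect is symmetric — each unordered pair normally appears once per
direction — but the best-score flags are per direction (the forward line's
reverse flag is the reverse line's forward flag), so collapsing directions
would lose information. Internal keys are assigned in first-seen order from
1, so a fixed input yields reproducible keys. Ingest is idempotent: species
are keyed by taxon, genes by accession, pairs by the directed
(from, to) tuple; duplicate input rows keep the first occurrence and are
counted, and rows pairing a gene with itself or two genes of one species are
rejected and counted. `validate_db()` checks all referential and uniqueness
invariants exhaustively.

The store is an in-memory environment of data frames with CSV persistence
(`write_db()`/`read_db()`): an embedded design that keeps the package free
of server dependencies, makes every table directly inspectable, and is
comfortably sufficient at the scale of these data (hundreds of thousands of
rows at most). Code that outgrows it can swap the storage behind the same
function surface.

## Identifier translation

The external system registers identifier sources in a `genedb` table; each
source maps to a namespace (curie) prefix. Conversion joins the prefix onto
bare accessions (`693363` + `Entrez` → `Entrez:693363`), leaves
already-prefixed accessions unchanged, and passes accessions of
empty-prefix sources through verbatim; it is idempotent by construction.
The reverse lookup (`agr_ref_to_ode_gene()`) is exact over a precomputed
converted column — there is no fuzzy or symbol-based matching, and
unmappable genes are skipped with a warning, never fabricated. If two
sources claim one prefix the first registered wins (a warning is raised);
the data gives no principled way to prefer one, and a deterministic policy
keeps reverse lookups well defined.

## Adding missing species

Species absent from the canonical source arrive as externally supplied
homology clusters (sets of genes across species treated as mutually
homologous). Each cluster is decomposed into its unordered member pairs and
a pair is kept — emitted in both directions — if and only if:

1. **at least one endpoint is from a newly added species** — the canonical
   pairs already cover existing-species relationships, and inferring new
   existing–existing edges from coarser cluster data would invite false
   positives;
2. **both endpoints resolve in the gene table** — a gene the canonical
   source does not carry is never added on cluster evidence alone;
3. **the endpoints are from different species** — the ortholog table is
   cross-species by construction, so within-cluster paralogs yield no pair.

Violations are counted, not raised. Kept pairs carry cleared best-score
flags and zero algorithm counts, because the external source supplies
neither; their `ort_source = "added:<name>"` label keeps them
distinguishable and lets augmentation be replayed idempotently
(deduplication is against the directed pair key, whether the earlier copy
came from canonical ingest or an earlier cluster). Canonical rows are never
modified or deleted.

Two readings of rule 1 are possible: "touches a new species" (symmetric) or
"runs from a new species to an existing one". The symmetric reading is
implemented, and pairs between two *different* new species are kept by
default — excluding them would leave added species orphaned from each other
even when the external clusters connect them. The `new_new_pairs = FALSE`
policy switch restricts augmentation to new–existing edges for users who
prefer the stricter reading. For a cluster with *k* resolvable members from
distinct species, *m* of them new, the yield is exactly
2·(C(k,2) − C(k−m,2)) directed pairs; the test suite verifies this closed
form against brute-force enumeration on 500 random clusters.

## Homology clustering

Clusters are the connected components of the undirected projection of the
pair table — direction encodes scoring, not connectivity. Two operations are
provided:

* `build_clusters()` rebuilds the partition from scratch with a union-find
  pass; cluster ids are deterministic (components ordered by smallest member
  `gn_id`, numbered from 1), and genes with no pairs are not materialized as
  singleton clusters.
* `assign_new_genes()` updates an existing partition incrementally: a gene
  linked to one existing cluster joins it, genes linked only to each other
  found a new cluster, and an edge bridging two clusters merges them under
  the smaller id (merges are counted and reported rather than refused — with
  cluster evidence from two systems, a bridge is information, not an error).

Incremental and batch results are equal as unlabelled partitions; the suite
checks this against an independent breadth-first-search oracle on 200 random
edge-set splits and cross-checks the batch builder against `igraph`
components. Memberships denormalize the gene's species and a provenance
label so cluster queries need no joins.

## The query catalog

Fifty endpoints in six categories (Genes 9, Species 4, Algorithms 3,
Orthology 14, Homology 6, Integration 14) are defined as a fixed in-process
catalog: `api_catalog()` enumerates the routes (the introspection view is
outside the count), `api_call()` returns R objects, `api_request()` the
JSON. The catalog is dispatched in-process rather than over HTTP: the
package's deliverable is the data model and query semantics, which this
design makes directly testable and embeddable; any web layer can mount
`api_request()` one-to-one, and the bundled CLI (`query` subcommand) covers
shell use. Filter endpoints return possibly-empty JSON arrays; unknown
entities return a structured `{"error":"not_found",...}` payload so an
empty result and a bad key are distinguishable. Boolean parameters accept
case-insensitive `true`/`false`; `all_*` routes paginate via
`limit`/`offset` with a default cap of 1000 rows.

## The fixture generator

`generate_agr_fixture()`/`generate_gw_fixture()` emulate the two input
systems with planted ground truth. Defaults are the study conditions the
package targets: the nine canonical species with their native namespaces
(HGNC, MGI, RGD, ZFIN, FB, WB, SGD, Xenbase), three externally mapped
species — *Gallus gallus* (CGNC), *Canis familiaris* (Ensembl),
*Macaca mulatta* (bare-integer Entrez accessions) — a pool of ten
orthology-algorithm labels, 25 planted clusters of 2–6 members (one gene
per species per cluster), 30-gene pools per species, and a 0.2 probability
that an extended cluster carries a member absent from the canonical source
(exercising rule 2). Cluster sizes and pool sizes are chosen so fixtures
build in milliseconds while every code path — both translation branches,
unresolvable members, added-only clusters, merges — is exercised; the
acceptance script runs the full pipeline on these sizes in seconds.
Accessions are synthesized per namespace *shape* only (e.g.
`WB:WBGene00006123`), with disjoint index ranges per species so namespaces
shared by two species (Xenbase) cannot collide; no real identifiers are
implied. A fixed seed yields byte-identical output, and generation
saves/restores the caller's RNG state.

What the fixtures do **not** emulate: the topology of real ortholog graphs
(real clusters have paralog fan-outs and missing edges; planted clusters are
cliques), realistic algorithm agreement structure, or real identifier
semantics. Passing tests therefore demonstrate the correctness of the data
transformations — parsing, normalization, filtering, clustering, translation
and querying — not biological validity of any particular orthology call.

## Numerical and degenerate-input choices

* Species-name matching is case-insensitive and otherwise exact; no fuzzy
  matching anywhere.
* Tri-state flags are validated at parse time with the offending line
  number; `Yes_Adjusted` decodes to best = TRUE with an adjusted marker.
* Empty cluster, single-member cluster, empty species spec, header-only TSV
  and empty store are all defined no-ops (empty results, zero counts), not
  errors.
* The number of algorithm *names* on a row is not forced to equal the match
  count in real inputs (the generator does make them equal, and the suite
  asserts it for fixtures only).
* Duplicate directed pairs: first wins, rest counted — deterministic and
  idempotence-compatible.

## Limitations

* Orthology is never inferred de novo; augmentation only re-expresses the
  given clusters as pairs, with no scoring of added pairs.
* Transitive inference beyond the supplied clusters is deliberately absent.
* The catalog is fixed at 50 routes; bespoke endpoints are added in code by
  extending the catalog table, not via configuration.
* HTTP transport, authentication and write endpoints are out of scope.
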