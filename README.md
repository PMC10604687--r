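# orthonorm

Cross-species comparative genomics needs a well-defined mapping of
orthologous genes — genes in different species descended from a single gene
in their last common ancestor. Model-organism data alliances publish
harmonized orthology calls for a fixed set of canonical species (human,
mouse, rat, zebrafish, fruit fly, worm, yeast and the two *Xenopus*) as a
combined-orthology TSV: directed gene pairs with per-direction best-score
flags and the list of prediction algorithms that called each pair. There is
no mechanism in that distribution to add further species.

`orthonorm` is an R toolkit that

1. **normalizes** the combined-orthology TSV into a relational store
   (species, genes, algorithms, directed ortholog pairs, pair–algorithm
   links), idempotently;
2. **translates identifiers** against a GeneWeaver-style external system
   (its `gene`, `species` and `genedb` tables), joining each source-native
   accession to its namespace prefix (`693363` + Entrez → `Entrez:693363`);
3. **augments** the store with species the canonical source does not carry
   (e.g. *Gallus gallus*, *Canis familiaris*, *Macaca mulatta*): externally
   supplied homology clusters are decomposed into pairwise orthologous
   relationships, filtered by three rules — a pair must touch a newly added
   species, both genes must resolve in the gene table, and the two genes
   must be from different species — then deduplicated and appended;
4. **aggregates** the pairwise table back into homology clusters — the
   connected components of the undirected pair graph — either from scratch
   or incrementally, sorting newly added genes into existing clusters and
   merging clusters when a new edge bridges them;
5. **serves** the result through a fixed catalog of **50 JSON query
   endpoints in six categories** (Genes, Species, Algorithms, Orthology,
   Homology, Integration), dispatched in-process by `api_request()` or from
   the shell via the bundled CLI.

A deterministic fixture generator (`generate_agr_fixture()`,
`generate_gw_fixture()`) emits the TSV/CSV inputs with known ground truth,
so the whole pipeline is testable offline.

## Worked example

```r
library(orthonorm)

fx  <- generate_gw_fixture(fixture_spec(seed = 1))
dir <- tempfile(); write_fixture(fx, dir)

db   <- ortho_db()
rows <- parse_orthology_file(file.path(dir, "orthology.tsv"))
ingest_orthology(db, rows)
#> ingest report:
#>   created: 9 species, 96 genes, 10 algorithms, 336 pairs, 2038 links
#>   skipped: 0 duplicate pairs, 0 invalid rows

load_gw_tables(db, file.path(dir, "gene.csv"),
               file.path(dir, "species.csv"), file.path(dir, "genedb.csv"))
augment_species(db, read_cluster_csv(file.path(dir, "clusters.csv")),
                data.frame(name  = c("Gallus gallus", "Canis familiaris",
                                     "Macaca mulatta"),
                           taxon = c(9031L, 9615L, 9544L)),
                source_name = "geneweaver")
#> augmentation report:
#>   3 new species, 30 new genes, 228 pairs added
#>   skipped: 11 unresolvable, 107 without new-species endpoint,
#>            0 same-species; 0 duplicates removed

hm <- build_clusters(db)   # 27 clusters over 126 genes

json <- api_request(db, "get_ortholog_by_to_and_from_species",
                    list(from_sp_name = "Macaca mulatta",
                         to_sp_name   = "Homo sapiens"))
jsonlite::fromJSON(json)[1, c("from_ref_id", "to_ref_id", "ort_source")]
#>     from_ref_id to_ref_id       ort_source
#> 1 Entrez:690001 HGNC:3002 added:geneweaver
```

The ingest report counts what the TSV contributed: 9 canonical species, one
gene record per distinct accession, one directed pair per distinct
(gene1, gene2) with its algorithm links. The augmentation report shows the
filtering at work — 228 directed pairs pass the three rules, 11 candidate
pairs are dropped because one endpoint is not represented in the canonical
gene table, 107 because neither endpoint is from a newly added species.
The final query returns macaque-to-human orthologs with each accession in
its native namespace (bare Entrez integers become `Entrez:` curies; human
genes stay `HGNC:`), and `ort_source` records that the relationship came
from decomposed external clusters rather than the canonical file.

The endpoint catalog itself is introspectable:

```r
nrow(api_catalog())                    # 50
table(api_catalog()$category)
#> Algorithms  Genes  Homology  Integration  Orthology  Species
#>          3      9         6           14         14        4
```

A shell front end lives at `inst/cli/orthonorm-cli.R`
(`fixtures`, `ingest`, `load-gw`, `augment`, `cluster`, `query`, `catalog`),
persisting the store as a directory of CSVs between invocations.

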