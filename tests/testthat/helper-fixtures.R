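# Shared fixture construction for the suite. Everything is generated in code
# at test time; nothing is read from disk except what the tests write.

# run the full pipeline (ingest -> external tables -> augment -> cluster) on
# a generated fixture and return all the pieces
make_pipeline_db <- function(seed = 7, spec = fixture_spec(seed = seed)) {
  fx <- generate_gw_fixture(spec)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fixture(fx, dir)
  db <- ortho_db()
  rows <- parse_orthology_file(file.path(dir, "orthology.tsv"))
  ing <- ingest_orthology(db, rows)
  load_gw_tables(db, file.path(dir, "gene.csv"), file.path(dir, "species.csv"),
                 file.path(dir, "genedb.csv"))
  clusters <- read_cluster_csv(file.path(dir, "clusters.csv"))
  aug <- augment_species(db, clusters,
                         fx$gw$truth$added_species[, c("name", "taxon")],
                         source_name = "geneweaver")
  build_clusters(db)
  list(db = db, fx = fx, dir = dir, rows = rows, ingest = ing, aug = aug,
       clusters = clusters)
}

# independent component finder: plain breadth-first search over an adjacency
# list, no union-find, used as the clustering oracle
bfs_partition <- function(genes, from, to) {
  adj <- lapply(setNames(vector("list", length(genes)), as.character(genes)),
                identity)
  for (e in seq_along(from)) {
    a <- as.character(from[e]); b <- as.character(to[e])
    adj[[a]] <- c(adj[[a]], to[e])
    adj[[b]] <- c(adj[[b]], from[e])
  }
  seen <- setNames(rep(FALSE, length(genes)), as.character(genes))
  parts <- list()
  for (g in genes) {
    if (seen[[as.character(g)]]) next
    queue <- g; comp <- integer()
    seen[[as.character(g)]] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[as.character(v)]]) {
        if (!seen[[as.character(w)]]) {
          seen[[as.character(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    parts[[length(parts) + 1L]] <- sort(comp)
  }
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

partition_of <- function(hm) {
  parts <- lapply(split(hm$gn_id, hm$hom_id), sort)
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# a bare store with explicit species/genes for augmentation unit tests;
# species 1..n_canonical are canonical, the rest added; one identifier
# source "T" with prefix "T"; gene g of species s has accession "T:<g>"
toy_db <- function(n_canonical, n_added, genes_per_species = 3L) {
  db <- ortho_db()
  n <- n_canonical + n_added
  db$species <- data.frame(
    sp_id = seq_len(n), sp_name = paste("Species", seq_len(n)),
    sp_taxon_id = 1000L + seq_len(n),
    sp_source = rep(c("canonical", "added"), c(n_canonical, n_added)),
    stringsAsFactors = FALSE
  )
  gn <- seq_len(n * genes_per_species)
  db$genes <- data.frame(
    gn_id = gn, gn_ref_id = paste0("T:", gn), gn_prefix = "T",
    gn_symbol = paste0("g", gn),
    sp_id = rep(seq_len(n), each = genes_per_species), stringsAsFactors = FALSE
  )
  load_genedb(db, data.frame(gdb_id = 1L, gdb_name = "TestSrc",
                             curie_prefix = "T", stringsAsFactors = FALSE))
  db
}

toy_members <- function(db, cluster_id, gn_ids) {
  data.frame(cluster_id = cluster_id, accession = paste0("T:", gn_ids),
             gdb_id = 1L, sp_id = NA_integer_, stringsAsFactors = FALSE)
}
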