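#' Create an empty orthology store
#'
#' An `ortho_db` is an embedded relational store holding the normalized
#' orthology model: species, genes, algorithms, directed ortholog pairs,
#' pair-to-algorithm links, homology-cluster memberships, and the
#' GeneWeaver-style mapping tables (genedb registry, external genes and
#' species, species id map). It is an environment, so the loader and
#' augmentation functions update it in place (reference semantics), the way a
#' database handle behaves.
#'
#' Internal integer keys (`sp_id`, `gn_id`, `alg_id`, `ort_id`, `hom_id`) are
#' assigned in first-seen order starting at 1, so a fixed input order yields
#' reproducible keys.
#'
#' @return An object of class `ortho_db`.
#' @seealso [write_db()], [read_db()], [ingest_orthology()]
#' @export
#' @examples
#' db <- ortho_db()
#' summary(db)
ortho_db <- function() {
  db <- new.env(parent = emptyenv())

  db$species <- data.frame(
    sp_id = integer(), sp_name = character(), sp_taxon_id = integer(),
    sp_source = character(), stringsAsFactors = FALSE
  )
  db$genes <- data.frame(
    gn_id = integer(), gn_ref_id = character(), gn_prefix = character(),
    gn_symbol = character(), sp_id = integer(), stringsAsFactors = FALSE
  )
  db$algorithms <- data.frame(
    alg_id = integer(), alg_name = character(), stringsAsFactors = FALSE
  )
  db$orthologs <- data.frame(
    ort_id = integer(), from_gene = integer(), to_gene = integer(),
    is_best = logical(), is_best_adjusted = logical(),
    is_best_revised = logical(), num_algorithms_match = integer(),
    out_of_algorithms = integer(), ort_source = character(),
    stringsAsFactors = FALSE
  )
  db$ortholog_algorithms <- data.frame(
    ort_id = integer(), alg_id = integer(), stringsAsFactors = FALSE
  )
  db$homology <- data.frame(
    hom_id = integer(), gn_id = integer(), sp_id = integer(),
    hom_source = character(), stringsAsFactors = FALSE
  )
  # GeneWeaver-style mapping tables
  db$genedb <- data.frame(
    gdb_id = integer(), gdb_name = character(), curie_prefix = character(),
    stringsAsFactors = FALSE
  )
  db$gw_species <- data.frame(
    gw_sp_id = integer(), gw_sp_name = character(), gw_taxon_id = integer(),
    stringsAsFactors = FALSE
  )
  db$gw_genes <- data.frame(
    ode_gene_id = integer(), ode_ref_id = character(), gdb_id = integer(),
    gw_sp_id = integer(), agr_ref = character(), stringsAsFactors = FALSE
  )
  db$species_map <- data.frame(
    sp_id = integer(), gw_sp_id = integer(), stringsAsFactors = FALSE
  )

  class(db) <- "ortho_db"
  db
}

# table names persisted by write_db/read_db, in a fixed order
DB_TABLES <- c(
  "species", "genes", "algorithms", "orthologs", "ortholog_algorithms",
  "homology", "genedb", "gw_species", "gw_genes", "species_map"
)

#' @export
print.ortho_db <- function(x, ...) {
  cat("<ortho_db> embedded orthology store\n")
  for (tb in DB_TABLES) {
    cat(sprintf("  %-20s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Summarize an orthology store
#'
#' @param object An `ortho_db`.
#' @param ... Unused.
#' @return Named integer vector of table row counts, invisibly printed.
#' @export
summary.ortho_db <- function(object, ...) {
  counts <- vapply(DB_TABLES, function(tb) nrow(object[[tb]]), integer(1))
  structure(counts, class = "summary.ortho_db")
}

#' @export
print.summary.ortho_db <- function(x, ...) {
  cat("orthology store row counts:\n")
  print(unclass(x))
  invisible(x)
}

#' Persist a store to a directory of CSV files
#'
#' Writes one plain-text CSV per table so a store can be reused across
#' command-line invocations and inspected with ordinary tools.
#'
#' @param db An `ortho_db`.
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  stopifnot(inherits(db, "ortho_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in DB_TABLES) {
    utils::write.csv(db[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a store previously written by [write_db()]
#'
#' @param dir Directory containing the table CSVs.
#' @return An `ortho_db`.
#' @export
read_db <- function(dir) {
  if (!dir.exists(dir)) stop("store directory not found: ", dir)
  db <- ortho_db()
  for (tb in DB_TABLES) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) next
    tmpl <- db[[tb]]
    got <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = vapply(tmpl, class, character(1)))
    db[[tb]] <- got[, names(tmpl), drop = FALSE]
  }
  db
}

# next free internal key for a table
next_id <- function(db, table, key) {
  n <- nrow(db[[table]])
  if (n == 0L) 1L else max(db[[table]][[key]]) + 1L
}

#' Check referential integrity of a store
#'
#' Verifies exhaustively that every foreign key resolves, that ortholog pairs
#' are cross-species and non-self, that uniqueness invariants hold
#' (case-insensitive species names, taxon ids, gene accessions, directed pair
#' keys), and that homology memberships form a partition consistent with gene
#' species.
#'
#' @param db An `ortho_db`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_db <- function(db) {
  sp <- db$species; gn <- db$genes; ort <- db$orthologs
  if (anyDuplicated(tolower(sp$sp_name))) stop("duplicate species name")
  if (anyDuplicated(sp$sp_taxon_id)) stop("duplicate species taxon id")
  if (anyDuplicated(sp$sp_id)) stop("duplicate sp_id")
  if (anyDuplicated(gn$gn_ref_id)) stop("duplicate gene accession")
  if (!all(gn$sp_id %in% sp$sp_id)) stop("gene with unknown species")
  if (anyDuplicated(db$algorithms$alg_name)) stop("duplicate algorithm name")
  if (!all(ort$from_gene %in% gn$gn_id) || !all(ort$to_gene %in% gn$gn_id))
    stop("ortholog pair references unknown gene")
  if (any(ort$from_gene == ort$to_gene)) stop("self-pair in ortholog table")
  if (anyDuplicated(paste(ort$from_gene, ort$to_gene)))
    stop("duplicate directed pair")
  sp_of <- gn$sp_id[match(ort$from_gene, gn$gn_id)]
  sp_to <- gn$sp_id[match(ort$to_gene, gn$gn_id)]
  if (any(sp_of == sp_to)) stop("same-species ortholog pair")
  lk <- db$ortholog_algorithms
  if (!all(lk$ort_id %in% ort$ort_id)) stop("link to unknown pair")
  if (!all(lk$alg_id %in% db$algorithms$alg_id)) stop("link to unknown algorithm")
  if (anyDuplicated(paste(lk$ort_id, lk$alg_id))) stop("duplicate algorithm link")
  hm <- db$homology
  if (anyDuplicated(hm$gn_id)) stop("gene in more than one homology cluster")
  if (!all(hm$gn_id %in% gn$gn_id)) stop("homology row references unknown gene")
  if (!all(hm$sp_id == gn$sp_id[match(hm$gn_id, gn$gn_id)]))
    stop("homology sp_id inconsistent with gene table")
  invisible(TRUE)
}
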