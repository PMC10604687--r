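# Identifier and species translation against a GeneWeaver-style external
# system: its genedb table registers identifier sources (Entrez, HGNC, ...),
# its gene table carries source-native accessions, and a species map joins
# its species keys to the store's internal ones.

#' Load the genedb identifier-source registry
#'
#' Each genedb row names an identifier source and the namespace (curie)
#' prefix its accessions map to; an empty prefix marks sources whose bare
#' accessions are used verbatim. When two sources claim the same prefix the
#' first registered wins and a warning is raised.
#'
#' @param db An [ortho_db()].
#' @param entries data.frame with columns `gdb_id`, `gdb_name`,
#'   `curie_prefix`.
#' @return Number of entries registered, invisibly.
#' @export
load_genedb <- function(db, entries) {
  stopifnot(all(c("gdb_id", "gdb_name", "curie_prefix") %in% names(entries)))
  entries <- entries[!(entries$gdb_id %in% db$genedb$gdb_id), , drop = FALSE]
  if (anyDuplicated(entries$gdb_name) ||
      any(entries$gdb_name %in% db$genedb$gdb_name)) {
    stop("duplicate genedb source name")
  }
  clash <- nzchar(entries$curie_prefix) &
    entries$curie_prefix %in% db$genedb$curie_prefix
  clash <- clash | duplicated(entries$curie_prefix) & nzchar(entries$curie_prefix)
  if (any(clash)) {
    warning("curie prefix already registered; first registration wins for: ",
            paste(entries$gdb_name[clash], collapse = ", "))
  }
  db$genedb <- rbind(db$genedb, data.frame(
    gdb_id = as.integer(entries$gdb_id), gdb_name = entries$gdb_name,
    curie_prefix = entries$curie_prefix, stringsAsFactors = FALSE
  ))
  invisible(nrow(entries))
}

#' Load GeneWeaver-style species rows and map them to store species
#'
#' Species are matched to the store's species table by binomial name
#' (case-insensitive); matched pairs enter the species map. Unmatched
#' external species stay loaded but unmapped until registered by
#' augmentation.
#'
#' @param db An [ortho_db()].
#' @param species data.frame with columns `gw_sp_id`, `sp_name`,
#'   `sp_taxon_id`.
#' @return Number of species mapped, invisibly.
#' @export
load_gw_species <- function(db, species) {
  stopifnot(all(c("gw_sp_id", "sp_name", "sp_taxon_id") %in% names(species)))
  species <- species[!(species$gw_sp_id %in% db$gw_species$gw_sp_id), ,
                     drop = FALSE]
  db$gw_species <- rbind(db$gw_species, data.frame(
    gw_sp_id = as.integer(species$gw_sp_id), gw_sp_name = species$sp_name,
    gw_taxon_id = as.integer(species$sp_taxon_id), stringsAsFactors = FALSE
  ))
  hit <- match(tolower(species$sp_name), tolower(db$species$sp_name))
  ok <- !is.na(hit)
  add <- data.frame(sp_id = db$species$sp_id[hit[ok]],
                    gw_sp_id = as.integer(species$gw_sp_id[ok]),
                    stringsAsFactors = FALSE)
  add <- add[!(add$gw_sp_id %in% db$species_map$gw_sp_id), , drop = FALSE]
  db$species_map <- rbind(db$species_map, add)
  invisible(nrow(add))
}

#' Load GeneWeaver-style gene rows
#'
#' Each row's converted (namespace-prefixed) accession is precomputed with
#' [gw_ref_to_agr_ref()] so lookups in either direction are a plain join.
#' Rows whose `gdb_id` is unregistered are skipped with a warning, never
#' fabricated.
#'
#' @param db An [ortho_db()].
#' @param genes data.frame with columns `ode_gene_id`, `ode_ref_id`,
#'   `gdb_id`, `sp_id` (the external species key).
#' @return Number of genes loaded, invisibly.
#' @export
load_gw_genes <- function(db, genes) {
  stopifnot(all(c("ode_gene_id", "ode_ref_id", "gdb_id", "sp_id") %in%
                  names(genes)))
  known <- genes$gdb_id %in% db$genedb$gdb_id
  if (any(!known)) {
    warning(sum(!known), " gene rows skipped: unregistered genedb source")
    genes <- genes[known, , drop = FALSE]
  }
  key <- paste(genes$ode_ref_id, genes$gdb_id)
  genes <- genes[!duplicated(key), , drop = FALSE]
  key <- paste(genes$ode_ref_id, genes$gdb_id)
  have <- paste(db$gw_genes$ode_ref_id, db$gw_genes$gdb_id)
  genes <- genes[!(key %in% have), , drop = FALSE]
  if (nrow(genes) == 0L) return(invisible(0L))
  prefix <- db$genedb$curie_prefix[match(genes$gdb_id, db$genedb$gdb_id)]
  conv <- gw_ref_to_agr_ref(genes$ode_ref_id, prefix)
  db$gw_genes <- rbind(db$gw_genes, data.frame(
    ode_gene_id = as.integer(genes$ode_gene_id), ode_ref_id = genes$ode_ref_id,
    gdb_id = as.integer(genes$gdb_id), gw_sp_id = as.integer(genes$sp_id),
    agr_ref = conv, stringsAsFactors = FALSE
  ))
  invisible(nrow(genes))
}

#' Convert a source-native accession to a namespace-prefixed accession
#'
#' If the accession already starts with the source's curie prefix followed by
#' a colon it is returned unchanged, otherwise the prefix is joined on; a
#' source with an empty prefix returns the accession verbatim. The operation
#' is idempotent.
#'
#' @param ode_ref_id Character vector of source-native accessions.
#' @param prefix Curie prefix of the identifier source (recycled), or a
#'   single genedb name registered in `db` when `db` is given.
#' @param db Optional [ortho_db()] used to resolve `prefix` as a genedb name.
#' @return Character vector of prefixed accessions.
#' @export
#' @examples
#' gw_ref_to_agr_ref("693363", "Entrez")   # "Entrez:693363"
#' gw_ref_to_agr_ref("MGI:87853", "MGI")   # unchanged
gw_ref_to_agr_ref <- function(ode_ref_id, prefix, db = NULL) {
  if (any(!nzchar(ode_ref_id))) stop("empty accession")
  if (!is.null(db)) {
    hit <- match(prefix, db$genedb$gdb_name)
    if (anyNA(hit)) stop("unregistered genedb source: ", prefix)
    prefix <- db$genedb$curie_prefix[hit]
  }
  prefix <- rep_len(as.character(prefix), length(ode_ref_id))
  want <- paste0(prefix, ":")
  done <- !nzchar(prefix) | startsWith(ode_ref_id, want)
  ifelse(done, ode_ref_id, paste0(want, ode_ref_id))
}

#' Find the external gene matching a prefixed accession
#'
#' Inverse of [gw_ref_to_agr_ref()] on mapped genes: returns the external
#' gene row whose converted accession equals `agr_ref`.
#'
#' @param db An [ortho_db()].
#' @param agr_ref A single prefixed accession.
#' @return One-row data.frame (`ode_gene_id`, `ode_ref_id`, `gdb_id`,
#'   `gw_sp_id`, `agr_ref`), or `NULL` when no mapping exists.
#' @export
agr_ref_to_ode_gene <- function(db, agr_ref) {
  stopifnot(length(agr_ref) == 1L, nzchar(agr_ref))
  hit <- which(db$gw_genes$agr_ref == agr_ref)
  if (length(hit) == 0L) return(NULL)
  db$gw_genes[hit[1L], , drop = FALSE]
}

#' Translate a species name or key between the two systems
#'
#' @param db An [ortho_db()].
#' @param x A binomial name (direction "name_to_sp") or an integer key.
#' @param direction One of `"name_to_sp"` (case-insensitive name to internal
#'   `sp_id`), `"sp_to_gw"` (internal to external key) or `"gw_to_sp"`.
#' @return The target key, or `NA_integer_` when the species is unknown.
#' @export
translate_species <- function(db, x, direction = c("name_to_sp", "sp_to_gw",
                                                   "gw_to_sp")) {
  direction <- match.arg(direction)
  switch(direction,
    name_to_sp = {
      hit <- match(tolower(as.character(x)), tolower(db$species$sp_name))
      if (is.na(hit)) NA_integer_ else db$species$sp_id[hit]
    },
    sp_to_gw = {
      hit <- match(as.integer(x), db$species_map$sp_id)
      if (is.na(hit)) NA_integer_ else db$species_map$gw_sp_id[hit]
    },
    gw_to_sp = {
      hit <- match(as.integer(x), db$species_map$gw_sp_id)
      if (is.na(hit)) NA_integer_ else db$species_map$sp_id[hit]
    }
  )
}

#' Load the three GeneWeaver-style CSV tables in one call
#'
#' @param db An [ortho_db()].
#' @param gene,species,genedb Paths to the gene, species and genedb CSVs
#'   (columns as in [load_gw_genes()], [load_gw_species()], [load_genedb()]).
#' @return Named list of loaded-row counts, invisibly.
#' @export
load_gw_tables <- function(db, gene, species, genedb) {
  gdb <- utils::read.csv(genedb, stringsAsFactors = FALSE,
                         colClasses = c(gdb_id = "integer",
                                        gdb_name = "character",
                                        curie_prefix = "character"))
  gdb$curie_prefix[is.na(gdb$curie_prefix)] <- ""
  n1 <- load_genedb(db, gdb)
  sp <- utils::read.csv(species, stringsAsFactors = FALSE)
  n2 <- load_gw_species(db, sp)
  gn <- utils::read.csv(gene, stringsAsFactors = FALSE,
                        colClasses = c(ode_ref_id = "character"))
  n3 <- load_gw_genes(db, gn)
  invisible(list(genedb = n1, species_mapped = n2, genes = n3))
}
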