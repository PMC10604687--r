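# Species augmentation: species absent from the canonical orthology source
# are added by decomposing externally supplied homology clusters into
# pairwise orthologous relationships, filtered by three rules (illustrated
# with genes A..F in the package vignette):
#   rule 1 - a pair is kept only if at least one endpoint belongs to a newly
#            added species (mappings must come from new species);
#   rule 2 - both endpoints must resolve in the gene table (a gene the
#            canonical source does not carry is never added);
#   rule 3 - endpoints must be from different species (the ortholog table is
#            cross-species by construction; within-species paralogs yield no
#            pair).

#' Register species absent from the canonical source
#'
#' Adds each species with `sp_source = "added"`, maps it to its external
#' species key (matched by name in the loaded external species table), and
#' creates a gene record for every cluster member belonging to a new species,
#' converting its accession through the genedb registry.
#'
#' @param db An [ortho_db()] with external tables loaded (see
#'   [load_gw_tables()]).
#' @param clusters data.frame of external cluster members with columns
#'   `cluster_id`, `accession`, `gdb_id`, `sp_id` (external species key).
#' @param species_spec data.frame with columns `name`, `taxon` naming the
#'   species to add.
#' @return List with `new_species` (count added) and `new_genes` (gene
#'   records created), plus the internal `sp_id`s assigned.
#' @export
register_new_species <- function(db, clusters, species_spec) {
  stopifnot(inherits(db, "ortho_db"),
            all(c("name", "taxon") %in% names(species_spec)))
  if (nrow(species_spec) == 0L) {
    return(list(new_species = 0L, new_genes = 0L, sp_ids = integer()))
  }
  clash <- tolower(species_spec$name) %in% tolower(db$species$sp_name) |
    species_spec$taxon %in% db$species$sp_taxon_id
  if (any(clash)) {
    stop("species already registered: ",
         paste(species_spec$name[clash], collapse = ", "))
  }
  ids <- next_id(db, "species", "sp_id") + seq_len(nrow(species_spec)) - 1L
  db$species <- rbind(db$species, data.frame(
    sp_id = ids, sp_name = species_spec$name,
    sp_taxon_id = as.integer(species_spec$taxon), sp_source = "added",
    stringsAsFactors = FALSE
  ))

  # map to external species keys by name and extend the species map
  gw_hit <- match(tolower(species_spec$name), tolower(db$gw_species$gw_sp_name))
  ok <- !is.na(gw_hit)
  if (any(ok)) {
    add <- data.frame(sp_id = ids[ok],
                      gw_sp_id = db$gw_species$gw_sp_id[gw_hit[ok]],
                      stringsAsFactors = FALSE)
    add <- add[!(add$gw_sp_id %in% db$species_map$gw_sp_id), , drop = FALSE]
    db$species_map <- rbind(db$species_map, add)
  }

  # gene records for cluster members of the new species
  new_gw <- db$species_map$gw_sp_id[db$species_map$sp_id %in% ids]
  mem <- clusters[clusters$sp_id %in% new_gw, , drop = FALSE]
  n_genes <- 0L
  if (nrow(mem) > 0L) {
    prefix <- db$genedb$curie_prefix[match(mem$gdb_id, db$genedb$gdb_id)]
    known <- !is.na(prefix)
    if (any(!known)) {
      warning(sum(!known), " cluster members skipped: unregistered genedb source")
      mem <- mem[known, , drop = FALSE]
      prefix <- prefix[known]
    }
    ref <- gw_ref_to_agr_ref(mem$accession, prefix)
    first <- !duplicated(ref)
    ref <- ref[first]; mem <- mem[first, , drop = FALSE]
    fresh <- !(ref %in% db$genes$gn_ref_id)
    ref <- ref[fresh]; mem <- mem[fresh, , drop = FALSE]
    n_genes <- length(ref)
    if (n_genes > 0L) {
      gids <- next_id(db, "genes", "gn_id") + seq_len(n_genes) - 1L
      cu <- split_curie(ref)
      sp_int <- db$species_map$sp_id[match(mem$sp_id, db$species_map$gw_sp_id)]
      db$genes <- rbind(db$genes, data.frame(
        gn_id = gids, gn_ref_id = ref, gn_prefix = cu$prefix,
        gn_symbol = cu$local, sp_id = sp_int, stringsAsFactors = FALSE
      ))
    }
  }
  list(new_species = nrow(species_spec), new_genes = n_genes, sp_ids = ids)
}

#' Decompose external homology clusters into filtered pairwise relationships
#'
#' Every unordered member pair of each cluster is emitted as two directed
#' pairs if and only if it passes the three filtering rules (new-species
#' endpoint; both endpoints resolvable; cross-species). Emitted pairs carry
#' cleared best-score flags and zero algorithm counts, since the external
#' source supplies neither; they remain distinguishable through their
#' `ort_source` label.
#'
#' @param db An [ortho_db()] whose gene table contains canonical and newly
#'   registered genes.
#' @param clusters data.frame of cluster members (`cluster_id`, `accession`,
#'   `gdb_id`, `sp_id` external species key).
#' @param new_sp_ids Internal `sp_id`s of the newly added species.
#' @param source_name Label recorded as `ort_source = "added:<source_name>"`.
#' @param new_new_pairs Keep pairs whose endpoints are both from new species
#'   (default TRUE); turning this off restricts augmentation to new-existing
#'   edges.
#' @return List with `pairs` (data.frame of directed candidate pairs) and
#'   skip counts `pairs_skipped_unknown_gene`, `pairs_skipped_no_new_species`,
#'   `pairs_skipped_same_species`.
#' @export
decompose_clusters <- function(db, clusters, new_sp_ids,
                               source_name = "external",
                               new_new_pairs = TRUE) {
  stopifnot(inherits(db, "ortho_db"))
  skip_unknown <- 0L; skip_nonew <- 0L; skip_same <- 0L
  out_from <- integer(); out_to <- integer()
  if (nrow(clusters) > 0L) {
    prefix <- db$genedb$curie_prefix[match(clusters$gdb_id, db$genedb$gdb_id)]
    ref <- gw_ref_to_agr_ref(clusters$accession, ifelse(is.na(prefix), "", prefix))
    gn <- db$genes$gn_id[match(ref, db$genes$gn_ref_id)]
    sp <- db$genes$sp_id[match(gn, db$genes$gn_id)]
    is_new <- sp %in% new_sp_ids
    for (cl in split(seq_along(gn), clusters$cluster_id)) {
      k <- length(cl)
      if (k < 2L) next
      for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
          a <- cl[i]; b <- cl[j]
          if (is.na(gn[a]) || is.na(gn[b])) { skip_unknown <- skip_unknown + 1L; next }
          if (!is_new[a] && !is_new[b]) { skip_nonew <- skip_nonew + 1L; next }
          if (!new_new_pairs && is_new[a] && is_new[b]) { skip_nonew <- skip_nonew + 1L; next }
          if (sp[a] == sp[b]) { skip_same <- skip_same + 1L; next }
          out_from <- c(out_from, gn[a], gn[b])
          out_to <- c(out_to, gn[b], gn[a])
        }
      }
    }
  }
  n <- length(out_from)
  pairs <- data.frame(
    from_gene = out_from, to_gene = out_to,
    is_best = rep(FALSE, n), is_best_adjusted = rep(FALSE, n),
    is_best_revised = rep(FALSE, n),
    num_algorithms_match = rep(0L, n), out_of_algorithms = rep(0L, n),
    ort_source = rep(paste0("added:", source_name), n),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       pairs_skipped_unknown_gene = skip_unknown,
       pairs_skipped_no_new_species = skip_nonew,
       pairs_skipped_same_species = skip_same)
}

#' Append decomposed pairs to the ortholog table, removing duplicates
#'
#' A candidate pair is appended only when its directed (from, to) key is not
#' already present, whether from canonical ingest or from an earlier cluster;
#' the operation is idempotent and never touches existing rows.
#'
#' @param db An [ortho_db()].
#' @param pairs data.frame of candidate pairs as produced by
#'   [decompose_clusters()].
#' @return List with `pairs_added` and `duplicates_removed`.
#' @export
dedupe_and_append <- function(db, pairs) {
  stopifnot(inherits(db, "ortho_db"))
  if (nrow(pairs) == 0L) return(list(pairs_added = 0L, duplicates_removed = 0L))
  key <- paste(pairs$from_gene, pairs$to_gene)
  dup_in <- duplicated(key)
  have <- paste(db$orthologs$from_gene, db$orthologs$to_gene)
  keep <- !dup_in & !(key %in% have)
  n <- sum(keep)
  if (n > 0L) {
    ids <- next_id(db, "orthologs", "ort_id") + seq_len(n) - 1L
    add <- pairs[keep, , drop = FALSE]
    add$ort_id <- ids
    db$orthologs <- rbind(db$orthologs, add[, names(db$orthologs)])
  }
  list(pairs_added = n, duplicates_removed = as.integer(nrow(pairs) - n))
}

#' Augment the store with missing species from external clusters
#'
#' Convenience wrapper running [register_new_species()],
#' [decompose_clusters()] and [dedupe_and_append()] in order.
#'
#' @inheritParams register_new_species
#' @inheritParams decompose_clusters
#' @return An `augmentation_report` with counts `new_species`, `new_genes`,
#'   `pairs_added`, `pairs_skipped_unknown_gene`,
#'   `pairs_skipped_no_new_species`, `pairs_skipped_same_species`,
#'   `duplicates_removed`.
#' @export
augment_species <- function(db, clusters, species_spec,
                            source_name = "external", new_new_pairs = TRUE) {
  reg <- register_new_species(db, clusters, species_spec)
  dec <- decompose_clusters(db, clusters, reg$sp_ids,
                            source_name = source_name,
                            new_new_pairs = new_new_pairs)
  app <- dedupe_and_append(db, dec$pairs)
  structure(list(
    new_species = reg$new_species, new_genes = reg$new_genes,
    pairs_added = app$pairs_added,
    pairs_skipped_unknown_gene = dec$pairs_skipped_unknown_gene,
    pairs_skipped_no_new_species = dec$pairs_skipped_no_new_species,
    pairs_skipped_same_species = dec$pairs_skipped_same_species,
    duplicates_removed = app$duplicates_removed
  ), class = "augmentation_report")
}

#' @export
print.augmentation_report <- function(x, ...) {
  cat("augmentation report:\n")
  cat(sprintf("  %d new species, %d new genes, %d pairs added\n",
              x$new_species, x$new_genes, x$pairs_added))
  cat(sprintf("  skipped: %d unresolvable, %d without new-species endpoint, %d same-species; %d duplicates removed\n",
              x$pairs_skipped_unknown_gene, x$pairs_skipped_no_new_species,
              x$pairs_skipped_same_species, x$duplicates_removed))
  invisible(x)
}

#' Read an external cluster CSV
#'
#' @param path CSV with columns `cluster_id`, `accession`, `gdb_id`, `sp_id`.
#' @return data.frame of cluster members.
#' @export
read_cluster_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(accession = "character"))
}
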