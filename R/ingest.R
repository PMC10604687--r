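#' Ingest parsed orthology rows into the normalized store
#'
#' Registers every distinct species, gene, and algorithm mentioned in the
#' rows exactly once and stores one directed ortholog pair per distinct
#' (gene1, gene2) accession pair, linked to the algorithms that called it.
#' Both directions of a relationship normally appear in the source and are
#' kept as distinct rows, preserving the per-direction best-score flags.
#'
#' The operation is idempotent: re-running it on the same rows creates zero
#' new records. Duplicate (from, to) rows keep the first occurrence and count
#' the rest as skipped; rows pairing a gene with itself or two genes of the
#' same species are rejected as invalid and counted.
#'
#' @param db An [ortho_db()].
#' @param rows data.frame from [parse_orthology_file()].
#' @param source Provenance label recorded on created pairs (default "agr";
#'   created species get `sp_source = "canonical"`).
#' @return An `ingest_report`: counts of species, genes, algorithms, pairs
#'   and links created, plus pairs skipped as duplicate or invalid.
#' @export
ingest_orthology <- function(db, rows, source = "agr") {
  stopifnot(inherits(db, "ortho_db"))
  empty <- list(species = 0L, genes = 0L, algorithms = 0L, pairs = 0L,
                links = 0L, pairs_skipped_duplicate = 0L,
                rows_skipped_invalid = 0L)
  if (nrow(rows) == 0L) return(structure(empty, class = "ingest_report"))

  bad <- rows$gene1_id == rows$gene2_id | rows$gene1_taxon == rows$gene2_taxon
  invalid <- sum(bad)
  rows <- rows[!bad, , drop = FALSE]

  # species: first-seen order across both sides of each row
  sp_tok <- c(rbind(rows$gene1_taxon, rows$gene2_taxon))
  sp_nam <- c(rbind(rows$gene1_species_name, rows$gene2_species_name))
  first <- !duplicated(sp_tok)
  sp_new <- data.frame(taxon = parse_taxon(sp_tok[first]),
                       name = sp_nam[first], stringsAsFactors = FALSE)
  sp_new <- sp_new[!(sp_new$taxon %in% db$species$sp_taxon_id), , drop = FALSE]
  n_sp <- nrow(sp_new)
  if (n_sp > 0L) {
    ids <- next_id(db, "species", "sp_id") + seq_len(n_sp) - 1L
    db$species <- rbind(db$species, data.frame(
      sp_id = ids, sp_name = sp_new$name, sp_taxon_id = sp_new$taxon,
      sp_source = "canonical", stringsAsFactors = FALSE
    ))
  }

  # genes: keyed by accession, first-seen symbol/species win
  g_ref <- c(rbind(rows$gene1_id, rows$gene2_id))
  g_sym <- c(rbind(rows$gene1_symbol, rows$gene2_symbol))
  g_tax <- c(rbind(rows$gene1_taxon, rows$gene2_taxon))
  first <- !duplicated(g_ref)
  gn_new <- data.frame(ref = g_ref[first], sym = g_sym[first],
                       taxon = parse_taxon(g_tax[first]),
                       stringsAsFactors = FALSE)
  gn_new <- gn_new[!(gn_new$ref %in% db$genes$gn_ref_id), , drop = FALSE]
  n_gn <- nrow(gn_new)
  if (n_gn > 0L) {
    ids <- next_id(db, "genes", "gn_id") + seq_len(n_gn) - 1L
    cu <- split_curie(gn_new$ref)
    db$genes <- rbind(db$genes, data.frame(
      gn_id = ids, gn_ref_id = gn_new$ref, gn_prefix = cu$prefix,
      gn_symbol = gn_new$sym,
      sp_id = db$species$sp_id[match(gn_new$taxon, db$species$sp_taxon_id)],
      stringsAsFactors = FALSE
    ))
  }

  # algorithms
  alg_lists <- strsplit(rows$algorithms, "|", fixed = TRUE)
  alg_all <- unique(unlist(alg_lists))
  alg_all <- alg_all[nzchar(alg_all)]
  alg_new <- setdiff(alg_all, db$algorithms$alg_name)
  n_alg <- length(alg_new)
  if (n_alg > 0L) {
    ids <- next_id(db, "algorithms", "alg_id") + seq_len(n_alg) - 1L
    db$algorithms <- rbind(db$algorithms, data.frame(
      alg_id = ids, alg_name = alg_new, stringsAsFactors = FALSE
    ))
  }

  # pairs: first occurrence of each directed accession pair wins
  key <- paste(rows$gene1_id, rows$gene2_id, sep = "\r")
  dup_in <- duplicated(key)
  cand <- rows[!dup_in, , drop = FALSE]
  cand_alg <- alg_lists[!dup_in]
  from_gn <- db$genes$gn_id[match(cand$gene1_id, db$genes$gn_ref_id)]
  to_gn <- db$genes$gn_id[match(cand$gene2_id, db$genes$gn_ref_id)]
  exist_key <- paste(db$orthologs$from_gene, db$orthologs$to_gene)
  is_new <- !(paste(from_gn, to_gn) %in% exist_key)
  n_pairs <- sum(is_new)
  skipped <- sum(dup_in) + sum(!is_new)
  n_links <- 0L
  if (n_pairs > 0L) {
    ids <- next_id(db, "orthologs", "ort_id") + seq_len(n_pairs) - 1L
    fb <- parse_best_flag(cand$is_best[is_new])
    rb <- parse_best_flag(cand$is_best_revised[is_new])
    db$orthologs <- rbind(db$orthologs, data.frame(
      ort_id = ids, from_gene = from_gn[is_new], to_gene = to_gn[is_new],
      is_best = fb$best, is_best_adjusted = fb$adjusted,
      is_best_revised = rb$best,
      num_algorithms_match = cand$algorithms_match[is_new],
      out_of_algorithms = cand$out_of_algorithms[is_new],
      ort_source = source, stringsAsFactors = FALSE
    ))
    new_alg <- cand_alg[is_new]
    link_ort <- rep(ids, lengths(new_alg))
    link_nm <- unlist(new_alg)
    keep <- nzchar(link_nm)
    link_alg <- db$algorithms$alg_id[match(link_nm[keep], db$algorithms$alg_name)]
    n_links <- sum(keep)
    if (n_links > 0L) {
      db$ortholog_algorithms <- rbind(db$ortholog_algorithms, data.frame(
        ort_id = link_ort[keep], alg_id = link_alg, stringsAsFactors = FALSE
      ))
    }
  }

  structure(list(
    species = n_sp, genes = n_gn, algorithms = n_alg, pairs = n_pairs,
    links = n_links, pairs_skipped_duplicate = as.integer(skipped),
    rows_skipped_invalid = as.integer(invalid)
  ), class = "ingest_report")
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("ingest report:\n")
  cat(sprintf("  created: %d species, %d genes, %d algorithms, %d pairs, %d links\n",
              x$species, x$genes, x$algorithms, x$pairs, x$links))
  cat(sprintf("  skipped: %d duplicate pairs, %d invalid rows\n",
              x$pairs_skipped_duplicate, x$rows_skipped_invalid))
  invisible(x)
}
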