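# Homology clusters are the connected components of the undirected graph
# whose edges are the ortholog pairs; direction encodes scoring, not
# connectivity. A hand-written union-find keeps the incremental assignment
# (sorting newly added genes into existing clusters, merging when an added
# edge bridges two clusters) equivalent to a batch rebuild.

# union-find over arbitrary integer ids; returns component label per id
uf_components <- function(ids, from, to) {
  parent <- seq_along(ids)
  idx <- function(x) match(x, ids)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  fi <- idx(from); ti <- idx(to)
  for (e in seq_along(fi)) {
    ra <- find(fi[e]); rb <- find(ti[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_along(ids), find, integer(1))
}

#' Build homology clusters from the whole ortholog table
#'
#' Partitions every gene participating in at least one pair into connected
#' components; genes without pairs belong to no cluster (singletons are not
#' materialized). Cluster ids are assigned deterministically: components are
#' ordered by their smallest member `gn_id` and numbered from 1. The store's
#' homology table is replaced by the result.
#'
#' @param db An [ortho_db()].
#' @param pairs Optional pair data.frame (columns `from_gene`, `to_gene`);
#'   defaults to the store's ortholog table.
#' @return The homology membership data.frame (`hom_id`, `gn_id`, `sp_id`,
#'   `hom_source`), invisibly also written to `db$homology`.
#' @export
build_clusters <- function(db, pairs = db$orthologs) {
  stopifnot(inherits(db, "ortho_db"))
  if (nrow(pairs) == 0L) {
    db$homology <- db$homology[0L, , drop = FALSE]
    return(invisible(db$homology))
  }
  ids <- sort(unique(c(pairs$from_gene, pairs$to_gene)))
  comp <- uf_components(ids, pairs$from_gene, pairs$to_gene)
  # relabel so that clusters are numbered by smallest member gn_id
  mins <- tapply(ids, comp, min)
  rank <- match(comp, names(sort(mins)))
  sp <- db$genes$sp_id[match(ids, db$genes$gn_id)]
  src <- db$species$sp_source[match(sp, db$species$sp_id)]
  hm <- data.frame(hom_id = as.integer(rank), gn_id = ids, sp_id = sp,
                   hom_source = src, stringsAsFactors = FALSE)
  hm <- hm[order(hm$hom_id, hm$gn_id), , drop = FALSE]
  rownames(hm) <- NULL
  db$homology <- hm
  invisible(hm)
}

#' Sort newly added pairs into the existing clusters
#'
#' Incrementally updates the homology table: an added gene linked to one
#' existing cluster joins it; genes linked only to each other form a new
#' cluster; an added edge connecting two existing clusters merges them, the
#' smaller cluster id surviving. The result equals a batch [build_clusters()]
#' over the union of old and added pairs, up to cluster labels.
#'
#' @param db An [ortho_db()] whose homology table is a valid partition.
#' @param added_pairs data.frame of the newly appended pairs (`from_gene`,
#'   `to_gene`).
#' @return An `assign_report`: `placed_in_existing` (genes attached to a
#'   pre-existing cluster), `new_clusters` (clusters created), `merges`
#'   (cluster merges performed). The updated membership is in `db$homology`.
#' @export
assign_new_genes <- function(db, added_pairs) {
  stopifnot(inherits(db, "ortho_db"))
  hm <- db$homology
  gene2hom <- structure(hm$hom_id, names = as.character(hm$gn_id))
  next_hom <- if (nrow(hm) == 0L) 1L else max(hm$hom_id) + 1L
  placed <- 0L; created <- 0L; merges <- 0L
  if (nrow(added_pairs) > 0L) {
    # undirected unique edges, processed in stable order
    a <- pmin(added_pairs$from_gene, added_pairs$to_gene)
    b <- pmax(added_pairs$from_gene, added_pairs$to_gene)
    ed <- unique(data.frame(a = a, b = b))
    ed <- ed[order(ed$a, ed$b), , drop = FALSE]
    for (e in seq_len(nrow(ed))) {
      ga <- as.character(ed$a[e]); gb <- as.character(ed$b[e])
      ha <- gene2hom[ga]; hb <- gene2hom[gb]
      if (is.na(ha) && is.na(hb)) {
        gene2hom[c(ga, gb)] <- next_hom
        next_hom <- next_hom + 1L
        created <- created + 1L
      } else if (is.na(ha)) {
        gene2hom[ga] <- hb
        placed <- placed + 1L
      } else if (is.na(hb)) {
        gene2hom[gb] <- ha
        placed <- placed + 1L
      } else if (ha != hb) {
        keep <- min(ha, hb); drop <- max(ha, hb)
        gene2hom[gene2hom == drop] <- keep
        merges <- merges + 1L
      }
    }
  }
  gn <- as.integer(names(gene2hom))
  sp <- db$genes$sp_id[match(gn, db$genes$gn_id)]
  src <- db$species$sp_source[match(sp, db$species$sp_id)]
  hm <- data.frame(hom_id = as.integer(gene2hom), gn_id = gn, sp_id = sp,
                   hom_source = src, stringsAsFactors = FALSE)
  hm <- hm[order(hm$hom_id, hm$gn_id), , drop = FALSE]
  rownames(hm) <- NULL
  db$homology <- hm
  structure(list(placed_in_existing = placed, new_clusters = created,
                 merges = merges), class = "assign_report")
}

#' @export
print.assign_report <- function(x, ...) {
  cat(sprintf("cluster assignment: %d genes placed in existing clusters, %d new clusters, %d merges\n",
              x$placed_in_existing, x$new_clusters, x$merges))
  invisible(x)
}

#' Export homology clusters with external-facing columns
#'
#' @param db An [ortho_db()].
#' @param path Optional CSV path to write.
#' @return data.frame (`hom_id`, `gn_ref_id`, `sp_name`, `hom_source`).
#' @export
export_clusters <- function(db, path = NULL) {
  hm <- db$homology
  out <- data.frame(
    hom_id = hm$hom_id,
    gn_ref_id = db$genes$gn_ref_id[match(hm$gn_id, db$genes$gn_id)],
    sp_name = db$species$sp_name[match(hm$sp_id, db$species$sp_id)],
    hom_source = hm$hom_source, stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Compare two cluster memberships as unlabelled partitions
#'
#' @param a,b Membership data.frames with columns `hom_id`, `gn_id`.
#' @return TRUE when both describe the same partition of the same genes,
#'   ignoring cluster labels.
#' @export
same_partition <- function(a, b) {
  canon <- function(m) {
    parts <- split(m$gn_id, m$hom_id)
    parts <- lapply(parts, sort)
    unname(parts[order(vapply(parts, min, numeric(1)))])
  }
  identical(canon(a), canon(b))
}
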