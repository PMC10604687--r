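# Embedded JSON query catalog: exactly 50 named endpoints in six categories
# (Genes, Species, Algorithms, Orthology, Homology, Integration), each a
# parameterized query over the normalized tables, dispatched in-process and
# rendered as JSON. Unknown-entity lookups return a structured not-found
# payload, distinguishable from an empty filter result ([]).

DEFAULT_PAGE_CAP <- 1000L

not_found <- function(entity, key) {
  structure(list(error = "not_found", entity = entity,
                 key = as.character(key)),
            class = c("api_not_found", "list"))
}

parse_bool <- function(x) {
  v <- tolower(as.character(x))
  if (!v %in% c("true", "false")) stop("boolean parameter must be true/false, got: ", x)
  v == "true"
}

paginate <- function(df, p, cap = DEFAULT_PAGE_CAP) {
  off <- if (!is.null(p$offset)) as.integer(p$offset) else 0L
  lim <- if (!is.null(p$limit)) min(as.integer(p$limit), cap) else cap
  if (off >= nrow(df)) return(df[0L, , drop = FALSE])
  df[seq.int(off + 1L, min(nrow(df), off + lim)), , drop = FALSE]
}

render_species <- function(db, idx = seq_len(nrow(db$species))) {
  out <- db$species[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

render_genes <- function(db, idx = seq_len(nrow(db$genes))) {
  g <- db$genes[idx, , drop = FALSE]
  g$sp_name <- db$species$sp_name[match(g$sp_id, db$species$sp_id)]
  rownames(g) <- NULL
  g
}

render_orthologs <- function(db, idx = seq_len(nrow(db$orthologs))) {
  o <- db$orthologs[idx, , drop = FALSE]
  gi <- match(o$from_gene, db$genes$gn_id)
  gj <- match(o$to_gene, db$genes$gn_id)
  # accessions rendered in each gene's native namespace
  o$from_ref_id <- db$genes$gn_ref_id[gi]
  o$to_ref_id <- db$genes$gn_ref_id[gj]
  o$from_species <- db$species$sp_name[match(db$genes$sp_id[gi], db$species$sp_id)]
  o$to_species <- db$species$sp_name[match(db$genes$sp_id[gj], db$species$sp_id)]
  rownames(o) <- NULL
  o
}

render_homology <- function(db, idx = seq_len(nrow(db$homology))) {
  h <- db$homology[idx, , drop = FALSE]
  h$gn_ref_id <- db$genes$gn_ref_id[match(h$gn_id, db$genes$gn_id)]
  h$sp_name <- db$species$sp_name[match(h$sp_id, db$species$sp_id)]
  rownames(h) <- NULL
  h
}

sp_id_by_name <- function(db, name) translate_species(db, name, "name_to_sp")

orthologs_of_species <- function(db, sp, side = c("from", "to")) {
  side <- match.arg(side)
  genes <- db$genes$gn_id[db$genes$sp_id == sp]
  col <- if (side == "from") db$orthologs$from_gene else db$orthologs$to_gene
  which(col %in% genes)
}

gw_gene_by_ode_id <- function(db, ode_gene_id) {
  hit <- which(db$gw_genes$ode_gene_id == as.integer(ode_gene_id))
  if (length(hit) == 0L) NULL else db$gw_genes[hit[1L], , drop = FALSE]
}

# internal gene record for an external gene key, or NULL
agr_gene_of_ode <- function(db, ode_gene_id) {
  gw <- gw_gene_by_ode_id(db, ode_gene_id)
  if (is.null(gw)) return(NULL)
  hit <- which(db$genes$gn_ref_id == gw$agr_ref)
  if (length(hit) == 0L) NULL else hit[1L]
}

endpoint <- function(category, name, params, handler) {
  list(category = category, name = name, params = params, handler = handler)
}

build_catalog <- function() {
  eps <- list()
  add <- function(...) eps[[length(eps) + 1L]] <<- endpoint(...)

  ## --- Genes (9) -----------------------------------------------------------
  add("Genes", "all_genes", c("limit", "offset"), function(db, p)
    paginate(render_genes(db), p))
  add("Genes", "gene_by_id", "gn_id", function(db, p) {
    i <- which(db$genes$gn_id == as.integer(p$gn_id))
    if (!length(i)) not_found("gene", p$gn_id) else render_genes(db, i)
  })
  add("Genes", "gene_by_ref_id", "gn_ref_id", function(db, p) {
    i <- which(db$genes$gn_ref_id == p$gn_ref_id)
    if (!length(i)) not_found("gene", p$gn_ref_id) else render_genes(db, i)
  })
  add("Genes", "genes_by_species_id", "sp_id", function(db, p) {
    sp <- as.integer(p$sp_id)
    if (!sp %in% db$species$sp_id) return(not_found("species", p$sp_id))
    render_genes(db, which(db$genes$sp_id == sp))
  })
  add("Genes", "genes_by_species_name", "sp_name", function(db, p) {
    sp <- sp_id_by_name(db, p$sp_name)
    if (is.na(sp)) return(not_found("species", p$sp_name))
    render_genes(db, which(db$genes$sp_id == sp))
  })
  add("Genes", "genes_by_algorithm", "alg_name", function(db, p) {
    ai <- match(p$alg_name, db$algorithms$alg_name)
    if (is.na(ai)) return(not_found("algorithm", p$alg_name))
    orts <- db$ortholog_algorithms$ort_id[
      db$ortholog_algorithms$alg_id == db$algorithms$alg_id[ai]]
    sel <- db$orthologs$ort_id %in% orts
    gn <- sort(unique(c(db$orthologs$from_gene[sel], db$orthologs$to_gene[sel])))
    render_genes(db, match(gn, db$genes$gn_id))
  })
  add("Genes", "genes_by_prefix", "gn_prefix", function(db, p)
    render_genes(db, which(db$genes$gn_prefix == p$gn_prefix)))
  add("Genes", "gene_count_by_species", character(), function(db, p) {
    n <- vapply(db$species$sp_id, function(s) sum(db$genes$sp_id == s), integer(1))
    data.frame(sp_id = db$species$sp_id, sp_name = db$species$sp_name,
               gene_count = n, stringsAsFactors = FALSE)
  })
  add("Genes", "species_name_of_gene", "gn_id", function(db, p) {
    i <- which(db$genes$gn_id == as.integer(p$gn_id))
    if (!length(i)) return(not_found("gene", p$gn_id))
    sp <- db$genes$sp_id[i]
    list(gn_id = db$genes$gn_id[i], sp_id = sp,
         sp_name = db$species$sp_name[match(sp, db$species$sp_id)])
  })

  ## --- Species (4) ---------------------------------------------------------
  add("Species", "all_species", c("limit", "offset"), function(db, p)
    paginate(render_species(db), p))
  add("Species", "species_by_id", "sp_id", function(db, p) {
    i <- which(db$species$sp_id == as.integer(p$sp_id))
    if (!length(i)) not_found("species", p$sp_id) else render_species(db, i)
  })
  add("Species", "species_by_name", "sp_name", function(db, p) {
    i <- which(tolower(db$species$sp_name) == tolower(p$sp_name))
    if (!length(i)) not_found("species", p$sp_name) else render_species(db, i)
  })
  add("Species", "species_by_taxon", "taxon_id", function(db, p) {
    i <- which(db$species$sp_taxon_id == as.integer(p$taxon_id))
    if (!length(i)) not_found("species", p$taxon_id) else render_species(db, i)
  })

  ## --- Algorithms (3) ------------------------------------------------------
  add("Algorithms", "all_algorithms", character(), function(db, p) {
    out <- db$algorithms; rownames(out) <- NULL; out
  })
  add("Algorithms", "algorithm_by_id", "alg_id", function(db, p) {
    i <- which(db$algorithms$alg_id == as.integer(p$alg_id))
    if (!length(i)) not_found("algorithm", p$alg_id)
    else db$algorithms[i, , drop = FALSE]
  })
  add("Algorithms", "algorithm_by_name", "alg_name", function(db, p) {
    i <- which(db$algorithms$alg_name == p$alg_name)
    if (!length(i)) not_found("algorithm", p$alg_name)
    else db$algorithms[i, , drop = FALSE]
  })

  ## --- Orthology (14) ------------------------------------------------------
  add("Orthology", "all_orthologs", c("limit", "offset"), function(db, p)
    paginate(render_orthologs(db), p))
  add("Orthology", "ortholog_by_id", "ort_id", function(db, p) {
    i <- which(db$orthologs$ort_id == as.integer(p$ort_id))
    if (!length(i)) not_found("ortholog", p$ort_id) else render_orthologs(db, i)
  })
  add("Orthology", "orthologs_by_from_gene", "gn_id", function(db, p) {
    g <- as.integer(p$gn_id)
    if (!g %in% db$genes$gn_id) return(not_found("gene", p$gn_id))
    render_orthologs(db, which(db$orthologs$from_gene == g))
  })
  add("Orthology", "orthologs_by_to_gene", "gn_id", function(db, p) {
    g <- as.integer(p$gn_id)
    if (!g %in% db$genes$gn_id) return(not_found("gene", p$gn_id))
    render_orthologs(db, which(db$orthologs$to_gene == g))
  })
  add("Orthology", "orthologs_by_from_and_to_gene", c("from_gn_id", "to_gn_id"),
      function(db, p)
        render_orthologs(db, which(db$orthologs$from_gene == as.integer(p$from_gn_id) &
                                   db$orthologs$to_gene == as.integer(p$to_gn_id))))
  add("Orthology", "orthologs_by_from_gene_best", c("gn_id", "best"),
      function(db, p) {
        g <- as.integer(p$gn_id)
        if (!g %in% db$genes$gn_id) return(not_found("gene", p$gn_id))
        render_orthologs(db, which(db$orthologs$from_gene == g &
                                   db$orthologs$is_best == parse_bool(p$best)))
      })
  add("Orthology", "orthologs_by_from_to_best",
      c("from_gn_id", "to_gn_id", "best"), function(db, p)
        render_orthologs(db, which(db$orthologs$from_gene == as.integer(p$from_gn_id) &
                                   db$orthologs$to_gene == as.integer(p$to_gn_id) &
                                   db$orthologs$is_best == parse_bool(p$best))))
  add("Orthology", "orthologs_by_from_to_revised",
      c("from_gn_id", "to_gn_id", "revised"), function(db, p)
        render_orthologs(db, which(db$orthologs$from_gene == as.integer(p$from_gn_id) &
                                   db$orthologs$to_gene == as.integer(p$to_gn_id) &
                                   db$orthologs$is_best_revised == parse_bool(p$revised))))
  add("Orthology", "orthologs_by_from_species", "sp_name", function(db, p) {
    sp <- sp_id_by_name(db, p$sp_name)
    if (is.na(sp)) return(not_found("species", p$sp_name))
    render_orthologs(db, orthologs_of_species(db, sp, "from"))
  })
  add("Orthology", "orthologs_by_to_species", "sp_name", function(db, p) {
    sp <- sp_id_by_name(db, p$sp_name)
    if (is.na(sp)) return(not_found("species", p$sp_name))
    render_orthologs(db, orthologs_of_species(db, sp, "to"))
  })
  add("Orthology", "get_ortholog_by_to_and_from_species",
      c("from_sp_name", "to_sp_name"), function(db, p) {
        spf <- sp_id_by_name(db, p$from_sp_name)
        if (is.na(spf)) return(not_found("species", p$from_sp_name))
        spt <- sp_id_by_name(db, p$to_sp_name)
        if (is.na(spt)) return(not_found("species", p$to_sp_name))
        render_orthologs(db, intersect(orthologs_of_species(db, spf, "from"),
                                       orthologs_of_species(db, spt, "to")))
      })
  add("Orthology", "orthologs_by_species_pair_and_algorithm",
      c("from_sp_name", "to_sp_name", "alg_name"), function(db, p) {
        spf <- sp_id_by_name(db, p$from_sp_name)
        if (is.na(spf)) return(not_found("species", p$from_sp_name))
        spt <- sp_id_by_name(db, p$to_sp_name)
        if (is.na(spt)) return(not_found("species", p$to_sp_name))
        ai <- match(p$alg_name, db$algorithms$alg_name)
        if (is.na(ai)) return(not_found("algorithm", p$alg_name))
        orts <- db$ortholog_algorithms$ort_id[
          db$ortholog_algorithms$alg_id == db$algorithms$alg_id[ai]]
        idx <- intersect(orthologs_of_species(db, spf, "from"),
                         orthologs_of_species(db, spt, "to"))
        render_orthologs(db, idx[db$orthologs$ort_id[idx] %in% orts])
      })
  add("Orthology", "orthologs_by_min_algorithm_matches", "min_matches",
      function(db, p)
        render_orthologs(db, which(db$orthologs$num_algorithms_match >=
                                   as.integer(p$min_matches))))
  add("Orthology", "orthologs_by_source", "ort_source", function(db, p)
    render_orthologs(db, which(db$orthologs$ort_source == p$ort_source)))

  ## --- Homology (6) --------------------------------------------------------
  add("Homology", "all_homology", c("limit", "offset"), function(db, p)
    paginate(render_homology(db), p))
  add("Homology", "homology_by_cluster", "hom_id", function(db, p) {
    i <- which(db$homology$hom_id == as.integer(p$hom_id))
    if (!length(i)) not_found("homology cluster", p$hom_id)
    else render_homology(db, i)
  })
  add("Homology", "homology_by_gene", "gn_id", function(db, p) {
    g <- as.integer(p$gn_id)
    if (!g %in% db$genes$gn_id) return(not_found("gene", p$gn_id))
    render_homology(db, which(db$homology$gn_id == g))
  })
  add("Homology", "homology_by_species", "sp_id", function(db, p) {
    sp <- as.integer(p$sp_id)
    if (!sp %in% db$species$sp_id) return(not_found("species", p$sp_id))
    render_homology(db, which(db$homology$sp_id == sp))
  })
  add("Homology", "homology_by_cluster_and_species", c("hom_id", "sp_id"),
      function(db, p)
        render_homology(db, which(db$homology$hom_id == as.integer(p$hom_id) &
                                  db$homology$sp_id == as.integer(p$sp_id))))
  add("Homology", "homology_by_source", "hom_source", function(db, p)
    render_homology(db, which(db$homology$hom_source == p$hom_source)))

  ## --- Integration (14) ----------------------------------------------------
  add("Integration", "agr_to_ode_gene", "agr_ref", function(db, p) {
    g <- agr_ref_to_ode_gene(db, p$agr_ref)
    if (is.null(g)) not_found("external gene", p$agr_ref)
    else { rownames(g) <- NULL; g }
  })
  add("Integration", "ode_to_agr_gene", "ode_gene_id", function(db, p) {
    i <- agr_gene_of_ode(db, p$ode_gene_id)
    if (is.null(i)) not_found("external gene", p$ode_gene_id)
    else render_genes(db, i)
  })
  add("Integration", "gw_genes_by_genedb", "gdb_id", function(db, p) {
    gd <- as.integer(p$gdb_id)
    if (!gd %in% db$genedb$gdb_id) return(not_found("genedb source", p$gdb_id))
    out <- db$gw_genes[db$gw_genes$gdb_id == gd, , drop = FALSE]
    rownames(out) <- NULL; out
  })
  add("Integration", "gw_gene_by_ref", c("ode_ref_id", "gdb_id"),
      function(db, p) {
        i <- which(db$gw_genes$ode_ref_id == p$ode_ref_id &
                   db$gw_genes$gdb_id == as.integer(p$gdb_id))
        if (!length(i)) not_found("external gene", p$ode_ref_id)
        else { out <- db$gw_genes[i, , drop = FALSE]; rownames(out) <- NULL; out }
      })
  add("Integration", "species_map_all", character(), function(db, p) {
    out <- db$species_map; rownames(out) <- NULL; out
  })
  add("Integration", "species_map_agr_to_gw", "sp_id", function(db, p) {
    v <- translate_species(db, p$sp_id, "sp_to_gw")
    if (is.na(v)) not_found("species", p$sp_id)
    else list(sp_id = as.integer(p$sp_id), gw_sp_id = v)
  })
  add("Integration", "species_map_gw_to_agr", "gw_sp_id", function(db, p) {
    v <- translate_species(db, p$gw_sp_id, "gw_to_sp")
    if (is.na(v)) not_found("species", p$gw_sp_id)
    else list(gw_sp_id = as.integer(p$gw_sp_id), sp_id = v)
  })
  add("Integration", "orthologs_by_ode_gene", "ode_gene_id", function(db, p) {
    i <- agr_gene_of_ode(db, p$ode_gene_id)
    if (is.null(i)) return(not_found("external gene", p$ode_gene_id))
    g <- db$genes$gn_id[i]
    render_orthologs(db, which(db$orthologs$from_gene == g |
                               db$orthologs$to_gene == g))
  })
  add("Integration", "best_orthologs_by_ode_gene", "ode_gene_id",
      function(db, p) {
        i <- agr_gene_of_ode(db, p$ode_gene_id)
        if (is.null(i)) return(not_found("external gene", p$ode_gene_id))
        g <- db$genes$gn_id[i]
        render_orthologs(db, which((db$orthologs$from_gene == g |
                                    db$orthologs$to_gene == g) &
                                   db$orthologs$is_best))
      })
  add("Integration", "has_ortholog_by_ode_gene", "ode_gene_id",
      function(db, p) {
        i <- agr_gene_of_ode(db, p$ode_gene_id)
        if (is.null(i)) return(not_found("external gene", p$ode_gene_id))
        g <- db$genes$gn_id[i]
        list(ode_gene_id = as.integer(p$ode_gene_id),
             has_ortholog = any(db$orthologs$from_gene == g |
                                db$orthologs$to_gene == g))
      })
  add("Integration", "homology_by_ode_gene", "ode_gene_id", function(db, p) {
    i <- agr_gene_of_ode(db, p$ode_gene_id)
    if (is.null(i)) return(not_found("external gene", p$ode_gene_id))
    render_homology(db, which(db$homology$gn_id == db$genes$gn_id[i]))
  })
  add("Integration", "genedb_sources", character(), function(db, p) {
    out <- db$genedb; rownames(out) <- NULL; out
  })
  add("Integration", "orthologous_species_of_ode_gene", "ode_gene_id",
      function(db, p) {
        i <- agr_gene_of_ode(db, p$ode_gene_id)
        if (is.null(i)) return(not_found("external gene", p$ode_gene_id))
        g <- db$genes$gn_id[i]
        partners <- c(db$orthologs$to_gene[db$orthologs$from_gene == g],
                      db$orthologs$from_gene[db$orthologs$to_gene == g])
        sp <- sort(unique(db$genes$sp_id[match(unique(partners), db$genes$gn_id)]))
        render_species(db, match(sp, db$species$sp_id))
      })
  add("Integration", "orthologs_from_ode_gene_to_species",
      c("ode_gene_id", "sp_name"), function(db, p) {
        i <- agr_gene_of_ode(db, p$ode_gene_id)
        if (is.null(i)) return(not_found("external gene", p$ode_gene_id))
        sp <- sp_id_by_name(db, p$sp_name)
        if (is.na(sp)) return(not_found("species", p$sp_name))
        g <- db$genes$gn_id[i]
        idx <- which(db$orthologs$from_gene == g)
        to_sp <- db$genes$sp_id[match(db$orthologs$to_gene[idx], db$genes$gn_id)]
        render_orthologs(db, idx[to_sp == sp])
      })

  names(eps) <- vapply(eps, `[[`, character(1), "name")
  eps
}

API_CATALOG <- build_catalog()

#' Describe the query endpoint catalog
#'
#' The catalog is fixed: 50 endpoints in six categories. This introspection
#' view (itself outside the catalog count) is what conformance tests
#' enumerate.
#'
#' @return data.frame with columns `category`, `name`, `params`
#'   (comma-joined parameter names).
#' @export
#' @examples
#' nrow(api_catalog())  # 50
api_catalog <- function() {
  data.frame(
    category = vapply(API_CATALOG, `[[`, character(1), "category"),
    name = vapply(API_CATALOG, `[[`, character(1), "name"),
    params = vapply(API_CATALOG, function(e) paste(e$params, collapse = ","),
                    character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run one catalog endpoint and return the R result
#'
#' @param db An [ortho_db()].
#' @param name Endpoint name (see [api_catalog()]).
#' @param params Named list of parameters; all values may be given as
#'   strings, as they would arrive in a query string.
#' @return A data.frame or list result; unknown entities yield an object of
#'   class `api_not_found`.
#' @export
api_call <- function(db, name, params = list()) {
  ep <- API_CATALOG[[name]]
  if (is.null(ep)) stop("unknown endpoint: ", name)
  # limit/offset are always optional; everything else declared is required
  missing <- setdiff(setdiff(ep$params, c("limit", "offset")), names(params))
  if (length(missing)) {
    stop("endpoint ", name, " missing parameter(s): ",
         paste(missing, collapse = ", "))
  }
  ep$handler(db, params)
}

#' Run one catalog endpoint and return its JSON response
#'
#' Every response is valid JSON: filter endpoints return arrays of row
#' objects (possibly `[]`), single-entity lookups return one-element arrays
#' or objects, and unknown entities return
#' `{"error":"not_found","entity":...,"key":...}`.
#'
#' @inheritParams api_call
#' @return A one-element character vector of JSON text with attribute
#'   `status` ("ok" or "not_found").
#' @export
api_request <- function(db, name, params = list()) {
  res <- api_call(db, name, params)
  status <- if (inherits(res, "api_not_found")) "not_found" else "ok"
  if (inherits(res, "api_not_found")) res <- unclass(res)
  json <- jsonlite::toJSON(res, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, null = "null")
  structure(as.character(json), status = status)
}
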