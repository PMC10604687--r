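# Deterministic synthetic fixtures: a combined-orthology TSV in the
# 13-column dialect plus GeneWeaver-style CSV tables (gene, species, genedb,
# clusters) with known ground truth, so ingest, translation, augmentation,
# clustering and the query catalog are all testable without downloads.
# Accessions are synthesized per namespace shape (HGNC:<int>, MGI:<int>,
# WB:WBGene<8 digits>, bare Entrez integers, ...): shapes only, no real
# identifiers.

# the nine canonical model organisms of the source, with their native
# identifier namespaces
CANONICAL_SPECIES <- data.frame(
  name = c("Homo sapiens", "Mus musculus", "Rattus norvegicus",
           "Danio rerio", "Drosophila melanogaster",
           "Caenorhabditis elegans", "Saccharomyces cerevisiae",
           "Xenopus laevis", "Xenopus tropicalis"),
  taxon = c(9606L, 10090L, 10116L, 7955L, 7227L, 6239L, 559292L, 8355L, 8364L),
  prefix = c("HGNC", "MGI", "RGD", "ZFIN", "FB", "WB", "SGD",
             "Xenbase", "Xenbase"),
  stringsAsFactors = FALSE
)

# the three species supplied through the external mapping system
DEFAULT_ADDED_SPECIES <- data.frame(
  name = c("Gallus gallus", "Canis familiaris", "Macaca mulatta"),
  taxon = c(9031L, 9615L, 9544L),
  source = c("CGNC", "Ensembl Gene", "Entrez"),
  stringsAsFactors = FALSE
)

DEFAULT_ALGORITHMS <- c(
  "OMA", "PANTHER", "Ensembl Compara", "InParanoid", "OrthoInspector",
  "PhylomeDB", "Hieranoid", "SonicParanoid", "TreeFam", "Roundup"
)

# external identifier-source registry and the namespace each maps to;
# Entrez accessions are bare integers (empty native prefix, curie "Entrez")
DEFAULT_GENEDB <- data.frame(
  gdb_id = 1:11,
  gdb_name = c("Entrez", "HGNC", "MGI", "RGD", "ZFIN", "FlyBase", "WormBase",
               "SGD", "Xenbase", "CGNC", "Ensembl Gene"),
  curie_prefix = c("Entrez", "HGNC", "MGI", "RGD", "ZFIN", "FB", "WB",
                   "SGD", "Xenbase", "CGNC", "Ensembl"),
  stringsAsFactors = FALSE
)

# accession shape per namespace, deterministic in the gene index
make_accession <- function(prefix, i) {
  switch(prefix,
    HGNC = sprintf("HGNC:%d", 1000L + i),
    MGI = sprintf("MGI:%d", 87000L + i),
    RGD = sprintf("RGD:%d", 61000L + i),
    ZFIN = sprintf("ZFIN:ZDB-GENE-%06d-%d", 990000L + i, i),
    FB = sprintf("FB:FBgn%07d", i),
    WB = sprintf("WB:WBGene%08d", i),
    SGD = sprintf("SGD:S%09d", i),
    Xenbase = sprintf("Xenbase:XB-GENE-%07d", 1000000L + i),
    CGNC = sprintf("CGNC:%d", 50000L + i),
    Ensembl = sprintf("Ensembl:ENSCAFG%011d", i),
    Entrez = sprintf("Entrez:%d", 690000L + i),
    sprintf("%s:%d", prefix, i)
  )
}

species_code <- function(name) {
  parts <- strsplit(tolower(name), " ", fixed = TRUE)[[1]]
  paste0(substr(parts[1], 1, 1), substr(parts[length(parts)], 1, 2))
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic fixture
#'
#' The defaults are the study conditions the fixtures emulate: the nine
#' canonical model organisms, the three externally mapped species
#' (Gallus gallus, Canis familiaris, Macaca mulatta) with their identifier
#' sources, and a pool of orthology-call algorithm labels. A fixed seed
#' yields byte-identical output.
#'
#' @param n_canonical_species Number of canonical species (1-9; the nine
#'   stock binomials are used in order).
#' @param genes_per_species Gene pool size per canonical species.
#' @param n_clusters Number of planted homology clusters.
#' @param cluster_size_range Integer (min, max) members per planted cluster;
#'   members are drawn from distinct species.
#' @param added_species data.frame (`name`, `taxon`, `source`) of species
#'   supplied through the external system; default the three above.
#' @param algorithm_pool Character vector of algorithm labels.
#' @param unresolvable_fraction Probability that an extended cluster also
#'   carries a canonical-species member absent from the orthology source
#'   (exercising the rule that such genes are never added).
#' @param seed Integer RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_canonical_species = 9L, genes_per_species = 30L,
                         n_clusters = 25L, cluster_size_range = c(2L, 6L),
                         added_species = DEFAULT_ADDED_SPECIES,
                         algorithm_pool = DEFAULT_ALGORITHMS,
                         unresolvable_fraction = 0.2, seed = 1L) {
  stopifnot(n_canonical_species >= 1L,
            n_canonical_species <= nrow(CANONICAL_SPECIES),
            genes_per_species >= 1L, genes_per_species <= 1000L,
            n_clusters >= 0L,
            length(cluster_size_range) == 2L,
            cluster_size_range[1] >= 2L,
            cluster_size_range[1] <= cluster_size_range[2],
            cluster_size_range[2] <= n_canonical_species |
              n_clusters == 0L,
            unresolvable_fraction >= 0, unresolvable_fraction <= 1,
            length(algorithm_pool) >= 1L)
  if (nrow(added_species) > 0L) {
    stopifnot(all(c("name", "taxon", "source") %in% names(added_species)),
              all(added_species$source %in% DEFAULT_GENEDB$gdb_name))
  }
  structure(list(
    n_canonical_species = as.integer(n_canonical_species),
    genes_per_species = as.integer(genes_per_species),
    n_clusters = as.integer(n_clusters),
    cluster_size_range = as.integer(cluster_size_range),
    added_species = added_species, algorithm_pool = algorithm_pool,
    unresolvable_fraction = unresolvable_fraction, seed = as.integer(seed)
  ), class = "fixture_spec")
}

# everything is generated under one seeded RNG stream so the TSV and the CSV
# fixtures are mutually consistent
generate_all <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    csp <- CANONICAL_SPECIES[seq_len(spec$n_canonical_species), , drop = FALSE]
    nsp <- nrow(csp)

    # canonical gene pools; index ranges are disjoint across species so that
    # species sharing a namespace (the two Xenopus, both Xenbase) never
    # collide on an accession
    pools <- lapply(seq_len(nsp), function(s) {
      idx <- s * 2000L + seq_len(spec$genes_per_species)
      data.frame(
        accession = vapply(idx, function(i) make_accession(csp$prefix[s], i),
                           character(1)),
        symbol = paste0(species_code(csp$name[s]), "-", idx),
        sp = s, stringsAsFactors = FALSE
      )
    })
    used <- integer(nsp) # per-species consumption counter

    # planted clusters: one gene per distinct species
    memb <- list()
    if (spec$n_clusters > 0L) {
      sizes <- sample(seq.int(spec$cluster_size_range[1],
                              spec$cluster_size_range[2]),
                      spec$n_clusters, replace = TRUE)
      for (ci in seq_len(spec$n_clusters)) {
        open <- which(used < spec$genes_per_species)
        if (length(open) < sizes[ci]) {
          stop("fixture spec exhausts the gene pools; increase genes_per_species")
        }
        sps <- sample(open, sizes[ci])
        rows <- do.call(rbind, lapply(sps, function(s) {
          used[s] <<- used[s] + 1L
          pools[[s]][used[s], , drop = FALSE]
        }))
        rows$cluster <- ci
        memb[[ci]] <- rows
      }
    }
    memb_df <- if (length(memb)) do.call(rbind, memb) else
      data.frame(accession = character(), symbol = character(),
                 sp = integer(), cluster = integer(), stringsAsFactors = FALSE)

    # directed pair rows with consistent per-direction flags: the reverse
    # direction's best flag is the forward direction's best-reverse flag
    npool <- length(spec$algorithm_pool)
    row_list <- list()
    truth_pairs_from <- character(); truth_pairs_to <- character()
    for (ci in seq_along(memb)) {
      m <- memb[[ci]]
      k <- nrow(m)
      for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
        nm <- sample.int(npool, 1L)
        oo <- nm + sample.int(npool - nm + 1L, 1L) - 1L
        algs <- paste(sort(sample(spec$algorithm_pool, nm)), collapse = "|")
        fb <- sample(TRISTATE_TOKENS, 1L, prob = c(0.45, 0.45, 0.10))
        rb <- sample(TRISTATE_TOKENS, 1L, prob = c(0.45, 0.45, 0.10))
        mk <- function(a, b, f1, f2) data.frame(
          gene1_id = m$accession[a], gene1_symbol = m$symbol[a],
          gene1_taxon = paste0("NCBITaxon:", csp$taxon[m$sp[a]]),
          gene1_species_name = csp$name[m$sp[a]],
          gene2_id = m$accession[b], gene2_symbol = m$symbol[b],
          gene2_taxon = paste0("NCBITaxon:", csp$taxon[m$sp[b]]),
          gene2_species_name = csp$name[m$sp[b]],
          algorithms = algs, algorithms_match = nm, out_of_algorithms = oo,
          is_best = f1, is_best_revised = f2, stringsAsFactors = FALSE
        )
        row_list[[length(row_list) + 1L]] <- mk(i, j, fb, rb)
        row_list[[length(row_list) + 1L]] <- mk(j, i, rb, fb)
        truth_pairs_from <- c(truth_pairs_from, m$accession[i], m$accession[j])
        truth_pairs_to <- c(truth_pairs_to, m$accession[j], m$accession[i])
      }
    }
    rows <- if (length(row_list)) do.call(rbind, row_list) else {
      out <- data.frame(matrix(character(), 0L, 13L), stringsAsFactors = FALSE)
      names(out) <- ORTHOLOGY_COLUMNS
      out$algorithms_match <- integer(); out$out_of_algorithms <- integer()
      out
    }

    genes_df <- do.call(rbind, lapply(seq_len(nsp), function(s) {
      g <- pools[[s]][seq_len(used[s]), , drop = FALSE]
      g$sp_name <- rep(csp$name[s], nrow(g))
      g
    }))

    agr <- list(
      rows = rows, tsv = write_orthology_file(rows),
      truth = list(
        clusters = data.frame(cluster = memb_df$cluster,
                              accession = memb_df$accession,
                              sp_name = csp$name[memb_df$sp],
                              stringsAsFactors = FALSE),
        pairs = data.frame(gene1_id = truth_pairs_from,
                           gene2_id = truth_pairs_to, stringsAsFactors = FALSE),
        genes = genes_df, species = csp
      )
    )

    ## ---- external (GeneWeaver-style) side ---------------------------------
    asp <- spec$added_species
    gw_species <- data.frame(
      gw_sp_id = 100L + seq_len(nsp + nrow(asp)),
      sp_name = c(csp$name, asp$name),
      sp_taxon_id = c(csp$taxon, asp$taxon), stringsAsFactors = FALSE
    )
    gdb_of_prefix <- function(pfx)
      DEFAULT_GENEDB$gdb_id[match(pfx, DEFAULT_GENEDB$curie_prefix)]

    # external gene rows for every canonical gene used in the TSV; species
    # with an odd external key store the bare local accession, the rest the
    # full curie, exercising both translation branches
    gw_rows <- list()
    add_gw <- function(ode_ref, gdb, gw_sp) {
      gw_rows[[length(gw_rows) + 1L]] <<- data.frame(
        ode_ref_id = ode_ref, gdb_id = gdb, sp_id = gw_sp,
        stringsAsFactors = FALSE)
    }
    native_ref <- function(curie, gw_sp) {
      if (gw_sp %% 2L == 1L) split_curie(curie)$local else curie
    }
    if (nrow(genes_df) > 0L) {
      for (r in seq_len(nrow(genes_df))) {
        s <- genes_df$sp[r]
        gw_sp <- gw_species$gw_sp_id[s]
        pfx <- csp$prefix[s]
        add_gw(native_ref(genes_df$accession[r], gw_sp), gdb_of_prefix(pfx), gw_sp)
      }
    }

    # unresolvable canonical genes: carried by the external system but absent
    # from the orthology source
    unresolved <- list()
    next_unres <- 2000L * seq_len(nsp) + spec$genes_per_species + 500L
    new_unresolvable <- function() {
      s <- sample.int(nsp, 1L)
      next_unres[s] <<- next_unres[s] + 1L
      acc <- make_accession(csp$prefix[s], next_unres[s])
      gw_sp <- gw_species$gw_sp_id[s]
      add_gw(native_ref(acc, gw_sp), gdb_of_prefix(csp$prefix[s]), gw_sp)
      list(accession = acc, sp = s, gw_sp = gw_sp,
           native = native_ref(acc, gw_sp), gdb = gdb_of_prefix(csp$prefix[s]))
    }

    # added-species gene factory
    added_counter <- integer(nrow(asp))
    new_added_gene <- function(a) {
      added_counter[a] <<- added_counter[a] + 1L
      pfx <- DEFAULT_GENEDB$curie_prefix[match(asp$source[a], DEFAULT_GENEDB$gdb_name)]
      curie <- make_accession(pfx, added_counter[a])
      native <- split_curie(curie)$local
      gw_sp <- gw_species$gw_sp_id[nsp + a]
      gdb <- DEFAULT_GENEDB$gdb_id[match(asp$source[a], DEFAULT_GENEDB$gdb_name)]
      add_gw(native, gdb, gw_sp)
      list(curie = curie, native = native, gw_sp = gw_sp, gdb = gdb, a = a,
           sp_name = asp$name[a])
    }

    # external clusters: extend planted clusters with added-species members
    # (every added species appears at least once), optionally plant an
    # unresolvable member, and add a couple of added-species-only clusters
    clus_rows <- list(); truth_ext <- list()
    add_member <- function(cid, native, gdb, gw_sp) {
      clus_rows[[length(clus_rows) + 1L]] <<- data.frame(
        cluster_id = cid, accession = native, gdb_id = gdb, sp_id = gw_sp,
        stringsAsFactors = FALSE)
    }
    n_ext <- if (spec$n_clusters > 0L && nrow(asp) > 0L)
      min(spec$n_clusters, max(nrow(asp), ceiling(0.6 * spec$n_clusters)))
    else 0L
    ext_ids <- if (n_ext > 0L) sort(sample.int(spec$n_clusters, n_ext)) else integer()
    for (e in seq_along(ext_ids)) {
      ci <- ext_ids[e]
      cid <- sprintf("EXT%03d", ci)
      m <- memb[[ci]]
      for (r in seq_len(nrow(m))) {
        gw_sp <- gw_species$gw_sp_id[m$sp[r]]
        add_member(cid, native_ref(m$accession[r], gw_sp),
                   gdb_of_prefix(csp$prefix[m$sp[r]]), gw_sp)
      }
      # round-robin guarantees every added species is used at least once
      picks <- if (e <= nrow(asp)) (e - 1L) %% nrow(asp) + 1L else
        sample.int(nrow(asp), sample.int(min(3L, nrow(asp)), 1L))
      new_members <- lapply(unique(picks), new_added_gene)
      for (g in new_members) add_member(cid, g$native, g$gdb, g$gw_sp)
      if (stats::runif(1) < spec$unresolvable_fraction) {
        u <- new_unresolvable()
        add_member(cid, u$native, u$gdb, u$gw_sp)
        unresolved[[length(unresolved) + 1L]] <- u
      }
      truth_ext[[cid]] <- list(cluster = ci,
                               added = vapply(new_members, `[[`, character(1), "curie"),
                               added_sp = vapply(new_members, `[[`, character(1), "sp_name"))
    }
    # added-species-only clusters (cross-species so they form real clusters)
    new_only <- list()
    if (spec$n_clusters > 0L && nrow(asp) >= 2L) {
      for (q in 1:2) {
        cid <- sprintf("NEW%03d", q)
        sps <- sample.int(nrow(asp), 2L)
        gs <- lapply(sps, new_added_gene)
        for (g in gs) add_member(cid, g$native, g$gdb, g$gw_sp)
        new_only[[cid]] <- gs
      }
    }
    clusters_df <- if (length(clus_rows)) do.call(rbind, clus_rows) else
      data.frame(cluster_id = character(), accession = character(),
                 gdb_id = integer(), sp_id = integer(), stringsAsFactors = FALSE)

    gw_genes_df <- if (length(gw_rows)) do.call(rbind, gw_rows) else
      data.frame(ode_ref_id = character(), gdb_id = integer(),
                 sp_id = integer(), stringsAsFactors = FALSE)
    gw_genes_df <- cbind(ode_gene_id = 5000L + seq_len(nrow(gw_genes_df)),
                         gw_genes_df)

    ## ---- ground truth for augmentation and clustering ----------------------
    # brute-force enumeration of the expected post-filter pair set, done
    # directly from the planted memberships, independent of the package's
    # decomposition code
    unresolved_acc <- vapply(unresolved, `[[`, character(1), "accession")
    exp_from <- character(); exp_to <- character()
    final_clusters <- list()
    for (ci in seq_along(memb)) {
      cid <- sprintf("EXT%03d", ci)
      m <- memb[[ci]]
      members <- data.frame(acc = m$accession, sp = csp$name[m$sp],
                            new = FALSE, stringsAsFactors = FALSE)
      te <- truth_ext[[cid]]
      if (!is.null(te)) {
        members <- rbind(members, data.frame(acc = te$added, sp = te$added_sp,
                                             new = TRUE, stringsAsFactors = FALSE))
      }
      final_clusters[[length(final_clusters) + 1L]] <-
        data.frame(cluster = ci, accession = members$acc, sp_name = members$sp,
                   stringsAsFactors = FALSE)
      k <- nrow(members)
      if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
        if (!members$new[i] && !members$new[j]) next     # no new-species endpoint
        if (members$sp[i] == members$sp[j]) next          # same species
        exp_from <- c(exp_from, members$acc[i], members$acc[j])
        exp_to <- c(exp_to, members$acc[j], members$acc[i])
      }
    }
    for (q in seq_along(new_only)) {
      gs <- new_only[[q]]
      acc <- vapply(gs, `[[`, character(1), "curie")
      spn <- vapply(gs, function(g) asp$name[g$a], character(1))
      final_clusters[[length(final_clusters) + 1L]] <-
        data.frame(cluster = spec$n_clusters + q, accession = acc,
                   sp_name = spn, stringsAsFactors = FALSE)
      exp_from <- c(exp_from, acc[1], acc[2])
      exp_to <- c(exp_to, acc[2], acc[1])
    }
    keep <- !duplicated(paste(exp_from, exp_to))

    gw <- list(
      genedb = DEFAULT_GENEDB, species = gw_species, genes = gw_genes_df,
      clusters = clusters_df,
      truth = list(
        expected_pairs = data.frame(from_ref = exp_from[keep],
                                    to_ref = exp_to[keep],
                                    stringsAsFactors = FALSE),
        final_clusters = if (length(final_clusters))
          do.call(rbind, final_clusters) else
            data.frame(cluster = integer(), accession = character(),
                       sp_name = character(), stringsAsFactors = FALSE),
        added_species = asp,
        n_new_genes = sum(added_counter),
        unresolvable = unresolved_acc
      )
    )
    list(agr = agr, gw = gw, spec = spec)
  })
}

#' Generate a synthetic combined-orthology TSV with ground truth
#'
#' Plants homology clusters over the canonical species and emits every
#' cross-species cluster edge in both directions with consistent tri-state
#' best-score flags; the algorithm list length equals the match count.
#'
#' @param spec A [fixture_spec()].
#' @return List with `rows` (parsed-form data.frame), `tsv` (file text) and
#'   `truth` (planted clusters, directed pair list, gene and species tables).
#' @export
generate_agr_fixture <- function(spec = fixture_spec()) {
  generate_all(spec)$agr
}

#' Generate GeneWeaver-style CSV fixtures consistent with the TSV fixture
#'
#' Produces the external gene/species/genedb tables and external homology
#' clusters that mix added-species members into the planted clusters; a
#' configurable fraction of extended clusters carries a member absent from
#' the orthology source, exercising the resolvability filter. The ground
#' truth records the exact expected post-filter pair set and the final
#' cluster partition, both computed by direct enumeration in the generator.
#'
#' @param spec A [fixture_spec()].
#' @return List with `agr` (as [generate_agr_fixture()]) and `gw` (tables
#'   `genedb`, `species`, `genes`, `clusters`, plus `truth`).
#' @export
generate_gw_fixture <- function(spec = fixture_spec()) {
  generate_all(spec)
}

#' Write a generated fixture to a directory of plain-text files
#'
#' @param fx Result of [generate_gw_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `orthology.tsv`, `gene.csv`,
#'   `species.csv`, `genedb.csv`, `clusters.csv` and `truth.json`.
#' @export
write_fixture <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cat(fx$agr$tsv, file = file.path(dir, "orthology.tsv"))
  utils::write.csv(fx$gw$genes, file.path(dir, "gene.csv"), row.names = FALSE)
  utils::write.csv(fx$gw$species, file.path(dir, "species.csv"), row.names = FALSE)
  utils::write.csv(fx$gw$genedb, file.path(dir, "genedb.csv"), row.names = FALSE)
  utils::write.csv(fx$gw$clusters, file.path(dir, "clusters.csv"), row.names = FALSE)
  jsonlite::write_json(fx$gw$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
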