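run <- make_pipeline_db(seed = 7)
db <- run$db

test_that("the catalog is exactly 50 uniquely named routes in six categories", {
  cat <- api_catalog()
  expect_equal(nrow(cat), 50L)
  expect_equal(length(unique(cat$name)), 50L)
  expect_setequal(unique(cat$category),
                  c("Genes", "Species", "Algorithms", "Orthology", "Homology",
                    "Integration"))
  expect_equal(length(unique(cat$category)), 6L)
})

test_that("every endpoint returns valid JSON that round-trips", {
  # one parameter set per endpoint, exercised on the populated store
  g1 <- db$genes$gn_id[1]
  added <- db$orthologs[db$orthologs$ort_source != "agr", ][1, ]
  ode <- db$gw_genes$ode_gene_id[match(db$genes$gn_ref_id[
    match(added$from_gene, db$genes$gn_id)], db$gw_genes$agr_ref)]
  params <- list(
    all_genes = list(), gene_by_id = list(gn_id = g1),
    gene_by_ref_id = list(gn_ref_id = db$genes$gn_ref_id[1]),
    genes_by_species_id = list(sp_id = 1),
    genes_by_species_name = list(sp_name = "Homo sapiens"),
    genes_by_algorithm = list(alg_name = db$algorithms$alg_name[1]),
    genes_by_prefix = list(gn_prefix = "HGNC"),
    gene_count_by_species = list(),
    species_name_of_gene = list(gn_id = g1),
    all_species = list(), species_by_id = list(sp_id = 1),
    species_by_name = list(sp_name = "Mus musculus"),
    species_by_taxon = list(taxon_id = 10090),
    all_algorithms = list(),
    algorithm_by_id = list(alg_id = db$algorithms$alg_id[1]),
    algorithm_by_name = list(alg_name = db$algorithms$alg_name[2]),
    all_orthologs = list(limit = 20),
    ortholog_by_id = list(ort_id = db$orthologs$ort_id[1]),
    orthologs_by_from_gene = list(gn_id = db$orthologs$from_gene[1]),
    orthologs_by_to_gene = list(gn_id = db$orthologs$to_gene[1]),
    orthologs_by_from_and_to_gene = list(from_gn_id = db$orthologs$from_gene[1],
                                         to_gn_id = db$orthologs$to_gene[1]),
    orthologs_by_from_gene_best = list(gn_id = db$orthologs$from_gene[1],
                                       best = "TRUE"),
    orthologs_by_from_to_best = list(from_gn_id = db$orthologs$from_gene[1],
                                     to_gn_id = db$orthologs$to_gene[1],
                                     best = "true"),
    orthologs_by_from_to_revised = list(from_gn_id = db$orthologs$from_gene[1],
                                        to_gn_id = db$orthologs$to_gene[1],
                                        revised = "false"),
    orthologs_by_from_species = list(sp_name = "Homo sapiens"),
    orthologs_by_to_species = list(sp_name = "Mus musculus"),
    get_ortholog_by_to_and_from_species = list(from_sp_name = "Macaca mulatta",
                                               to_sp_name = "Homo sapiens"),
    orthologs_by_species_pair_and_algorithm = list(
      from_sp_name = "Homo sapiens", to_sp_name = "Mus musculus",
      alg_name = db$algorithms$alg_name[1]),
    orthologs_by_min_algorithm_matches = list(min_matches = 5),
    orthologs_by_source = list(ort_source = "added:geneweaver"),
    all_homology = list(), homology_by_cluster = list(hom_id = 1),
    homology_by_gene = list(gn_id = db$homology$gn_id[1]),
    homology_by_species = list(sp_id = 1),
    homology_by_cluster_and_species = list(hom_id = 1, sp_id = 1),
    homology_by_source = list(hom_source = "added"),
    agr_to_ode_gene = list(agr_ref = db$gw_genes$agr_ref[1]),
    ode_to_agr_gene = list(ode_gene_id = ode),
    gw_genes_by_genedb = list(gdb_id = 1),
    gw_gene_by_ref = list(ode_ref_id = db$gw_genes$ode_ref_id[1],
                          gdb_id = db$gw_genes$gdb_id[1]),
    species_map_all = list(),
    species_map_agr_to_gw = list(sp_id = 1),
    species_map_gw_to_agr = list(gw_sp_id = db$species_map$gw_sp_id[1]),
    orthologs_by_ode_gene = list(ode_gene_id = ode),
    best_orthologs_by_ode_gene = list(ode_gene_id = ode),
    has_ortholog_by_ode_gene = list(ode_gene_id = ode),
    homology_by_ode_gene = list(ode_gene_id = ode),
    genedb_sources = list(),
    orthologous_species_of_ode_gene = list(ode_gene_id = ode),
    orthologs_from_ode_gene_to_species = list(ode_gene_id = ode,
                                              sp_name = "Homo sapiens")
  )
  expect_setequal(names(params), api_catalog()$name)
  for (ep in names(params)) {
    json <- api_request(db, ep, params[[ep]])
    expect_true(jsonlite::validate(json), info = ep)
    parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
    re <- jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = NA, null = "null")
    expect_identical(jsonlite::fromJSON(re, simplifyVector = FALSE), parsed,
                     info = ep)
    expect_equal(attr(json, "status"), "ok", info = ep)
  }
})

test_that("filtered endpoints agree with direct table scans", {
  genes <- db$genes; orts <- db$orthologs; sp <- db$species

  got <- api_call(db, "genes_by_species_name", list(sp_name = "Danio rerio"))
  want <- genes[genes$sp_id == sp$sp_id[sp$sp_name == "Danio rerio"], ]
  expect_setequal(got$gn_id, want$gn_id)

  got <- api_call(db, "genes_by_prefix", list(gn_prefix = "Entrez"))
  expect_setequal(got$gn_id, genes$gn_id[genes$gn_prefix == "Entrez"])

  alg <- db$algorithms$alg_name[3]
  got <- api_call(db, "genes_by_algorithm", list(alg_name = alg))
  aid <- db$algorithms$alg_id[db$algorithms$alg_name == alg]
  oid <- db$ortholog_algorithms$ort_id[db$ortholog_algorithms$alg_id == aid]
  sel <- orts[orts$ort_id %in% oid, ]
  expect_setequal(got$gn_id, unique(c(sel$from_gene, sel$to_gene)))
  expect_false(anyDuplicated(got$gn_id) > 0)

  got <- api_call(db, "gene_count_by_species", list())
  expect_equal(got$gene_count,
               vapply(sp$sp_id, function(s) sum(genes$sp_id == s), integer(1)))

  got <- api_call(db, "orthologs_by_min_algorithm_matches",
                  list(min_matches = 4))
  expect_setequal(got$ort_id, orts$ort_id[orts$num_algorithms_match >= 4])
  expect_true(all(got$num_algorithms_match >= 4))

  got <- api_call(db, "orthologs_by_source", list(ort_source = "agr"))
  expect_setequal(got$ort_id, orts$ort_id[orts$ort_source == "agr"])

  best <- api_call(db, "orthologs_by_from_gene_best",
                   list(gn_id = orts$from_gene[1], best = "true"))
  expect_true(all(best$is_best))
  expect_setequal(best$ort_id,
                  orts$ort_id[orts$from_gene == orts$from_gene[1] & orts$is_best])

  hom <- api_call(db, "homology_by_cluster_and_species",
                  list(hom_id = 1, sp_id = db$homology$sp_id[1]))
  expect_setequal(hom$gn_id,
                  db$homology$gn_id[db$homology$hom_id == 1 &
                                    db$homology$sp_id == db$homology$sp_id[1]])

  gd <- api_call(db, "gw_genes_by_genedb", list(gdb_id = 2))
  expect_setequal(gd$ode_gene_id,
                  db$gw_genes$ode_gene_id[db$gw_genes$gdb_id == 2])
})

test_that("the species-pair route returns exactly the planted cross-species pairs", {
  got <- api_call(db, "get_ortholog_by_to_and_from_species",
                  list(from_sp_name = "Macaca mulatta",
                       to_sp_name = "Homo sapiens"))
  truth <- run$fx$gw$truth$expected_pairs
  is_mac <- startsWith(truth$from_ref, "Entrez:") &
    startsWith(truth$to_ref, "HGNC:")
  expect_gt(sum(is_mac), 0L)
  expect_setequal(paste(got$from_ref_id, got$to_ref_id),
                  paste(truth$from_ref[is_mac], truth$to_ref[is_mac]))
  # accessions are rendered in each gene's native namespace
  expect_true(all(startsWith(got$from_ref_id, "Entrez:")))
  expect_true(all(startsWith(got$to_ref_id, "HGNC:")))
})

test_that("a same-species query is empty and unknown entities are structured not-found", {
  same <- api_call(db, "get_ortholog_by_to_and_from_species",
                   list(from_sp_name = "Homo sapiens",
                        to_sp_name = "Homo sapiens"))
  expect_equal(nrow(same), 0L)
  json <- api_request(db, "get_ortholog_by_to_and_from_species",
                      list(from_sp_name = "Homo sapiens",
                           to_sp_name = "Homo sapiens"))
  expect_equal(attr(json, "status"), "ok")
  expect_identical(as.character(json), "[]")

  nf <- api_request(db, "get_ortholog_by_to_and_from_species",
                    list(from_sp_name = "Vulpes vulpes",
                         to_sp_name = "Homo sapiens"))
  expect_equal(attr(nf, "status"), "not_found")
  parsed <- jsonlite::fromJSON(nf)
  expect_equal(parsed$error, "not_found")
  expect_equal(parsed$entity, "species")

  expect_equal(attr(api_request(db, "genes_by_algorithm",
                                list(alg_name = "NoSuchAlgorithm")), "status"),
               "not_found")
  expect_equal(attr(api_request(db, "gene_by_ref_id",
                                list(gn_ref_id = "HGNC:0")), "status"),
               "not_found")
})

test_that("list endpoints on an empty store return empty JSON lists", {
  empty <- ortho_db()
  for (ep in c("all_genes", "all_species", "all_algorithms", "all_orthologs",
               "all_homology", "species_map_all", "genedb_sources")) {
    json <- api_request(empty, ep)
    expect_identical(as.character(json), "[]", info = ep)
    expect_equal(attr(json, "status"), "ok", info = ep)
  }
})

test_that("pagination caps and offsets the all_* routes", {
  page <- api_call(db, "all_orthologs", list(limit = 5, offset = 2))
  expect_equal(nrow(page), 5L)
  expect_equal(page$ort_id, db$orthologs$ort_id[3:7])
  rest <- api_call(db, "all_orthologs", list(offset = nrow(db$orthologs)))
  expect_equal(nrow(rest), 0L)
})

test_that("missing and malformed parameters raise errors, unknown endpoints too", {
  expect_error(api_call(db, "gene_by_id", list()), "missing parameter")
  expect_error(api_call(db, "no_such_route", list()), "unknown endpoint")
  expect_error(api_call(db, "orthologs_by_from_gene_best",
                        list(gn_id = 1, best = "maybe")), "true/false")
})

test_that("integration routes translate external keys end to end", {
  gw <- db$gw_genes[db$gw_genes$agr_ref %in% db$genes$gn_ref_id, ][1, ]
  g <- api_call(db, "ode_to_agr_gene", list(ode_gene_id = gw$ode_gene_id))
  expect_equal(g$gn_ref_id, gw$agr_ref)
  back <- api_call(db, "agr_to_ode_gene", list(agr_ref = gw$agr_ref))
  expect_equal(back$ode_gene_id, gw$ode_gene_id)

  orts <- api_call(db, "orthologs_by_ode_gene", list(ode_gene_id = gw$ode_gene_id))
  gid <- g$gn_id
  expect_setequal(orts$ort_id,
                  db$orthologs$ort_id[db$orthologs$from_gene == gid |
                                      db$orthologs$to_gene == gid])
  has <- api_call(db, "has_ortholog_by_ode_gene", list(ode_gene_id = gw$ode_gene_id))
  expect_equal(has$has_ortholog, nrow(orts) > 0)

  osp <- api_call(db, "orthologous_species_of_ode_gene",
                  list(ode_gene_id = gw$ode_gene_id))
  partners <- c(db$orthologs$to_gene[db$orthologs$from_gene == gid],
                db$orthologs$from_gene[db$orthologs$to_gene == gid])
  expect_setequal(osp$sp_id,
                  unique(db$genes$sp_id[match(partners, db$genes$gn_id)]))
})
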