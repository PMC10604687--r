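# Filtering rules under test, with genes labelled as in the worked example:
# A, B from newly added species, C, D from canonical species, F carried by
# the external system but absent from the gene table.

test_that("a mixed cluster keeps exactly the new-species, resolvable, cross-species pairs", {
  db <- toy_db(n_canonical = 2, n_added = 2, genes_per_species = 1)
  # gene ids: 1 = C (sp1), 2 = D (sp2), 3 = A (sp3 added), 4 = B (sp4 added)
  members <- rbind(toy_members(db, "cl1", c(3L, 4L, 1L, 2L)),
                   data.frame(cluster_id = "cl1", accession = "T:999",
                              gdb_id = 1L, sp_id = NA_integer_)) # F
  dec <- decompose_clusters(db, members, new_sp_ids = c(3L, 4L))
  # kept unordered: {A,B},{A,C},{A,D},{B,C},{B,D} -> 10 directed
  expect_equal(nrow(dec$pairs), 10L)
  und <- unique(paste(pmin(dec$pairs$from_gene, dec$pairs$to_gene),
                      pmax(dec$pairs$from_gene, dec$pairs$to_gene)))
  expect_setequal(und, c("3 4", "1 3", "2 3", "1 4", "2 4"))
  expect_equal(dec$pairs_skipped_no_new_species, 1L) # {C,D}
  expect_equal(dec$pairs_skipped_unknown_gene, 4L)   # F against each other
  expect_true(all(!dec$pairs$is_best))
  expect_true(all(dec$pairs$num_algorithms_match == 0L))
  expect_equal(unique(dec$pairs$ort_source), "added:external")
})

test_that("degenerate clusters yield no pairs", {
  db <- toy_db(2, 2, genes_per_species = 2)
  single <- toy_members(db, "solo", 1L)
  expect_equal(nrow(decompose_clusters(db, single, 5:6)$pairs), 0L)

  canon_only <- toy_members(db, "c2", c(1L, 3L)) # two canonical genes
  dec <- decompose_clusters(db, canon_only, new_sp_ids = c(3L, 4L))
  expect_equal(nrow(dec$pairs), 0L)
  expect_equal(dec$pairs_skipped_no_new_species, 1L)
})

test_that("same-species members yield no pair", {
  db <- toy_db(1, 1, genes_per_species = 2)
  # genes 3,4 both belong to added species 2
  dec <- decompose_clusters(db, toy_members(db, "p", c(3L, 4L)),
                            new_sp_ids = 2L)
  expect_equal(nrow(dec$pairs), 0L)
  expect_equal(dec$pairs_skipped_same_species, 1L)
})

test_that("new-new pairs can be excluded by policy", {
  db <- toy_db(1, 2, genes_per_species = 1)
  dec <- decompose_clusters(db, toy_members(db, "nn", c(1L, 2L, 3L)),
                            new_sp_ids = c(2L, 3L), new_new_pairs = FALSE)
  und <- unique(paste(pmin(dec$pairs$from_gene, dec$pairs$to_gene),
                      pmax(dec$pairs$from_gene, dec$pairs$to_gene)))
  expect_setequal(und, c("1 2", "1 3")) # the new-new edge {2,3} is dropped
})

test_that("appending is deduplicated against earlier clusters and idempotent", {
  db <- toy_db(2, 1, genes_per_species = 2)
  a <- decompose_clusters(db, toy_members(db, "x", c(1L, 5L)), 3L)
  b <- decompose_clusters(db, toy_members(db, "y", c(1L, 3L, 5L)), 3L)
  r1 <- dedupe_and_append(db, a$pairs)
  expect_equal(r1$pairs_added, 2L)
  r2 <- dedupe_and_append(db, b$pairs) # shares the 1-5 edge with cluster x
  expect_equal(r2$pairs_added, 2L)
  expect_gte(r2$duplicates_removed, 2L)
  r3 <- dedupe_and_append(db, b$pairs) # idempotence
  expect_equal(r3$pairs_added, 0L)
  expect_true(validate_db(db))
})

test_that("pairs already present from canonical ingest are not re-added", {
  run <- make_pipeline_db(seed = 41)
  before <- nrow(run$db$orthologs)
  redo <- decompose_clusters(run$db, run$clusters,
                             run$db$species$sp_id[run$db$species$sp_source == "added"],
                             source_name = "geneweaver")
  rep <- dedupe_and_append(run$db, redo$pairs)
  expect_equal(rep$pairs_added, 0L)
  expect_equal(nrow(run$db$orthologs), before)
})

test_that("re-registering an existing species is a conflict; empty spec is a no-op", {
  run <- make_pipeline_db(seed = 43)
  expect_error(
    register_new_species(run$db, run$clusters,
                         data.frame(name = "Gallus gallus", taxon = 9031L)),
    "already registered"
  )
  before <- summary(run$db)
  out <- register_new_species(run$db, run$clusters,
                              data.frame(name = character(),
                                         taxon = integer()))
  expect_equal(out$new_species, 0L)
  expect_equal(summary(run$db), before)
})

test_that("augmentation adds the three missing species and matches ground truth", {
  run <- make_pipeline_db(seed = 47)
  db <- run$db; truth <- run$fx$gw$truth
  expect_equal(run$aug$new_species, 3L)
  expect_equal(sum(db$species$sp_source == "added"), 3L)
  expect_equal(run$aug$new_genes, truth$n_new_genes)
  expect_equal(run$aug$pairs_added, nrow(truth$expected_pairs))
  # the added pair set is exactly the generator's expected set
  added <- db$orthologs[db$orthologs$ort_source != "agr", ]
  got <- paste(db$genes$gn_ref_id[match(added$from_gene, db$genes$gn_id)],
               db$genes$gn_ref_id[match(added$to_gene, db$genes$gn_id)])
  expect_setequal(got, paste(truth$expected_pairs$from_ref,
                             truth$expected_pairs$to_ref))
})

test_that("every added pair touches an added species and resolves; canonical rows untouched", {
  run <- make_pipeline_db(seed = 53)
  db <- run$db
  canonical_before <- db$orthologs[db$orthologs$ort_source == "agr", ]

  added <- db$orthologs[db$orthologs$ort_source != "agr", ]
  expect_gt(nrow(added), 0L)
  sp_from <- db$genes$sp_id[match(added$from_gene, db$genes$gn_id)]
  sp_to <- db$genes$sp_id[match(added$to_gene, db$genes$gn_id)]
  added_sp <- db$species$sp_id[db$species$sp_source == "added"]
  expect_true(all(sp_from %in% added_sp | sp_to %in% added_sp)) # rule 1
  expect_false(anyNA(sp_from) || anyNA(sp_to))                  # rule 2
  expect_true(all(sp_from != sp_to))                            # rule 3
  # no unresolvable accession ever enters the gene table
  expect_false(any(run$fx$gw$truth$unresolvable %in% db$genes$gn_ref_id))

  # canonical rows unchanged by augmenting again on a fresh decomposition
  dec <- decompose_clusters(db, run$clusters, added_sp)
  dedupe_and_append(db, dec$pairs)
  expect_equal(db$orthologs[db$orthologs$ort_source == "agr", ],
               canonical_before)
})

test_that("unresolvable fraction zero means no unknown-gene skips", {
  spec <- fixture_spec(seed = 59, unresolvable_fraction = 0)
  run <- make_pipeline_db(spec = spec)
  expect_equal(run$aug$pairs_skipped_unknown_gene, 0L)
})

test_that("pair yield matches 2*(C(k,2) - C(k-m,2)) on random distinct-species clusters", {
  # brute-force enumerator vs closed form, 500 random clusters, k <= 8
  db <- toy_db(n_canonical = 8, n_added = 8, genes_per_species = 1)
  new_sp <- 9:16
  set.seed(271)
  for (trial in seq_len(500)) {
    k <- sample(2:8, 1)
    m <- sample(0:k, 1)
    # one gene per species: gene id == species id in toy_db with 1 gene each
    genes <- c(sample(new_sp, m), sample(1:8, k - m))
    dec <- decompose_clusters(db, toy_members(db, "t", genes), new_sp)
    expected <- 2 * (choose(k, 2) - choose(k - m, 2))
    expect_equal(nrow(dec$pairs), expected)
    # brute force: enumerate and filter
    brute <- 0L
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      if (genes[i] %in% new_sp || genes[j] %in% new_sp) brute <- brute + 2L
    }
    expect_equal(nrow(dec$pairs), brute)
  }
})
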