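# a small calibrated representative database over three planted families
fx_triage_db <- function() {
  memo("triagedb", {
    dec <- fx_decoys(seed = 17)
    fams <- lapply(1:3, function(i)
      make_family(family_spec(sprintf("TF%d", i), 4, 140, c(75, 90), 0.01,
                              seed = 51 + i)))
    profs <- lapply(fams, function(f)
      calibrate(build_profile(star_alignment(f[[1]], f[2:3]),
                              family_name = substr(f[[1]]$seq_id, 1, 3)),
                dec))
    list(db = profile_db(profs), fams = fams)
  })
}

test_that("triage categorises planted members, decoys and multi-hits", {
  tri <- fx_triage_db()
  # held-out member of each family picks exactly its own profile
  for (i in 1:3) {
    tr <- triage(tri$fams[[i]][[4]], tri$db, 1e-3)
    expect_equal(tr$category, "single")
    expect_equal(tr$families, sprintf("TF%d", i))
  }
  # 500 random decoys: at least 99% pick nothing
  rand <- make_dummy_db(500, seed = 888)
  cats <- vapply(rand, function(r) triage(r, tri$db, 1e-3)$category,
                 character(1))
  expect_gte(mean(cats == "none"), 0.99)
})

test_that("hits to several representatives of one family collapse to single", {
  tri <- fx_triage_db()
  f1 <- tri$fams[[1]]
  dec <- fx_decoys(seed = 17)
  # second representative for family TF1, anchored on another member
  p2 <- calibrate(build_profile(star_alignment(f1[[2]], f1[c(1, 3)]),
                                family_name = "TF1"), dec)
  p2$rep_id <- "rep2"
  db2 <- profile_db(c(tri$db$profiles, list(p2)))
  tr <- triage(f1[[4]], db2, 1e-3)
  expect_length(tr$hits, 2L)       # both representatives hit
  expect_equal(tr$category, "single")  # but one family
  expect_equal(tr$families, "TF1")
})

test_that("ternary detection distinguishes copies from distinct proteins", {
  a <- fx_narrow_family()[[1]]
  b <- make_dummy_db(1, length_range = c(150, 150), seed = 66)[[1]]
  homo <- complex_entry("HOMO", 2, chains = list(
    seq_record("HOMO_A", a$residues), seq_record("HOMO_B", a$residues)))
  expect_false(detect_ternary(homo))
  tern <- make_ternary(a, b, complex_id = "TERN")
  expect_true(detect_ternary(tern))
  # two copies plus one distinct chain
  mixed <- complex_entry("MIXD", 2, chains = list(
    seq_record("MIXD_A", a$residues), seq_record("MIXD_B", a$residues),
    seq_record("MIXD_C", b$residues)))
  expect_true(detect_ternary(mixed))
  expect_false(detect_ternary(complex_entry("SOLO", 2, chains = list(a))))
})

test_that("multi-profile pickers resolve by collapse, split or flagged call", {
  tri <- fx_triage_db()
  f1 <- tri$fams[[1]]; f2 <- tri$fams[[2]]
  # ternary with chains from two families: two clean assignments
  tern <- make_ternary(f1[[4]], f2[[4]], complex_id = "TRNX")
  tr <- triage_complex(tern, tri$db, 1e-3)
  expect_equal(tr$category, "multiple")
  rows <- resolve_multi(tern, tr, tri$db, 1e-3)
  expect_equal(nrow(rows), 2L)
  expect_setequal(rows$family, c("TF1", "TF2"))
  expect_true(all(rows$note == "ternary_split"))
  expect_false(any(rows$ambiguous))

  # same-family multi-hit collapses to one assignment
  fake <- structure(list(query_id = "q", category = "multiple",
                         families = "TF1",
                         hits = list(structure(list(
                           query_id = "q", family_name = "TF1",
                           bit_score = 50, e_value = 1e-9,
                           query_span = c(0L, 10L),
                           profile_span = c(0L, 10L)),
                           class = "search_hit"))),
                    class = "triage_result")
  one <- resolve_multi(complex_entry("QQQQ", 2, chains = f1[4]), fake,
                       tri$db, 1e-3)
  expect_equal(nrow(one), 1L)
  expect_equal(one$note, "collapsed")

  # non-ternary chain hitting two families: lowest E plus ambiguity flag
  chimera_res <- paste0(substr(f1[[1]]$residues, 1, 80),
                        substr(f2[[1]]$residues, 1, 80))
  chim <- complex_entry("CHIM", 2,
                        chains = list(seq_record("CHIM_A", chimera_res)))
  trc <- triage(chim$chains[[1]], tri$db, 1e-3)
  expect_equal(trc$category, "multiple")
  amb <- resolve_multi(chim, trc, tri$db, 1e-3)
  expect_equal(nrow(amb), 1L)
  expect_true(amb$ambiguous)
  expect_equal(amb$family, trc$hits[[1]]$family_name)
})

test_that("clustering finds planted families, loners and chained links", {
  dec <- fx_decoys(seed = 17)
  fams <- lapply(1:3, function(i)
    make_family(family_spec(sprintf("CU%d", i), 5, 130, c(75, 90), 0.01,
                            seed = 59 + i)))
  lone <- make_dummy_db(4, seed = 5959, prefix = "lone")
  pool <- c(unlist(fams, recursive = FALSE), lone)
  cs <- cluster_unassigned(pool, 1e-3, dec)
  expect_length(cs$clusters, 3L)
  expect_length(cs$loners, 4L)
  expect_true(all(lengths(cs$clusters) == 5L))
  for (cl in cs$clusters)
    expect_length(unique(substr(cl, 1, 3)), 1L)
  # partition: clusters and loners cover the input exactly once
  ids <- vapply(pool, `[[`, character(1), "seq_id")
  expect_setequal(c(unlist(cs$clusters), cs$loners), ids)

  # permutation invariance
  perm <- profam:::with_seed(4, sample(pool))
  cs2 <- cluster_unassigned(perm, 1e-3, dec)
  expect_identical(cs, cs2)

  # all mutually unrelated: all loners
  cs3 <- cluster_unassigned(lone, 1e-3, dec)
  expect_length(cs3$clusters, 0L)
  expect_length(cs3$loners, 4L)
})

test_that("single linkage joins a-b-c chains without a direct a-c edge", {
  dec <- fx_decoys(seed = 17)
  a <- make_ancestor(120, 7101, seq_id = "chn_a")
  c_ <- make_ancestor(120, 7103, seq_id = "chn_c")
  # b is a chimera of a's and c's halves: associated with both, a-c unrelated
  b <- seq_record("chn_b", paste0(substr(a$residues, 1, 60),
                                  substr(c_$residues, 61, 120)))
  expect_null(pairwise_association(a, c_, decoys = dec))
  expect_false(is.null(pairwise_association(a, b, decoys = dec)))
  expect_false(is.null(pairwise_association(b, c_, decoys = dec)))
  cs <- cluster_unassigned(list(a, b, c_), 1e-3, dec)
  expect_length(cs$clusters, 1L)
  expect_setequal(cs$clusters[[1]], c("chn_a", "chn_b", "chn_c"))
})

test_that("cluster promotion consumes annotations and validates groups", {
  cs <- structure(list(clusters = list(c("DDB1_A", "DDB2_A")),
                       loners = "LONE_A"),
                  class = "cluster_set")
  ann <- data.frame(
    member_id = c("DDB1_A", "DDB2_A", "LONE_A"),
    family_name = c("DDB1-DDB2", "DDB1-DDB2", "Loner LONE_A"),
    group_name = c("\u03b2-Propeller", "\u03b2-Propeller", "Other"),
    stringsAsFactors = FALSE)
  fams <- promote_clusters(cs, ann)
  expect_length(fams, 2L)
  expect_equal(fams[[1]]$name, "DDB1-DDB2")
  expect_equal(fams[[1]]$group_name, "\u03b2-Propeller")
  expect_equal(unname(fams[[1]]$member_provenance),
               rep("pairwise_association", 2))
  expect_equal(unname(fams[[2]]$member_provenance), "loner")
  expect_length(fams[[2]]$member_ids, 1L)

  expect_error(promote_clusters(cs, ann[-1, ]), "DDB1_A")
  bad <- ann; bad$group_name[1] <- "Spiral"
  expect_error(promote_clusters(cs, bad), "unknown group")
})

test_that("the pipeline recovers the planted benchmark truth", {
  bm <- fx_benchmark()
  cfg <- pf_config(rng_seed = 61)
  rep <- run_pipeline(bm$manifest, bm$sequences, bm$legacy, bm$annotations,
                      cfg)
  # triage categories partition the queries
  expect_equal(sum(rep$counts), rep$n_queries)
  expect_equal(rep$n_queries, length(bm$manifest))

  rr <- recovery_rate(rep, bm$truth)
  expect_gte(rr$rate, 0.95)

  # the ternary's chains land in two different families
  tern_ids <- vapply(bm$ternary_entries[[1]]$chains, `[[`, character(1),
                     "seq_id")
  tern_rows <- rep$assignments[rep$assignments$chain_id %in% tern_ids, ]
  expect_equal(nrow(tern_rows), 2L)
  expect_length(unique(tern_rows$family), 2L)
  expect_true(all(tern_rows$route == "ternary_split"))

  # every planted loner ends as a single-member family with loner provenance
  expect_setequal(rep$cluster_set$loners,
                  names(bm$truth)[bm$truth == "loner"])
  for (id in rep$cluster_set$loners) {
    fam <- NULL
    for (f in profam:::all_families(rep$updated))
      if (id %in% f$member_ids) fam <- f
    expect_false(is.null(fam))
    expect_length(fam$member_ids, 1L)
    expect_equal(unname(fam$member_provenance[id]), "loner")
  }
  expect_equal(rep$loner_count, 4L)
  validate_classification(rep$updated)
})

test_that("the pipeline is deterministic and inert on empty input", {
  bm <- fx_benchmark()
  cfg <- pf_config(rng_seed = 61)
  r1 <- run_pipeline(bm$manifest, bm$sequences, bm$legacy, bm$annotations,
                     cfg, reselect = FALSE)
  r2 <- run_pipeline(bm$manifest, bm$sequences, bm$legacy, bm$annotations,
                     cfg, reselect = FALSE)
  keep <- c("counts", "assignments", "cluster_set", "audit", "loner_count")
  expect_identical(r1[keep], r2[keep])

  r0 <- run_pipeline(list(), bm$sequences, bm$legacy, bm$annotations, cfg,
                     reselect = FALSE)
  expect_equal(sum(r0$counts), 0L)
  expect_equal(r0$loner_count, 0L)
  expect_equal(r0$updated$groups, bm$legacy$groups)
})

test_that("every input chain ends in exactly one destination", {
  bm <- fx_benchmark()
  rep <- run_pipeline(bm$manifest, bm$sequences, bm$legacy, bm$annotations,
                      pf_config(rng_seed = 61), reselect = FALSE)
  assigned <- rep$assignments$chain_id
  clustered <- unlist(rep$cluster_set$clusters)
  loners <- rep$cluster_set$loners
  all_out <- c(assigned, clustered, loners)
  expect_equal(anyDuplicated(all_out), 0L)
  # every kept query chain is accounted for
  kept <- filter_manifest(bm$manifest, pf_config())$kept
  expected_chains <- unlist(lapply(kept, function(e) {
    if (detect_ternary(e)) vapply(e$chains, `[[`, character(1), "seq_id")
    else e$chains[[1]]$seq_id
  }))
  expect_setequal(all_out, expected_chains)
})
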