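mk_reports <- function(family, picks, bits = NULL) {
  lapply(names(picks), function(id)
    coverage_report(id, family$name, length(family$member_ids), picks[[id]],
                    mean_bits = if (is.null(bits)) NA_real_ else bits[[id]]))
}

test_that("coverage reports obey the definition and its bounds", {
  f <- pf_family("F", "HTH", c("a", "b", "c", "d"))
  r_all <- coverage_report("a", "F", 4, c("a", "b", "c", "d"))
  expect_equal(r_all$coverage, 1.0)
  r_half <- coverage_report("a", "F", 4, c("a", "b"))
  expect_equal(r_half$coverage, 0.5)
  expect_equal(r_half$n_picking, 2L)
  expect_error(coverage_report("a", "F", 2, c("a", "b", "c")), "n_picking")
})

test_that("a single-member family covers itself through its own profile", {
  fam <- fx_narrow_family()[1]
  be <- fx_backend(fam)
  f <- pf_family("Solo", "HTH", names(fam))
  r <- coverage(names(fam), f, be)
  expect_equal(r$coverage, 1.0)
  expect_equal(r$picking_ids, names(fam))
  expect_error(coverage("ghost", f, be), "not a member")
})

test_that("jackknife gives every member of a tight family full coverage", {
  fam <- fx_narrow_family()
  be <- fx_backend(fam)
  f <- pf_family("NF", "HTH", names(fam))
  reports <- jackknife(f, be)
  expect_length(reports, length(fam))
  expect_equal(vapply(reports, `[[`, character(1), "candidate_id"),
               sort(names(fam)))
  expect_true(all(vapply(reports, `[[`, numeric(1), "coverage") == 1))
  expect_length(attr(reports, "errors"), 0L)
  expect_error(jackknife(pf_family("One", "HTH", "x"), be), "size >= 2")
})

test_that("in a two-cluster family candidates cover only their cluster", {
  seqs <- fx_two_cluster_family()
  be <- fx_backend(seqs)
  f <- pf_family("MIX", "HTH", names(seqs))
  reports <- jackknife(f, be)
  for (r in reports) {
    own <- substr(r$candidate_id, 1, 2)
    expect_equal(r$coverage, 0.5, info = r$candidate_id)
    expect_true(all(startsWith(r$picking_ids, own)))
  }
  # greedy combination needs exactly two representatives for full coverage
  rs <- select_combination(f, reports)
  expect_length(rs$representative_ids, 2L)
  expect_equal(rs$combined_coverage, 1.0)
  expect_setequal(substr(rs$representative_ids, 1, 2), c("CA", "CB"))
  # exhaustive check: no single member reaches full coverage
  expect_true(all(vapply(reports, `[[`, numeric(1), "coverage") < 1))
})

test_that("greedy combination is minimal and flags unreachable members", {
  f <- pf_family("F", "HTH", c("a", "b", "c", "d", "e"))
  # one candidate already covers everything: singleton set
  rs <- select_combination(f, mk_reports(f, list(
    a = c("a", "b", "c", "d", "e"), b = c("a", "b"))))
  expect_equal(rs$representative_ids, "a")
  expect_equal(rs$combined_coverage, 1.0)

  # no candidate set reaches 'e': flagged incomplete, no zero-gain members
  rs2 <- select_combination(f, mk_reports(f, list(
    a = c("a", "b"), b = c("b", "c", "d"), c = c("c", "d"))))
  expect_lt(rs2$combined_coverage, 1.0)
  expect_false(rs2$complete)
  expect_setequal(rs2$representative_ids, c("a", "b"))  # c adds nothing

  # ties broken by mean bit score, then lexicographic id
  rs3 <- select_combination(f, mk_reports(f,
    list(a = c("a", "b"), b = c("c", "d")),
    bits = list(a = 10, b = 50)))
  expect_equal(rs3$representative_ids[1], "b")
  rs4 <- select_combination(f, mk_reports(f,
    list(z = c("a", "b"), b = c("c", "d")),
    bits = list(z = 10, b = 10)))
  expect_equal(rs4$representative_ids[1], "b")
})

test_that("strategy dispatch is a pure function of size and spread", {
  cfg <- pf_config()
  expect_equal(dispatch_strategy(1, NA, cfg), "self")
  expect_equal(dispatch_strategy(2, "wide", cfg), "two_member_trial")
  expect_equal(dispatch_strategy(2, "narrow", cfg), "two_member_trial")
  expect_equal(dispatch_strategy(10, "narrow", cfg), "any_one_narrow")
  expect_equal(dispatch_strategy(10, "wide", cfg), "jackknife")
  expect_equal(dispatch_strategy(49, "wide", cfg), "jackknife")
  expect_equal(dispatch_strategy(50, "wide", cfg), "cluster_seeds")
  expect_equal(dispatch_strategy(60, "wide", cfg), "cluster_seeds")
  cfg2 <- pf_config(jackknife_size_limit = 10)
  expect_equal(dispatch_strategy(10, "wide", cfg2), "cluster_seeds")
})

test_that("selection handles one-, two- and multi-member families", {
  fam <- fx_narrow_family()
  be <- fx_backend(fam)
  # single member: itself, strategy self
  rs1 <- select_representatives(pf_family("S", "HTH", names(fam)[1]), be)
  expect_equal(rs1$strategy, "self")
  expect_equal(rs1$representative_ids, names(fam)[1])
  expect_equal(rs1$combined_coverage, 1.0)

  # two members, both cover: lexicographically first kept
  rs2 <- select_representatives(pf_family("P", "HTH", names(fam)[1:2]), be)
  expect_equal(rs2$strategy, "two_member_trial")
  expect_equal(rs2$representative_ids, sort(names(fam)[1:2])[1])
  expect_equal(rs2$combined_coverage, 1.0)

  # narrow multi-member family: any one member suffices
  rs3 <- select_representatives(pf_family("NF", "HTH", names(fam)), be)
  expect_equal(rs3$strategy, "any_one_narrow")
  expect_equal(rs3$combined_coverage, 1.0)
  expect_length(rs3$representative_ids, 1L)
})

test_that("a large wide family goes through clustering to full coverage", {
  fa <- make_family(family_spec("LA", 30, 150, c(75, 90), 0.01, seed = 43))
  fb <- make_family(family_spec("LB", 30, 150, c(75, 90), 0.01, seed = 44))
  seqs <- setNames(c(fa, fb),
                   vapply(c(fa, fb), `[[`, character(1), "seq_id"))
  be <- search_backend(seqs, fx_decoys(seed = 1), pf_config())
  f <- pf_family("BIG", "HTH", names(seqs))
  rs <- select_representatives(f, be, pf_config())
  expect_equal(rs$strategy, "cluster_seeds")
  expect_equal(rs$combined_coverage, 1.0)
  expect_length(rs$representative_ids, 2L)
  expect_setequal(substr(rs$representative_ids, 1, 2), c("LA", "LB"))
})

test_that("dummy-database validation confirms clean representatives", {
  fam <- fx_narrow_family()
  be <- fx_backend(fam)
  f <- pf_family("NF", "HTH", names(fam))
  rs <- select_representatives(f, be)
  dummy <- make_dummy_db(5, seed = 202, families = fam[1],
                         prefix = "unrelated")
  out <- validate_with_dummy(rs, f, dummy, be)
  expect_true(out$dummy_validated)
  expect_equal(attr(out, "dummy_coverage"), 1.0)
  expect_error(validate_with_dummy(rs, f, list(), be), "empty")

  # adversarial dummy set containing family copies is recorded, not hidden
  adv <- fam[2]
  adv[[1]]$seq_id <- "adv_copy"
  out2 <- validate_with_dummy(rs, f, unname(adv), be)
  expect_true(out2$dummy_validated %in% c(TRUE, FALSE))
  expect_false(is.null(attr(out2, "dummy_coverage")))
})

test_that("old representatives are retained only while they still cover", {
  fam <- make_family(family_spec("GR", 4, 150, c(85, 95), 0.005, seed = 47))
  grown <- c(fam, lapply(1:3, function(i)
    evolve_member(fam[[1]], 90, 0.005, seed = 470 + i,
                  seq_id = sprintf("GR_new%02d", i))))
  seqs <- setNames(grown, vapply(grown, `[[`, character(1), "seq_id"))
  be <- search_backend(seqs, fx_decoys(seed = 1), pf_config())
  f <- pf_family("GR", "HTH", names(seqs))
  rs <- retain_or_replace("GR_m01", f, be)
  expect_equal(attr(rs, "note"), "retained")
  expect_equal(rs$representative_ids, "GR_m01")
  expect_equal(rs$combined_coverage, 1.0)

  # a divergent clade breaks the old representative: reselected
  clade <- make_family(family_spec("CL", 3, 150, c(80, 90), 0.01, seed = 48))
  seqs2 <- c(seqs, setNames(clade, vapply(clade, `[[`, character(1),
                                          "seq_id")))
  be2 <- search_backend(seqs2, fx_decoys(seed = 1), pf_config())
  f2 <- pf_family("GR", "HTH", names(seqs2))
  rs2 <- retain_or_replace("GR_m01", f2, be2)
  expect_equal(attr(rs2, "note"), "reselected")
  expect_gt(length(rs2$representative_ids), 1L)
  expect_equal(rs2$combined_coverage, 1.0)

  # empty old set: fresh selection
  rs3 <- retain_or_replace(character(), f, be)
  expect_equal(attr(rs3, "note"), "reselected")
  expect_equal(rs3$combined_coverage, 1.0)
})

test_that("coverage is non-increasing under a more stringent cutoff", {
  seqs <- fx_two_cluster_family()
  be <- fx_backend(seqs)
  f <- pf_family("MIX", "HTH", names(seqs))
  for (id in names(seqs)[c(1, 4)]) {
    loose <- coverage(id, f, be, cutoff = 1e-3)
    tight <- coverage(id, f, be, cutoff = 1e-30)
    expect_lte(tight$coverage, loose$coverage)
    expect_true(all(tight$picking_ids %in% loose$picking_ids))
  }
})
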