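uniform_bg <- setNames(rep(0.05, 20), profam:::AA20)

test_that("single-column profiles match the closed-form log-odds", {
  aln <- matrix("G", nrow = 10, ncol = 1,
                dimnames = list(paste0("s", 1:10), NULL))
  p <- build_profile(aln, background = uniform_bg, pseudocount_weight = 0)
  expect_equal(unname(p$scores[1, "G"]), log2(1 / 0.05), tolerance = 1e-12)
  expect_equal(unname(p$scores[1, "G"]), 4.3219, tolerance = 1e-4)

  # observed frequencies equal to background give all-zero scores
  aln2 <- matrix(profam:::AA20, nrow = 20, ncol = 1,
                 dimnames = list(paste0("s", 1:20), NULL))
  p2 <- build_profile(aln2, background = uniform_bg, pseudocount_weight = 0)
  expect_equal(unname(p2$scores[1, ]), rep(0, 20), tolerance = 1e-12)
  # pseudocount mixing with f_obs == background is also the identity
  p3 <- build_profile(aln2, background = uniform_bg, pseudocount_weight = 10)
  expect_equal(unname(p3$scores[1, ]), rep(0, 20), tolerance = 1e-12)
})

test_that("adding an observation of a residue never decreases its score", {
  set.seed(3)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    col <- sample(profam:::AA20, n, replace = TRUE)
    before <- build_profile(
      matrix(col, ncol = 1, dimnames = list(paste0("s", seq_len(n)), NULL)),
      pseudocount_weight = sample(c(0, 5, 10), 1))
    after <- build_profile(
      matrix(c(col, "G"), ncol = 1,
             dimnames = list(paste0("s", seq_len(n + 1)), NULL)),
      pseudocount_weight = before$pseudocount_weight)
    expect_gte(after$scores[1, "G"], before$scores[1, "G"] - 1e-9)
  }
})

test_that("profile build is deterministic and drops all-gap columns", {
  fam <- fx_narrow_family()
  aln <- star_alignment(fam[[1]], fam[-1])
  p1 <- build_profile(aln, family_name = "NF")
  p2 <- build_profile(aln, family_name = "NF")
  expect_identical(p1$scores, p2$scores)

  gappy <- rbind(c("A", "-", "C"), c("A", "-", "C"))
  rownames(gappy) <- c("x", "y")
  expect_warning(pg <- build_profile(gappy), "all-gap")
  expect_equal(pg$length, 2L)
  expect_true(all(is.finite(pg$scores)))
})

test_that("calibration fits a usable tail and scales linearly in n", {
  fam <- fx_narrow_family()
  p0 <- build_profile(fam[[1]], family_name = "NF")
  expect_error(calibrate(p0, fx_decoys(50, seed = 5), min_decoys = 100),
               "at least 100")
  p <- calibrate(p0, fx_decoys(200, seed = 17))
  expect_gt(p$lambda, 0)
  expect_gt(p$K, 0)
  # doubling the database size doubles the E-value at fixed score
  expect_equal(e_value(p, 30, n = 2 * p$decoy_db_size),
               2 * e_value(p, 30, n = p$decoy_db_size))
  # reproducible under an identical decoy set
  p2 <- calibrate(p0, fx_decoys(200, seed = 17))
  expect_identical(c(p$lambda, p$K), c(p2$lambda, p2$K))
  # degenerate input is refused with advice
  const <- lapply(1:120, function(i) seq_record(paste0("c", i),
                                                strrep("A", 50)))
  expect_error(calibrate(p0, const), "degenerate")
})

test_that("calibrated E-values average about one E<=1 hit per decoy scan", {
  fam <- fx_narrow_family()
  p <- calibrate(build_profile(fam[[1]], family_name = "NF"),
                 fx_decoys(200, seed = 17))
  counts <- vapply(1:10, function(i) {
    scan <- make_dummy_db(200, seed = 17000 + i)
    enc <- profam:::encode_set(scan)
    ev <- e_value(p, profam:::profile_scores(p, enc), n = sum(lengths(enc)))
    sum(ev <= 1)
  }, numeric(1))
  expect_gte(mean(counts), 1 / 3)
  expect_lte(mean(counts), 3)
})

test_that("E-values decrease strictly as bit scores increase", {
  fam <- fx_narrow_family()
  p <- calibrate(build_profile(fam[[1]], family_name = "NF"),
                 fx_decoys(seed = 17))
  s <- seq(5, 80, by = 5)
  ev <- e_value(p, s)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev > 0))
})

test_that("profile-local scores equal brute-force enumeration on tiny instances", {
  set.seed(99)
  for (k in 1:12) {
    m <- sample(2:6, 1)
    aln <- matrix(sample(profam:::AA20, 3 * m, replace = TRUE), nrow = 3,
                  dimnames = list(paste0("s", 1:3), NULL))
    p <- build_profile(aln)
    s <- random_protein(sample(2:6, 1), seed = 700 + k)
    got <- profam:::pssm_local_align_cpp(p$scores, profam:::encode_residues(s),
                                         p$gap_open, p$gap_extend)
    expect_equal(got$score, bf_profile_local_score(p$scores, s),
                 info = paste("case", k))
  }
})

test_that("the seed consensus outscores shuffles of itself", {
  fam <- fx_narrow_family()
  aln <- star_alignment(fam[[1]], fam[-1])
  p <- calibrate(build_profile(aln, family_name = "NF"), fx_decoys(seed = 17))
  cons <- p$consensus
  h <- score_sequence(p, seq_record("cons", cons))
  shuffles <- profam:::with_seed(7, vapply(1:100, function(i)
    paste(sample(strsplit(cons, "")[[1]]), collapse = ""), character(1)))
  enc <- profam:::encode_set(lapply(seq_along(shuffles), function(i)
    seq_record(paste0("sh", i), shuffles[i])))
  expect_true(all(h$bit_score >= profam:::profile_scores(p, enc)))
})

test_that("unrelated sequences rarely reach the assignment cutoff", {
  fam <- fx_narrow_family()
  p <- calibrate(build_profile(fam[[1]], family_name = "NF"),
                 fx_decoys(seed = 17))
  rand <- make_dummy_db(500, seed = 4242)
  enc <- profam:::encode_set(rand)
  ev <- e_value(p, profam:::profile_scores(p, enc))
  expect_gte(mean(ev > 1e-3), 0.99)
})

test_that("search hits carry spans inside the query and profile", {
  fam <- fx_narrow_family()
  p <- calibrate(build_profile(fam[[1]], family_name = "NF"),
                 fx_decoys(seed = 17))
  h <- score_sequence(p, fam[[2]])
  expect_s3_class(h, "search_hit")
  expect_true(h$e_value > 0)
  expect_true(h$query_span[1] >= 0 &&
              h$query_span[2] <= nchar(fam[[2]]$residues))
  expect_true(h$profile_span[1] >= 0 && h$profile_span[2] <= p$length)
  expect_lt(h$query_span[1], h$query_span[2])
  expect_error(score_sequence(p, ""), "length")
})

test_that("profile iteration reaches a fixed point and absorbs the family", {
  fam <- fx_narrow_family()
  dec <- fx_decoys(seed = 17)
  p0 <- calibrate(build_profile(fam[[1]], family_name = "NF"), dec)

  # empty corpus: unchanged
  p_id <- iterate_profile(p0, list(), decoys = dec)
  expect_identical(p_id$scores, p0$scores)

  # corpus with no possible hits at an impossible cutoff: fixed point
  p_fix <- iterate_profile(p0, unname(fam[-1]), inclusion_evalue = 0,
                           decoys = dec)
  expect_identical(p_fix$scores, p0$scores)
  expect_length(attr(p_fix, "included_ids"), 0L)

  # corpus = the family itself: converges with all members included
  p_all <- iterate_profile(p0, unname(fam[-1]), inclusion_evalue = 1e-10,
                           max_iter = 20, decoys = dec)
  expect_setequal(attr(p_all, "included_ids"),
                  names(fam)[-1])
  expect_lte(attr(p_all, "iterations"), 20L)
  # unrelated decoys are not absorbed
  p_dec <- iterate_profile(p0, make_dummy_db(20, seed = 55),
                           inclusion_evalue = 1e-10, decoys = dec)
  expect_length(attr(p_dec, "included_ids"), 0L)
})

test_that("profile database search sorts and filters deterministically", {
  expect_equal(search_profile_db(fx_narrow_family()[[1]], profile_db()), list())

  dec <- fx_decoys(seed = 17)
  fams <- lapply(1:6, function(i)
    make_family(family_spec(sprintf("DB%02d", i), 3, 120, c(75, 90), 0.01,
                            seed = 23 + i)))
  profs <- lapply(fams, function(f)
    calibrate(build_profile(star_alignment(f[[1]], f[-1]),
                            family_name = f[[1]]$seq_id), dec))
  db <- profile_db(profs)
  # a member of a planted family finds its own family first
  for (k in c(1, 4, 6)) {
    hits <- search_profile_db(fams[[k]][[2]], db, cutoff = 1e-3)
    expect_gt(length(hits), 0)
    expect_equal(hits[[1]]$family_name, fams[[k]][[1]]$seq_id)
  }
  # insertion order does not change the result
  db_rev <- profile_db(rev(profs))
  h1 <- search_profile_db(fams[[2]][[2]], db, 1e-3)
  h2 <- search_profile_db(fams[[2]][[2]], db_rev, 1e-3)
  expect_identical(lapply(h1, `[[`, "family_name"),
                   lapply(h2, `[[`, "family_name"))
  # two copies of one profile under different names: both reported, sorted
  twin <- profs[[1]]; twin$family_name <- "AA_twin"
  db_tw <- profile_db(list(profs[[1]], twin))
  ht <- search_profile_db(fams[[1]][[2]], db_tw, 1e-3)
  expect_equal(vapply(ht, `[[`, character(1), "family_name"),
               c("AA_twin", "DB01_m01"))
})

test_that("pairwise association is symmetric and rejects unrelated pairs", {
  dec <- fx_decoys(seed = 17)
  fam <- fx_narrow_family()
  # identical sequences associate with essentially the smallest E
  self <- pairwise_association(fam[[1]], fam[[1]], decoys = dec)
  expect_false(is.null(self))
  other <- pairwise_association(fam[[1]], fam[[2]], decoys = dec)
  expect_lte(self$e_value, other$e_value)

  # symmetry of the decision and of the reported E-value
  cache <- new.env()
  ab <- pairwise_association(fam[[1]], fam[[3]], decoys = dec, cache = cache)
  ba <- pairwise_association(fam[[3]], fam[[1]], decoys = dec, cache = cache)
  expect_equal(ab$e_value, ba$e_value)

  # unrelated 150-mers associate in under 1% of pairs
  rand <- make_dummy_db(40, length_range = c(150, 150), seed = 29)
  cache2 <- new.env()
  n_assoc <- 0L; n_pairs <- 0L
  for (i in 1:39) for (j in (i + 1):40) {
    n_pairs <- n_pairs + 1L
    if (!is.null(pairwise_association(rand[[i]], rand[[j]], decoys = dec,
                                      cache = cache2)))
      n_assoc <- n_assoc + 1L
  }
  expect_gte(n_pairs, 500L)
  expect_lte(n_assoc / n_pairs, 0.01)
})

test_that("search hits export to the tabular text convention", {
  fam <- fx_narrow_family()
  p <- calibrate(build_profile(fam[[1]], family_name = "NF"),
                 fx_decoys(seed = 17))
  hits <- search_profile_db(fam[[2]], profile_db(list(p)), cutoff = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(hits))
  expect_equal(tab$family[1], "NF")
  expect_true(all(tab$query_end > tab$query_start))
  write_hits_tsv(list(), path)
  expect_equal(nrow(read.delim(path)), 0L)
})

test_that("profiles and profile databases round-trip through text", {
  fam <- fx_narrow_family()
  p <- calibrate(build_profile(star_alignment(fam[[1]], fam[-1]),
                               family_name = "NF"), fx_decoys(seed = 17))
  path <- withr::local_tempfile(fileext = ".pssm")
  write_profile(p, path)
  q <- read_profile(path)
  expect_equal(q$scores, p$scores)
  expect_equal(q$lambda, p$lambda)
  expect_equal(q$K, p$K)
  expect_equal(q$master, p$master)
  expect_equal(q$seed_member_ids, p$seed_member_ids)

  dir <- withr::local_tempdir()
  p2 <- p; p2$family_name <- "NF2"
  write_profile_db(profile_db(list(p, p2)), dir)
  db <- read_profile_db(dir)
  expect_setequal(names(db$profiles), c("NF", "NF2"))
  expect_equal(db$profiles[["NF"]]$scores, p$scores)
})
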