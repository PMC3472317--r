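#' Create a profile-search backend
#'
#' Bundles the sequence universe, the calibration decoy set and the
#' configuration, and caches candidate profiles so repeated coverage
#' evaluations (jack-knifing) never rebuild the same profile twice.
#'
#' A candidate's profile is grown from the candidate's own sequence by
#' iterative inclusion over its family corpus at the stringent inclusion
#' E-value (default 1e-10, at most 20 iterations), then used to count which
#' family members pick it at the assignment cutoff.
#'
#' @param sequences Named list of [seq_record()]s (must contain every family
#'   member referenced later).
#' @param decoys List of unrelated decoy [seq_record()]s used for E-value
#'   calibration (>= 100).
#' @param config A [pf_config()].
#' @return A `search_backend` environment.
#' @export
search_backend <- function(sequences, decoys, config = pf_config()) {
  if (is.null(names(sequences)))
    names(sequences) <- vapply(sequences, seq_id_of, character(1))
  be <- new.env(parent = emptyenv())
  be$seqs <- sequences
  be$decoys <- decoys
  be$decoys_enc <- encode_set(decoys)
  be$config <- config
  be$params <- align_params()
  be$cache <- new.env(parent = emptyenv())
  be$pair_cache <- new.env(parent = emptyenv())
  class(be) <- c("search_backend", "environment")
  be
}

backend_records <- function(backend, ids) {
  missing <- setdiff(ids, names(backend$seqs))
  if (length(missing) > 0L)
    stop("sequences not known to backend: ", paste(missing, collapse = ", "))
  backend$seqs[ids]
}

# candidate profile for coverage: single-sequence jump start, iterated over
# the family corpus; cached by candidate id + member set
backend_candidate_profile <- function(backend, candidate_id, family) {
  key <- paste0(candidate_id, "|", paste(sort(family$member_ids), collapse = ","))
  if (!is.null(backend$cache[[key]])) return(backend$cache[[key]])
  cfg <- backend$config
  cand <- backend_records(backend, candidate_id)[[1]]
  corpus <- backend_records(backend, setdiff(family$member_ids, candidate_id))
  p <- tryCatch({
    p0 <- calibrate(build_profile(cand, family_name = family$name),
                    backend$decoys_enc)
    iterate_profile(p0, unname(corpus),
                    inclusion_evalue = cfg$profile_inclusion_evalue,
                    max_iter = cfg$max_profile_iterations,
                    decoys = backend$decoys_enc, params = backend$params)
  }, error = function(e)
    stop("profile build failed for candidate ", candidate_id, ": ",
         conditionMessage(e)))
  backend$cache[[key]] <- p
  p
}

# representative profile for the searchable database: jump start from the
# full-family star alignment anchored on the representative
backend_family_profile <- function(backend, rep_id, family,
                                   corpus = NULL) {
  key <- paste0("famdb|", rep_id, "|",
                paste(sort(family$member_ids), collapse = ","))
  if (!is.null(backend$cache[[key]])) return(backend$cache[[key]])
  cfg <- backend$config
  seed <- backend_records(backend, rep_id)[[1]]
  others <- backend_records(backend, setdiff(family$member_ids, rep_id))
  aln <- star_alignment(seed, unname(others), backend$params)
  p <- calibrate(build_profile(aln, family_name = family$name),
                 backend$decoys_enc)
  p$rep_id <- rep_id
  if (!is.null(corpus))
    p <- iterate_profile(p, corpus,
                         inclusion_evalue = cfg$profile_inclusion_evalue,
                         max_iter = cfg$max_profile_iterations,
                         decoys = backend$decoys_enc, params = backend$params)
  backend$cache[[key]] <- p
  p
}

#' Coverage of a candidate representative over its family
#'
#' The fraction of family members whose search against the candidate's
#' profile scores at or below the E-value cutoff (the candidate counts
#' itself when it hits its own profile): `coverage = n_picking / n_members`.
#'
#' @param candidate_id Member id of the candidate (must belong to the
#'   family).
#' @param family A [pf_family()].
#' @param backend A [search_backend()].
#' @param cutoff E-value cutoff (default: the backend's assignment E-value).
#' @return A `coverage_report`: `candidate_id`, `family_name`, `n_members`,
#'   `n_picking`, `coverage`, `picking_ids`, `mean_bits`.
#' @export
coverage <- function(candidate_id, family, backend,
                     cutoff = backend$config$assignment_evalue) {
  if (!candidate_id %in% family$member_ids)
    stop(candidate_id, " is not a member of family ", family$name)
  p <- backend_candidate_profile(backend, candidate_id, family)
  members <- backend_records(backend, family$member_ids)
  enc <- encode_set(members)
  sc <- profile_scores(p, enc)
  ev <- e_value(p, sc)
  picking <- family$member_ids[ev <= cutoff]
  coverage_report(candidate_id, family$name,
                  n_members = length(family$member_ids),
                  picking_ids = picking, mean_bits = mean(sc))
}

#' Construct a coverage report
#'
#' @param candidate_id,family_name Identifiers.
#' @param n_members Family size (denominator).
#' @param picking_ids Member ids that pick the candidate's profile
#'   (numerator is their count).
#' @param mean_bits Mean bit score of the family members against the
#'   candidate's profile (used for deterministic tie-breaking).
#' @return A `coverage_report`.
#' @export
coverage_report <- function(candidate_id, family_name, n_members,
                            picking_ids, mean_bits = NA_real_) {
  n_picking <- length(picking_ids)
  stopifnot(n_picking >= 0L, n_picking <= n_members)
  structure(list(candidate_id = candidate_id, family_name = family_name,
                 n_members = as.integer(n_members),
                 n_picking = as.integer(n_picking),
                 coverage = n_picking / n_members,
                 picking_ids = sort(picking_ids),
                 mean_bits = mean_bits),
            class = "coverage_report")
}

#' Jack-knife coverage evaluation of a family
#'
#' Gives every member an equal chance to act as the representative: each in
#' turn gets its own profile and is scored by its coverage of the family.
#' Per-candidate failures are recorded and do not abort the remaining
#' candidates.
#'
#' @param family A [pf_family()] with at least 2 members.
#' @param backend A [search_backend()].
#' @param cutoff E-value cutoff.
#' @return List of `coverage_report`s ordered by member id, with attribute
#'   `errors` (named list of failure messages, possibly empty).
#' @export
jackknife <- function(family, backend,
                      cutoff = backend$config$assignment_evalue) {
  if (length(family$member_ids) < 2L)
    stop("jackknife requires a family of size >= 2")
  errors <- list()
  reports <- list()
  for (id in sort(family$member_ids)) {
    r <- tryCatch(coverage(id, family, backend, cutoff),
                  error = function(e) conditionMessage(e))
    if (inherits(r, "coverage_report")) reports[[id]] <- r
    else errors[[id]] <- r
  }
  structure(unname(reports), errors = errors)
}

#' Greedy combination of representatives for full coverage
#'
#' Greedy set cover over the jack-knife pick sets: repeatedly add the
#' candidate covering the most still-uncovered members until combined
#' coverage reaches 1.0 or no candidate adds coverage. Ties are broken by
#' higher mean bit score, then lexicographic candidate id. The returned set
#' never contains a candidate that added zero coverage.
#'
#' @param family A [pf_family()].
#' @param reports List of `coverage_report`s (one per candidate).
#' @param strategy Strategy label recorded on the result.
#' @return A `representative_set`: `family_name`, `representative_ids`,
#'   `combined_coverage`, `strategy`, `covered_ids`, `complete` flag.
#' @export
select_combination <- function(family, reports, strategy = "jackknife") {
  members <- family$member_ids
  pool <- reports
  chosen <- character()
  covered <- character()
  while (length(covered) < length(members) && length(pool) > 0L) {
    gain <- vapply(pool, function(r)
      length(setdiff(r$picking_ids, covered)), integer(1))
    if (max(gain) == 0L) break
    bits <- vapply(pool, function(r) r$mean_bits %||% NA_real_, numeric(1))
    ids <- vapply(pool, `[[`, character(1), "candidate_id")
    ord <- order(-gain, -ifelse(is.na(bits), -Inf, bits), ids)
    best <- pool[[ord[1]]]
    chosen <- c(chosen, best$candidate_id)
    covered <- union(covered, best$picking_ids)
    pool <- pool[ids != best$candidate_id]
  }
  representative_set(family$name, chosen, members, covered, strategy)
}

#' Construct a representative set
#'
#' @param family_name Family name.
#' @param representative_ids Chosen representatives.
#' @param member_ids All family members.
#' @param covered_ids Union of members picking any representative's profile.
#' @param strategy One of `"self"`, `"two_member_trial"`,
#'   `"any_one_narrow"`, `"jackknife"`, `"cluster_seeds"`, `"retained"`.
#' @param dummy_validated Dummy-database validation flag (`NA` until
#'   [validate_with_dummy()] runs).
#' @return A `representative_set`.
#' @export
representative_set <- function(family_name, representative_ids, member_ids,
                               covered_ids, strategy,
                               dummy_validated = NA) {
  if (length(representative_ids) == 0L)
    stop("representative set for ", family_name, " is empty")
  cc <- length(intersect(covered_ids, member_ids)) / length(member_ids)
  structure(list(family_name = family_name,
                 representative_ids = representative_ids,
                 combined_coverage = cc,
                 strategy = strategy,
                 covered_ids = sort(intersect(covered_ids, member_ids)),
                 complete = isTRUE(all.equal(cc, 1)),
                 dummy_validated = dummy_validated),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("<representative_set %s: [%s], coverage %.0f%%, strategy %s>\n",
              x$family_name, paste(x$representative_ids, collapse = ", "),
              100 * x$combined_coverage, x$strategy))
  invisible(x)
}

#' Strategy dispatch for representative selection
#'
#' Pure function of family size, spread call and configuration: size 1 ->
#' `self`; size 2 -> `two_member_trial`; multi-member narrow ->
#' `any_one_narrow`; multi-member wide below the jack-knife size limit ->
#' `jackknife`; at or above the limit -> `cluster_seeds`.
#'
#' @param n_members Family size.
#' @param spread_call `"narrow"`, `"wide"` or `NA` (only used for
#'   multi-member families).
#' @param config A [pf_config()].
#' @return Strategy label.
#' @export
dispatch_strategy <- function(n_members, spread_call, config = pf_config()) {
  if (n_members == 1L) return("self")
  if (n_members == 2L) return("two_member_trial")
  if (identical(spread_call, "narrow")) return("any_one_narrow")
  if (n_members < config$jackknife_size_limit) return("jackknife")
  "cluster_seeds"
}

#' Select representatives for a family
#'
#' Implements the selection decision tree. Single-member families represent
#' themselves. In two-member families both members are trialled and one with
#' full coverage is kept (lexicographically first on ties). Multi-member
#' families with a narrow identity spread trial the lexicographically first
#' member and accept it at full coverage, falling back to jack-knifing
#' otherwise. Wide families below the size limit are jack-knifed and
#' combined greedily; at or above the limit the family is clustered first
#' and cluster seeds (the member with the highest within-cluster mean
#' identity) are assessed singly and in combination, extending greedily over
#' any still-uncovered members.
#'
#' @param family A [pf_family()].
#' @param backend A [search_backend()].
#' @param config A [pf_config()].
#' @param identity_matrix Optional precomputed [percent_identity_matrix()].
#' @param cutoff Coverage E-value cutoff.
#' @return A `representative_set`.
#' @export
select_representatives <- function(family, backend, config = pf_config(),
                                   identity_matrix = NULL,
                                   cutoff = config$assignment_evalue) {
  members <- sort(family$member_ids)
  n <- length(members)
  if (n == 1L)
    return(representative_set(family$name, members, members, members, "self"))

  if (n == 2L) {
    reps <- lapply(members, coverage, family = family, backend = backend,
                   cutoff = cutoff)
    full <- vapply(reps, function(r) r$coverage == 1, logical(1))
    if (any(full)) {
      best <- reps[full][[1]]  # members sorted: lexicographically first wins
      return(representative_set(family$name, best$candidate_id, members,
                                best$picking_ids, "two_member_trial"))
    }
    return(select_combination(family, reps, strategy = "two_member_trial"))
  }

  if (is.null(identity_matrix))
    identity_matrix <-
      percent_identity_matrix(backend_records(backend, members),
                              backend$params)
  spread <- classify_spread(identity_matrix, config$spread_threshold)
  strategy <- dispatch_strategy(n, spread$call, config)

  if (strategy == "any_one_narrow") {
    r <- coverage(members[1], family, backend, cutoff)
    if (r$coverage == 1)
      return(representative_set(family$name, r$candidate_id, members,
                                r$picking_ids, "any_one_narrow"))
    strategy <- "jackknife"  # narrow shortcut failed; fall through
  }

  if (strategy == "jackknife") {
    reports <- jackknife(family, backend, cutoff)
    return(select_combination(family, reports, strategy = "jackknife"))
  }

  # cluster_seeds: cluster members, pick one seed per cluster, assess seeds
  # singly and in combination, then extend over uncovered members
  cs <- cluster_unassigned(backend_records(backend, members),
                           cutoff = config$cluster_evalue,
                           decoys = backend$decoys_enc,
                           cache = backend$pair_cache)
  seeds <- vapply(cs$clusters, function(cl) {
    v <- identity_matrix$values[cl, cl, drop = FALSE]
    mean_id <- (rowSums(v) - 100) / pmax(length(cl) - 1L, 1L)
    cl[order(-mean_id, cl)][1]
  }, character(1))
  seeds <- sort(unique(c(seeds, cs$loners)))
  reports <- lapply(seeds, coverage, family = family, backend = backend,
                    cutoff = cutoff)
  rs <- select_combination(family, reports, strategy = "cluster_seeds")
  uncovered <- setdiff(members, rs$covered_ids)
  while (length(uncovered) > 0L) {
    extra <- coverage(sort(uncovered)[1], family, backend, cutoff)
    reports <- c(reports, list(extra))
    rs <- select_combination(family, reports, strategy = "cluster_seeds")
    still <- setdiff(members, rs$covered_ids)
    if (length(still) == length(uncovered)) break
    uncovered <- still
  }
  rs
}

#' Validate a representative set against a dummy database
#'
#' Rebuilds each representative's profile with the dummy database of
#' completely unrelated sequences as the iteration background and re-counts
#' the combined family coverage: the set is validated when coverage stays at
#' 100%, showing the profiles are not propped up by extraneous homologs.
#' When no dummy sequence enters a profile at the inclusion threshold, the
#' profile (and hence the flag) is unchanged by construction.
#'
#' @param repset A `representative_set`.
#' @param family The family it represents.
#' @param dummy_db Non-empty list of unrelated [seq_record()]s.
#' @param backend A [search_backend()].
#' @param cutoff Coverage E-value cutoff.
#' @return The `representative_set` with `dummy_validated` set; attribute
#'   `dummy_coverage` carries the re-counted combined coverage.
#' @export
validate_with_dummy <- function(repset, family, dummy_db, backend,
                                cutoff = backend$config$assignment_evalue) {
  if (length(dummy_db) == 0L) stop("dummy database is empty")
  cfg <- backend$config
  members <- backend_records(backend, family$member_ids)
  enc <- encode_set(members)
  covered <- character()
  for (rep_id in repset$representative_ids) {
    cand <- backend_records(backend, rep_id)[[1]]
    p0 <- calibrate(build_profile(cand, family_name = family$name),
                    backend$decoys_enc)
    p <- iterate_profile(p0, unname(dummy_db),
                         inclusion_evalue = cfg$profile_inclusion_evalue,
                         max_iter = cfg$max_profile_iterations,
                         decoys = backend$decoys_enc,
                         params = backend$params)
    ev <- e_value(p, profile_scores(p, enc))
    covered <- union(covered, family$member_ids[ev <= cutoff])
  }
  cc <- length(intersect(covered, family$member_ids)) /
    length(family$member_ids)
  repset$dummy_validated <- isTRUE(all.equal(cc, 1))
  attr(repset, "dummy_coverage") <- cc
  repset
}

#' Retain old representatives or reselect
#'
#' If the previously chosen representative set still achieves 100% combined
#' coverage on the (possibly enlarged) family it is retained unchanged;
#' otherwise representatives are selected afresh and the change is recorded
#' in the result's `note`.
#'
#' @param old_reps Character vector of previous representative ids (possibly
#'   empty; ids not among current members are ignored for coverage and force
#'   reselection).
#' @param family The current [pf_family()].
#' @param backend A [search_backend()].
#' @param config A [pf_config()].
#' @param cutoff Coverage E-value cutoff.
#' @return A `representative_set`; attribute `note` is `"retained"` or
#'   `"reselected"`.
#' @export
retain_or_replace <- function(old_reps, family, backend,
                              config = pf_config(),
                              cutoff = config$assignment_evalue) {
  old_reps <- intersect(old_reps, family$member_ids)
  if (length(old_reps) > 0L) {
    reports <- lapply(sort(old_reps), coverage, family = family,
                      backend = backend, cutoff = cutoff)
    covered <- sort(unique(unlist(lapply(reports, `[[`, "picking_ids"))))
    if (length(intersect(covered, family$member_ids)) ==
        length(family$member_ids)) {
      rs <- representative_set(family$name, sort(old_reps),
                               family$member_ids, covered, "retained")
      attr(rs, "note") <- "retained"
      return(rs)
    }
  }
  rs <- select_representatives(family, backend, config, cutoff = cutoff)
  attr(rs, "note") <- "reselected"
  rs
}

#' Export coverage reports / representative sets as TSV
#'
#' @param x List of `coverage_report`s or of `representative_set`s.
#' @param path Output TSV path.
#' @export
write_coverage_tsv <- function(x, path) {
  df <- do.call(rbind, lapply(x, function(r) {
    if (inherits(r, "coverage_report"))
      data.frame(family = r$family_name, candidate = r$candidate_id,
                 n_members = r$n_members, n_picking = r$n_picking,
                 coverage = r$coverage, strategy = NA, dummy_validated = NA,
                 stringsAsFactors = FALSE)
    else
      data.frame(family = r$family_name,
                 candidate = paste(r$representative_ids, collapse = ","),
                 n_members = length(r$covered_ids) / max(r$combined_coverage,
                                                         .Machine$double.eps),
                 n_picking = length(r$covered_ids),
                 coverage = r$combined_coverage, strategy = r$strategy,
                 dummy_validated = r$dummy_validated,
                 stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
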