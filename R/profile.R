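#' Background amino-acid composition
#'
#' Standard background frequencies over the 20 residues (Robinson-Robinson
#' style composition), used for log-odds scoring, pseudocounts and synthetic
#' sequence generation.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
aa_background <- function() {
  bg <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
          Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
          L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
          S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  bg / sum(bg)
}

encode_residues <- function(residues) {
  idx <- match(strsplit(residues, "")[[1]], AA20)
  idx[is.na(idx)] <- 0L  # X / unknown -> code -1 after shift
  as.integer(idx - 1L)
}

encode_set <- function(records) {
  out <- lapply(records, function(r) encode_residues(residues_of(r)))
  ids <- vapply(records, function(r) seq_id_of(r) %||% NA_character_,
                character(1))
  if (!anyNA(ids)) names(out) <- ids
  structure(out, class = "encoded_seqs",
            total_residues = sum(lengths(out)))
}

as_encoded <- function(x) {
  if (inherits(x, "encoded_seqs")) x else encode_set(x)
}

#' Star alignment of family members to a seed
#'
#' Builds a family alignment progressively from pairwise global alignments of
#' every member to the seed: columns are the seed's residue positions;
#' member residues falling in insertions relative to the seed are dropped.
#' This is the documented construction used for profile seeds (not a general
#' multiple-sequence alignment optimiser).
#'
#' @param seed A [seq_record()] anchoring the columns.
#' @param others Further [seq_record()] objects to align to the seed.
#' @param params An [align_params()].
#' @return Character matrix (rows = sequences, first row the seed, gap `-`),
#'   with member ids as rownames.
#' @export
star_alignment <- function(seed, others = list(), params = align_params()) {
  rows <- list()
  rows[[seq_id_of(seed) %||% "seed"]] <- strsplit(residues_of(seed), "")[[1]]
  if (length(others) > 0L) {
    al <- align_batch(vapply(others, residues_of, character(1)),
                      residues_of(seed), params)
    for (k in seq_along(others)) {
      ca <- strsplit(al$pattern[k], "")[[1]]
      cb <- strsplit(al$subject[k], "")[[1]]
      rows[[seq_id_of(others[[k]])]] <- ca[cb != "-"]  # seed columns only
    }
  }
  do.call(rbind, rows)
}

#' Build a position-specific score matrix from a seed alignment
#'
#' Per-column residue frequencies are estimated with position-based
#' (Henikoff) sequence weights, mixed with background pseudocounts at weight
#' `beta / (Neff + beta)` where `Neff` is the mean number of distinct
#' residues per column, and converted to log-odds scores in bits. All-gap
#' columns are dropped with a warning. Profile construction is fully
#' deterministic: an identical seed alignment yields a bit-identical matrix.
#'
#' @param aln Character matrix from [star_alignment()] (rows = sequences,
#'   gap `-`), or a single [seq_record()].
#' @param family_name Name recorded on the profile.
#' @param background Background residue frequencies (see [aa_background()]).
#' @param pseudocount_weight Pseudocount mass `beta` (0 disables mixing;
#'   zero observed frequencies are floored at 1e-8 to keep scores finite).
#' @param gap_open,gap_extend Affine gap penalties used when aligning
#'   sequences to this profile.
#' @return A `pssm_profile` with per-position 20-residue bit scores,
#'   uncalibrated (`lambda`/`K` are `NA` until [calibrate()]).
#' @export
build_profile <- function(aln, family_name = "",
                          background = aa_background(),
                          pseudocount_weight = 10,
                          gap_open = 11, gap_extend = 1) {
  if (inherits(aln, "seq_record")) aln <- star_alignment(aln)
  stopifnot(is.matrix(aln), nrow(aln) >= 1L)
  bg <- background[AA20]
  if (anyNA(bg) || abs(sum(bg) - 1) > 1e-6)
    stop("background must cover the 20 residues and sum to 1")
  nseq <- nrow(aln)
  known <- matrix(aln %in% AA20, nrow = nseq)  # neither gap nor X
  all_gap <- colSums(aln != "-") == 0L
  if (any(all_gap)) {
    warning(sum(all_gap), " all-gap column(s) dropped")
    aln <- aln[, !all_gap, drop = FALSE]
    known <- known[, !all_gap, drop = FALSE]
  }
  ncol_a <- ncol(aln)
  if (ncol_a == 0L) stop("alignment has no usable columns")

  # position-based sequence weights
  w <- rep(0, nseq)
  distinct <- rep(0L, ncol_a)
  for (j in seq_len(ncol_a)) {
    res <- aln[, j]
    ok <- known[, j]
    if (!any(ok)) next
    tab <- table(res[ok])
    distinct[j] <- length(tab)
    w[ok] <- w[ok] + 1 / (length(tab) * as.numeric(tab[res[ok]]))
  }
  if (sum(w) == 0) w <- rep(1, nseq)
  w <- w / sum(w)
  neff <- mean(pmax(distinct[distinct > 0L], 1L))
  if (!is.finite(neff) || neff < 1) neff <- 1

  beta <- pseudocount_weight
  scores <- matrix(0, nrow = ncol_a, ncol = 20,
                   dimnames = list(NULL, AA20))
  consensus <- character(ncol_a)
  for (j in seq_len(ncol_a)) {
    ok <- known[, j]
    if (any(ok)) {
      wt <- w[ok] / sum(w[ok])
      f_obs <- vapply(AA20, function(a) sum(wt[aln[ok, j] == a]), numeric(1))
    } else {
      f_obs <- bg  # column of only X: fall back to background
    }
    f <- if (beta > 0) (neff * f_obs + beta * bg) / (neff + beta) else f_obs
    f <- pmax(f, 1e-8)
    scores[j, ] <- log2(f / bg)
    consensus[j] <- AA20[which.max(f_obs)]
  }

  structure(list(family_name = family_name,
                 length = nrow(scores),
                 scores = scores,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = NA_real_, K = NA_real_,
                 decoy_db_size = NA_real_,
                 seed_member_ids = rownames(aln) %||% character(),
                 master = paste(aln[1, aln[1, ] != "-"], collapse = ""),
                 consensus = paste(consensus, collapse = ""),
                 aln = aln,
                 background = bg,
                 pseudocount_weight = pseudocount_weight,
                 neff = neff),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile '%s': %d positions, %d seed seq(s), %s>\n",
              x$family_name, x$length, length(x$seed_member_ids),
              if (is.na(x$lambda)) "uncalibrated"
              else sprintf("lambda=%.3f K=%.3g", x$lambda, x$K)))
  invisible(x)
}

is_calibrated <- function(p) {
  is.finite(p$lambda) && is.finite(p$K) && p$lambda > 0 && p$K > 0
}

#' Calibrate a profile's E-value statistics against decoys
#'
#' Scores every decoy against the profile (optimal local alignment) and fits
#' the extreme-value tail model `E = K * m * n * exp(-lambda * S)` (m =
#' profile length, n = database residues) by Gumbel moment matching on the
#' per-decoy maximal scores. The fitted constants and the decoy database size
#' are stored on the profile. Deterministic given the decoy set.
#'
#' @param p A `pssm_profile`.
#' @param decoys List of at least `min_decoys` unrelated [seq_record()]s (or
#'   a pre-encoded set).
#' @param min_decoys Minimum decoy count (default 100).
#' @return The calibrated profile.
#' @export
calibrate <- function(p, decoys, min_decoys = 100L) {
  enc <- as_encoded(decoys)
  if (length(enc) < min_decoys)
    stop("need at least ", min_decoys, " decoy sequences to calibrate (got ",
         length(enc), ")")
  s <- pssm_local_scores_cpp(p$scores, unclass(enc), p$gap_open, p$gap_extend)
  if (sd(s) <= 0)
    stop("degenerate calibration fit (constant decoy scores); ",
         "provide more or longer decoys")
  euler <- 0.5772156649015329
  lambda <- pi / (sd(s) * sqrt(6))
  if (!is.finite(lambda) || lambda <= 0)
    stop("degenerate calibration fit (non-positive lambda); ",
         "provide more decoys")
  mu <- mean(s) - euler / lambda
  nbar <- mean(lengths(enc))
  K <- exp(lambda * mu) / (p$length * nbar)
  p$lambda <- lambda
  p$K <- K
  p$decoy_db_size <- sum(lengths(enc))
  p
}

#' E-value of a bit score under a calibrated profile
#'
#' @param p Calibrated `pssm_profile`.
#' @param score Alignment score in bits.
#' @param n Database size in residues (defaults to the calibration database
#'   size); E-values scale linearly in `n`.
#' @return Expected number of chance hits of at least `score`.
#' @export
e_value <- function(p, score, n = p$decoy_db_size) {
  if (!is_calibrated(p)) stop("profile '", p$family_name, "' is not calibrated")
  pmax(p$K * p$length * n * exp(-p$lambda * score), .Machine$double.xmin)
}

#' Score a sequence against a calibrated profile
#'
#' Optimal local alignment of the sequence against the position-specific
#' matrix under affine gaps, with the E-value from the stored calibration.
#'
#' @param p Calibrated `pssm_profile`.
#' @param s A [seq_record()] (or residue string).
#' @param n Database size for the E-value (default: calibration size).
#' @return A `search_hit`: `query_id`, `family_name`, `bit_score`,
#'   `e_value`, `query_span`, `profile_span` (0-based half-open).
#' @export
score_sequence <- function(p, s, n = p$decoy_db_size) {
  res <- residues_of(s)
  if (is.na(res) || nchar(res) < 1L) stop("sequence must have length >= 1")
  if (!is_calibrated(p)) stop("profile '", p$family_name, "' is not calibrated")
  al <- pssm_local_align_cpp(p$scores, encode_residues(res),
                             p$gap_open, p$gap_extend)
  structure(list(query_id = seq_id_of(s),
                 family_name = p$family_name,
                 bit_score = al$score,
                 e_value = unname(e_value(p, al$score, n)),
                 query_span = al$query_span,
                 profile_span = al$profile_span),
            class = "search_hit")
}

# maximal local scores of many (pre-encoded) sequences against one profile
profile_scores <- function(p, encoded) {
  pssm_local_scores_cpp(p$scores, unclass(encoded), p$gap_open, p$gap_extend)
}

#' Iteratively refine a profile over a corpus
#'
#' Jump-start refinement: the seed alignment defines the first profile
#' directly; each iteration searches the corpus, adds hits at or below the
#' inclusion E-value to the seed alignment (aligned to the profile's master
#' sequence), rebuilds the matrix and recalibrates, stopping when no new
#' member joins or after `max_iter` iterations.
#'
#' @param p Calibrated `pssm_profile` whose first alignment row is ungapped
#'   (a star alignment master).
#' @param corpus List of candidate [seq_record()]s (sequences already in the
#'   profile are skipped).
#' @param inclusion_evalue Inclusion threshold (default 1e-10).
#' @param max_iter Iteration cap (default 20).
#' @param decoys Decoy set for recalibration after each rebuild; if `NULL`
#'   the previous `lambda`/`K` are carried over.
#' @param params [align_params()] used to align inclusions to the master.
#' @return The final profile, with attributes `included_ids` (corpus members
#'   absorbed) and `iterations`.
#' @export
iterate_profile <- function(p, corpus, inclusion_evalue = 1e-10,
                            max_iter = 20L, decoys = NULL,
                            params = align_params()) {
  stopifnot(inherits(p, "pssm_profile"))
  if (length(corpus) == 0L) {
    attr(p, "included_ids") <- character()
    attr(p, "iterations") <- 0L
    return(p)
  }
  if (!is_calibrated(p)) {
    if (is.null(decoys)) stop("profile must be calibrated (or supply decoys)")
    p <- calibrate(p, decoys)
  }
  corpus_ids <- vapply(corpus, seq_id_of, character(1))
  included <- character()
  it <- 0L
  repeat {
    it <- it + 1L
    pool_idx <- which(!(corpus_ids %in% c(p$seed_member_ids, included)))
    if (length(pool_idx) == 0L) break
    enc <- encode_set(corpus[pool_idx])
    sc <- profile_scores(p, enc)
    ev <- e_value(p, sc)
    hit <- pool_idx[ev <= inclusion_evalue]
    if (length(hit) == 0L) break
    al <- align_batch(vapply(corpus[hit], residues_of, character(1)),
                      p$master, params)
    for (k in seq_along(hit)) {
      ca <- strsplit(al$pattern[k], "")[[1]]
      cb <- strsplit(al$subject[k], "")[[1]]
      row <- ca[cb != "-"]
      aln2 <- rbind(p$aln, row)
      rownames(aln2) <- c(rownames(p$aln), corpus_ids[hit[k]])
      p$aln <- aln2
    }
    included <- c(included, corpus_ids[hit])
    lambda_old <- p$lambda; K_old <- p$K; n_old <- p$decoy_db_size
    p2 <- build_profile(p$aln, family_name = p$family_name,
                        background = p$background,
                        pseudocount_weight = p$pseudocount_weight,
                        gap_open = p$gap_open, gap_extend = p$gap_extend)
    if (!is.null(decoys)) {
      p <- calibrate(p2, decoys)
    } else {
      p2$lambda <- lambda_old; p2$K <- K_old; p2$decoy_db_size <- n_old
      p <- p2
    }
    if (it >= max_iter) break
  }
  attr(p, "included_ids") <- included
  attr(p, "iterations") <- it
  p
}

#' Assemble calibrated profiles into a searchable database
#'
#' @param profiles List of calibrated `pssm_profile`s. A family may appear
#'   more than once when it has several representatives; list names are
#'   made unique while triage groups hits by `family_name`.
#' @return A `profile_db` with `profiles` and `total_size` (summed profile
#'   lengths).
#' @export
profile_db <- function(profiles = list()) {
  fam <- vapply(profiles, `[[`, character(1), "family_name")
  # several representatives of one family may each contribute a profile;
  # list names stay unique while family_name is what triage groups on
  names(profiles) <- make.unique(fam, sep = "#")
  structure(list(profiles = profiles,
                 total_size = sum(vapply(profiles, `[[`, numeric(1), "length"))),
            class = "profile_db")
}

#' Search a sequence against a profile database
#'
#' Scores the query against every profile and returns hits at or below the
#' E-value cutoff, sorted by ascending E-value, then descending bit score,
#' then family name; the order is invariant to profile insertion order.
#'
#' @param s Query [seq_record()].
#' @param db A [profile_db()].
#' @param cutoff E-value cutoff.
#' @return List of `search_hit`s (possibly empty).
#' @export
search_profile_db <- function(s, db, cutoff = 1e-3) {
  stopifnot(inherits(db, "profile_db"))
  if (length(db$profiles) == 0L) return(list())
  hits <- lapply(db$profiles, function(p) score_sequence(p, s))
  keep <- vapply(hits, function(h) h$e_value <= cutoff, logical(1))
  hits <- hits[keep]
  if (length(hits) == 0L) return(list())
  ord <- order(vapply(hits, `[[`, numeric(1), "e_value"),
               -vapply(hits, `[[`, numeric(1), "bit_score"),
               vapply(hits, `[[`, character(1), "family_name"))
  unname(hits[ord])
}

#' Symmetric pairwise profile association of two sequences
#'
#' Builds the single-sequence profile of each sequence, searches the other
#' against it, and declares the pair associated when the smaller of the two
#' E-values is at or below the cutoff. The decision is symmetric in its
#' arguments.
#'
#' @param a,b [seq_record()]s.
#' @param cutoff Association E-value cutoff (default 1e-3).
#' @param decoys Decoy set for calibrating the single-sequence profiles.
#' @param cache Optional environment caching calibrated profiles by seq id.
#' @return `NULL` when not associated, else a list with `e_value` and
#'   `score` of the better direction.
#' @export
pairwise_association <- function(a, b, cutoff = 1e-3, decoys, cache = NULL) {
  pa <- single_seq_profile(a, decoys, cache)
  pb <- single_seq_profile(b, decoys, cache)
  hab <- score_sequence(pa, b)
  hba <- score_sequence(pb, a)
  best <- if (hab$e_value <= hba$e_value) hab else hba
  if (best$e_value <= cutoff)
    list(e_value = best$e_value, score = best$bit_score)
  else NULL
}

single_seq_profile <- function(rec, decoys, cache = NULL) {
  id <- seq_id_of(rec)
  if (!is.null(cache) && !is.null(cache[[id]])) return(cache[[id]])
  p <- calibrate(build_profile(rec, family_name = id), decoys)
  if (!is.null(cache)) cache[[id]] <- p
  p
}

#' Export search hits as tabular text
#'
#' One row per hit: query, family, bit score, E-value and the 0-based
#' half-open query/profile spans, mirroring tabular search-output
#' conventions.
#'
#' @param hits List of `search_hit`s.
#' @param path Output TSV path.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- if (length(hits) == 0L)
    data.frame(query = character(), family = character(), bits = numeric(),
               evalue = numeric(), query_start = integer(),
               query_end = integer(), profile_start = integer(),
               profile_end = integer())
  else do.call(rbind, lapply(hits, function(h) data.frame(
    query = h$query_id, family = h$family_name, bits = h$bit_score,
    evalue = h$e_value, query_start = h$query_span[1],
    query_end = h$query_span[2], profile_start = h$profile_span[1],
    profile_end = h$profile_span[2], stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write profiles and profile databases as text
#'
#' Profiles serialise to a diffable text format: `#`-prefixed header lines
#' (family, length, gap penalties, calibration constants, seed members)
#' followed by one line per position with 20 tab-separated bit scores. A
#' profile database is a directory of such files plus an `index.tsv`.
#'
#' @param p A `pssm_profile`.
#' @param path Output file path.
#' @export
write_profile <- function(p, path) {
  hdr <- c(
    paste0("# family\t", p$family_name),
    paste0("# length\t", p$length),
    paste0("# gap_open\t", format(p$gap_open)),
    paste0("# gap_extend\t", format(p$gap_extend)),
    paste0("# lambda\t", format(p$lambda, digits = 17)),
    paste0("# K\t", format(p$K, digits = 17)),
    paste0("# decoy_db_size\t", format(p$decoy_db_size, digits = 17)),
    paste0("# master\t", p$master),
    paste0("# seed_members\t", paste(p$seed_member_ids, collapse = ",")),
    paste0("# residues\t", paste(AA20, collapse = "\t")))
  body <- apply(p$scores, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "#")]
  fields <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^# ", "", h), "\t")[[1]]
    fields[[parts[1]]] <- if (length(parts) > 1L) parts[-1] else ""
  }
  scores <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  colnames(scores) <- AA20
  structure(list(family_name = fields$family %||% "",
                 length = nrow(scores),
                 scores = scores,
                 gap_open = as.numeric(fields$gap_open),
                 gap_extend = as.numeric(fields$gap_extend),
                 lambda = as.numeric(fields$lambda),
                 K = as.numeric(fields$K),
                 decoy_db_size = as.numeric(fields$decoy_db_size),
                 seed_member_ids =
                   strsplit(fields$seed_members %||% "", ",")[[1]],
                 master = fields$master %||% "",
                 consensus = NULL, aln = NULL,
                 background = aa_background(),
                 pseudocount_weight = NA_real_, neff = NA_real_),
            class = "pssm_profile")
}

#' @rdname write_profile
#' @param db A `profile_db`.
#' @param dir Directory for the profile files and `index.tsv`.
#' @export
write_profile_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (k in seq_along(db$profiles)) {
    f <- paste0(gsub("[^A-Za-z0-9._-]", "_", names(db$profiles)[k]), ".pssm")
    write_profile(db$profiles[[k]], file.path(dir, f))
    files <- c(files, f)
  }
  idx <- data.frame(family = names(db$profiles), file = files,
                    length = vapply(db$profiles, `[[`, numeric(1), "length"))
  write.table(idx, file.path(dir, "index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_profile
#' @export
read_profile_db <- function(dir) {
  idx <- read.delim(file.path(dir, "index.tsv"), stringsAsFactors = FALSE)
  profile_db(lapply(idx$file, function(f) read_profile(file.path(dir, f))))
}
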