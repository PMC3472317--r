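#' Specification of one synthetic protein family
#'
#' @param name Family name (used to derive the family's RNG stream, so adding
#'   a family to a benchmark never perturbs the others).
#' @param n_members Number of members (>= 1).
#' @param ancestor_length Ancestor length in residues (>= 30).
#' @param target_identity Percent-identity range `c(lo, hi)` of members to
#'   the common ancestor; each member draws its own target uniformly.
#' @param indel_rate Per-site indel probability during member evolution.
#' @param seed Integer seed for the family's stream.
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, n_members, ancestor_length = 150,
                        target_identity = c(60, 90), indel_rate = 0.01,
                        seed = 1L) {
  stopifnot(n_members >= 1, ancestor_length >= 30,
            length(target_identity) == 2L,
            all(target_identity > 0), all(target_identity <= 100))
  structure(list(name = name, n_members = as.integer(n_members),
                 ancestor_length = as.integer(ancestor_length),
                 target_identity = as.numeric(target_identity),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "family_spec")
}

#' Draw a random ancestor sequence
#'
#' Residues are drawn i.i.d. from the stated background composition
#' ([aa_background()]); reproducible under the seed.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @param seq_id Identifier for the record.
#' @return A [seq_record()].
#' @export
make_ancestor <- function(length, seed, seq_id = "ancestor") {
  stopifnot(length >= 1)
  bg <- aa_background()
  res <- with_seed(seed,
    paste(sample(names(bg), length, replace = TRUE, prob = bg), collapse = ""))
  seq_record(seq_id, res)
}

# residue-exchange distribution: P(b | a) over b != a, derived from the same
# substitution matrix used for alignment so generator and scorer agree
# (indels and placement randomness keep the check non-circular)
exchange_matrix <- function() {
  if (is.null(submat_cache[["..exchange"]])) {
    b62 <- get_submat("BLOSUM62")[AA20, AA20]
    bg <- aa_background()
    ex <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
    for (a in AA20) {
      p <- bg * 2^(b62[a, ] / 2)
      p[a] <- 0
      ex[a, ] <- p / sum(p)
    }
    submat_cache[["..exchange"]] <- ex
  }
  submat_cache[["..exchange"]]
}

#' Evolve a family member from an ancestor
#'
#' Places substitutions uniformly at random so that the expected identity to
#' the ancestor matches the target (substitution partners drawn from a
#' BLOSUM-derived residue-exchange distribution), then applies indels at the
#' given per-site rate with geometric(0.5) lengths. Because percent identity
#' is measured over gap-free aligned columns, the realised global-alignment
#' identity stays within a few points of the target.
#'
#' @param ancestor A [seq_record()].
#' @param target_identity Target percent identity to the ancestor, in
#'   (0, 100].
#' @param indel_rate Per-site indel probability.
#' @param seed Integer seed.
#' @param seq_id Identifier for the evolved record.
#' @return A [seq_record()].
#' @export
evolve_member <- function(ancestor, target_identity, indel_rate = 0.01,
                          seed = 1L, seq_id = "member") {
  stopifnot(target_identity > 0, target_identity <= 100)
  if (target_identity == 100 && indel_rate > 0)
    stop("target identity 100 is unreachable with a non-zero indel rate")
  res <- strsplit(residues_of(ancestor), "")[[1]]
  L <- length(res)
  ex <- exchange_matrix()
  out <- with_seed(seed, {
    n_sub <- round(L * (1 - target_identity / 100))
    if (n_sub > 0) {
      pos <- sample.int(L, n_sub)
      for (i in pos) {
        a <- res[i]
        res[i] <- if (a %in% AA20)
          sample(AA20, 1, prob = ex[a, ]) else sample(AA20, 1)
      }
    }
    if (indel_rate > 0) {
      bg <- aa_background()
      keep <- list()
      i <- 1L
      while (i <= length(res)) {
        if (stats::runif(1) < indel_rate) {
          len <- stats::rgeom(1, 0.5) + 1L
          if (stats::runif(1) < 0.5) {
            i <- i + len  # deletion
            next
          } else {
            ins <- sample(names(bg), len, replace = TRUE, prob = bg)
            keep[[length(keep) + 1L]] <- ins  # insertion before site
          }
        }
        keep[[length(keep) + 1L]] <- res[i]
        i <- i + 1L
      }
      res <- unlist(keep)
    }
    res
  })
  if (length(out) == 0L) out <- res[1]
  seq_record(seq_id, paste(out, collapse = ""))
}

#' Generate a synthetic family of homologous sequences
#'
#' Draws an ancestor from the family's stream and evolves each member
#' independently at its own target identity sampled from the spec's range.
#'
#' @param spec A [family_spec()].
#' @return List of [seq_record()]s with ids `<name>_mNN`.
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  base <- derive_seed(spec$seed, spec$name)
  anc <- make_ancestor(spec$ancestor_length, base,
                       seq_id = paste0(spec$name, "_anc"))
  targets <- with_seed(derive_seed(base, "targets"),
    stats::runif(spec$n_members, spec$target_identity[1],
                 spec$target_identity[2]))
  lapply(seq_len(spec$n_members), function(i)
    evolve_member(anc, targets[i], spec$indel_rate,
                  seed = derive_seed(base, paste0("m", i)),
                  seq_id = sprintf("%s_m%02d", spec$name, i)))
}

#' Generate unrelated decoy / dummy sequences
#'
#' Random background-composition sequences emulating a database of completely
#' unrelated, non-DNA-binding proteins. When `families` is supplied, each
#' candidate is rejection-sampled until its best global-alignment identity to
#' every family member is below `max_identity` (at most 1000 tries each).
#'
#' @param n Number of sequences.
#' @param length_range Length range in residues (default 80-300, straddling
#'   typical profile lengths).
#' @param seed Integer seed.
#' @param families Optional list of [seq_record()]s to stay unrelated to.
#' @param max_identity Rejection threshold in percent (default 25).
#' @param prefix Id prefix.
#' @return List of [seq_record()]s.
#' @export
make_dummy_db <- function(n, length_range = c(80, 300), seed = 1L,
                          families = NULL, max_identity = 25,
                          prefix = "decoy") {
  bg <- aa_background()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, paste0(prefix, i))
    rec <- NULL
    for (try in seq_len(1000L)) {
      len <- with_seed(derive_seed(si, paste0("len", try)),
                       sample(length_range[1]:length_range[2], 1))
      cand <- make_ancestor(len, derive_seed(si, paste0("seq", try)),
                            seq_id = sprintf("%s_%03d", prefix, i))
      ok <- TRUE
      if (!is.null(families)) {
        al <- align_batch(vapply(families, residues_of, character(1)),
                          cand$residues)
        pids <- vapply(seq_along(families), function(k)
          percent_identity(al$pattern[k], al$subject[k]), numeric(1))
        ok <- all(pids < max_identity)
      }
      if (ok) { rec <- cand; break }
    }
    if (is.null(rec))
      stop("rejection sampling exceeded 1000 tries for dummy sequence ", i)
    out[[i]] <- rec
  }
  out
}

#' Assemble a ternary complex entry from two family members
#'
#' A ternary complex carries two distinct proteins bound to one DNA; its
#' chains come from two different families and are classified chain-wise
#' after splitting.
#'
#' @param fam_a_member,fam_b_member [seq_record()]s from different families.
#' @param complex_id Four-character id for the entry.
#' @param resolution Resolution in Angstrom.
#' @return A [complex_entry()] with two chains (ids `<complex_id>_A/_B`).
#' @export
make_ternary <- function(fam_a_member, fam_b_member, complex_id = "TERN",
                         resolution = 2.0) {
  ca <- fam_a_member; cb <- fam_b_member
  ca$seq_id <- paste0(complex_id, "_A")
  cb$seq_id <- paste0(complex_id, "_B")
  complex_entry(complex_id, resolution, "dsDNA", chains = list(ca, cb))
}

#' Study-condition family sets for representative selection
#'
#' `representative_benchmark_specs()` draws a set of multi-member family
#' specifications whose sizes and within-family identity ranges are sampled
#' from the seed: sizes uniform over `size_range`, identity-range lower
#' bounds uniform over `identity_low`, widths uniform over `width_range`
#' (capped at 95%), so the collection spans the twilight-to-near-identical
#' regime. `narrow_benchmark_specs()` draws families of near-identical
#' members (85-95% target identity) for the narrow-family shortcut.
#'
#' @param n_families Number of families.
#' @param seed Integer seed.
#' @param size_range Member-count range.
#' @param identity_low Range of the identity-range lower bound (percent).
#' @param width_range Range of the identity-range width (percentage
#'   points).
#' @param indel_rate Per-site indel probability.
#' @return List of [family_spec()]s.
#' @export
representative_benchmark_specs <- function(n_families = 20, seed = 1234L,
                                           size_range = c(5, 30),
                                           identity_low = c(35, 70),
                                           width_range = c(5, 25),
                                           indel_rate = 0.01) {
  lapply(seq_len(n_families), function(i) {
    si <- derive_seed(seed, paste0("spec", i))
    pars <- with_seed(si, c(
      size = sample(size_range[1]:size_range[2], 1),
      lo = stats::runif(1, identity_low[1], identity_low[2]),
      w = stats::runif(1, width_range[1], width_range[2])))
    family_spec(sprintf("T%02d", i), pars[["size"]], ancestor_length = 150,
                target_identity = c(pars[["lo"]],
                                    min(pars[["lo"]] + pars[["w"]], 95)),
                indel_rate = indel_rate, seed = seed)
  })
}

#' @rdname representative_benchmark_specs
#' @param n_members Members per family.
#' @export
narrow_benchmark_specs <- function(n_families = 10, n_members = 6,
                                   seed = 77L, indel_rate = 0.005) {
  lapply(seq_len(n_families), function(i)
    family_spec(sprintf("N%02d", i), n_members, ancestor_length = 150,
                target_identity = c(85, 95), indel_rate = indel_rate,
                seed = seed))
}

default_benchmark_specs <- function(seed = 61L) {
  list(family_spec("FA", n_members = 5, ancestor_length = 150,
                   target_identity = c(70, 90), indel_rate = 0.01, seed = seed),
       family_spec("FB", n_members = 5, ancestor_length = 160,
                   target_identity = c(65, 90), indel_rate = 0.01, seed = seed),
       family_spec("FC", n_members = 5, ancestor_length = 140,
                   target_identity = c(70, 95), indel_rate = 0.01, seed = seed))
}

#' Generate a full planted-truth benchmark
#'
#' Builds synthetic families, unrelated loner sequences, ternary complexes
#' whose two chains come from the first two families, a dummy database and a
#' complete truth map. The first `n_legacy_per_family` members of each family
#' form a legacy classification (provenance `legacy`, first member flagged
#' representative); the remaining members, the loners and the ternary entries
#' become the query manifest. Generation asserts the separation invariant:
#' the minimum within-family identity must exceed the maximum
#' family-to-loner/dummy identity.
#'
#' @param specs List of [family_spec()]s (>= 2 when `n_ternary` > 0).
#' @param n_loners Number of unrelated loner sequences.
#' @param n_ternary Number of ternary complexes.
#' @param seed Integer master seed (each component derives its own stream).
#' @param n_legacy_per_family Members per family seeding the legacy
#'   classification.
#' @param n_dummy Size of the dummy database.
#' @param dir Optional directory; when given, FASTA, manifest TSV and truth
#'   TSV are written there.
#' @param check_separation Verify the separation invariant (on by default;
#'   costs one alignment per family x loner/dummy pair).
#' @return A `benchmark` list: `families`, `loners`, `ternary_entries`,
#'   `dummy_db`, `truth` (named map seq_id -> family or "loner"), `legacy`
#'   (classification), `manifest`, `sequences`, `annotations`.
#' @export
make_benchmark <- function(specs = default_benchmark_specs(),
                           n_loners = 4, n_ternary = 1, seed = 61L,
                           n_legacy_per_family = 2, n_dummy = 5,
                           dir = NULL, check_separation = TRUE) {
  if (n_ternary > 0 && length(specs) < 2L)
    stop("need at least 2 family specs to generate ternary complexes")
  specs <- lapply(specs, function(sp) { sp$seed <- seed; sp })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  fams <- lapply(specs, make_family)

  # complex-style ids: one single-chain complex per member
  truth <- character()
  sequences <- list()
  manifest <- list()
  groups_cycle <- GROUP_NAMES[c(1, 8, 4, 2, 7, 3, 5, 6, 9)]
  legacy_groups <- list()
  annotations <- list()

  for (fi in seq_along(fams)) {
    fname <- names(fams)[fi]
    gname <- groups_cycle[(fi - 1L) %% length(groups_cycle) + 1L]
    member_ids <- character()
    for (mi in seq_along(fams[[fi]])) {
      rec <- fams[[fi]][[mi]]
      cid <- sprintf("%s%02d", substr(fname, 1, 2), mi)
      rec$seq_id <- paste0(cid, "_A")
      fams[[fi]][[mi]] <- rec
      sequences[[rec$seq_id]] <- rec
      truth[rec$seq_id] <- fname
      member_ids <- c(member_ids, rec$seq_id)
      if (mi > n_legacy_per_family) {
        manifest[[length(manifest) + 1L]] <-
          complex_entry(cid, 2.0, "dsDNA", chains = list(rec))
        annotations[[rec$seq_id]] <- c(fname, gname)
      }
    }
    leg <- head(member_ids, n_legacy_per_family)
    if (length(leg) > 0L)
      legacy_groups[[gname]] <- c(legacy_groups[[gname]] %||% list(),
        list(pf_family(fname, gname, leg,
                       representative_ids = leg[1],
                       provenance = setNames(rep("legacy", length(leg)), leg))))
  }

  loners <- make_dummy_db(n_loners, seed = derive_seed(seed, "loners"),
                          families = if (check_separation)
                            lapply(fams, `[[`, 1) else NULL,
                          prefix = "LN")
  for (i in seq_along(loners)) {
    cid <- sprintf("LN%02d", i)
    loners[[i]]$seq_id <- paste0(cid, "_A")
    rec <- loners[[i]]
    sequences[[rec$seq_id]] <- rec
    truth[rec$seq_id] <- "loner"
    manifest[[length(manifest) + 1L]] <-
      complex_entry(cid, 2.2, "dsDNA", chains = list(rec))
    annotations[[rec$seq_id]] <- c(paste0("Loner ", rec$seq_id), "Other")
  }

  ternary_entries <- list()
  if (n_ternary > 0) {
    for (t in seq_len(n_ternary)) {
      fa <- names(fams)[(2 * t - 2L) %% length(fams) + 1L]
      fb <- names(fams)[(2 * t - 1L) %% length(fams) + 1L]
      if (fa == fb) fb <- names(fams)[fa != names(fams)][1]
      ca <- fams[[fa]][[length(fams[[fa]])]]
      cb <- fams[[fb]][[length(fams[[fb]])]]
      # evolve fresh chains so ternary chains are new sequences, not copies
      ca2 <- evolve_member(ca, 85, 0.01,
                           seed = derive_seed(seed, paste0("ternA", t)))
      cb2 <- evolve_member(cb, 85, 0.01,
                           seed = derive_seed(seed, paste0("ternB", t)))
      cid <- sprintf("TC%02d", t)
      te <- make_ternary(ca2, cb2, complex_id = cid)
      ternary_entries[[t]] <- te
      for (ch in te$chains) sequences[[ch$seq_id]] <- ch
      truth[te$chains[[1]]$seq_id] <- fa
      truth[te$chains[[2]]$seq_id] <- fb
      annotations[[te$chains[[1]]$seq_id]] <-
        c(fa, find_group_of(legacy_groups, fa))
      annotations[[te$chains[[2]]$seq_id]] <-
        c(fb, find_group_of(legacy_groups, fb))
      manifest[[length(manifest) + 1L]] <- te
    }
  }

  dummy_db <- make_dummy_db(n_dummy, seed = derive_seed(seed, "dummy"),
                            families = if (check_separation)
                              lapply(fams, `[[`, 1) else NULL,
                            prefix = "DY")

  if (check_separation) assert_separation(fams, c(loners, dummy_db))

  legacy <- classification(lapply(names(legacy_groups), function(g)
    pf_group(g, legacy_groups[[g]])))

  ann_df <- data.frame(
    member_id = names(annotations),
    family_name = vapply(annotations, `[`, character(1), 1),
    group_name = vapply(annotations, `[`, character(1), 2),
    stringsAsFactors = FALSE, row.names = NULL)

  bm <- structure(list(families = fams, loners = loners,
                       ternary_entries = ternary_entries,
                       dummy_db = dummy_db, truth = truth,
                       legacy = legacy, manifest = manifest,
                       sequences = sequences, annotations = ann_df,
                       specs = specs, seed = seed),
                  class = "benchmark")
  if (!is.null(dir)) write_benchmark(bm, dir)
  bm
}

find_group_of <- function(legacy_groups, fam_name) {
  for (g in names(legacy_groups))
    for (f in legacy_groups[[g]])
      if (f$name == fam_name) return(g)
  "Other"
}

# separation invariant: min within-family identity > max family-to-background
assert_separation <- function(fams, background) {
  min_within <- Inf
  for (f in fams) {
    if (length(f) < 2L) next
    res <- vapply(f, residues_of, character(1))
    al <- align_batch(res[-length(res)], res[-1])
    pids <- vapply(seq_len(length(res) - 1L), function(k)
      percent_identity(al$pattern[k], al$subject[k]), numeric(1))
    min_within <- min(min_within, pids)
  }
  max_cross <- 0
  bres <- vapply(background, residues_of, character(1))
  for (f in fams) {
    al <- align_batch(bres, residues_of(f[[1]]))
    pids <- vapply(seq_along(bres), function(k)
      percent_identity(al$pattern[k], al$subject[k]), numeric(1))
    max_cross <- max(max_cross, pids)
  }
  if (is.finite(min_within) && min_within <= max_cross)
    stop(sprintf(paste0("separation violated: min within-family identity ",
                        "%.1f <= max family-to-background identity %.1f"),
                 min_within, max_cross))
  invisible(TRUE)
}

#' Write benchmark inputs to disk
#'
#' Emits `sequences.fasta`, `manifest.tsv`, `truth.tsv`, `annotations.tsv`,
#' `dummy.fasta` and the legacy `legacy.tsv` master table.
#'
#' @param bm A `benchmark`.
#' @param dir Output directory (created if needed).
#' @export
write_benchmark <- function(bm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bm$sequences, file.path(dir, "sequences.fasta"))
  write_fasta(bm$dummy_db, file.path(dir, "dummy.fasta"))
  write_manifest(bm$manifest, file.path(dir, "manifest.tsv"))
  truth_df <- data.frame(seq_id = names(bm$truth), family = unname(bm$truth))
  write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bm$annotations, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_master_table(bm$legacy, file.path(dir, "legacy.tsv"))
  invisible(dir)
}

#' FASTA and manifest I/O
#'
#' Sequences are read and written through Biostrings; the FASTA header token
#' is the seq id. The manifest TSV has columns `complex_id`, `resolution`,
#' `na_type`, `nucleosomal`, `previously_classified`, `taxon`; chains are
#' attached from the FASTA by matching `complexid_` id prefixes.
#'
#' @param records Named list of [seq_record()]s.
#' @param path File path.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::AAStringSet(
    vapply(records, residues_of, character(1)))
  names(ss) <- vapply(records, seq_id_of, character(1))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  out <- lapply(seq_along(ss), function(i)
    seq_record(ids[i], as.character(ss[[i]])))
  names(out) <- ids
  out
}

#' @rdname write_fasta
#' @param entries List of [complex_entry()]s.
#' @export
write_manifest <- function(entries, path) {
  df <- do.call(rbind, lapply(entries, function(e) data.frame(
    complex_id = e$complex_id, resolution = e$resolution,
    na_type = e$nucleic_acid_type, nucleosomal = e$nucleosomal,
    previously_classified = e$previously_classified,
    taxon = e$chains[[1]]$source_taxon, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fasta
#' @param sequences Named list of [seq_record()]s providing the chains.
#' @export
read_manifest <- function(path, sequences) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(complex_id = "character"))
  ids <- names(sequences)
  lapply(seq_len(nrow(df)), function(i) {
    cid <- df$complex_id[i]
    chains <- sequences[startsWith(ids, paste0(cid, "_"))]
    if (length(chains) == 0L)
      stop("no chains found in FASTA for complex ", cid)
    complex_entry(cid, df$resolution[i], df$na_type[i],
                  df$nucleosomal[i], df$previously_classified[i],
                  chains = unname(chains))
  })
}
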