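#' Triage a query against the representative profile database
#'
#' Searches the query against every representative profile and categorises
#' it by the number of distinct families hit at the cutoff: `single`
#' (exactly one family, possibly via several representatives of that
#' family), `multiple` (two or more families) or `none`.
#'
#' @param query A [seq_record()].
#' @param db A [profile_db()] of calibrated representative profiles.
#' @param cutoff Assignment E-value cutoff (default 1e-3).
#' @return A `triage_result`: `query_id`, `category`, `hits`.
#' @export
triage <- function(query, db, cutoff = 1e-3) {
  hits <- search_profile_db(query, db, cutoff)
  fams <- unique(vapply(hits, `[[`, character(1), "family_name"))
  category <- if (length(fams) == 0L) "none"
  else if (length(fams) == 1L) "single"
  else "multiple"
  structure(list(query_id = seq_id_of(query), category = category,
                 hits = hits, families = fams),
            class = "triage_result")
}

#' Entry-level triage of a complex
#'
#' Triages a complex against the representative database. Ternary complexes
#' (detected via [detect_ternary()]) are triaged chain by chain and their
#' hits merged; other complexes are represented by their first chain
#' (further chains of a non-ternary complex are crystallographic copies).
#' The category reflects the number of distinct families hit across the
#' triaged chains.
#'
#' @param entry A [complex_entry()].
#' @param db A [profile_db()].
#' @param cutoff Assignment E-value cutoff.
#' @param identity_cutoff Ternary detection identity cutoff (percent).
#' @return A `triage_result` with additional fields `ternary` (flag) and
#'   `chain_results` (per-chain `triage_result`s).
#' @export
triage_complex <- function(entry, db, cutoff = 1e-3, identity_cutoff = 95) {
  is_tern <- detect_ternary(entry, identity_cutoff)
  chains <- if (is_tern) entry$chains else entry$chains[1]
  trs <- lapply(chains, triage, db = db, cutoff = cutoff)
  fams <- unique(unlist(lapply(trs, `[[`, "families")))
  hits <- do.call(c, c(lapply(trs, `[[`, "hits"), list(list())))
  if (length(hits) > 0L)
    hits <- hits[order(vapply(hits, `[[`, numeric(1), "e_value"))]
  category <- if (length(fams) == 0L) "none"
  else if (length(fams) == 1L) "single" else "multiple"
  structure(list(query_id = entry$complex_id, category = category,
                 hits = hits, families = fams, ternary = is_tern,
                 chain_results = trs),
            class = "triage_result")
}

#' Detect a ternary complex
#'
#' A complex is ternary when it carries at least two chains that are
#' distinct proteins — pairwise identity below the cutoff — rather than
#' crystallographic copies of one protein.
#'
#' @param entry A [complex_entry()].
#' @param identity_cutoff Percent identity below which chains count as
#'   distinct (default 95).
#' @param params [align_params()].
#' @return Logical flag.
#' @export
detect_ternary <- function(entry, identity_cutoff = 95,
                           params = align_params()) {
  ch <- entry$chains
  if (length(ch) < 2L) return(FALSE)
  for (i in seq_len(length(ch) - 1L)) for (j in (i + 1L):length(ch)) {
    pid <- global_align(ch[[i]], ch[[j]], params)$percent_identity
    if (pid < identity_cutoff) return(TRUE)
  }
  FALSE
}

#' Resolve a multiple-profile picker
#'
#' Hits to several representatives of one family collapse to a single
#' assignment. Ternary complexes are split into chains and each chain is
#' re-triaged independently. Genuinely ambiguous non-ternary multi-family
#' hits are assigned to the lowest-E-value family with the ambiguity
#' recorded, never silently.
#'
#' @param entry The [complex_entry()] that picked multiple profiles.
#' @param result Its `triage_result` (category `multiple`).
#' @param db The representative [profile_db()].
#' @param cutoff Assignment E-value cutoff.
#' @param identity_cutoff Ternary detection cutoff.
#' @return Data frame with one row per assigned chain: `chain_id`, `family`
#'   (`NA` when a split chain hits nothing and falls through to clustering),
#'   `e_value`, `ambiguous`, `note`.
#' @export
resolve_multi <- function(entry, result, db, cutoff = 1e-3,
                          identity_cutoff = 95) {
  stopifnot(identical(result$category, "multiple"))
  if (length(result$families) == 1L) {
    best <- result$hits[[1]]
    return(data.frame(chain_id = result$query_id, family = best$family_name,
                      e_value = best$e_value, ambiguous = FALSE,
                      note = "collapsed", stringsAsFactors = FALSE))
  }
  if (detect_ternary(entry, identity_cutoff)) {
    rows <- lapply(entry$chains, function(ch) {
      tr <- triage(ch, db, cutoff)
      if (tr$category == "none")
        data.frame(chain_id = ch$seq_id, family = NA_character_,
                   e_value = NA_real_, ambiguous = FALSE,
                   note = "ternary_split_no_hit", stringsAsFactors = FALSE)
      else
        data.frame(chain_id = ch$seq_id, family = tr$hits[[1]]$family_name,
                   e_value = tr$hits[[1]]$e_value,
                   ambiguous = tr$category == "multiple",
                   note = "ternary_split", stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  best <- result$hits[[1]]
  data.frame(chain_id = result$query_id, family = best$family_name,
             e_value = best$e_value, ambiguous = TRUE,
             note = "ambiguous_multi_family", stringsAsFactors = FALSE)
}

#' Cluster unassigned sequences by pairwise association
#'
#' Builds the all-vs-all association graph (an edge wherever
#' [pairwise_association()] holds at the cutoff) and takes connected
#' components: components of size >= 2 are candidate new families,
#' singletons are loners. Single-linkage by components realises "all
#' pairwise associations": a chain a-b, b-c joins a, b, c even when a-c is
#' not itself associated. The output is independent of input order.
#'
#' @param seqs List of [seq_record()]s.
#' @param cutoff Association E-value cutoff (default 1e-3).
#' @param decoys Decoy set for calibrating single-sequence profiles.
#' @param cache Optional environment caching the profiles.
#' @return A `cluster_set`: `clusters` (list of member-id vectors, each
#'   sorted, ordered by first member) and `loners` (sorted ids).
#' @export
cluster_unassigned <- function(seqs, cutoff = 1e-3, decoys, cache = NULL) {
  if (length(seqs) == 0L)
    return(structure(list(clusters = list(), loners = character()),
                     class = "cluster_set"))
  ids <- vapply(seqs, seq_id_of, character(1))
  ord <- order(ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  n <- length(seqs)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  profs <- lapply(seqs, single_seq_profile, decoys = decoys, cache = cache)
  enc <- encode_set(seqs)
  # E[i, j]: E-value of sequence j against profile of sequence i
  em <- matrix(Inf, n, n)
  for (i in seq_len(n))
    em[i, ] <- e_value(profs[[i]], profile_scores(profs[[i]], enc))
  assoc <- pmin(em, t(em)) <= cutoff
  edges <- which(assoc & upper.tri(assoc), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(cbind(edges[, 1], edges[, 2])))
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership)
  sizes <- lengths(groups)
  clusters <- lapply(unname(groups[sizes >= 2L]), sort)
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  structure(list(clusters = clusters,
                 loners = sort(unlist(groups[sizes == 1L], use.names = FALSE)
                               %||% character())),
            class = "cluster_set")
}

#' Promote clusters and loners to new families
#'
#' Turns each cluster into one new family (provenance
#' `pairwise_association`) and each loner into a single-member family
#' (provenance `loner`). Family and group names come from the annotation
#' input — functional annotation is manual curation, consumed as given, and
#' group names are validated against the nine recognised groups.
#'
#' @param cs A `cluster_set`.
#' @param annotations Data frame with columns `member_id`, `family_name`,
#'   `group_name` covering every cluster member and loner.
#' @return List of [pf_family()] objects.
#' @export
promote_clusters <- function(cs, annotations) {
  ann <- annotations
  stopifnot(all(c("member_id", "family_name", "group_name") %in% names(ann)))
  need <- c(unlist(cs$clusters), cs$loners)
  missing <- setdiff(need, ann$member_id)
  if (length(missing) > 0L)
    stop("missing annotations for: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(ann$group_name[ann$member_id %in% need]), GROUP_NAMES)
  if (length(bad) > 0L)
    stop("unknown group name(s) in annotations: ", paste(bad, collapse = ", "))
  lookup <- ann[match(need, ann$member_id), ]
  fams <- list()
  for (cl in cs$clusters) {
    a <- lookup[match(cl[1], lookup$member_id), ]
    fams[[length(fams) + 1L]] <- pf_family(
      a$family_name, a$group_name, cl,
      provenance = setNames(rep("pairwise_association", length(cl)), cl))
  }
  for (id in cs$loners) {
    a <- lookup[match(id, lookup$member_id), ]
    fams[[length(fams) + 1L]] <- pf_family(
      a$family_name, a$group_name, id,
      provenance = setNames("loner", id))
  }
  fams
}

add_member_to_family <- function(c, family_name, member_id, provenance) {
  loc <- find_family(c, family_name)
  if (is.null(loc)) stop("no such family: ", family_name)
  f <- loc$family
  f$member_ids <- c(f$member_ids, member_id)
  f$member_provenance <- c(f$member_provenance,
                           setNames(provenance, member_id))
  f$fold_labels <- c(f$fold_labels, setNames(NA_character_, member_id))
  c$groups[[loc$gi]]$families[[loc$fi]] <- f
  validate_classification(c)
  c
}

add_families_to_classification <- function(c, fams) {
  for (f in fams) {
    gi <- which(vapply(c$groups, `[[`, character(1), "name") == f$group_name)
    if (length(gi) == 0L) {
      c$groups[[length(c$groups) + 1L]] <- pf_group(f$group_name, list(f))
    } else {
      c$groups[[gi]]$families <- c(c$groups[[gi]]$families, list(f))
    }
  }
  validate_classification(c)
  c
}

#' Run the full classification pipeline
#'
#' Filters the manifest, builds and calibrates representative profiles for
#' every legacy family (full-family alignments anchored on each
#' representative, refined over the run's sequence corpus), triages every
#' kept complex against the profile database, resolves multi-profile
#' pickers (collapsing same-family hits, splitting ternary complexes
#' chain-wise, flagging genuine ambiguity), clusters no-profile pickers into
#' candidate new families, promotes them under the supplied annotations,
#' re-selects representatives for grown and new families (retaining old
#' representatives that still give full coverage), and assembles the updated
#' classification. Fully deterministic given `config$rng_seed`.
#'
#' @param manifest List of [complex_entry()]s to classify.
#' @param sequences Named list of [seq_record()]s containing every legacy
#'   member and query chain.
#' @param legacy The existing `pf_classification`.
#' @param annotations Annotation data frame for [promote_clusters()].
#' @param config A [pf_config()].
#' @param decoys Optional decoy set (default: generated from
#'   `config$rng_seed`).
#' @param reselect Re-select representatives for grown/new families
#'   (default `TRUE`).
#' @return A `pipeline_report`: triage `counts`, `new_family_count`,
#'   `loner_count`, `assignments` data frame, `updated` classification,
#'   `repsets`, `audit` log.
#' @export
run_pipeline <- function(manifest, sequences, legacy, annotations,
                         config = pf_config(), decoys = NULL,
                         reselect = TRUE) {
  validate_classification(legacy)
  audit <- sprintf("pipeline start: %d manifest entries, %d sequences, seed %d",
                   length(manifest), length(sequences), config$rng_seed)
  if (is.null(decoys)) {
    decoys <- make_dummy_db(config$n_calibration_decoys,
                            seed = derive_seed(config$rng_seed, "decoys"))
    audit <- c(audit, sprintf("generated %d calibration decoys",
                              length(decoys)))
  }
  backend <- search_backend(sequences, decoys, config)

  filt <- filter_manifest(manifest, config)
  audit <- c(audit, sprintf("filter: %d kept, %d rejected",
                            length(filt$kept), length(filt$rejected)))

  # representative profiles from the legacy classification
  corpus <- unname(backend$seqs)
  profiles <- list()
  errors <- list()
  for (f in all_families(legacy)) {
    reps <- if (length(f$representative_ids) > 0L)
      f$representative_ids else sort(f$member_ids)[1]
    for (rid in reps) {
      p <- tryCatch(backend_family_profile(backend, rid, f, corpus = corpus),
                    error = function(e) conditionMessage(e))
      if (inherits(p, "pssm_profile"))
        profiles[[length(profiles) + 1L]] <- p
      else errors[[paste0("profile:", f$name, ":", rid)]] <- p
    }
  }
  db <- profile_db(profiles)
  audit <- c(audit, sprintf("profile database: %d profiles, %d positions",
                            length(db$profiles), db$total_size))

  counts <- c(single = 0L, multiple = 0L, none = 0L)
  assignments <- list()
  unassigned <- list()

  for (entry in filt$kept) {
    tc <- triage_complex(entry, db, config$assignment_evalue,
                         config$ternary_identity_cutoff)
    is_tern <- tc$ternary
    chains <- if (is_tern) entry$chains else entry$chains[1]
    category <- tc$category
    counts[category] <- counts[category] + 1L

    # ternary complexes are split and classified chain-wise regardless of
    # their entry-level category
    for (k in seq_along(chains)) {
      tr <- tc$chain_results[[k]]
      ch <- chains[[k]]
      if (tr$category == "none") {
        unassigned[[ch$seq_id]] <- ch
        if (is_tern) audit <- c(audit,
          sprintf("ternary chain %s: no hit, sent to clustering", ch$seq_id))
      } else {
        best <- tr$hits[[1]]
        assignments[[length(assignments) + 1L]] <- data.frame(
          complex_id = entry$complex_id, chain_id = ch$seq_id,
          family = best$family_name, category = category,
          e_value = best$e_value,
          ambiguous = tr$category == "multiple" && !is_tern,
          route = if (is_tern) "ternary_split" else "triage",
          stringsAsFactors = FALSE)
        if (tr$category == "multiple" && !is_tern)
          audit <- c(audit, sprintf(
            "ambiguous multi-family hit for %s: assigned to lowest-E '%s'",
            ch$seq_id, best$family_name))
      }
    }
    if (is_tern)
      audit <- c(audit, sprintf("ternary complex %s split into %d chains",
                                entry$complex_id, length(chains)))
  }

  cs <- cluster_unassigned(unname(unassigned),
                           cutoff = config$cluster_evalue,
                           decoys = backend$decoys_enc,
                           cache = backend$pair_cache)
  audit <- c(audit, sprintf("clustering: %d clusters, %d loners",
                            length(cs$clusters), length(cs$loners)))
  new_fams <- if (length(cs$clusters) + length(cs$loners) > 0L)
    promote_clusters(cs, annotations) else list()

  updated <- legacy
  grown <- character()
  for (a in assignments) {
    updated <- add_member_to_family(updated, a$family, a$chain_id,
                                    "representative_association")
    grown <- union(grown, a$family)
  }
  for (f in new_fams) {
    loc <- find_family(updated, f$name)
    if (is.null(loc)) {
      updated <- add_families_to_classification(updated, list(f))
    } else {
      for (m in f$member_ids)
        updated <- add_member_to_family(updated, f$name, m,
                                        unname(f$member_provenance[m]))
      grown <- union(grown, f$name)
    }
  }
  for (a in assignments) if (isTRUE(a$ambiguous))
    audit <- c(audit, sprintf("ambiguity persisted for %s", a$chain_id))

  repsets <- list()
  if (reselect) {
    for (fname in sort(grown)) {
      loc <- find_family(updated, fname)
      rs <- retain_or_replace(loc$family$representative_ids, loc$family,
                              backend, config)
      repsets[[fname]] <- rs
      updated$groups[[loc$gi]]$families[[loc$fi]]$representative_ids <-
        rs$representative_ids
      audit <- c(audit, sprintf("representatives for grown family '%s': %s (%s)",
                                fname,
                                paste(rs$representative_ids, collapse = ","),
                                attr(rs, "note")))
    }
    for (f in new_fams) {
      if (f$name %in% names(repsets)) next
      loc <- find_family(updated, f$name)
      rs <- select_representatives(loc$family, backend, config)
      repsets[[f$name]] <- rs
      updated$groups[[loc$gi]]$families[[loc$fi]]$representative_ids <-
        rs$representative_ids
      audit <- c(audit, sprintf("representatives for new family '%s': %s (%s)",
                                f$name,
                                paste(rs$representative_ids, collapse = ","),
                                rs$strategy))
    }
  }

  assignments_df <- if (length(assignments) > 0L)
    do.call(rbind, assignments) else
    data.frame(complex_id = character(), chain_id = character(),
               family = character(), category = character(),
               e_value = numeric(), ambiguous = logical(),
               route = character(), stringsAsFactors = FALSE)

  loner_fams <- vapply(new_fams, function(f)
    length(f$member_ids) == 1L &&
      identical(unname(f$member_provenance), "loner"), logical(1))
  report <- structure(list(
    counts = counts,
    n_queries = length(filt$kept),
    n_rejected = length(filt$rejected),
    new_family_count = sum(!loner_fams),
    loner_count = length(cs$loners),
    assignments = assignments_df,
    cluster_set = cs,
    updated = updated,
    repsets = repsets,
    errors = errors,
    audit = c(audit, "pipeline complete")),
    class = "pipeline_report")
  validate_classification(report$updated)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_report: %d queries (%d single / %d multiple",
                     " / %d none), %d new families, %d loners>\n"),
              x$n_queries, x$counts["single"], x$counts["multiple"],
              x$counts["none"], x$new_family_count, x$loner_count))
  invisible(x)
}

#' Planted-truth recovery rate of a pipeline run
#'
#' Fraction of truth-mapped query chains that the pipeline routed to their
#' planted family (loners count as recovered when reported as loners).
#'
#' @param report A `pipeline_report`.
#' @param truth Named map seq_id -> family name or `"loner"`.
#' @return List with `rate`, `n_correct`, `n_total` and the per-chain
#'   `detail` data frame.
#' @export
recovery_rate <- function(report, truth) {
  assigned <- setNames(report$assignments$family, report$assignments$chain_id)
  cluster_fam <- character()
  for (f in all_families(report$updated))
    for (m in f$member_ids)
      if (f$member_provenance[m] %in% c("pairwise_association", "loner"))
        cluster_fam[m] <- f$name
  ids <- names(truth)
  seen <- ids[ids %in% c(names(assigned), names(cluster_fam),
                         report$cluster_set$loners)]
  ok <- vapply(seen, function(id) {
    if (truth[id] == "loner") id %in% report$cluster_set$loners
    else if (id %in% names(assigned)) assigned[id] == truth[id]
    else if (id %in% names(cluster_fam)) cluster_fam[id] == truth[id]
    else FALSE
  }, logical(1))
  list(rate = mean(ok), n_correct = sum(ok), n_total = length(seen),
       detail = data.frame(seq_id = seen, truth = truth[seen], correct = ok,
                           row.names = NULL, stringsAsFactors = FALSE))
}
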