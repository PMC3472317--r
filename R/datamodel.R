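#' Construct a protein chain record
#'
#' One protein chain of a DNA-protein complex, identified by
#' `<complex id>_<chain letter>`, with optional source-taxon and SCOP-style
#' fold annotation.
#'
#' @param seq_id Unique identifier, conventionally `complexid_chain`.
#' @param residues Amino-acid string over the 20 standard residues plus `X`.
#' @param description Free-text description.
#' @param source_taxon One of `"prokaryote"`, `"eukaryote"`, `"virus"`,
#'   `"unknown"`.
#' @param fold_label Optional fold annotation (free text), `NA` if unknown.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(seq_id, residues, description = "",
                       source_taxon = "unknown", fold_label = NA_character_) {
  stopifnot(is_string(seq_id), is_string(residues))
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("residues must be non-empty for ", seq_id)
  bad <- setdiff(strsplit(residues, "")[[1]], ALLOWED_RESIDUES)
  if (length(bad) > 0L)
    stop("invalid residues in ", seq_id, ": ", paste(unique(bad), collapse = ""))
  source_taxon <- match.arg(source_taxon, TAXA)
  structure(list(seq_id = seq_id, residues = residues,
                 description = description, source_taxon = source_taxon,
                 fold_label = fold_label),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d aa, taxon=%s>\n",
              x$seq_id, nchar(x$residues), x$source_taxon))
  invisible(x)
}

#' Construct a DNA-protein complex entry
#'
#' A structure-like record carrying the metadata the dataset filter acts on
#' (resolution, nucleic-acid type, nucleosomal and previously-classified
#' flags) plus its protein chains.
#'
#' @param complex_id Four-character accession-like identifier.
#' @param resolution Resolution in Angstrom (positive).
#' @param nucleic_acid_type One of `"dsDNA"`, `"ssDNA"`, `"quadruplex"`,
#'   `"none"`.
#' @param nucleosomal,previously_classified Logical flags.
#' @param chains List of [seq_record()] objects (at least one).
#' @return An object of class `complex_entry`.
#' @export
complex_entry <- function(complex_id, resolution, nucleic_acid_type = "dsDNA",
                          nucleosomal = FALSE, previously_classified = FALSE,
                          chains) {
  stopifnot(is_string(complex_id))
  if (nchar(complex_id) != 4L)
    stop("complex_id must be 4 characters: ", complex_id)
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      is.na(resolution) || resolution <= 0)
    stop("resolution must be a positive number for ", complex_id)
  nucleic_acid_type <- match.arg(nucleic_acid_type, NA_TYPES)
  if (length(chains) < 1L) stop("complex ", complex_id, " has no chains")
  stopifnot(all(vapply(chains, inherits, logical(1), "seq_record")))
  structure(list(complex_id = complex_id, resolution = resolution,
                 nucleic_acid_type = nucleic_acid_type,
                 nucleosomal = isTRUE(nucleosomal),
                 previously_classified = isTRUE(previously_classified),
                 chains = chains),
            class = "complex_entry")
}

#' Construct a protein family
#'
#' The family tier of the classification: members share biological function.
#' Provenance records how each member entered the family.
#'
#' @param name Family name.
#' @param group_name Name of the enclosing group.
#' @param member_ids Character vector of member sequence ids.
#' @param representative_ids Representatives (subset of members or legacy
#'   representative ids).
#' @param provenance Named character vector, one of `"legacy"`,
#'   `"representative_association"`, `"pairwise_association"`, `"loner"` per
#'   member; defaults to `"legacy"` for all members.
#' @param fold_labels Optional named character vector of fold labels per
#'   member.
#' @return An object of class `pf_family`.
#' @export
pf_family <- function(name, group_name, member_ids,
                      representative_ids = character(),
                      provenance = NULL, fold_labels = NULL) {
  stopifnot(is_string(name), is_string(group_name))
  member_ids <- as.character(member_ids)
  if (length(member_ids) == 0L) stop("family ", name, " has no members")
  if (anyDuplicated(member_ids))
    stop("duplicate member ids in family ", name)
  if (is.null(provenance))
    provenance <- setNames(rep("legacy", length(member_ids)), member_ids)
  if (!all(member_ids %in% names(provenance)))
    stop("provenance missing for members of family ", name, ": ",
         paste(setdiff(member_ids, names(provenance)), collapse = ", "))
  provenance <- provenance[member_ids]
  if (!all(provenance %in% PROVENANCE_LEVELS))
    stop("invalid provenance values in family ", name)
  extra <- setdiff(representative_ids, member_ids)
  # representatives outside the member list are allowed only as carried-over
  # legacy representatives; they must be explicitly flagged by the caller
  if (length(extra) > 0L && !isTRUE(attr(representative_ids, "legacy_ok")))
    stop("representatives not among members of family ", name, ": ",
         paste(extra, collapse = ", "))
  if (is.null(fold_labels))
    fold_labels <- setNames(rep(NA_character_, length(member_ids)), member_ids)
  structure(list(name = name, group_name = group_name,
                 member_ids = member_ids,
                 representative_ids = as.character(representative_ids),
                 member_provenance = provenance,
                 fold_labels = fold_labels[member_ids]),
            class = "pf_family")
}

#' Construct a group of families
#'
#' The group tier: families sharing a DNA-binding structural motif (or, for
#' the Enzyme group, catalytic activity upon DNA binding).
#'
#' @param name One of the nine recognised group names (see `group_names()`).
#' @param families List of [pf_family()] objects.
#' @return An object of class `pf_group`.
#' @export
pf_group <- function(name, families = list()) {
  if (!name %in% GROUP_NAMES)
    stop("unknown group name: ", name, " (see group_names())")
  fam_names <- vapply(families, `[[`, character(1), "name")
  if (anyDuplicated(fam_names))
    stop("duplicate family names in group ", name)
  structure(list(name = name, families = families), class = "pf_group")
}

#' The nine recognised group names
#' @return Character vector of valid group names.
#' @export
group_names <- function() GROUP_NAMES

#' Construct and validate a two-tier classification
#'
#' @param groups List of [pf_group()] objects.
#' @param audit Character vector of audit-log lines carried with the object.
#' @return An object of class `pf_classification`.
#' @export
classification <- function(groups = list(), audit = character()) {
  obj <- structure(list(groups = groups, audit = audit),
                   class = "pf_classification")
  validate_classification(obj)
  obj
}

#' Validate classification invariants
#'
#' Checks that group names are unique and that every member id appears in
#' exactly one family across all groups. Called on every construction and
#' edit.
#'
#' @param c A `pf_classification`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_classification <- function(c) {
  stopifnot(inherits(c, "pf_classification"))
  gnames <- vapply(c$groups, `[[`, character(1), "name")
  if (anyDuplicated(gnames))
    stop("duplicate group names: ", paste(gnames[duplicated(gnames)], collapse = ", "))
  seen <- character()
  owner <- character()
  for (g in c$groups) for (f in g$families) {
    dup <- intersect(f$member_ids, seen)
    if (length(dup) > 0L) {
      prev <- owner[match(dup[1], seen)]
      stop("member ", dup[1], " appears in both family '", prev,
           "' and family '", f$name, "'")
    }
    seen <- c(seen, f$member_ids)
    owner <- c(owner, rep(f$name, length(f$member_ids)))
  }
  invisible(TRUE)
}

#' @export
print.pf_classification <- function(x, ...) {
  nf <- sum(vapply(x$groups, function(g) length(g$families), integer(1)))
  nm <- length(all_members(x))
  cat(sprintf("<classification: %d groups, %d families, %d members>\n",
              length(x$groups), nf, nm))
  invisible(x)
}

all_families <- function(c) {
  out <- list()
  for (g in c$groups) for (f in g$families) out[[f$name]] <- f
  out
}

all_members <- function(c) {
  unlist(lapply(all_families(c), `[[`, "member_ids"), use.names = FALSE)
}

find_family <- function(c, name) {
  for (gi in seq_along(c$groups)) {
    fams <- c$groups[[gi]]$families
    for (fi in seq_along(fams)) if (fams[[fi]]$name == name)
      return(list(gi = gi, fi = fi, family = fams[[fi]]))
  }
  NULL
}

#' Default pipeline configuration
#'
#' Houses the printed thresholds of the method: resolution cutoff 3 Angstrom,
#' profile inclusion E-value 1e-10 over at most 20 refinement iterations,
#' assignment/association E-value 1e-3, jack-knife size limit 50 members, and
#' the narrow/wide spread threshold (20 percentage points on the off-diagonal
#' identity range).
#'
#' @param resolution_cutoff Resolution cutoff in Angstrom; entries at or above
#'   it are rejected ("better than" reads as strictly less).
#' @param profile_inclusion_evalue E-value at which corpus hits join a profile
#'   during iterative refinement.
#' @param max_profile_iterations Cap on refinement iterations.
#' @param assignment_evalue E-value cutoff for family assignment and coverage.
#' @param cluster_evalue E-value cutoff for all-vs-all pairwise association.
#' @param jackknife_size_limit Families at or above this size are clustered
#'   before representative selection instead of exhaustive jack-knifing.
#' @param spread_threshold Percentage points of off-diagonal identity range
#'   separating narrow from wide families.
#' @param ternary_identity_cutoff Percent identity below which two chains of
#'   one complex count as distinct proteins.
#' @param rng_seed Integer seed driving all randomness.
#' @param n_calibration_decoys Number of unrelated decoy sequences used to
#'   calibrate profile E-values.
#' @return A `pf_config` list.
#' @export
pf_config <- function(resolution_cutoff = 3.0,
                      profile_inclusion_evalue = 1e-10,
                      max_profile_iterations = 20L,
                      assignment_evalue = 1e-3,
                      cluster_evalue = 1e-3,
                      jackknife_size_limit = 50L,
                      spread_threshold = 20,
                      ternary_identity_cutoff = 95,
                      rng_seed = 1L,
                      n_calibration_decoys = 100L) {
  cfg <- list(resolution_cutoff = resolution_cutoff,
              profile_inclusion_evalue = profile_inclusion_evalue,
              max_profile_iterations = as.integer(max_profile_iterations),
              assignment_evalue = assignment_evalue,
              cluster_evalue = cluster_evalue,
              jackknife_size_limit = as.integer(jackknife_size_limit),
              spread_threshold = spread_threshold,
              ternary_identity_cutoff = ternary_identity_cutoff,
              rng_seed = as.integer(rng_seed),
              n_calibration_decoys = as.integer(n_calibration_decoys))
  for (ev in c("profile_inclusion_evalue", "assignment_evalue", "cluster_evalue"))
    if (cfg[[ev]] <= 0 || cfg[[ev]] > 10)
      stop(ev, " must lie in (0, 10]")
  if (cfg$resolution_cutoff <= 0) stop("resolution_cutoff must be positive")
  structure(cfg, class = "pf_config")
}

#' Filter a complex manifest by the dataset rules
#'
#' Keeps complexes with resolution strictly better than the cutoff, bound to
#' double-stranded DNA, not nucleosomal and not previously classified. Each
#' rejected entry carries a single machine-readable reason code, assigned in
#' the fixed rule order `previously_classified`, `nucleic_acid_type`,
#' `nucleosomal`, `resolution` (first failing rule wins). Malformed entries
#' yield a per-entry `malformed` record rather than a global failure.
#'
#' @param entries List of [complex_entry()] objects.
#' @param config A [pf_config()].
#' @return List with `kept` (list of entries) and `rejected` (list of
#'   `list(entry=, reason=)`); together they partition the input.
#' @export
filter_manifest <- function(entries, config = pf_config()) {
  kept <- list(); rejected <- list()
  for (e in entries) {
    reason <- NULL
    if (!inherits(e, "complex_entry")) {
      reason <- "malformed"
    } else if (isTRUE(e$previously_classified)) {
      reason <- "previously_classified"
    } else if (!identical(e$nucleic_acid_type, "dsDNA")) {
      reason <- "nucleic_acid_type"
    } else if (isTRUE(e$nucleosomal)) {
      reason <- "nucleosomal"
    } else if (!(e$resolution < config$resolution_cutoff)) {
      reason <- "resolution"
    }
    if (is.null(reason)) kept[[length(kept) + 1L]] <- e
    else rejected[[length(rejected) + 1L]] <- list(entry = e, reason = reason)
  }
  list(kept = kept, rejected = rejected)
}

#' Read / write the master classification table
#'
#' The master table is a UTF-8 TSV with mandatory header and columns
#' `group`, `family`, `member_id`, `provenance`, `representative_flag`,
#' `fold_label`, one row per family membership. `write_master_table()` /
#' `read_master_table()` round-trip a classification exactly.
#'
#' @param path File path.
#' @return `read_master_table()` returns a `pf_classification`.
#' @export
read_master_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8",
                   check.names = FALSE)
  need <- c("group", "family", "member_id", "provenance",
            "representative_flag", "fold_label")
  if (!all(need %in% names(df)))
    stop("master table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  groups <- list()
  if (nrow(df) > 0L) {
    dupm <- df$member_id[duplicated(df$member_id)]
    if (length(dupm) > 0L) {
      fams <- unique(df$family[df$member_id == dupm[1]])
      stop("member ", dupm[1], " appears in both family '", fams[1],
           "' and family '", fams[length(fams)], "'")
    }
    for (gname in unique(df$group)) {
      gdf <- df[df$group == gname, , drop = FALSE]
      fams <- lapply(unique(gdf$family), function(fname) {
        fdf <- gdf[gdf$family == fname, , drop = FALSE]
        fold <- ifelse(fdf$fold_label == "", NA_character_, fdf$fold_label)
        pf_family(name = fname, group_name = gname,
                  member_ids = fdf$member_id,
                  representative_ids =
                    fdf$member_id[fdf$representative_flag == "TRUE"],
                  provenance = setNames(fdf$provenance, fdf$member_id),
                  fold_labels = setNames(fold, fdf$member_id))
      })
      groups[[length(groups) + 1L]] <- pf_group(gname, fams)
    }
  }
  classification(groups)
}

#' @rdname read_master_table
#' @param c A `pf_classification`.
#' @export
write_master_table <- function(c, path) {
  validate_classification(c)
  rows <- list()
  for (g in c$groups) for (f in g$families) for (m in f$member_ids) {
    rows[[length(rows) + 1L]] <- data.frame(
      group = g$name, family = f$name, member_id = m,
      provenance = unname(f$member_provenance[m]),
      representative_flag = m %in% f$representative_ids,
      fold_label = if (is.na(f$fold_labels[m])) "" else unname(f$fold_labels[m]),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(group = character(), family = character(),
               member_id = character(), provenance = character(),
               representative_flag = logical(), fold_label = character())
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

replace_families <- function(c, drop_names, add, group_name, audit_line) {
  groups <- c$groups
  for (gi in seq_along(groups)) {
    keep <- vapply(groups[[gi]]$families,
                   function(f) !(f$name %in% drop_names), logical(1))
    groups[[gi]]$families <- groups[[gi]]$families[keep]
  }
  gi <- which(vapply(groups, `[[`, character(1), "name") == group_name)
  if (length(gi) == 0L) {
    groups[[length(groups) + 1L]] <- pf_group(group_name, add)
  } else {
    groups[[gi]]$families <- c(groups[[gi]]$families, add)
  }
  classification(groups, audit = c(c$audit, audit_line))
}

#' Curator edit operations on a classification
#'
#' Rename a family, merge several families into one, or split a family into
#' subfamilies by an explicit member partition. Member sets and provenance are
#' conserved and every edit is appended to the classification's audit log.
#'
#' @param c A `pf_classification`.
#' @param old_name,new_name Family names for renaming.
#' @return The edited `pf_classification`.
#' @export
rename_family <- function(c, old_name, new_name) {
  loc <- find_family(c, old_name)
  if (is.null(loc)) stop("no such family: ", old_name)
  f <- loc$family
  f$name <- new_name
  replace_families(c, old_name, list(f), c$groups[[loc$gi]]$name,
                   sprintf("rename_family: '%s' -> '%s'", old_name, new_name))
}

#' @rdname rename_family
#' @param names Family names to merge (all must exist; the merged family is
#'   placed in the group of the first).
#' @export
merge_families <- function(c, names, new_name) {
  locs <- lapply(names, function(n) {
    loc <- find_family(c, n)
    if (is.null(loc)) stop("no such family: ", n)
    loc
  })
  fams <- lapply(locs, `[[`, "family")
  merged <- pf_family(
    name = new_name, group_name = c$groups[[locs[[1]]$gi]]$name,
    member_ids = unlist(lapply(fams, `[[`, "member_ids")),
    representative_ids = unlist(lapply(fams, `[[`, "representative_ids")),
    provenance = unlist(unname(lapply(fams, `[[`, "member_provenance"))),
    fold_labels = unlist(unname(lapply(fams, `[[`, "fold_labels"))))
  replace_families(c, names, list(merged), merged$group_name,
                   sprintf("merge_families: [%s] -> '%s'",
                           paste(names, collapse = ", "), new_name))
}

#' @rdname rename_family
#' @param name Family to split.
#' @param partition Named character vector mapping every member id to its
#'   subfamily name; must cover all members.
#' @export
split_family <- function(c, name, partition) {
  loc <- find_family(c, name)
  if (is.null(loc)) stop("no such family: ", name)
  f <- loc$family
  missing <- setdiff(f$member_ids, names(partition))
  if (length(missing) > 0L)
    stop("partition missing members of family ", name, ": ",
         paste(missing, collapse = ", "))
  parts <- split(f$member_ids, partition[f$member_ids])
  subs <- lapply(names(parts), function(sub) {
    ids <- parts[[sub]]
    pf_family(name = sub, group_name = f$group_name, member_ids = ids,
              representative_ids = intersect(f$representative_ids, ids),
              provenance = f$member_provenance[ids],
              fold_labels = f$fold_labels[ids])
  })
  replace_families(c, name, subs, f$group_name,
                   sprintf("split_family: '%s' -> [%s]", name,
                           paste(names(parts), collapse = ", ")))
}

#' Source-taxon distribution of a complex set
#'
#' Percentage of complexes per source taxon (a complex takes the taxon of its
#' first chain); percentages sum to 100.
#'
#' @param entries List of [complex_entry()] objects.
#' @return Named numeric vector of percentages (empty for empty input).
#' @export
report_source_distribution <- function(entries) {
  if (length(entries) == 0L) return(setNames(numeric(), character()))
  tax <- vapply(entries, function(e) e$chains[[1]]$source_taxon, character(1))
  tab <- table(factor(tax, levels = unique(tax)))
  setNames(100 * as.numeric(tab) / length(tax), names(tab))
}

#' Family-size census of a classification
#'
#' Counts single-member, two-member and multi-member (>2) families per group
#' and in total.
#'
#' @param c A `pf_classification`.
#' @return List with `per_group` (data.frame: group, single, two, multi) and
#'   `total` (named integer vector).
#' @export
report_family_sizes <- function(c) {
  validate_classification(c)
  per <- lapply(c$groups, function(g) {
    sizes <- vapply(g$families, function(f) length(f$member_ids), integer(1))
    data.frame(group = g$name,
               single = sum(sizes == 1L), two = sum(sizes == 2L),
               multi = sum(sizes > 2L), stringsAsFactors = FALSE)
  })
  per_group <- if (length(per) > 0L) do.call(rbind, per) else
    data.frame(group = character(), single = integer(), two = integer(),
               multi = integer())
  total <- c(single = sum(per_group$single), two = sum(per_group$two),
             multi = sum(per_group$multi))
  list(per_group = per_group, total = total)
}

fold_counts <- function(c) {
  labs <- unlist(lapply(all_families(c), `[[`, "fold_labels"), use.names = FALSE)
  labs <- labs[!is.na(labs) & labs != ""]
  if (length(labs) == 0L) return(list(counts = integer(), unlabelled = 0L))
  list(counts = table(labs),
       unlabelled = sum(is.na(labs) | labs == ""))
}

#' Compare fold usage between two classifications
#'
#' Tallies member counts per fold label in an old and a new classification,
#' reporting folds common to both (with fold-change of member counts), folds
#' exclusive to either, and the number of unlabelled members skipped.
#'
#' @param old,new `pf_classification` objects with (partial) fold labels.
#' @return List with `common_folds`, `old_only`, `new_only`, `counts`
#'   (data.frame: fold, old_n, new_n, fold_change for common folds) and
#'   `n_unlabelled` (old, new).
#' @export
fold_census <- function(old, new) {
  get_labs <- function(c) {
    labs <- unlist(lapply(all_families(c), `[[`, "fold_labels"),
                   use.names = FALSE)
    list(known = labs[!is.na(labs) & labs != ""],
         n_unknown = sum(is.na(labs) | labs == ""))
  }
  lo <- get_labs(old); ln <- get_labs(new)
  to <- table(lo$known); tn <- table(ln$known)
  common <- sort(intersect(names(to), names(tn)))
  counts <- data.frame(
    fold = common,
    old_n = as.integer(to[common]),
    new_n = as.integer(tn[common]),
    stringsAsFactors = FALSE)
  counts$fold_change <- counts$new_n / counts$old_n
  list(common_folds = common,
       old_only = sort(setdiff(names(to), names(tn))),
       new_only = sort(setdiff(names(tn), names(to))),
       counts = counts,
       n_unlabelled = c(old = lo$n_unknown, new = ln$n_unknown))
}
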