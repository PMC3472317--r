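#' Alignment scoring parameters
#'
#' Conventional protein defaults: BLOSUM62 substitution scores with affine
#' gaps costing `gap_open + L * gap_extend` for a gap of length `L`.
#'
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`), or a numeric matrix.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An `align_params` list.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  m <- if (is.character(substitution_matrix))
    get_submat(substitution_matrix) else substitution_matrix
  alpha <- ALLOWED_RESIDUES
  if (!all(alpha %in% rownames(m)))
    stop("substitution matrix must cover the 20 residues and X")
  structure(list(submat = m[alpha, alpha],
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# residue codes over the 21-letter alphabet (0..19 = AA20, 20 = X)
encode_full <- function(residues) {
  idx <- match(strsplit(residues, "")[[1]], ALLOWED_RESIDUES)
  if (anyNA(idx)) stop("invalid residues in sequence")
  as.integer(idx - 1L)
}

decode_full <- function(codes) {
  paste(c(ALLOWED_RESIDUES, "-")[ifelse(codes < 0L, 22L, codes + 1L)],
        collapse = "")
}

submat_cache <- new.env(parent = emptyenv())

get_submat <- function(name) {
  if (is.null(submat_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    submat_cache[[name]] <- e[[name]]
  }
  submat_cache[[name]]
}

# vectorised core: elementwise global alignment of two equal-length string
# vectors (or many-vs-one) via the native affine-gap kernel
align_batch <- function(pat, subj, params = align_params()) {
  if (any(nchar(pat) == 0L) || any(nchar(subj) == 0L))
    stop("cannot align empty sequences")
  if (length(subj) == 1L) subj <- rep(subj, length(pat))
  stopifnot(length(pat) == length(subj))
  res <- nw_align_batch_cpp(lapply(pat, encode_full),
                            lapply(subj, encode_full),
                            params$submat, params$gap_open, params$gap_extend)
  list(score = vapply(res, `[[`, numeric(1), "score"),
       pattern = vapply(res, function(r) decode_full(r$a), character(1)),
       subject = vapply(res, function(r) decode_full(r$b), character(1)))
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (via
#' Biostrings), reporting the gapped strings, the optimal score and the
#' percent identity. Percent identity is defined as identical aligned columns
#' divided by the number of columns in which neither sequence has a gap,
#' times 100 — the usual multiple-alignment convention, robust to gap length.
#'
#' @param a,b [seq_record()] objects or plain residue strings (non-empty).
#' @param params An [align_params()].
#' @return A `pairwise_alignment` list with `aligned_a`, `aligned_b`,
#'   `score`, `percent_identity`.
#' @export
global_align <- function(a, b, params = align_params()) {
  al <- align_batch(residues_of(a), residues_of(b), params)
  structure(list(aligned_a = al$pattern, aligned_b = al$subject,
                 score = al$score,
                 percent_identity = percent_identity(al$pattern, al$subject)),
            class = "pairwise_alignment")
}

#' Percent identity of two gapped strings
#'
#' @param ga,gb Gapped strings of equal length.
#' @return Identical columns / columns where neither has a gap, times 100.
#' @export
percent_identity <- function(ga, gb) {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' All-pairs percent-identity matrix of a family
#'
#' Computes global alignments for all N(N-1)/2 member pairs.
#'
#' @param members List of at least two [seq_record()] objects.
#' @param params An [align_params()].
#' @return An `identity_matrix`: list with `member_ids` and the symmetric
#'   `values` matrix (diagonal 100).
#' @export
percent_identity_matrix <- function(members, params = align_params()) {
  if (length(members) < 2L)
    stop("need at least 2 members for an identity matrix")
  ids <- vapply(members, seq_id_of, character(1))
  if (anyDuplicated(ids)) stop("duplicate member ids")
  n <- length(members)
  res <- vapply(members, residues_of, character(1))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  al <- align_batch(res[idx[, 1]], res[idx[, 2]], params)
  v <- matrix(100, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(idx))) {
    pid <- percent_identity(al$pattern[k], al$subject[k])
    v[idx[k, 1], idx[k, 2]] <- pid
    v[idx[k, 2], idx[k, 1]] <- pid
  }
  structure(list(member_ids = ids, values = v), class = "identity_matrix")
}

#' Narrow/wide call on a family's identity distribution
#'
#' A family is `wide` when the range (max - min) of its off-diagonal pairwise
#' identities exceeds the threshold, else `narrow`. Narrow families contain
#' near-identical members, so any one member can be assessed as
#' representative; wide families require jack-knifing.
#'
#' @param m An `identity_matrix`.
#' @param threshold Range threshold in percentage points.
#' @return A `spread_call` list: `call` (`"narrow"`/`"wide"`), `min`, `max`,
#'   `range`, `interquartile_range`.
#' @export
classify_spread <- function(m, threshold = 20) {
  stopifnot(inherits(m, "identity_matrix"))
  off <- m$values[upper.tri(m$values)]
  if (length(off) == 0L) stop("identity matrix has no off-diagonal values")
  rng <- max(off) - min(off)
  structure(list(call = if (rng > threshold) "wide" else "narrow",
                 min = min(off), max = max(off), range = rng,
                 interquartile_range =
                   unname(diff(quantile(off, c(0.25, 0.75))))),
            class = "spread_call")
}

#' Export an identity matrix
#'
#' `write_identity_matrix()` writes the square TSV (ids as header row and
#' first column); `identity_long_format()` returns box-plot-ready long format
#' (family, pair, identity).
#'
#' @param m An `identity_matrix`.
#' @param path Output TSV path.
#' @export
write_identity_matrix <- function(m, path) {
  df <- data.frame(member_id = m$member_ids, m$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_identity_matrix
#' @param family Family name recorded in the long format.
#' @export
identity_long_format <- function(m, family = "") {
  idx <- which(upper.tri(m$values), arr.ind = TRUE)
  data.frame(family = family,
             pair = paste(m$member_ids[idx[, 1]], m$member_ids[idx[, 2]],
                          sep = ":"),
             identity = m$values[idx],
             stringsAsFactors = FALSE)
}
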