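# Independent oracles: exhaustive enumeration of gapped alignments.
# Deliberately naive (plain recursion over alignment moves, no memoisation)
# so they share nothing with the package's dynamic-programming kernels.

# optimal global affine-gap score by enumerating every alignment path;
# a gap of length L costs gap_open + L * gap_extend
bf_global_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > la && j > lb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= la && j <= lb)
      rec(i + 1, j + 1, sc + unname(submat[ca[i], cb[j]]), "M")
    if (i <= la)
      rec(i + 1, j, sc - (if (last == "F") gap_extend
                          else gap_open + gap_extend), "F")
    if (j <= lb)
      rec(i, j + 1, sc - (if (last == "E") gap_extend
                          else gap_open + gap_extend), "E")
  }
  rec(1L, 1L, 0, "")
  best
}

# optimal local profile-vs-sequence affine score by enumerating every
# global alignment of every (profile-window, sequence-substring) pair;
# the empty alignment scores 0
bf_profile_local_score <- function(scores, residues, gap_open = 11,
                                   gap_extend = 1) {
  cs <- strsplit(residues, "")[[1]]
  m <- nrow(scores); n <- length(cs)
  cell <- function(i, j) {
    if (cs[j] %in% colnames(scores)) unname(scores[i, cs[j]]) else 0
  }
  best <- 0
  for (i0 in seq_len(m)) for (i1 in i0:m)
    for (j0 in seq_len(n)) for (j1 in j0:n) {
      la <- i1 - i0 + 1L; lb <- j1 - j0 + 1L
      sub_best <- -Inf
      rec <- function(i, j, sc, last) {
        if (i > la && j > lb) {
          if (sc > sub_best) sub_best <<- sc
          return(invisible())
        }
        if (i <= la && j <= lb)
          rec(i + 1, j + 1, sc + cell(i0 + i - 1L, j0 + j - 1L), "M")
        if (i <= la)
          rec(i + 1, j, sc - (if (last == "F") gap_extend
                              else gap_open + gap_extend), "F")
        if (j <= lb)
          rec(i, j + 1, sc - (if (last == "E") gap_extend
                              else gap_open + gap_extend), "E")
      }
      rec(1L, 1L, 0, "")
      if (sub_best > best) best <- sub_best
    }
  best
}

random_protein <- function(n, seed) {
  bg <- aa_background()
  profam:::with_seed(seed,
    paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = ""))
}
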