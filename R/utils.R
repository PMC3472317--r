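#' @useDynLib profam, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd quantile setNames
#' @importFrom utils read.delim write.table head
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

ALLOWED_RESIDUES <- c(AA20, "X")

GROUP_NAMES <- c("HTH", "Zinc Co-ordinating", "Zipper type",
                 "Other-\u03b1 Helix", "\u03b2-Sheet",
                 "\u03b2-Hairpin/Ribbon", "Other", "Enzyme",
                 "\u03b2-Propeller")

TAXA <- c("prokaryote", "eukaryote", "virus", "unknown")

NA_TYPES <- c("dsDNA", "ssDNA", "quadruplex", "none")

PROVENANCE_LEVELS <- c("legacy", "representative_association",
                       "pairwise_association", "loner")

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed from a base seed and a label, kept inside 32-bit
# integer range so adding one stream never perturbs another.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 1999999973
  as.integer(((as.numeric(seed) %% 65011 + 1) * 29269 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

residues_of <- function(x) {
  if (inherits(x, "seq_record")) x$residues else as.character(x)
}

seq_id_of <- function(x) {
  if (inherits(x, "seq_record")) x$seq_id else NA_character_
}
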