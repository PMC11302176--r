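#' @importFrom methods is
#' @importFrom stats quantile rbinom rpois runif cor prcomp
#' @importFrom utils write.table read.table
NULL

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific sub-seed from a master seed (kept below 2^31).
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1000003 + stream) %% 2147483647
}

DNA_BASES <- c("A", "C", "G", "T")

# transition partner for each base; everything else is a transversion
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

# EMBOSS-style DNA scoring used throughout (match +5 / mismatch -4)
dna_submat <- function(match = 5L, mismatch = -4L) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
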