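#' @useDynLib hdrquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rmultinom rnbinom rlnorm rgeom runif sd setNames t.test pt
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pat, x)
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (length(x) == 0L || any(is.na(x)) || !all(nzchar(x)))
    stop(what, " must be non-empty", call. = FALSE)
  bad <- !is_dna(x, allow_n = allow_n)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T",
         if (allow_n) ",N", "}", call. = FALSE)
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred+33 helpers
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

## Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
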