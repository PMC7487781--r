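## NEEDLE-equivalent global pairwise alignment (Gotoh three-state affine
## recursion, compiled) and coordinate-mapped event extraction.

#' Alignment scoring scheme
#'
#' Defaults are the EMBOSS NEEDLE DNA defaults: match +5 / mismatch -4
#' (EDNAFULL diagonal), gap open 10, gap extend 0.5 per residue. A gap of
#' length L costs `gap_open + gap_extend * L`.
#'
#' @param match match score.
#' @param mismatch mismatch score.
#' @param gap_open gap opening penalty (>= 0).
#' @param gap_extend per-residue gap extension penalty (>= 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = 10,
                           gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global alignment of `a` (reference frame) against `b` under the
#' Gotoh three-state recursion. Tie-breaking is deterministic: prefer
#' match/substitution, then deletion (gap in `b`), then insertion (gap in
#' `a`). With `end_gaps = FALSE`, terminal gaps in either sequence are free
#' (used e.g. to place a short donor on the reference).
#'
#' @param a,b DNA strings; `a` is treated as the reference.
#' @param scheme a [scoring_scheme()].
#' @param end_gaps penalize end gaps (`TRUE`, the NEEDLE default)?
#' @return an object of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length, gapped with `-`), `score`, and `ops`, a run-length
#'   data.frame of operations (`match`, `substitution`, `insertion`,
#'   `deletion`) with lengths.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(), end_gaps = TRUE) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- .gotoh_align(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
                    scheme$gap_extend, end_gaps)
  structure(list(a = a, b = b, aligned_a = r$aligned_a,
                 aligned_b = r$aligned_b, score = r$score,
                 ops = alignment_ops(r$aligned_a, r$aligned_b),
                 scheme = scheme, end_gaps = end_gaps),
            class = "pairwise_alignment")
}

## run-length operation list from a pair of gapped strings
alignment_ops <- function(aligned_a, aligned_b) {
  ca <- chars(aligned_a); cb <- chars(aligned_b)
  op <- ifelse(ca == "-", "insertion",
        ifelse(cb == "-", "deletion",
        ifelse(ca == cb, "match", "substitution")))
  r <- rle(op)
  data.frame(op = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat("Global alignment, score ", x$score, "\n", sep = "")
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    aa <- substr(x$aligned_a, s, e)
    bb <- substr(x$aligned_b, s, e)
    mid <- paste(ifelse(chars(aa) == chars(bb) & chars(aa) != "-", "|", " "),
                 collapse = "")
    cat(aa, "\n", mid, "\n", bb, "\n\n", sep = "")
  }
  invisible(x)
}

#' Extract indel and substitution events from an alignment
#'
#' Walks the alignment columns with `a` as the reference row. Adjacent gap
#' columns in one row coalesce into single events. Insertions are anchored at
#' the inter-base reference index between their flanking reference columns;
#' deletions report their 0-based reference start coordinate and length.
#'
#' @param aln a [global_align()] result with the reference as sequence `a`.
#' @return list with `indels` (data.frame: `kind`, `anchor`, `length`,
#'   `sequence`), `substitutions` (data.frame: `ref_coord`, `ref_base`,
#'   `read_base`), and gap-excluded identity statistics (`matches`,
#'   `mismatches`, `identity`).
#' @export
extract_events <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- chars(aln$aligned_a); cb <- chars(aln$aligned_b)
  ## 0-based reference coordinate of each column's reference base;
  ## for insertion columns, the inter-base anchor = index of the next
  ## reference base.
  refpos <- cumsum(ca != "-")        # after-column count of consumed ref bases
  op <- ifelse(ca == "-", "I", ifelse(cb == "-", "D",
               ifelse(ca == cb, "M", "S")))
  r <- rle(op)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  indels <- list()
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == "I") {
      anchor <- refpos[starts[k]] # bases consumed before this run
      indels[[length(indels) + 1L]] <- data.frame(
        kind = "insertion", anchor = anchor, length = r$lengths[k],
        sequence = paste(cb[starts[k]:ends[k]], collapse = ""),
        stringsAsFactors = FALSE)
    } else if (v == "D") {
      start <- refpos[starts[k]] - 1L # 0-based coord of first deleted base
      indels[[length(indels) + 1L]] <- data.frame(
        kind = "deletion", anchor = start, length = r$lengths[k],
        sequence = paste(ca[starts[k]:ends[k]], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(kind = character(0), anchor = integer(0), length = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  sub_cols <- which(op == "S")
  substitutions <- data.frame(ref_coord = refpos[sub_cols] - 1L,
                              ref_base = ca[sub_cols],
                              read_base = cb[sub_cols],
                              stringsAsFactors = FALSE)
  n_match <- sum(op == "M"); n_mm <- sum(op == "S")
  list(indels = indels, substitutions = substitutions,
       matches = n_match, mismatches = n_mm,
       identity = if (n_match + n_mm > 0) n_match / (n_match + n_mm) else NA_real_)
}
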