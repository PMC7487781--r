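## HDR/NHEJ outcome classification of merged amplicon reads.
##
## A read is NHEJ when any insertion or deletion overlaps the cut site or
## lies within the cut window (any deletion removing a base of the window's
## deleted-coordinate set or a base adjacent to the cut, any insertion
## anchored within the window's inter-base anchor set). A non-NHEJ read is
## HDR when it converts the primary donor edit, else UNMODIFIED. NHEJ takes
## precedence over conversion, so a converted read with a window indel counts
## once, as NHEJ, and keeps `primary_converted = TRUE` for optional
## HDR+indel reporting.

CATEGORIES <- c("HDR", "NHEJ", "UNMODIFIED", "DISCARD")

## does any indel event hit the cut window (or the cut itself)?
window_hit <- function(indels, window) {
  if (nrow(indels) == 0L) return(FALSE)
  ci <- window$cut_index
  ## deletions: interval [anchor, anchor+length) vs deleted coords plus the
  ## two cut-adjacent bases (the "overlaps the cutsite" core, independent of w)
  del_targets <- sort(unique(c(window$deleted, ci - 1L, ci)))
  for (k in seq_len(nrow(indels))) {
    if (indels$kind[k] == "deletion") {
      cov <- seq.int(indels$anchor[k], indels$anchor[k] + indels$length[k] - 1L)
      if (any(cov %in% del_targets)) return(TRUE)
    } else {
      if (indels$anchor[k] %in% window$anchors) return(TRUE)
    }
  }
  FALSE
}

#' Classify merged reads into editing outcomes
#'
#' Aligns each read globally to the reference (and to the donor, for a
#' diagnostic score), extracts indel and substitution events in reference
#' coordinates, and applies the outcome rules: reads with gap-excluded
#' identity below `min_identity` are discarded; reads with any indel
#' overlapping the cut site or the cut window are NHEJ; remaining reads are
#' HDR when the primary donor edit is converted, else UNMODIFIED.
#' Substitutions never count toward NHEJ.
#'
#' @param seq character vector of merged read sequences.
#' @param locus a [target_locus()].
#' @param id optional read identifiers.
#' @param min_identity gap-excluded identity below which a read is discarded
#'   (default 0.60).
#' @param scheme a [scoring_scheme()].
#' @param align_donor also align each read to the donor for a diagnostic
#'   score (default TRUE).
#' @return data.frame of read calls: `id`, `category`, `primary_converted`,
#'   `aux_converted_count`, `window_indel`, `identity`, `ref_score`,
#'   `donor_score`, `discard_reason`.
#' @export
classify_reads <- function(seq, locus, id = NULL, min_identity = 0.60,
                           scheme = scoring_scheme(), align_donor = TRUE) {
  stopifnot(inherits(locus, "target_locus"))
  n <- length(seq)
  if (n == 0L) stop("no reads to classify")
  if (is.null(id)) id <- paste0("read", seq_len(n))
  assert_dna(seq, "read sequence", allow_n = TRUE)
  ref <- locus$reference$sequence
  window <- locus$window
  edits <- locus$donor$edits
  prim <- edits[edits$role == "primary", , drop = FALSE]
  aux <- edits[edits$role == "auxiliary", , drop = FALSE]
  footprint_len <- locus$donor$footprint_end - locus$donor$offset

  batch <- .gotoh_align_batch(ref, seq, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend, TRUE)
  donor_scores <- rep(NA_real_, n)
  if (align_donor) {
    db <- .gotoh_align_batch(locus$donor$donor, seq, scheme$match,
                             scheme$mismatch, scheme$gap_open,
                             scheme$gap_extend, FALSE)
    donor_scores <- db$score
  }

  category <- character(n)
  primary_converted <- logical(n)
  aux_converted <- integer(n)
  win_indel <- logical(n)
  identity <- numeric(n)
  reason <- rep(NA_character_, n)

  converted_at <- function(subs, coord, base) {
    any(subs$ref_coord == coord & subs$read_base == base)
  }

  for (k in seq_len(n)) {
    aln <- structure(list(aligned_a = batch$aligned_a[k],
                          aligned_b = batch$aligned_b[k]),
                     class = "pairwise_alignment")
    ev <- extract_events(aln)
    identity[k] <- ev$identity
    primary_converted[k] <- converted_at(ev$substitutions, prim$ref_coord,
                                         prim$donor_base)
    aux_converted[k] <- if (nrow(aux)) sum(mapply(
      converted_at, coord = aux$ref_coord, base = aux$donor_base,
      MoreArgs = list(subs = ev$substitutions))) else 0L
    win_indel[k] <- window_hit(ev$indels, window)
    if (nchar(seq[k]) < footprint_len) {
      category[k] <- "DISCARD"; reason[k] <- "short_read"
    } else if (is.na(ev$identity) || ev$identity < min_identity) {
      category[k] <- "DISCARD"; reason[k] <- "low_identity"
    } else if (win_indel[k]) {
      category[k] <- "NHEJ"
    } else if (primary_converted[k]) {
      category[k] <- "HDR"
    } else {
      category[k] <- "UNMODIFIED"
    }
  }

  data.frame(id = id,
             category = factor(category, levels = CATEGORIES),
             primary_converted = primary_converted,
             aux_converted_count = aux_converted,
             window_indel = win_indel,
             identity = identity,
             ref_score = batch$score,
             donor_score = donor_scores,
             discard_reason = reason,
             stringsAsFactors = FALSE)
}

#' Tabulate per-sample outcome counts, rates and the HDR/NHEJ ratio
#'
#' Rates are fractions of the classified reads (`n_total`); discarded reads
#' and unmerged pairs are excluded from the denominator. The HDR/NHEJ ratio
#' is flagged undefined when no NHEJ reads were observed.
#'
#' @param calls a [classify_reads()] data.frame.
#' @param n_unmerged count of pairs that failed merging (reported, not part
#'   of any rate denominator).
#' @return an object of class `outcome_table` with counts (`n_total`,
#'   `n_hdr`, `n_nhej`, `n_unmodified`, `n_discard`, `n_unmerged`), rates
#'   (`hdr_rate`, `nhej_rate`), `hdr_nhej_ratio` and `ratio_defined`.
#' @export
quantify <- function(calls, n_unmerged = 0L) {
  tab <- table(calls$category)
  n_hdr <- unname(tab["HDR"]); n_nhej <- unname(tab["NHEJ"])
  n_unmod <- unname(tab["UNMODIFIED"]); n_disc <- unname(tab["DISCARD"])
  n_total <- n_hdr + n_nhej + n_unmod
  if (n_total == 0L) stop("zero classifiable reads")
  ratio_defined <- n_nhej > 0L
  structure(list(n_total = n_total, n_hdr = n_hdr, n_nhej = n_nhej,
                 n_unmodified = n_unmod, n_discard = n_disc,
                 n_unmerged = as.integer(n_unmerged),
                 hdr_rate = n_hdr / n_total,
                 nhej_rate = n_nhej / n_total,
                 hdr_nhej_ratio = if (ratio_defined) (n_hdr / n_total) / (n_nhej / n_total) else NA_real_,
                 ratio_defined = ratio_defined),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Editing outcomes over", x$n_total, "classified reads",
      sprintf("(+%d discarded, +%d unmerged)\n", x$n_discard, x$n_unmerged))
  cat(sprintf("  HDR        %6d  (%.2f%%)\n", x$n_hdr, 100 * x$hdr_rate))
  cat(sprintf("  NHEJ       %6d  (%.2f%%)\n", x$n_nhej, 100 * x$nhej_rate))
  cat(sprintf("  unmodified %6d  (%.2f%%)\n", x$n_unmodified,
              100 * x$n_unmodified / x$n_total))
  if (x$ratio_defined)
    cat(sprintf("  HDR/NHEJ ratio: %.4f\n", x$hdr_nhej_ratio))
  else cat("  HDR/NHEJ ratio: undefined (no NHEJ reads)\n")
  invisible(x)
}

#' @export
as.data.frame.outcome_table <- function(x, ...) {
  data.frame(n_total = x$n_total, n_hdr = x$n_hdr, n_nhej = x$n_nhej,
             n_unmodified = x$n_unmodified, n_discard = x$n_discard,
             n_unmerged = x$n_unmerged, hdr_rate = x$hdr_rate,
             nhej_rate = x$nhej_rate, hdr_nhej_ratio = x$hdr_nhej_ratio,
             ratio_defined = x$ratio_defined)
}

#' Write / read an outcome table as JSON
#'
#' @param x an [quantify()] result.
#' @param path JSON file.
#' @export
write_outcome_json <- function(x, path) {
  stopifnot(inherits(x, "outcome_table"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_outcome_json
#' @export
read_outcome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hdr_nhej_ratio <- if (is.null(x$hdr_nhej_ratio)) NA_real_ else x$hdr_nhej_ratio
  structure(x, class = "outcome_table")
}
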