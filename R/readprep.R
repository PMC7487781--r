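## Read preparation: FASTQ I/O, adapter trimming, paired-end merging.

#' Read a FASTQ file
#'
#' @param path FASTQ file, plain or gzip-compressed.
#' @return list with character vectors `id`, `seq`, `qual` (Phred+33).
#' @export
read_fastq <- function(path) {
  ## metadata-column warnings from the XStringSet conversions are noise here
  suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
    list(id = names(x),
         seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
  })
}

#' Write a FASTQ file
#'
#' Output is plain text (deterministic bytes); use downstream compression if
#' needed.
#'
#' @param id,seq,qual parallel character vectors.
#' @param path output file.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  con <- file(path, "wb") # binary mode: byte-identical across platforms
  on.exit(close(con))
  lines <- character(4L * length(id))
  lines[seq(1, by = 4, length.out = length(id))] <- paste0("@", id)
  lines[seq(2, by = 4, length.out = length(id))] <- seq
  lines[seq(3, by = 4, length.out = length(id))] <- "+"
  lines[seq(4, by = 4, length.out = length(id))] <- qual
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Trim a 3' adapter from reads
#'
#' Removes the longest 3' suffix of each read that matches a prefix of the
#' adapter with mismatch fraction `<= max_err_frac` and length
#' `>= min_overlap`; qualities are trimmed in lockstep. Reads without a
#' qualifying match pass through untouched.
#'
#' @param seq,qual parallel character vectors (Phred+33 qualities).
#' @param adapter adapter sequence (the technical sequence a read runs into
#'   when the insert is shorter than the read).
#' @param min_overlap minimum match length (default 3).
#' @param max_err_frac maximum mismatch fraction within the match (default 0.1).
#' @return list with trimmed `seq`, `qual`, and `trimmed_len` per read.
#' @export
trim_adapter <- function(seq, qual, adapter, min_overlap = 3L,
                         max_err_frac = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  .trim_adapter_batch(seq, qual, toupper(adapter), as.integer(min_overlap),
                      max_err_frac)
}

#' Merge paired-end reads into amplicon-spanning sequences
#'
#' Mate 2 is reverse-complemented, then the overlap length maximizing matched
#' bases subject to mismatch fraction `<= max_mismatch_frac` and length
#' `>= min_overlap` is chosen (ties favor the longer overlap). At discordant
#' overlap positions the base with the higher Phred quality wins and its
#' quality is kept; failure to find a qualifying overlap is recorded, not
#' raised.
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual parallel character vectors for the
#'   two mates (mate 2 in its original orientation).
#' @param id optional read identifiers.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_frac maximum overlap mismatch fraction (default 0.1).
#' @return data.frame with columns `id`, `seq`, `qual`, `overlap_len`,
#'   `merged`. Unmerged pairs have `NA` sequence.
#' @export
merge_pairs <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                        id = NULL, min_overlap = 10L, max_mismatch_frac = 0.1) {
  n <- length(r1_seq)
  stopifnot(length(r1_qual) == n, length(r2_seq) == n, length(r2_qual) == n)
  if (is.null(id)) id <- paste0("read", seq_len(n))
  r2c <- revcomp(r2_seq)
  q2c <- vapply(r2_qual, function(q) paste(rev(chars(q)), collapse = ""),
                character(1), USE.NAMES = FALSE)
  m <- .merge_pairs_batch(r1_seq, r1_qual, r2c, q2c, as.integer(min_overlap),
                          max_mismatch_frac)
  data.frame(id = id, seq = m$seq, qual = m$qual, overlap_len = m$overlap_len,
             merged = m$merged, stringsAsFactors = FALSE)
}

#' Trim and merge a FASTQ read pair into merged amplicon reads
#'
#' Convenience wrapper: reads both FASTQ files, trims the 3' adapter from
#' each mate, merges pairs, and reports merge statistics.
#'
#' @param fastq1,fastq2 FASTQ paths (mate 1, mate 2).
#' @param adapter1,adapter2 3' adapter for each mate (set `NULL` to skip
#'   trimming).
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @param adapter_min_overlap,adapter_max_err_frac see [trim_adapter()].
#' @return list with `merged` (the [merge_pairs()] data.frame) and `stats`
#'   (`n_pairs`, `n_merged`, `n_unmerged`, `mean_overlap`).
#' @export
prep_reads <- function(fastq1, fastq2, adapter1 = NULL, adapter2 = NULL,
                       min_overlap = 10L, max_mismatch_frac = 0.1,
                       adapter_min_overlap = 3L, adapter_max_err_frac = 0.1) {
  f1 <- read_fastq(fastq1)
  f2 <- read_fastq(fastq2)
  if (length(f1$seq) != length(f2$seq))
    stop("mate files differ in read count")
  if (!is.null(adapter1)) {
    t1 <- trim_adapter(f1$seq, f1$qual, adapter1, adapter_min_overlap,
                       adapter_max_err_frac)
    f1$seq <- t1$seq; f1$qual <- t1$qual
  }
  if (!is.null(adapter2)) {
    t2 <- trim_adapter(f2$seq, f2$qual, adapter2, adapter_min_overlap,
                       adapter_max_err_frac)
    f2$seq <- t2$seq; f2$qual <- t2$qual
  }
  merged <- merge_pairs(f1$seq, f1$qual, f2$seq, f2$qual, id = f1$id,
                        min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
  stats <- data.frame(n_pairs = nrow(merged),
                      n_merged = sum(merged$merged),
                      n_unmerged = sum(!merged$merged),
                      mean_overlap = mean(merged$overlap_len[merged$merged]))
  list(merged = merged, stats = stats)
}
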