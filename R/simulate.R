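## Ground-truth-labeled synthetic inputs: MiSeq-like amplicon read pairs and
## sparse single-cell count matrices.

## 240-bp synthetic amplicon with a unique protospacer+NGG placement
## (guide at 0-based 100..119, PAM AGG at 120..122, cut index 117).
## Fully synthetic stand-in for a real target amplicon; generated once with
## a fixed seed and frozen.
SYNTH_REFERENCE <- paste0(
  "TGATACTCACCGAGAAATTCCATTCACATTAGCATAATAAAAGGAAGTTATACTTGGAGG",
  "GAGAAGCAATGATTAAGCTCCGCTACCGTCAGGGTTTGTCGCGTCATAGCCAATGATTAC",
  "AGGTTCTACCCAATCGGGGCATTCGTGGTTCATAGTTTGGCACGGTTGAGTCAAAGCTGA",
  "AGATTCCAATGAACGATGATGAATCGTCTGTGTAGGACATATCCACACCGGTAAACAATG")
SYNTH_PROTOSPACER <- "GCGTCATAGCCAATGATTAC"

## Illumina TruSeq read-through technical sequences (adapter + index + flow
## cell side), long enough that short inserts never run past them.
TRUSEQ_R1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACATCACGATCTCGTATGCCGTCTTCTGCTTG"
TRUSEQ_R2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTCGGTGGTCGCCGTATCATTAAAAAA"

#' Synthetic toy target locus
#'
#' A fully synthetic 240-bp amplicon with one guide placement (cut index
#' 117) and a substitution-only donor spanning reference coordinates
#' 67..166 with a primary edit at 114 and a PAM-blocking auxiliary edit at
#' 121. The same locus ships as FASTA/YAML fixtures under
#' `inst/extdata/synthetic_locus/`.
#'
#' @param w cut-window half-width (default 3).
#' @return a [target_locus()].
#' @export
synthetic_locus <- function(w = 3L) {
  ref <- reference_amplicon(SYNTH_REFERENCE, name = "synthetic_amplicon")
  guide <- locate_guide(ref, SYNTH_PROTOSPACER, pam = "NGG")
  donor <- substr(SYNTH_REFERENCE, 68, 167) # 0-based 67..166
  substr(donor, 115 - 67, 115 - 67) <- "A"  # primary edit at 0-based 114 (G>A)
  substr(donor, 122 - 67, 122 - 67) <- "C"  # PAM-blocking aux at 121 (G>C)
  ds <- derive_edits(ref, donor, primary = "nearest-to-cut",
                     cut_index = guide$cut_index)
  target_locus(ref, guide, cut_window(guide, w = w), ds)
}

#' Amplicon read simulation configuration
#'
#' Defaults emulate the study design this simulator targets: 300-bp
#' paired-end MiSeq reads to a depth of 10,000 read pairs over a
#' few-hundred-bp amplicon. Mixture fractions are experiment knobs.
#'
#' @param locus a [target_locus()] (default [synthetic_locus()]).
#' @param n_reads read pairs to simulate (default 10000).
#' @param fractions named fractions summing to 1 over `hdr`, `nhej`,
#'   `unmodified`, and optionally `indel_outside` (an outside-window indel
#'   contaminant class).
#' @param error_rate per-base substitution sequencing error rate.
#' @param read_length maximum read length (default 300); reads are truncated
#'   at the end of the sequenced template (fragment + adapter).
#' @param deletion_prob probability an NHEJ indel is a deletion (vs
#'   insertion), default 2/3.
#' @param indel_geom_p geometric size parameter for indel lengths
#'   (default 0.3), truncated at `indel_max` (default 25).
#' @param aux_co_conversion probability each auxiliary donor edit co-converts
#'   on an HDR molecule (default 1).
#' @param low_qual_prob,qual_low,qual_high two-state per-base quality model:
#'   with `low_qual_prob` the Phred score is drawn from `qual_low`, else from
#'   `qual_high`.
#' @param adapter1,adapter2 technical read-through sequences appended after
#'   the fragment on each mate.
#' @param seed RNG seed.
#' @return an object of class `amplicon_sim_config`.
#' @export
amplicon_sim_config <- function(locus = synthetic_locus(), n_reads = 10000L,
                                fractions = c(hdr = 0.25, nhej = 0.40,
                                              unmodified = 0.35),
                                error_rate = 0.001, read_length = 300L,
                                deletion_prob = 2 / 3, indel_geom_p = 0.3,
                                indel_max = 25L, aux_co_conversion = 1,
                                low_qual_prob = 0.05, qual_low = 8:20,
                                qual_high = 35:40,
                                adapter1 = TRUSEQ_R1, adapter2 = TRUSEQ_R2,
                                seed = 1L) {
  if (n_reads < 1L) stop("n_reads must be >= 1")
  allowed <- c("hdr", "nhej", "unmodified", "indel_outside")
  if (!all(names(fractions) %in% allowed))
    stop("fractions must be named among: ", paste(allowed, collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  probs <- c(error_rate, deletion_prob, indel_geom_p, aux_co_conversion,
             low_qual_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  structure(list(locus = locus, n_reads = as.integer(n_reads),
                 fractions = fractions, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 deletion_prob = deletion_prob, indel_geom_p = indel_geom_p,
                 indel_max = as.integer(indel_max),
                 aux_co_conversion = aux_co_conversion,
                 low_qual_prob = low_qual_prob, qual_low = qual_low,
                 qual_high = qual_high, adapter1 = adapter1,
                 adapter2 = adapter2, seed = as.integer(seed)),
            class = "amplicon_sim_config")
}

## --- indel placement ambiguity -------------------------------------------
## A deletion or insertion in repeat context admits several alignment-
## equivalent placements. Ground-truth labels must not depend on which
## placement an optimal aligner picks, so strict-inside (and strict-outside)
## sampling only accepts events whose whole equivalent-placement range stays
## on one side of the window.

## range of equivalent 0-based start coords for deleting ref[s, s+len)
deletion_shift_range <- function(ref_chars, s, len) {
  n <- length(ref_chars)
  smin <- s
  while (smin > 0 && ref_chars[smin] == ref_chars[smin + len]) smin <- smin - 1L
  smax <- s
  while (smax + len < n && ref_chars[smax + 1L] == ref_chars[smax + len + 1L])
    smax <- smax + 1L
  c(smin, smax)
}

## range of equivalent inter-base anchors for inserting string S at anchor a
insertion_shift_range <- function(ref_chars, a, s_chars) {
  n <- length(ref_chars)
  len <- length(s_chars)
  amin <- a; sl <- s_chars
  while (amin > 0 && sl[len] == ref_chars[amin]) {
    sl <- c(ref_chars[amin], sl[-len]); amin <- amin - 1L
  }
  amax <- a; sr <- s_chars
  while (amax < n && sr[1] == ref_chars[amax + 1L]) {
    sr <- c(sr[-1], ref_chars[amax + 1L]); amax <- amax + 1L
  }
  c(amin, amax)
}

## sample one indel whose every equivalent placement is inside (or outside)
## the cut window; returns list(kind, anchor, length, sequence, molecule)
sample_indel <- function(cfg, inside = TRUE) {
  locus <- cfg$locus
  ref <- locus$reference$sequence
  cr <- chars(ref)
  n <- length(cr)
  win <- locus$window
  ci <- win$cut_index
  del_targets <- sort(unique(c(win$deleted, ci - 1L, ci)))
  w1 <- min(del_targets); w2 <- max(del_targets)
  a1 <- min(win$anchors); a2 <- max(win$anchors)
  for (try in 1:200) {
    len <- min(rgeom(1, cfg$indel_geom_p) + 1L, cfg$indel_max)
    is_del <- runif(1) < cfg$deletion_prob
    if (is_del) {
      if (inside) {
        d <- del_targets[sample.int(length(del_targets), 1)]
        s <- d - sample.int(len, 1) + 1L
      } else {
        s <- sample.int(n - len + 1L, 1) - 1L
      }
      if (s < 0L || s + len > n) next
      rng <- deletion_shift_range(cr, s, len)
      ## s values whose deletion intersects the window core
      hit_lo <- w1 - len + 1L; hit_hi <- w2
      if (inside) {
        if (rng[1] < hit_lo || rng[2] > hit_hi) next
      } else {
        if (rng[2] >= hit_lo && rng[1] <= hit_hi) next
      }
      molecule <- paste0(substr(ref, 1, s), substr(ref, s + len + 1L, n))
      return(list(kind = "deletion", anchor = s, length = len,
                  sequence = paste(cr[(s + 1L):(s + len)], collapse = ""),
                  molecule = molecule))
    } else {
      a <- if (inside) win$anchors[sample.int(length(win$anchors), 1)] else
        sample.int(n + 1L, 1) - 1L
      S <- sample(DNA_ALPHABET, len, replace = TRUE)
      rng <- insertion_shift_range(cr, a, S)
      if (inside) {
        if (rng[1] < a1 || rng[2] > a2) next
      } else {
        if (rng[2] >= a1 && rng[1] <= a2) next
      }
      molecule <- paste0(substr(ref, 1, a), paste(S, collapse = ""),
                         substr(ref, a + 1L, n))
      return(list(kind = "insertion", anchor = a, length = len,
                  sequence = paste(S, collapse = ""), molecule = molecule))
    }
  }
  stop("could not sample an unambiguous ", if (inside) "inside" else "outside",
       "-window indel in 200 tries")
}

apply_donor_edits <- function(ref, edits, aux_prob) {
  mol <- ref
  for (k in seq_len(nrow(edits))) {
    use <- edits$role[k] == "primary" || runif(1) < aux_prob
    if (use)
      substr(mol, edits$ref_coord[k] + 1L, edits$ref_coord[k] + 1L) <-
        edits$donor_base[k]
  }
  mol
}

add_seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  cr <- chars(seq)
  hit <- which(runif(length(cr)) < rate)
  for (i in hit) cr[i] <- sample(setdiff(DNA_ALPHABET, cr[i]), 1)
  paste(cr, collapse = "")
}

sample_quals <- function(len, cfg) {
  low <- runif(len) < cfg$low_qual_prob
  q <- integer(len)
  q[low] <- sample(cfg$qual_low, sum(low), replace = TRUE)
  q[!low] <- sample(cfg$qual_high, sum(!low), replace = TRUE)
  intToUtf8(q + 33L)
}

#' Simulate MiSeq-like amplicon read pairs with ground-truth labels
#'
#' Each read pair derives from a molecule that is the reference, the
#' reference with donor conversions, or the reference with one sampled
#' cut-window indel (strict-inside placement; optionally an outside-window
#' contaminant class). Category counts are drawn once from a multinomial,
#' then reads are built. Reads run off the fragment into the ligated
#' technical sequence and are truncated at `read_length`; per-base
#' substitution errors and two-state Phred qualities are applied.
#' Deterministic under the config seed.
#'
#' @param cfg an [amplicon_sim_config()].
#' @param dir optional output directory; when given, writes `r1.fastq`,
#'   `r2.fastq` and `truth.tsv` there.
#' @return list with `r1`, `r2` (each `id`/`seq`/`qual`), `truth`
#'   (data.frame: `id`, `category`, `indel_kind`, `indel_anchor`,
#'   `indel_length`, `primary_converted`, `aux_converted`, `molecule`),
#'   and `locus`.
#' @export
simulate_amplicon_reads <- function(cfg = amplicon_sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "amplicon_sim_config"))
  locus <- cfg$locus
  ref <- locus$reference$sequence
  footprint_len <- locus$donor$footprint_end - locus$donor$offset
  if (nchar(ref) < footprint_len)
    stop("fragment shorter than the donor footprint")
  res <- with_seed(cfg$seed, {
    fr <- cfg$fractions
    counts <- drop(rmultinom(1, cfg$n_reads, fr))
    cats <- sample(rep(names(fr), counts))
    n <- cfg$n_reads
    ids <- sprintf("read%06d", seq_len(n))
    mol <- character(n)
    indel_kind <- rep(NA_character_, n)
    indel_anchor <- rep(NA_integer_, n)
    indel_length <- rep(NA_integer_, n)
    prim_conv <- logical(n)
    aux_conv <- integer(n)
    edits <- locus$donor$edits
    n_aux <- sum(edits$role == "auxiliary")
    for (k in seq_len(n)) {
      if (cats[k] == "unmodified") {
        mol[k] <- ref
      } else if (cats[k] == "hdr") {
        mol[k] <- apply_donor_edits(ref, edits, cfg$aux_co_conversion)
        prim_conv[k] <- TRUE
        aux_conv[k] <- sum(vapply(which(edits$role == "auxiliary"),
          function(i) substr(mol[k], edits$ref_coord[i] + 1L,
                             edits$ref_coord[i] + 1L) == edits$donor_base[i],
          logical(1)))
      } else {
        ind <- sample_indel(cfg, inside = cats[k] == "nhej")
        mol[k] <- ind$molecule
        indel_kind[k] <- ind$kind
        indel_anchor[k] <- ind$anchor
        indel_length[k] <- ind$length
      }
    }
    r1_seq <- character(n); r2_seq <- character(n)
    r1_qual <- character(n); r2_qual <- character(n)
    rc_mol <- revcomp(mol)
    for (k in seq_len(n)) {
      t1 <- paste0(mol[k], cfg$adapter1)
      t2 <- paste0(rc_mol[k], cfg$adapter2)
      s1 <- substr(t1, 1, min(cfg$read_length, nchar(t1)))
      s2 <- substr(t2, 1, min(cfg$read_length, nchar(t2)))
      r1_seq[k] <- add_seq_errors(s1, cfg$error_rate)
      r2_seq[k] <- add_seq_errors(s2, cfg$error_rate)
      r1_qual[k] <- sample_quals(nchar(s1), cfg)
      r2_qual[k] <- sample_quals(nchar(s2), cfg)
    }
    truth <- data.frame(id = ids,
                        category = toupper(cats),
                        indel_kind = indel_kind,
                        indel_anchor = indel_anchor,
                        indel_length = indel_length,
                        primary_converted = prim_conv,
                        aux_converted = aux_conv,
                        molecule = mol,
                        stringsAsFactors = FALSE)
    out <- list(r1 = list(id = ids, seq = r1_seq, qual = r1_qual),
                r2 = list(id = ids, seq = r2_seq, qual = r2_qual),
                truth = truth, locus = locus)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_fastq(ids, r1_seq, r1_qual, file.path(dir, "r1.fastq"))
      write_fastq(ids, r2_seq, r2_qual, file.path(dir, "r2.fastq"))
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })
  invisible(res)
}

#' Single-cell count simulation configuration
#'
#' Emulates the statistical structure marker-module phase scoring assumes:
#' cells of a phase over-express that phase's markers by a configured fold
#' over a low off-state baseline, on top of a negative-binomial background
#' with log-normal library sizes and a small mitochondrial count share.
#'
#' @param n_cells named integer vector of cells per phase
#'   (`G0`, `G1S`, `G2M`).
#' @param fold_change marker over-expression fold in the matching phase
#'   (default 10).
#' @param n_background number of background genes (default 3000).
#' @param marker_baseline marker off-state expression relative to the median
#'   background gene (default 0.3).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param dispersion negative-binomial size parameter (default 2).
#' @param mito_frac expected mitochondrial count fraction (default 0.03).
#' @param n_lowcomplex,n_highmito extra QC-fodder cells: low-complexity
#'   cells expressing only 150 genes, and high-mito cells (~20% mito).
#' @param condition condition label attached to all cells.
#' @param seed RNG seed.
#' @return an object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells = c(G0 = 100L, G1S = 100L, G2M = 100L),
                          fold_change = 10, n_background = 3000L,
                          marker_baseline = 0.3,
                          libsize_meanlog = log(5000), libsize_sdlog = 0.3,
                          dispersion = 2, mito_frac = 0.03,
                          n_lowcomplex = 0L, n_highmito = 0L,
                          condition = "sim", seed = 1L) {
  if (any(n_cells < 1L)) stop("n_cells must be >= 1 per phase")
  if (fold_change <= 0) stop("fold_change must be > 0")
  stopifnot(all(c("G0", "G1S", "G2M") %in% names(n_cells)))
  structure(list(n_cells = n_cells, fold_change = fold_change,
                 n_background = as.integer(n_background),
                 marker_baseline = marker_baseline,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, dispersion = dispersion,
                 mito_frac = mito_frac, n_lowcomplex = as.integer(n_lowcomplex),
                 n_highmito = as.integer(n_highmito), condition = condition,
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

MITO_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
                "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
                "MT-CYB")

#' Simulate a sparse single-cell count matrix with truth phase labels
#'
#' @param cfg an [sc_sim_config()].
#' @param markers marker lists as from [cc_markers()].
#' @param dir optional output directory for Cell Ranger-layout files plus
#'   `truth.tsv`.
#' @return list with `counts` (genes x cells `dgCMatrix`), `truth`
#'   (data.frame: `barcode`, `phase`, `condition`, `qc_class`).
#' @export
simulate_sc_counts <- function(cfg = sc_sim_config(), markers = cc_markers(),
                               dir = NULL) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  if (length(markers$g1s) == 0L || length(markers$g2m) == 0L)
    stop("empty marker list")
  res <- with_seed(cfg$seed, {
    bg_names <- sprintf("BG%04d", seq_len(cfg$n_background))
    genes <- c(markers$g1s, markers$g2m, MITO_GENES, bg_names)
    ng <- length(genes)
    is_g1s <- genes %in% markers$g1s
    is_g2m <- genes %in% markers$g2m
    is_mito <- genes %in% MITO_GENES

    w <- numeric(ng)
    w[!is_g1s & !is_g2m & !is_mito] <- rlnorm(sum(!is_g1s & !is_g2m & !is_mito),
                                              0, 1)
    med_bg <- stats::median(w[!is_g1s & !is_g2m & !is_mito])
    w[is_g1s | is_g2m] <- cfg$marker_baseline * med_bg *
      rlnorm(sum(is_g1s | is_g2m), 0, 0.3)
    nonmito_total <- sum(w)
    w[is_mito] <- nonmito_total * cfg$mito_frac / (1 - cfg$mito_frac) *
      rlnorm(sum(is_mito), 0, 0.2)
    w[is_mito] <- w[is_mito] / sum(w[is_mito]) *
      nonmito_total * cfg$mito_frac / (1 - cfg$mito_frac)

    phases <- rep(names(cfg$n_cells), cfg$n_cells)
    qc_class <- rep("normal", length(phases))
    if (cfg$n_lowcomplex > 0L) {
      phases <- c(phases, rep("G0", cfg$n_lowcomplex))
      qc_class <- c(qc_class, rep("low_complexity", cfg$n_lowcomplex))
    }
    if (cfg$n_highmito > 0L) {
      phases <- c(phases, rep("G0", cfg$n_highmito))
      qc_class <- c(qc_class, rep("high_mito", cfg$n_highmito))
    }
    nc <- length(phases)
    barcodes <- sprintf("cell%05d", seq_len(nc))
    libsize <- rlnorm(nc, cfg$libsize_meanlog, cfg$libsize_sdlog)

    mat <- matrix(0L, nrow = ng, ncol = nc, dimnames = list(genes, barcodes))
    for (j in seq_len(nc)) {
      wj <- w
      if (phases[j] == "G1S") wj[is_g1s] <- wj[is_g1s] * cfg$fold_change
      if (phases[j] == "G2M") wj[is_g2m] <- wj[is_g2m] * cfg$fold_change
      ls <- libsize[j]
      if (qc_class[j] == "low_complexity") {
        keep <- sample(which(!is_mito), 150L)
        mask <- logical(ng); mask[keep] <- TRUE
        wj[!mask] <- 0
        ls <- 400
      }
      if (qc_class[j] == "high_mito") {
        wj[is_mito] <- sum(wj[!is_mito]) * 0.25 / length(MITO_GENES)
      }
      mu <- wj / sum(wj) * ls
      mat[, j] <- rnbinom(ng, mu = mu, size = cfg$dispersion)
    }
    counts <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
    truth <- data.frame(barcode = barcodes, phase = phases,
                        condition = cfg$condition, qc_class = qc_class,
                        stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      write_cellranger_mtx(counts, dir)
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(counts = counts, truth = truth)
  })
  invisible(res)
}
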