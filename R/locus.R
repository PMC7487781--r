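## Locus model: reference amplicon, guide placement, cut window, donor edits.
## All user-facing coordinates are 0-based; the cut index is an inter-base
## index, i.e. the blunt Cas9 cut lies between reference bases cut_index - 1
## and cut_index.

#' Construct a reference amplicon
#'
#' @param sequence uppercase DNA string over A/C/G/T (no N in the reference).
#' @param name identifier for the amplicon.
#' @return an object of class `reference_amplicon` with elements `name` and
#'   `sequence`.
#' @export
reference_amplicon <- function(sequence, name = "amplicon") {
  sequence <- toupper(sequence)
  assert_dna(sequence, "reference sequence", allow_n = FALSE)
  structure(list(name = name, sequence = sequence),
            class = "reference_amplicon")
}

#' Read a reference amplicon from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return a [reference_amplicon()].
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  reference_amplicon(as.character(ss[[1]]), name = names(ss)[1])
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat("Reference amplicon '", x$name, "': ", nchar(x$sequence), " bp\n", sep = "")
  invisible(x)
}

pam_regex <- function(pam) {
  assert_dna(gsub("N", "A", pam), "PAM pattern")
  gsub("N", "[ACGT]", pam)
}

#' Locate a guide (protospacer + PAM) on a reference amplicon
#'
#' Scans both strands for the unique placement of a 20-nt protospacer
#' immediately followed (3') by a PAM matching `pam` (IUPAC N allowed).
#' The blunt cut site is placed 3 nt 5' of the PAM on the protospacer strand
#' and reported as an inter-base reference index.
#'
#' @param reference a [reference_amplicon()].
#' @param protospacer 20-nt DNA string (protospacer-strand sequence).
#' @param pam PAM pattern, default `"NGG"`.
#' @return an object of class `guide_site` with elements `protospacer`,
#'   `strand` (`"+"`/`"-"`), `pam_start` (0-based reference coordinate of the
#'   first PAM base) and `cut_index` (0-based inter-base index).
#' @export
locate_guide <- function(reference, protospacer, pam = "NGG") {
  stopifnot(inherits(reference, "reference_amplicon"))
  protospacer <- toupper(protospacer)
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L)
    stop("protospacer must be 20 nt, got ", nchar(protospacer))
  ref <- reference$sequence
  L <- nchar(ref)
  lp <- nchar(protospacer)
  lpam <- nchar(pam)
  rx <- pam_regex(pam)

  hits <- list()
  ## + strand: protospacer at s..s+19 (0-based), PAM at s+20..s+20+lpam-1
  starts <- gregexpr(protospacer, ref, fixed = TRUE)[[1]]
  if (starts[1] != -1L) {
    for (p in starts) { # 1-based
      s0 <- p - 1L
      pam_seq <- substr(ref, p + lp, p + lp + lpam - 1L)
      if (nchar(pam_seq) == lpam && grepl(paste0("^", rx, "$"), pam_seq)) {
        hits[[length(hits) + 1L]] <- list(strand = "+", pam_start = s0 + lp,
                                          cut_index = s0 + lp - 3L)
      }
    }
  }
  ## - strand: revcomp(protospacer) at s..s+19, revcomp(PAM) ends at s-1
  rcp <- revcomp(protospacer)
  rcpam_rx <- {
    ## reverse complement of the PAM pattern, with N kept as wildcard
    comp <- chartr("ACGTN", "TGCAN", pam)
    rc <- paste(rev(chars(comp)), collapse = "")
    gsub("N", "[ACGT]", rc)
  }
  starts <- gregexpr(rcp, ref, fixed = TRUE)[[1]]
  if (starts[1] != -1L) {
    for (p in starts) {
      s0 <- p - 1L
      if (s0 - lpam >= 0L) {
        pam_seq <- substr(ref, p - lpam, p - 1L)
        if (grepl(paste0("^", rcpam_rx, "$"), pam_seq)) {
          hits[[length(hits) + 1L]] <- list(strand = "-", pam_start = s0 - lpam,
                                            cut_index = s0 + 3L)
        }
      }
    }
  }

  if (length(hits) != 1L)
    stop("guide placement must be unique: ", length(hits),
         " placements of protospacer+PAM found", call. = FALSE)
  h <- hits[[1]]
  structure(list(protospacer = protospacer, strand = h$strand,
                 pam_start = h$pam_start, cut_index = h$cut_index),
            class = "guide_site")
}

#' @export
print.guide_site <- function(x, ...) {
  cat("Guide site: strand ", x$strand, ", PAM at ", x$pam_start,
      ", cut between bases ", x$cut_index - 1L, " and ", x$cut_index,
      " (0-based)\n", sep = "")
  invisible(x)
}

#' Cut-site indel window
#'
#' Positions within `w` bp of the inter-base cut. Deleted-base coordinates
#' are the closed set `{cut_index - w, ..., cut_index + w - 1}` (empty for
#' `w = 0`); insertion anchors are the inter-base indices
#' `{cut_index - w, ..., cut_index + w}`. Independently of `w`, a deletion
#' removing base `cut_index - 1` or `cut_index`, or an insertion anchored
#' exactly at `cut_index`, overlaps the cut itself.
#'
#' @param site a [locate_guide()] result, or a single integer cut index.
#' @param w window half-width in bp (default 3).
#' @return an object of class `cut_window` with elements `cut_index`, `w`,
#'   `deleted` (reference coordinates) and `anchors` (inter-base indices).
#' @export
cut_window <- function(site, w = 3L) {
  ci <- if (inherits(site, "guide_site")) site$cut_index else as.integer(site)
  w <- as.integer(w)
  if (w < 0L) stop("w must be >= 0")
  deleted <- if (w > 0L) seq.int(ci - w, ci + w - 1L) else integer(0)
  anchors <- seq.int(ci - w, ci + w)
  structure(list(cut_index = ci, w = w, deleted = deleted, anchors = anchors),
            class = "cut_window")
}

#' @export
print.cut_window <- function(x, ...) {
  cat("Cut window: +/-", x$w, " bp around inter-base cut ", x$cut_index, "\n",
      sep = "")
  invisible(x)
}

#' Derive donor-programmed edit positions
#'
#' Maps a substitution-only donor (e.g. an ssODN) onto the reference with a
#' free-end-gap global alignment and turns every mismatch column into an edit
#' position. Exactly one edit is flagged as the primary (intended) edit;
#' the rest are auxiliary (e.g. PAM-blocking silent edits).
#'
#' @param reference a [reference_amplicon()].
#' @param donor donor DNA string (or a single-record FASTA path).
#' @param primary either a 0-based reference coordinate of the primary edit,
#'   or `"nearest-to-cut"` (requires `cut_index`).
#' @param cut_index inter-base cut index; needed for `"nearest-to-cut"`.
#' @param scheme a [scoring_scheme()] for the donor-reference alignment.
#' @return an object of class `donor_spec`: `donor` (sequence), `offset`
#'   (0-based reference coordinate of the donor footprint start),
#'   `footprint_end` (0-based, exclusive), and `edits`, a data.frame with
#'   columns `ref_coord`, `ref_base`, `donor_base`, `role`.
#' @export
derive_edits <- function(reference, donor, primary = "nearest-to-cut",
                         cut_index = NULL, scheme = scoring_scheme()) {
  stopifnot(inherits(reference, "reference_amplicon"))
  if (file.exists(donor) && grepl("\\.(fa|fasta|fna)$", donor, ignore.case = TRUE)) {
    donor <- as.character(Biostrings::readDNAStringSet(donor)[[1]])
  }
  donor <- toupper(donor)
  assert_dna(donor, "donor sequence")
  aln <- global_align(reference$sequence, donor, scheme = scheme,
                      end_gaps = FALSE)
  a <- chars(aln$aligned_a)
  b <- chars(aln$aligned_b)
  nb <- b != "-"
  span <- range(which(nb))
  ## internal gaps (either row) within the donor footprint are unsupported:
  ## the donor class handled here is substitution-only
  inside <- seq.int(span[1], span[2])
  if (any(b[inside] == "-") || any(a[inside] == "-"))
    stop("donor-reference alignment contains internal gaps; ",
         "only substitution-only donors are supported", call. = FALSE)
  ref_coord <- cumsum(a != "-") - 1L # 0-based coord of each reference column
  offset <- ref_coord[span[1]]
  footprint_end <- ref_coord[span[2]] + 1L
  mm <- inside[a[inside] != b[inside]]
  if (length(mm) == 0L)
    stop("no edits found: donor equals its reference footprint", call. = FALSE)
  edits <- data.frame(ref_coord = ref_coord[mm],
                      ref_base = a[mm],
                      donor_base = b[mm],
                      role = "auxiliary",
                      stringsAsFactors = FALSE)
  if (identical(primary, "nearest-to-cut")) {
    if (is.null(cut_index))
      stop("primary = \"nearest-to-cut\" requires cut_index")
    ## distance of a base coordinate to the inter-base cut
    d <- pmin(abs(edits$ref_coord - cut_index),
              abs(edits$ref_coord + 1L - cut_index))
    idx <- which.min(d)
  } else {
    primary <- as.integer(primary)
    idx <- which(edits$ref_coord == primary)
    if (length(idx) != 1L)
      stop("primary edit coordinate ", primary,
           " is not among donor-reference mismatches", call. = FALSE)
  }
  edits$role[idx] <- "primary"
  structure(list(donor = donor, offset = offset,
                 footprint_end = footprint_end, edits = edits),
            class = "donor_spec")
}

#' @export
print.donor_spec <- function(x, ...) {
  cat("Donor: ", nchar(x$donor), " nt over reference [", x$offset, ", ",
      x$footprint_end, "); ", nrow(x$edits), " programmed edit(s), primary at ",
      x$edits$ref_coord[x$edits$role == "primary"], "\n", sep = "")
  invisible(x)
}

#' Bundle a target locus
#'
#' @param reference a [reference_amplicon()].
#' @param guide a [locate_guide()] result.
#' @param window a [cut_window()].
#' @param donor_spec a [derive_edits()] result.
#' @return an object of class `target_locus`.
#' @export
target_locus <- function(reference, guide, window, donor_spec) {
  stopifnot(inherits(reference, "reference_amplicon"),
            inherits(guide, "guide_site"),
            inherits(window, "cut_window"),
            inherits(donor_spec, "donor_spec"))
  if (window$cut_index != guide$cut_index)
    stop("window and guide disagree on the cut index")
  structure(list(reference = reference, guide = guide, window = window,
                 donor = donor_spec),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  print(x$reference); print(x$guide); print(x$window); print(x$donor)
  invisible(x)
}

#' Build a target locus from a YAML config
#'
#' The config carries `reference` (FASTA path), `protospacer`, optional
#' `pam` (default NGG), optional `window` (default 3), `donor` (FASTA path or
#' literal sequence) and optional `primary_edit` (0-based coordinate or
#' `"nearest-to-cut"`). Relative paths are resolved against the config file
#' location.
#'
#' @param path YAML file.
#' @return a [target_locus()].
#' @export
load_locus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  need <- c("reference", "protospacer", "donor")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("locus config is missing field(s): ", paste(miss, collapse = ", "))
  ref <- read_reference(resolve(cfg$reference))
  guide <- locate_guide(ref, cfg$protospacer, pam = cfg$pam %||% "NGG")
  win <- cut_window(guide, w = cfg$window %||% 3L)
  donor <- cfg$donor
  if (!is_dna(toupper(donor))) donor <- resolve(donor)
  ds <- derive_edits(ref, donor, primary = cfg$primary_edit %||% "nearest-to-cut",
                     cut_index = guide$cut_index)
  target_locus(ref, guide, win, ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Verbatim HBB assay oligonucleotides
#'
#' Returns the published HBB amplicon primers and the ssODN donor string as a
#' packaged fixture. The published table lists FP2 and RP1 with an identical
#' sequence; both are stored verbatim and the collision is flagged
#' (`fp2_rp1_identical`) rather than silently resolved.
#'
#' @param quiet suppress the collision warning.
#' @return named list with `FP1`, `FP2`, `RP1`, `RP2`, `ssODN`,
#'   `fp2_rp1_identical`.
#' @export
hbb_oligos <- function(quiet = FALSE) {
  path <- system.file("extdata", "hbb_oligos.yaml", package = "hdrquant")
  x <- yaml::read_yaml(path)
  if (isTRUE(x$fp2_rp1_identical) && !quiet)
    warning("FP2 and RP1 share the identical published sequence; ",
            "stored verbatim", call. = FALSE)
  x
}
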