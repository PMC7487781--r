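## Single-cell QC filtering and marker-based cell-cycle phase scoring with an
## explicit G0 call.

#' Read a Cell Ranger-layout sparse count matrix
#'
#' Expects Matrix Market triplets plus gene and barcode text lists
#' (`matrix.mtx`, `genes.tsv` or `features.tsv`, `barcodes.tsv`).
#'
#' @param dir directory containing the three files.
#' @return list with `counts` (genes x cells `dgCMatrix`, dimnames set),
#'   `genes`, `barcodes`.
#' @export
read_cellranger_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  genes_f <- file.path(dir, "genes.tsv")
  if (!file.exists(genes_f)) genes_f <- file.path(dir, "features.tsv")
  bc_f <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, genes_f, bc_f))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes_tab <- read.delim(genes_f, header = FALSE, stringsAsFactors = FALSE)
  ## Cell Ranger genes.tsv: id, symbol; use the symbol column when present
  genes <- if (ncol(genes_tab) >= 2) genes_tab[[2]] else genes_tab[[1]]
  barcodes <- readLines(bc_f)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop("matrix dimensions do not match gene/barcode lists")
  dimnames(m) <- list(genes, barcodes)
  list(counts = m, genes = genes, barcodes = barcodes)
}

#' Write a count matrix in Cell Ranger layout
#'
#' @param counts genes x cells sparse matrix with dimnames.
#' @param dir output directory (created if needed).
#' @export
write_cellranger_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "TsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(paste(rownames(counts), rownames(counts), sep = "\t"),
             file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Per-cell QC metrics
#'
#' @param counts genes x cells matrix (sparse or dense) with gene rownames.
#' @param mito_pattern regex matching mitochondrial gene names (default
#'   `"^MT-"`).
#' @return data.frame: `barcode`, `n_genes`, `mito_fraction`.
#' @export
cell_qc <- function(counts, mito_pattern = "^MT-") {
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- grepl(mito_pattern, rownames(counts))
  mito_counts <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else
    rep(0, ncol(counts))
  mito_fraction <- ifelse(total > 0, mito_counts / total, 0)
  data.frame(barcode = colnames(counts), n_genes = as.integer(n_genes),
             mito_fraction = mito_fraction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' QC-filter cells
#'
#' Keeps cells with strictly more than `min_genes` detected genes and a
#' mitochondrial count fraction strictly below `max_mito` (both inequalities
#' strict).
#'
#' @param counts genes x cells matrix with dimnames.
#' @param min_genes detected-gene threshold (default 200, exclusive).
#' @param max_mito mitochondrial fraction threshold (default 0.06, exclusive).
#' @param mito_pattern regex matching mitochondrial gene names.
#' @return list with filtered `counts` and a per-cell `report` (QC values,
#'   `pass`, `fail_reason`).
#' @export
qc_filter <- function(counts, min_genes = 200L, max_mito = 0.06,
                      mito_pattern = "^MT-") {
  qc <- cell_qc(counts, mito_pattern)
  pass_genes <- qc$n_genes > min_genes
  pass_mito <- qc$mito_fraction < max_mito
  qc$pass <- pass_genes & pass_mito
  qc$fail_reason <- ifelse(qc$pass, NA_character_,
                    ifelse(!pass_genes & !pass_mito, "genes;mito",
                    ifelse(!pass_genes, "genes", "mito")))
  if (!any(qc$pass)) stop("no cells pass QC")
  list(counts = counts[, qc$pass, drop = FALSE], report = qc)
}

#' Default cell-cycle marker gene lists
#'
#' A reconstruction of the standard human G1/S (43 genes) and G2/M (55
#' genes) cell-cycle marker lists; user-overridable via `path` (TSV with
#' columns `symbol`, `phase` in {G1S, G2M}).
#'
#' @param path optional TSV overriding the packaged list.
#' @return list with character vectors `g1s`, `g2m`.
#' @export
cc_markers <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cell_cycle_markers.tsv", package = "hdrquant")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  list(g1s = tab$symbol[tab$phase == "G1S"],
       g2m = tab$symbol[tab$phase == "G2M"])
}

## library-size normalization (counts-per-10k) then log1p, preserving
## sparsity; all-zero cells stay all-zero
normalize_log1p <- function(counts, scale = 1e4) {
  m <- methods::as(counts, "CsparseMatrix")
  cs <- Matrix::colSums(m)
  fac <- ifelse(cs > 0, scale / cs, 0)
  m@x <- log1p(m@x * rep.int(fac, diff(m@p)))
  m
}

#' Score cells for a marker module against expression-matched controls
#'
#' Per-cell module score = mean normalized (counts-per-10k, log1p)
#' expression over the marker set minus the mean over a size-matched control
#' gene set drawn from the same average-expression bins (binned-control
#' scheme; `n_ctrl` control genes per marker, sampled without replacement
#' within each bin). Seeded and reproducible.
#'
#' @param counts genes x cells matrix with gene rownames.
#' @param markers character vector of marker gene symbols; markers missing
#'   from the matrix are dropped with a message (at least 5 must remain).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes per marker (default 100).
#' @param seed RNG seed for control sampling.
#' @return numeric vector of per-cell scores.
#' @export
module_score <- function(counts, markers, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  norm <- normalize_log1p(counts)
  present <- intersect(markers, rownames(norm))
  miss <- setdiff(markers, present)
  if (length(miss))
    message(length(miss), " marker(s) absent from the matrix: ",
            paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) ", ...")
  if (length(present) < 5L)
    stop("fewer than 5 markers found in the gene list")
  avg <- Matrix::rowMeans(norm)
  ## average-rank ties + sorted pools keep scores invariant to gene order
  bins <- cut(rank(avg, ties.method = "average"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      pool <- sort(setdiff(names(bins)[bins == bins[g]], present))
      if (length(pool) < n_ctrl)
        stop("n_ctrl (", n_ctrl, ") exceeds the control pool (",
             length(pool), ") in an expression bin", call. = FALSE)
      sample(pool, n_ctrl)
    })))
  })
  marker_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  unname(marker_mean - ctrl_mean)
}

#' Score cells for cell-cycle phase
#'
#' Computes G1/S and G2/M module scores per cell (see [module_score()]).
#'
#' @param counts genes x cells matrix with gene rownames.
#' @param g1s,g2m marker gene vectors (defaults from [cc_markers()]).
#' @inheritParams module_score
#' @return data.frame: `barcode`, `g1s_score`, `g2m_score`, `score_diff`
#'   (g1s - g2m).
#' @export
score_phase <- function(counts, g1s = NULL, g2m = NULL, n_bins = 24L,
                        n_ctrl = 100L, seed = 1L) {
  mk <- cc_markers()
  if (is.null(g1s)) g1s <- mk$g1s
  if (is.null(g2m)) g2m <- mk$g2m
  s1 <- module_score(counts, g1s, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  s2 <- module_score(counts, g2m, n_bins = n_bins, n_ctrl = n_ctrl,
                     seed = seed + 1L)
  data.frame(barcode = colnames(counts), g1s_score = s1, g2m_score = s2,
             score_diff = s1 - s2, stringsAsFactors = FALSE)
}

#' Call cell-cycle phase from module scores
#'
#' G0 when both scores are at or below `threshold` (cells lacking both
#' marker programs); otherwise G2M when the G2/M score exceeds the G1/S
#' score, else G1S (ties above threshold go to G1S).
#'
#' @param scores a [score_phase()] data.frame.
#' @param threshold score threshold for the G0 call (default 0).
#' @return the input with a `phase` factor column (levels G0, G1S, G2M).
#' @export
call_phase <- function(scores, threshold = 0) {
  stopifnot(all(c("g1s_score", "g2m_score") %in% names(scores)))
  if (any(!is.finite(scores$g1s_score)) || any(!is.finite(scores$g2m_score)))
    stop("scores must be finite")
  phase <- ifelse(scores$g1s_score <= threshold & scores$g2m_score <= threshold,
                  "G0",
                  ifelse(scores$g2m_score > scores$g1s_score, "G2M", "G1S"))
  scores$phase <- factor(phase, levels = c("G0", "G1S", "G2M"))
  scores
}

#' Per-condition cell-cycle phase fractions
#'
#' @param phase factor/character vector of per-cell phase calls.
#' @param condition per-cell condition labels (single label recycled).
#' @return data.frame: `condition`, `phase`, `n`, `fraction` (fractions sum
#'   to 1 within each condition).
#' @export
phase_fractions <- function(phase, condition = "all") {
  if (length(phase) == 0L) stop("empty condition: no cells")
  if (length(condition) == 1L) condition <- rep(condition, length(phase))
  stopifnot(length(condition) == length(phase))
  phase <- factor(phase, levels = c("G0", "G1S", "G2M"))
  out <- list()
  for (cond in unique(condition)) {
    p <- phase[condition == cond]
    if (length(p) == 0L) stop("empty condition: ", cond)
    tab <- table(p)
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, phase = names(tab), n = as.integer(tab),
      fraction = as.numeric(tab) / length(p), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
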