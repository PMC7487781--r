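# Independent oracles and small generators shared across tests.

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                collapse = "")

# Independent affine-gap optimum: plain three-matrix recursion written in R,
# separate from the compiled implementation under test. End gaps penalized.
oracle_affine_score <- function(a, b, match = 5, mismatch = -4,
                                go = 10, ge = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every alignment path (no dynamic programming):
# feasible only for tiny strings; used to certify the recursion oracle and
# the implementation at small scale.
enum_align_score <- function(a, b, match = 5, mismatch = -4,
                             go = 10, ge = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > na && j > nb) { best <<- max(best, sc); return(invisible(NULL)) }
    if (i <= na && j <= nb)
      rec(i + 1, j + 1, "M", sc + if (A[i] == B[j]) match else mismatch)
    if (i <= na)
      rec(i + 1, j, "X", sc - if (identical(prev, "X")) ge else go + ge)
    if (j <= nb)
      rec(i, j + 1, "Y", sc - if (identical(prev, "Y")) ge else go + ge)
  }
  rec(1, 1, "none", 0)
  best
}

# Exhaustive suffix-vs-adapter-prefix scan used as the trimming oracle.
trim_oracle <- function(s, adapter, min_ov = 3, max_err = 0.1) {
  l <- nchar(s); la <- nchar(adapter)
  best <- 0
  for (k in seq_len(min(l, la))) {
    if (k < min_ov) next
    suf <- substr(s, l - k + 1, l)
    pre <- substr(adapter, 1, k)
    mm <- sum(strsplit(suf, "")[[1]] != strsplit(pre, "")[[1]])
    if (mm / k <= max_err && k > best) best <- k
  }
  substr(s, 1, l - best)
}

# Toy 5-cell QC matrix with exact detected-gene counts and mito fractions:
# (250 genes, 2% mito), (150, 2%), (250, 8%), (201, 5.9%), (200, 0%).
qc_toy_matrix <- function() {
  genes <- c(paste0("MT-", 1:5), sprintf("G%03d", 1:300))
  m <- matrix(0, nrow = length(genes), ncol = 5,
              dimnames = list(genes, paste0("c", 1:5)))
  fill <- function(col, n_bg, bg_total, mito_total, n_mito) {
    if (n_mito > 0) m[seq_len(n_mito), col] <<- mito_total / n_mito
    m[5 + seq_len(n_bg), col] <<- bg_total / n_bg
  }
  fill(1, 245, 980, 20, 5)    # 250 genes, 20/1000 = 2% mito
  fill(2, 147, 490, 10, 3)    # 150 genes, 2% mito
  fill(3, 245, 920, 80, 5)    # 250 genes, 8% mito
  fill(4, 196, 941, 59, 5)    # 201 genes, 59/1000 = 5.9% mito
  fill(5, 200, 1000, 0, 0)    # 200 genes, 0% mito
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# Mutate one position (1-based) of a string.
str_sub_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

# Delete len chars starting at 0-based coord s.
str_del_at <- function(s, start0, len) {
  paste0(substr(s, 1, start0), substr(s, start0 + len + 1, nchar(s)))
}

# Insert ins at inter-base 0-based anchor a.
str_ins_at <- function(s, anchor0, ins) {
  paste0(substr(s, 1, anchor0), ins, substr(s, anchor0 + 1, nchar(s)))
}
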