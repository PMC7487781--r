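test_that("the 5-cell toy matrix is filtered by the strict QC thresholds", {
  m <- qc_toy_matrix()
  qc <- cell_qc(m, mito_pattern = "^MT-")
  expect_equal(qc$n_genes, c(250L, 150L, 250L, 201L, 200L))
  expect_equal(qc$mito_fraction, c(0.02, 0.02, 0.08, 0.059, 0), tolerance = 1e-12)
  res <- qc_filter(m, min_genes = 200, max_mito = 0.06)
  # under strict > 200 genes and < 6% mito, cells 1 and 4 survive:
  # cell 2 fails genes (150), cell 3 fails mito (8%), cell 5 sits exactly on
  # the 200-gene boundary and the printed rule is strict
  expect_equal(colnames(res$counts), c("c1", "c4"))
  expect_equal(res$report$pass, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$report$fail_reason, c(NA, "genes", "mito", NA, "genes"))
})

test_that("qc_filter is monotone in its thresholds", {
  m <- qc_toy_matrix()
  base <- qc_filter(m, min_genes = 200, max_mito = 0.06)$report$pass
  relaxed_genes <- qc_filter(m, min_genes = 100, max_mito = 0.06)$report$pass
  relaxed_mito <- qc_filter(m, min_genes = 200, max_mito = 0.10)$report$pass
  expect_true(all(relaxed_genes[base]))
  expect_true(all(relaxed_mito[base]))
  expect_error(qc_filter(m, min_genes = 300, max_mito = 0.001), "no cells pass")
})

test_that("the shipped marker reconstruction has 43 G1/S and 55 G2/M genes", {
  mk <- cc_markers()
  expect_length(mk$g1s, 43L)
  expect_length(mk$g2m, 55L)
  expect_false(any(duplicated(c(mk$g1s, mk$g2m))))
  expect_true(all(c("TYMS", "PCNA", "MCM2", "CDCA7") %in% mk$g1s))
  expect_true(all(c("CDK1", "CKS1B", "CCNB2", "CDC20") %in% mk$g2m))
})

sim_sc <- simulate_sc_counts(sc_sim_config(
  n_cells = c(G0 = 60L, G1S = 60L, G2M = 60L), fold_change = 10, seed = 61))

test_that("module scores separate spiked marker sets and zero cells score zero", {
  counts <- sim_sc$counts
  truth <- sim_sc$truth
  scores <- score_phase(counts, seed = 5)
  # sign structure: each phase over-expresses its own module only
  expect_gt(mean(scores$g1s_score[truth$phase == "G1S"]), 0)
  expect_gt(mean(scores$g2m_score[truth$phase == "G2M"]), 0)
  expect_lt(mean(scores$g1s_score[truth$phase == "G0"]), 0)
  expect_lt(mean(scores$g2m_score[truth$phase == "G0"]), 0)

  # a cell with all-zero counts scores exactly (0, 0)
  z <- counts
  z[, 1] <- 0
  sz <- score_phase(z, seed = 5)
  expect_equal(sz$g1s_score[1], 0)
  expect_equal(sz$g2m_score[1], 0)

  # permuting gene order leaves all scores unchanged
  perm <- sample(nrow(counts))
  sp <- score_phase(counts[perm, ], seed = 5)
  expect_equal(sp$g1s_score, scores$g1s_score, tolerance = 1e-12)
  expect_equal(sp$g2m_score, scores$g2m_score, tolerance = 1e-12)

  # missing markers are tolerated down to 5, then an error
  few <- counts[c(hdrquant:::MITO_GENES, rownames(counts)[200:400]), ]
  expect_error(suppressMessages(module_score(few, cc_markers()$g1s)),
               "fewer than 5")
})

test_that("phase calls follow the two-score threshold rule", {
  sc <- data.frame(barcode = c("a", "b", "c", "d"),
                   g1s_score = c(-0.2, 0.5, 0.1, 0.2),
                   g2m_score = c(-0.1, 0.1, 0.5, 0.2))
  called <- call_phase(sc)
  expect_equal(as.character(called$phase), c("G0", "G1S", "G2M", "G1S"))
  sc$g1s_score[1] <- NaN
  expect_error(call_phase(sc), "finite")
})

test_that("phase fractions sum to one per condition and conserve cells", {
  ph <- c(rep("G0", 6), rep("G1S", 3), rep("G2M", 1))
  fr <- phase_fractions(ph)
  expect_equal(fr$fraction, c(0.6, 0.3, 0.1))
  expect_equal(sum(fr$n), 10L)
  fr2 <- phase_fractions(rep("G0", 5), "x")
  expect_equal(fr2$fraction, c(1, 0, 0))
  expect_error(phase_fractions(character(0), "x"), "empty")
  two <- phase_fractions(c(ph, rep("G1S", 4)),
                         c(rep("A", 10), rep("B", 4)))
  agg <- tapply(two$fraction, two$condition, sum)
  expect_equal(as.numeric(agg), c(1, 1))
})

test_that("phase calls recover simulated truth at high marker fold change", {
  calls <- call_phase(score_phase(sim_sc$counts, seed = 9))
  acc <- mean(as.character(calls$phase) == sim_sc$truth$phase)
  expect_gte(acc, 0.90)
})

test_that("low-complexity cells are exactly the ones QC removes", {
  sim <- simulate_sc_counts(sc_sim_config(
    n_cells = c(G0 = 30L, G1S = 30L, G2M = 30L), n_lowcomplex = 8L,
    n_highmito = 5L, seed = 62))
  res <- qc_filter(sim$counts)
  bad <- sim$truth$barcode[sim$truth$qc_class != "normal"]
  expect_true(all(!res$report$pass[res$report$barcode %in% bad]))
  expect_true(all(res$report$pass[!res$report$barcode %in% bad]))
  # and the failure reasons match the injected defect
  rep_bad <- res$report[match(bad, res$report$barcode), ]
  cls <- sim$truth$qc_class[match(bad, sim$truth$barcode)]
  expect_true(all(grepl("genes", rep_bad$fail_reason[cls == "low_complexity"])))
  expect_true(all(grepl("mito", rep_bad$fail_reason[cls == "high_mito"])))
})

test_that("count matrices round-trip through the Cell Ranger layout", {
  dir <- file.path(tempdir(), "mtx_roundtrip")
  write_cellranger_mtx(sim_sc$counts, dir)
  back <- read_cellranger_mtx(dir)
  expect_equal(dim(back$counts), dim(sim_sc$counts))
  expect_equal(back$genes, rownames(sim_sc$counts))
  expect_equal(Matrix::norm(back$counts - sim_sc$counts, "F"), 0)
})
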