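test_that("guide placement on the plus strand puts the cut 3 nt 5' of the PAM", {
  set.seed(1)
  proto <- rand_dna(20)
  ref <- reference_amplicon(paste0(proto, "AGG", rand_dna(30)))
  g <- locate_guide(ref, proto)
  expect_equal(g$strand, "+")
  expect_equal(g$pam_start, 20)
  expect_equal(g$cut_index, 17)
  # reading the reference at the placement reproduces the protospacer
  expect_equal(substr(ref$sequence, 1, 20), proto)
})

test_that("minus-strand placement agrees with a brute-force scan of both strands", {
  set.seed(7)
  proto <- rand_dna(20)
  construct <- paste0(proto, "AGG")
  ref_seq <- paste0(rand_dna(37), revcomp(construct)) # 60 nt
  ref <- reference_amplicon(ref_seq)
  g <- locate_guide(ref, proto)
  expect_equal(g$strand, "-")
  expect_equal(g$cut_index, nchar(ref_seq) - 17)

  # independent brute force: try every offset on both strands
  hits <- integer(0)
  L <- nchar(ref_seq)
  for (i in 0:(L - 23)) {
    win <- substr(ref_seq, i + 1, i + 23)
    if (substr(win, 1, 20) == proto && grepl("^[ACGT]GG$", substr(win, 21, 23)))
      hits <- c(hits, i + 17)
    rcwin <- revcomp(win)
    if (substr(rcwin, 1, 20) == proto && grepl("^[ACGT]GG$", substr(rcwin, 21, 23)))
      hits <- c(hits, i + 23 - 17)
  }
  expect_equal(length(hits), 1L)
  expect_equal(g$cut_index, hits)
})

test_that("absent or ambiguous protospacers are hard errors naming the count", {
  set.seed(2)
  ref <- reference_amplicon(rand_dna(60))
  expect_error(locate_guide(ref, "ACGTACGTACGTACGTACGT"), "0 placements")
  proto <- rand_dna(20)
  ref2 <- reference_amplicon(paste0(proto, "AGG", rand_dna(5), proto, "TGG"))
  expect_error(locate_guide(ref2, proto), "2 placements")
  expect_error(locate_guide(ref, "ACGT"), "20 nt")
})

test_that("cut window sets enumerate positions within w of the inter-base cut", {
  w3 <- cut_window(20, w = 3)
  expect_equal(w3$deleted, 17:22)
  expect_equal(w3$anchors, 17:23)
  # boundary: coord 16 outside, 17 inside
  expect_false(16 %in% w3$deleted)
  expect_true(17 %in% w3$deleted)
  # degenerate window: no deleted-base coords, only the cut anchor
  w0 <- cut_window(20, w = 0)
  expect_equal(w0$deleted, integer(0))
  expect_equal(w0$anchors, 20L)
  expect_error(cut_window(20, w = -1), "w must be")
})

test_that("window sets are monotone in w", {
  for (w in 0:5) {
    a <- cut_window(31, w)
    b <- cut_window(31, w + 1)
    expect_true(all(a$deleted %in% b$deleted))
    expect_true(all(a$anchors %in% b$anchors))
  }
})

test_that("derive_edits reports every mismatch column with one primary edit", {
  set.seed(3)
  ref_seq <- rand_dna(40)
  ref <- reference_amplicon(ref_seq)
  donor <- ref_seq
  # substitutions at 0-based 18 and 24
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  donor <- str_sub_at(donor, 19, other(substr(donor, 19, 19)))
  donor <- str_sub_at(donor, 25, other(substr(donor, 25, 25)))
  ds <- derive_edits(ref, donor, primary = 18)
  expect_equal(nrow(ds$edits), 2L)
  expect_equal(ds$edits$ref_coord, c(18L, 24L))
  expect_equal(ds$edits$role, c("primary", "auxiliary"))
  # position-by-position comparison oracle: edit count = Hamming distance
  ham <- sum(strsplit(ref_seq, "")[[1]] != strsplit(donor, "")[[1]])
  expect_equal(nrow(ds$edits), ham)

  # nearest-to-cut selector with cut at 20: |18-20| < |24-20|
  ds2 <- derive_edits(ref, donor, primary = "nearest-to-cut", cut_index = 20)
  expect_equal(ds2$edits$ref_coord[ds2$edits$role == "primary"], 18L)
})

test_that("derive_edits handles a short donor placed inside a longer reference", {
  set.seed(4)
  ref_seq <- rand_dna(120)
  ref <- reference_amplicon(ref_seq)
  donor <- substr(ref_seq, 31, 90) # footprint 0-based 30..89
  donor <- str_sub_at(donor, 20, setdiff(c("A", "C", "G", "T"),
                                         substr(donor, 20, 20))[1])
  ds <- derive_edits(ref, donor, primary = "nearest-to-cut", cut_index = 60)
  expect_equal(ds$offset, 30L)
  expect_equal(ds$footprint_end, 90L)
  expect_equal(ds$edits$ref_coord, 49L) # 30 + 19
})

test_that("derive_edits rejects unsupported donors", {
  set.seed(5)
  ref_seq <- rand_dna(50)
  ref <- reference_amplicon(ref_seq)
  expect_error(derive_edits(ref, substr(ref_seq, 6, 45)), "no edits found")
  # donor with an internal deletion relative to the reference
  gapped <- paste0(substr(ref_seq, 6, 20), substr(ref_seq, 26, 45))
  expect_error(derive_edits(ref, gapped), "internal gaps")
  # primary selector not among mismatches
  donor <- str_sub_at(substr(ref_seq, 6, 45), 10,
                      setdiff(c("A", "C", "G", "T"), substr(ref_seq, 15, 15))[1])
  expect_error(derive_edits(ref, donor, primary = 3), "not among")
})

test_that("random substitution-only donors round-trip their Hamming distance", {
  set.seed(6)
  for (rep in 1:20) {
    ref_seq <- rand_dna(80)
    ref <- reference_amplicon(ref_seq)
    k <- sample(1:5, 1)
    pos <- sort(sample(10:70, k)) # 1-based, interior
    donor <- ref_seq
    for (p in pos)
      donor <- str_sub_at(donor, p, setdiff(c("A", "C", "G", "T"),
                                            substr(donor, p, p))[1])
    ds <- derive_edits(ref, donor, primary = pos[1] - 1L)
    expect_equal(nrow(ds$edits), k)
    expect_equal(ds$edits$ref_coord, pos - 1L)
    expect_equal(sum(ds$edits$role == "primary"), 1L)
  }
})

test_that("reference validation rejects bad alphabets and empty input", {
  expect_error(reference_amplicon(""), "non-empty")
  expect_error(reference_amplicon("ACGTN"), "outside")
  expect_silent(reference_amplicon("acgt")) # case-normalized
})

test_that("the packaged fixtures load: synthetic locus config and HBB oligos", {
  cfgdir <- system.file("extdata", "synthetic_locus", package = "hdrquant")
  loc <- load_locus_config(file.path(cfgdir, "locus.yaml"))
  expect_s3_class(loc, "target_locus")
  expect_equal(loc$guide$cut_index, 117L)
  expect_equal(loc$donor$edits$ref_coord, c(114L, 121L))
  expect_equal(loc$donor$edits$role, c("primary", "auxiliary"))
  # in-code locus and fixture agree
  loc2 <- synthetic_locus()
  expect_equal(loc2$reference$sequence, loc$reference$sequence)
  expect_equal(loc2$donor$donor, loc$donor$donor)

  expect_warning(o <- hbb_oligos(), "FP2 and RP1")
  expect_identical(o$FP2, o$RP1)
  expect_equal(nchar(o$ssODN), 168L)
  expect_true(grepl("^[ACGT]+$", o$ssODN))
})
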