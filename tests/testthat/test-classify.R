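# Rule-forced read classification on the synthetic locus (cut index 117,
# window +/-3, primary edit 114, auxiliary PAM edit 121).

locus <- synthetic_locus()
REF <- locus$reference$sequence
hdr_read <- function() {
  r <- str_sub_at(REF, 115, "A") # primary, 0-based 114
  str_sub_at(r, 122, "C")        # auxiliary, 0-based 121
}

test_that("reads hit the forced outcome rules exactly", {
  reads <- c(
    identity      = REF,
    full_conv     = hdr_read(),
    cut_del       = str_del_at(REF, 116, 1),           # deletes base cut-1
    conv_plus_del = str_del_at(hdr_read(), 117, 2),    # converted + window del
    far_ins       = str_ins_at(REF, 121, "C"),         # anchored 4 bp from cut
    aux_only      = str_sub_at(REF, 122, "C")          # PAM-silent edit only
  )
  calls <- classify_reads(unname(reads), locus, id = names(reads))
  got <- setNames(as.character(calls$category), calls$id)
  expect_equal(got[["identity"]], "UNMODIFIED")
  expect_equal(got[["full_conv"]], "HDR")
  expect_equal(got[["cut_del"]], "NHEJ")
  expect_equal(got[["conv_plus_del"]], "NHEJ") # window rule supersedes
  expect_equal(got[["far_ins"]], "UNMODIFIED") # outside the w=3 window
  expect_equal(got[["aux_only"]], "UNMODIFIED")
  # flags allow HDR+indel recomputation and aux reporting
  expect_true(calls$primary_converted[calls$id == "conv_plus_del"])
  expect_equal(calls$aux_converted_count[calls$id == "aux_only"], 1L)
  expect_equal(calls$aux_converted_count[calls$id == "full_conv"], 1L)
  expect_false(calls$window_indel[calls$id == "far_ins"])
})

test_that("insertions anchored exactly on the window boundary are NHEJ", {
  # anchors {114..120} for w=3; 120 inside, 121 outside (checked above)
  r <- str_ins_at(REF, 120, "C") # base at 0-based 120 is "A", ref[121]="G"
  calls <- classify_reads(r, locus)
  expect_equal(as.character(calls$category), "NHEJ")
})

test_that("low-identity and too-short reads are discarded with a reason", {
  set.seed(41)
  cr <- strsplit(REF, "")[[1]]
  hit <- which(runif(length(cr)) < 0.25) # scattered divergence
  for (i in hit) cr[i] <- sample(setdiff(c("A", "C", "G", "T"), cr[i]), 1)
  diverged <- paste(cr, collapse = "")
  short <- substr(REF, 1, 60) # shorter than the 100-nt donor footprint
  calls <- classify_reads(c(diverged, short), locus, min_identity = 0.95)
  expect_equal(as.character(calls$category), c("DISCARD", "DISCARD"))
  expect_equal(calls$discard_reason, c("low_identity", "short_read"))
  expect_error(quantify(calls), "zero classifiable")
  # the same diverged read survives at a permissive threshold
  keep <- classify_reads(diverged, locus, min_identity = 0.5)
  expect_false(keep$category == "DISCARD")
})

test_that("outcome tables report rates over classified reads and the ratio", {
  cats <- c(rep("HDR", 2), rep("NHEJ", 3), rep("UNMODIFIED", 5))
  calls <- data.frame(id = seq_along(cats),
                      category = factor(cats, levels = hdrquant:::CATEGORIES))
  oc <- quantify(calls, n_unmerged = 7)
  expect_equal(oc$n_total, 10L)
  expect_equal(oc$hdr_rate, 0.20)
  expect_equal(oc$nhej_rate, 0.30)
  expect_equal(oc$hdr_nhej_ratio, 2 / 3, tolerance = 1e-12)
  expect_equal(oc$n_unmerged, 7L)
  # all-unmodified: rates zero, ratio undefined-flagged
  calls0 <- data.frame(id = 1:4,
                       category = factor(rep("UNMODIFIED", 4),
                                         levels = hdrquant:::CATEGORIES))
  oc0 <- quantify(calls0)
  expect_equal(oc0$hdr_rate, 0)
  expect_false(oc0$ratio_defined)
  expect_true(is.na(oc0$hdr_nhej_ratio))
  # JSON round trip
  f <- tempfile(fileext = ".json")
  write_outcome_json(oc, f)
  back <- read_outcome_json(f)
  expect_equal(back$n_hdr, oc$n_hdr)
  expect_equal(back$hdr_nhej_ratio, oc$hdr_nhej_ratio, tolerance = 1e-12)
})

test_that("every read maps to exactly one category and counts conserve n", {
  cfg <- amplicon_sim_config(n_reads = 120, error_rate = 0.002, seed = 42)
  sim <- simulate_amplicon_reads(cfg)
  calls <- classify_reads(sim$truth$molecule, locus, id = sim$truth$id,
                          align_donor = FALSE)
  expect_equal(nrow(calls), 120L)
  expect_false(any(is.na(calls$category)))
  oc <- quantify(calls)
  expect_equal(oc$n_hdr + oc$n_nhej + oc$n_unmodified, oc$n_total)
  expect_equal(oc$n_total + oc$n_discard, 120L)
  # permutation invariance of the table
  perm <- sample(120)
  oc2 <- quantify(calls[perm, ])
  expect_equal(as.data.frame(oc2), as.data.frame(oc))
})

test_that("perfect reads with strictly inside/outside indels classify at 100%", {
  cfg <- amplicon_sim_config(
    n_reads = 150, error_rate = 0, seed = 43,
    fractions = c(hdr = 0.25, nhej = 0.35, unmodified = 0.2,
                  indel_outside = 0.2))
  sim <- simulate_amplicon_reads(cfg)
  calls <- classify_reads(sim$truth$molecule, locus, id = sim$truth$id,
                          align_donor = FALSE)
  expected <- c(HDR = "HDR", NHEJ = "NHEJ", UNMODIFIED = "UNMODIFIED",
                INDEL_OUTSIDE = "UNMODIFIED")[sim$truth$category]
  expect_equal(as.character(calls$category), unname(expected))
})

test_that("widening the window never decreases NHEJ nor increases HDR", {
  cfg <- amplicon_sim_config(n_reads = 250, error_rate = 0.001, seed = 44)
  sim <- simulate_amplicon_reads(cfg)
  n_nhej <- n_hdr <- integer(0)
  for (w in 0:6) {
    loc_w <- synthetic_locus(w = w)
    calls <- classify_reads(sim$truth$molecule, loc_w, align_donor = FALSE)
    oc <- quantify(calls)
    n_nhej <- c(n_nhej, oc$n_nhej)
    n_hdr <- c(n_hdr, oc$n_hdr)
  }
  expect_true(all(diff(n_nhej) >= 0))
  expect_true(all(diff(n_hdr) <= 0))
})

test_that("sequencing substitutions alone never produce NHEJ calls", {
  set.seed(45)
  reads <- vapply(1:25, function(i) {
    r <- REF
    for (p in sample(nchar(REF), 4)) # 4 random substitution errors
      r <- str_sub_at(r, p, sample(c("A", "C", "G", "T"), 1))
    r
  }, character(1))
  calls <- classify_reads(reads, locus, align_donor = FALSE)
  expect_false(any(calls$category == "NHEJ"))
})
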