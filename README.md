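# hdrquant

Quantification of CRISPR-Cas9 editing outcomes from next-generation amplicon
sequencing, for experiments that compare homology-directed repair (HDR)
against end-joining (NHEJ) across sorted cell populations — for example
hematopoietic stem and progenitor subpopulations edited at the *HBB* locus
with an ssODN donor. The package also implements the accompanying single-cell
RNA-seq QC filter and marker-based cell-cycle phase caller (with an explicit
G0/quiescence call), and seeded simulators that generate ground-truth-labeled
MiSeq-like read pairs and sparse count matrices so the whole pipeline can be
exercised and validated without any external data.

## What it computes

Merged amplicon reads are aligned globally to the reference with an
affine-gap Needleman–Wunsch (Gotoh) aligner using the EMBOSS NEEDLE DNA
defaults (match +5, mismatch −4, gap open 10, gap extend 0.5). With the
blunt Cas9 cut placed 3 nt 5′ of the NGG PAM (an inter-base index *c*), each
read is classified by two rules over its indel events and donor-programmed
substitutions:

* **NHEJ** — any insertion or deletion overlaps the cut site or lies within
  *w* = 3 bp of either side of it (deletions touching coordinates
  {c−w, …, c+w−1} or the cut-adjacent bases; insertions anchored in
  {c−w, …, c+w}).
* **HDR** — no such indel, and the primary (intended, non-PAM) donor edit is
  converted to the donor base. Auxiliary PAM-blocking edits are reported but
  do not gate the call.
* **UNMODIFIED** — everything else. Reads below an identity threshold or
  shorter than the donor footprint are discarded and excluded from all
  denominators.

Per sample, rates are fractions of classified reads, and the headline
comparative metric is the HDR/NHEJ ratio. Across samples the package
reports group means ± SD (n−1), fold changes of means and unpaired
two-tailed Student *t* tests (Welch optional), e.g. for ratios between
culture conditions or cell-cycle-sorted fractions.

The single-cell stage keeps cells with > 200 detected genes and < 6%
mitochondrial expression (strict inequalities), scores each cell against
43 G1/S and 55 G2/M marker genes using binned expression-matched control
sets, and calls **G0** when both module scores are at or below 0 —
otherwise the larger score decides G1/S vs G2/M.

## Worked example

Simulate a 2,000-pair MiSeq-like sample over the packaged synthetic locus
(15% HDR / 45% NHEJ molecules, 0.1% per-base error), then run the full
quantification pipeline (adapter trim → merge → classify → count):

```r
library(hdrquant)

cfg <- amplicon_sim_config(n_reads = 2000, error_rate = 0.001,
                           fractions = c(hdr = 0.15, nhej = 0.45,
                                         unmodified = 0.40),
                           seed = 42)
simulate_amplicon_reads(cfg, dir = "sim")

oc <- run_quantify(list(fastq1 = "sim/r1.fastq", fastq2 = "sim/r2.fastq",
                        locus = system.file("extdata", "synthetic_locus",
                                            "locus.yaml", package = "hdrquant"),
                        sample = "demo"),
                   "out")
print(oc)
#> Editing outcomes over 2000 classified reads (+0 discarded, +0 unmerged)
#>   HDR           288  (14.40%)
#>   NHEJ          891  (44.55%)
#>   unmodified    821  (41.05%)
#>   HDR/NHEJ ratio: 0.3232
```

The recovered rates sit within binomial sampling error of the simulated
truth (15% / 45%), and the HDR/NHEJ ratio (0.32 vs truth 0.33) is the
per-sample statistic that `ratio_table()` / `run_compare()` then summarize
and compare across conditions with fold changes and *t* tests. `out/`
contains the per-read calls TSV, the outcome table as TSV and JSON, and a
provenance record.

A thin command-line dispatcher over the same functions ships at
`system.file("cli", "hdrquant.R", package = "hdrquant")` with subcommands
`quantify`, `compare`, `simulate`, `scphase`.

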