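---
title: "Classifying HDR and NHEJ editing outcomes in amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying HDR and NHEJ editing outcomes in amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrquant)
```

## The measurement problem

A Cas9 ribonucleoprotein cuts a target locus; the cell repairs the
double-strand break either by end joining (NHEJ), leaving insertions or
deletions at the break, or by homology-directed repair (HDR) from a
single-stranded oligonucleotide donor, copying in programmed substitutions.
Deep amplicon sequencing of the locus turns the repair outcome of every
allele into a read-classification problem: each merged read pair must be
assigned to HDR, NHEJ, or unmodified, and per-sample rates and the HDR/NHEJ
ratio become the quantities compared across sorted cell populations,
culture conditions and time points. This package implements that
classification and the surrounding statistics, together with the single-cell
cell-cycle scoring used to connect repair outcomes to quiescence, and
simulators that generate labeled inputs for every stage.

## Coordinate model

All coordinates are 0-based. The blunt Cas9 cut is represented as an
*inter-base* index `c`: the cut lies between reference bases `c - 1` and
`c`, three nucleotides 5′ of the NGG PAM on the protospacer strand. This
makes the symmetric indel window unambiguous:

* deleted-base coordinates within the window: `{c - w, ..., c + w - 1}`
  (empty at `w = 0`);
* insertion anchors (inter-base) within the window: `{c - w, ..., c + w}`.

Independently of `w`, a deletion removing base `c - 1` or `c`, or an
insertion anchored exactly at `c`, *overlaps the cut* itself. For the
default `w = 3` the overlap set is contained in the window sets, so the two
formulations coincide; keeping the overlap core explicit makes the `w = 0`
degenerate window behave sensibly (only cut-touching events qualify).

`locate_guide()` scans both strands for the unique protospacer+PAM
placement and refuses ambiguous or absent guides with an error naming the
placement count — a silent wrong placement would corrupt every downstream
coordinate.

## Alignment

Reads are aligned to the reference with a three-state affine-gap global
aligner (Gotoh recursion) compiled in C++. The scoring scheme defaults to
the EMBOSS NEEDLE DNA defaults — match +5, mismatch −4 (the EDNAFULL
diagonal), gap open 10, gap extend 0.5, a gap of length $L$ costing
$10 + 0.5L$ — because the classification rules were formulated around
NEEDLE-style global alignments. End gaps are penalized by default (merged
reads span the amplicon); a free-end-gap mode exists and is used internally
to place the shorter donor on the reference. Tie-breaking is fixed
(match/substitution, then deletion, then insertion) so alignments are
bit-reproducible. Tests certify the implementation three independent ways:
full enumeration of every alignment path at tiny lengths, an independent
plain-R affine recursion on a thousand random pairs, and score agreement
with `Biostrings::pairwiseAlignment` on longer pairs.

`extract_events()` walks the alignment columns, coalescing adjacent gap
columns into single indel events with reference coordinates (deletions:
start + length; insertions: inter-base anchor) and collecting substitutions.

## Classification rules and their edge cases

For each merged read, in order:

1. **Discard** reads shorter than the donor footprint, or whose
   gap-excluded identity (matches / (matches + mismatches) over aligned
   columns) falls below `min_identity` (default 0.60). Note that with
   NEEDLE-default scoring, cheap gap extension lets optimal alignments gap
   around divergence, so column identity stays high (~0.7) even for heavily
   diverged same-length reads: the default threshold mainly guards
   truncated or partially matching chimeric reads, and stricter filtering
   is available by raising the knob.
2. **NHEJ** if any indel event intersects the cut window or overlaps the
   cut, as defined above. This rule is unconditional: a read that both
   converts the donor edit and carries a window indel counts once, as NHEJ,
   with `primary_converted = TRUE` retained so an HDR+indel tally can be
   recomputed if wanted. Substitutions never count toward NHEJ — a literal
   reading of "insertion or deletion" that also makes the call robust to
   sequencing errors.
3. **HDR** if the primary donor edit position carries the donor base.
   Auxiliary (PAM-blocking, silent) edits are counted in
   `aux_converted_count` but do not gate HDR; a read converting only
   auxiliary edits is UNMODIFIED.
4. **UNMODIFIED** otherwise.

The primary edit defaults to the donor-programmed substitution nearest the
cut (overridable by explicit coordinate), since published assay materials
often do not pin the intended edit's coordinate. Donors are restricted to
the substitution-only class: a donor whose placement on the reference
requires internal gaps is rejected, because the HDR rule presumes
substitution conversion at fixed reference coordinates.

Rates are fractions of *classified* reads; discarded reads and unmerged
pairs are excluded from the denominator and reported separately. The
HDR/NHEJ ratio is flagged undefined when a sample has no NHEJ reads, and
undefined ratios are excluded from group means with an excluded count
rather than imputed.

## Read preparation

Adapter trimming removes the longest read suffix matching a prefix of the
configured technical sequence (mismatch fraction ≤ 0.1, ≥ 3 bp). Merging
reverse-complements mate 2 and chooses the overlap maximizing matched bases
subject to a mismatch fraction ≤ 0.1 and a minimum overlap of 10 bp; at
discordant overlap columns the higher-Phred base wins (ties to mate 1) and
the winning quality is kept. These are conventional joiner semantics with
all knobs exposed; pairs that fail to merge are counted and excluded rather
than analyzed single-ended, since a half-amplicon read cannot be evaluated
against window rules that sit mid-amplicon.

## Group statistics

`compare_groups()` uses the pooled-variance Student *t* test by default —
the classic "unpaired t test" of point-and-click statistics packages — with
Welch available as an option, and reports fold changes of group means with
significance tiers at 0.05/0.01/0.001. No multiple-testing correction is
applied; comparisons are reported per pair, and the output notes this. *t*
and *p* are scale-invariant, so percentages and fractions give identical
tests.

## Single-cell QC and cell-cycle calling

Cells pass QC with strictly more than 200 detected genes and strictly less
than 6% of counts on mitochondrial genes (names matching `^MT-`). Both
inequalities are strict as printed in the protocols this follows; the
boundary cell with exactly 200 genes fails.

Phase scoring normalizes counts per 10k and log1p-transforms, then scores
each cell for a marker module as the mean normalized expression over the
markers minus the mean over control genes drawn from the same
average-expression bins (24 bins over average-expression ranks, 100
controls per marker, sampled without replacement, seeded). Binned controls
subtract the cell's overall expression level, so the score measures
program-specific activity. The G1/S and G2/M marker lists ship as a
reconstruction of the standard human cell-cycle lists (43 + 55 gene
symbols; the file under `inst/extdata/` is user-overridable). Ties and
order-dependence are engineered away: ranks use average ties and control
pools are sorted before seeded sampling, so permuting gene order leaves
scores unchanged exactly.

Calls: **G0** when both scores ≤ 0 (the cell expresses neither program),
else **G2M** when the G2/M score strictly exceeds the G1/S score, else
**G1S** — a deterministic tie-break for the measure-zero tie. Per-condition
phase fractions always sum to one and conserve the cell count.

## What the simulators emulate — and what they do not

The amplicon simulator draws category counts once from a multinomial over
(HDR, NHEJ, unmodified) fractions, then builds each molecule: reference,
reference with donor conversions (auxiliary edits co-converting with a
configurable probability), or reference with one sampled indel. Indel sizes
are geometric (p = 0.3) truncated at 25 bp with a 2:1 deletion:insertion
ratio and anchors jittered across the window — a plausible Cas9 spectrum,
though no downstream check depends on these specific choices, only on the
truth labels. Reads are 300 bp paired-end at 10,000 pairs by default,
running off the fragment into a TruSeq-style technical sequence and
truncated there (so mates are at most the read length), with a two-state
Phred model and uniform per-base substitution errors.

One subtlety makes "100% fidelity on perfect reads" a well-defined claim:
an indel inside a repeat admits several alignment-equivalent placements,
and an optimal aligner is free to report any of them. The simulator's
strict-inside mode therefore computes the full equivalent-placement range
of each candidate event and resamples any event whose range straddles the
window boundary; the optional outside-window contaminant class does the
same on the other side. Ground-truth labels are thus invariant to aligner
tie-breaking. Real data have no such guarantee — boundary-ambiguous indels
are intrinsically arbitrary at ±1–2 bp — so passing fidelity tests show
rule correctness, not that biological boundary cases are unambiguous.

The single-cell simulator gives each phase's cells a fold-change boost
(default 10×) of that phase's markers over a low off-state baseline (0.3×
the median background gene), negative-binomial counts (size 2) over
log-normal library sizes (median 5,000), ~3% mitochondrial counts, and
optional QC-fodder cells (low-complexity: 150 genes; high-mito: ~20%).
It emulates the statistical structure module scoring assumes — marker
programs off in G0, on in their phase — not transcriptome realism: no
intermediate phase states, no doublets or ambient RNA, no batch structure.
Recovery results on it bound what the caller does under its own model, not
performance on real tissue.

Neither simulator models PCR chimeras or position-dependent error
profiles. Both are deterministic down to the byte under a fixed seed, and
restore the caller's RNG state.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make binomial/multinomial
sampling error small relative to the tolerances checked: 10,000 read pairs
for rate recovery (3·SE ≈ 1.3–1.5 percentage points), three replicates of
3,000 reads per condition for ratio fold changes (delta-method CI ≈ ±22%
at 3σ), 400 error-free pairs for merge fidelity, 100 cells per phase for
phase recovery, and a thousand random short pairs for aligner–oracle
equivalence. Alignment is exact dynamic programming — no banding or
heuristics — so read length only affects time, not results. Scores are
IEEE doubles; the half-unit gap-extend penalty is exactly representable,
so score comparisons in tests use exact equality against oracles.

## Known limitations

* Donors with programmed insertions or deletions are rejected; only
  substitution donors are classified.
* Large structural variants, translocations and UMI handling are out of
  scope; every read is treated as an independent allele observation.
* The identity-based discard is weak at its default (see above) by design
  fidelity to the alignment scoring; tighten `min_identity` for noisy
  libraries.
* The marker lists are a reconstruction of the standard human sets, not a
  copy of any particular study's unpublished list; results on real data
  depend on the list supplied.
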