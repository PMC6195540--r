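---
title: "Methods: poly(A)-site calling and termination profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A)-site calling and termination profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAterm)
```

This vignette documents the models and conventions behind the package's
four analysis stages, the synthetic-data generator that stands in for
deposited sequencing data, and the design decisions that were genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Coordinate conventions

All internal coordinates are 0-based half-open. GTF (1-based closed) is
converted at the read/write boundary, bedGraph is already half-open, and
fixed-step WIG is written 1-based. A gene's `annotated_3end` is stored as
the strand-aware half-open boundary (`end` on `+`, `start` on `-`); its
`tss` is the opposite extremity.

The **cleavage position** of a PAS read is the 0-based coordinate of the
*last templated* transcript nucleotide — the aligned base adjacent to the
untemplated-T soft clip. The 3′READS protocol does not itself fix this
convention, so the package picks the last templated base and measures the
**signed distance** of a site to a gene's 3′ end along the sense strand,
with 0 meaning the cleavage base *is* the last annotated base and positive
values downstream. Any such affine convention reproduces published
distances that are differences of positions (e.g. a distal site 118 nt
past a major site 78 nt downstream of the mature end lies at 196 nt);
the chosen origin makes "cleavage flush with the mature 3′ end" read as 0.

When the strongest PAS of a gene updates its transcriptional 3′ end, the
gene is extended *through* the cleavage base: new `end = position + 1` on
`+`, new `start = position` on `-`. This keeps the update idempotent and
makes the strongest site's recomputed distance exactly 0 — an update that
set the half-open boundary *at* the cleavage base would leave its own
strongest site nominally outside the gene.

## PAS calling

A record qualifies as a PAS read iff `mapq > 10` (strict, as the original
filter is stated) and the *leading* run of `T` in its 5′ soft clip (read
orientation) has length ≥ 2. Non-T bases after the run are ignored: the
run length is the number of untemplated adenosines evidenced, and a
trailing mismatch does not disqualify the tail. No genomic A-run
(internal-priming) filter is applied by default — the analysis this
package reproduces does not describe one — and none is needed for the
synthetic data; the T-run threshold is exposed (`min_t`) for stricter
settings.

Sites are single-nucleotide by default (`merge_window = 0`): the source
analysis does not state a clustering window, and single-base sites keep
closure against the planted truth exact. A merge window is available; it
collapses same-strand positions within the window to the read-weighted
mode. RPM is computed per sample over *PAS reads*, so `sum(rpm)` over a
sample's site table is 10⁶ by construction.

The ≥ 2-read support threshold is enforced at **assignment**, not at
calling, because the original description attaches it to the assignment
sentence; singleton sites stay visible in the site table for diagnostics.
Assignment is strand-specific: nearest same-strand 3′ end with
|distance| ≤ 1000 nt for sites outside every CDS, and ≤ 500 nt for sites
inside a CDS (the rescue for genes overlapping coding regions). The 1 kb
window is implemented symmetrically (|distance|) rather than
downstream-only; the source wording ("closest 3′ end … within 1 kb") does
not resolve this, and the symmetric reading also captures cleavage
slightly upstream of an annotated end. Ties on |distance| go to the gene
the site is downstream of, then to the lexicographically smaller id; the
strongest site per gene maximizes read count, breaking ties by proximity
and then by the upstream-most position. All tie-breaks are deterministic
so re-runs are byte-identical.

## Wilcoxon signed-rank test

Per-gene distances and summed RPM are compared between conditions on the
genes present in both, with a paired Wilcoxon signed-rank test implemented
in the package: zero differences dropped, midranks for ties, and for
n ≤ 25 the *exact* null distribution of W under all 2ⁿ sign assignments,
computed by a generating-function convolution over doubled ranks (doubling
makes midranks integral). `stats::wilcox.test`'s exact path declines ties
and zeros, which paired RPM data produce routinely; the in-package kernel
handles them exactly and is validated in the tests against brute-force
enumeration (n ≤ 10) and against `wilcox.test` on tie-free data. Above
n = 25 a normal approximation with continuity correction and tie-corrected
variance takes over; the two-sided p is `min(1, 2·min(P≤, P≥))`.

## ChIP-seq normalization

Tracks are mean-per-base binned at 10 nt (`bin_track`); the partial last
bin of a chromosome averages over its actual length. The bin statistic is
the **mean**, not the sum: the source pipeline's bin statistic is not
stated, and the mean keeps units per-base, makes partial bins comparable,
and renders total signal independent of bin width. "Total signal" is the
per-base integral, Σ value × covered length, and the reference total is
10⁸ coverage-bases (1 M reads × 100 nt).

The spike-in chain (`normalize_spikein_pair`) follows the data-set
wording uniformly: each data set — IP *and* input — is first scaled by its
own spike-in factor (target / spike-in total), then the WT member of each
IP (and input) pair is scaled to the target and the same factor applied to
its mutant counterpart, and finally each input is subtracted from its IP.
Scaling the inputs by their own spike factors (rather than their IP's)
was the open choice; per-sample factors keep every track in the same units
before subtraction. Negative post-subtraction values are retained by
default (subtraction is applied without comment in the source analysis);
a clamp is available for display. All factors are recorded in order and
`replay_factors()` reproduces a normalized track from the raw one.

The recovered occupancy factor α̂ is measured on the `normSI_sclWT` stage
(before input subtraction): with identical WT and mutant inputs the
subtracted totals cancel toward 0 and a total-ratio would be undefined
there, while the sclWT totals carry the spike-calibrated ratio directly.

## Metagene profiles

Layouts are absolute (fixed window counts, 10 nt windows by default). In
four-anchor mode the five blocks are: upstream gene (x-axis space only),
upstream intergenic aligned toward the TSS, the gene split so the first
⌈n/2⌉ windows anchor at the TSS and the rest at the 3′ end (the TSS half
takes the extra window when n is odd), downstream intergenic aligned at
the 3′ end, and downstream gene (ignored). Intergenic windows reaching
into a neighbor (strand-agnostic nearest gene; chromosome ends act as
neighbors) are missing, which is what makes the mode contamination-free.
Two-anchor mode keeps only the middle three blocks and clips intergenic
windows at chromosome ends only, deliberately admitting neighbor signal so
read-through past the 3′ end stays visible; it is the mode used for the
termination-defect comparisons. Gene windows beyond the feature length are
missing. Aggregation is the arithmetic mean per window with missing
counted as 0 — every gene contributes to every non-ignored window, so
short genes pull the aggregate toward zero rather than silently dropping
out — and `n_contributing` records how many genes actually covered each
window.

"Smoothing of 6" is implemented as a centered, unweighted moving average
extending up to 6 windows each side, shrinking at edges and never crossing
block boundaries (blocks are anchored differently, so averaging across a
boundary would mix anchors). The upstream tool's exact kernel (one-sided
vs centered, weighting) is not restated in the source; profiles smoothed
with a different kernel should be compared qualitatively only.

Read-through is quantified by `halfmax_crossing_3p()`: over the
3′-anchored gene half and the downstream intergenic block, the first
window after the profile maximum that falls below half-maximum, reported
as nt from the 3′ anchor. The statistic is insensitive to global scaling,
so a mutant with lower overall occupancy still reports its shift.

## Correlation

`genome_matrix()` resamples all tracks to a common resolution (10 nt) and
keeps bins present in every track, so each pairwise coefficient is
computed over identical bins (pairwise-complete mode is behind a flag).
Pearson coefficients come from `stats::cor`; clustering is average linkage
on 1 − r — the source names neither a linkage nor a distance, and average
linkage on correlation distance is the common choice for assay-similarity
matrices. Correlations are computed on final normalized tracks, including
any negative input-subtracted bins.

## The synthetic-data generator

The generator's defaults encode the study conditions at desk scale:

* 31 monocistronic snoRNAs, 4 of them without a planted PAS (emulating
  snoRNA genes with barely detectable polymerase occupancy, for a 27/31
  assignable structure), plus 20 mRNAs and 5 snRNAs by default;
* 1–2 planted PAS per gene, 20–300 nt downstream of the annotated 3′ end,
  with 5–50 expected reads each — the distance range brackets the
  reported ~80 nt median pre-snoRNA extension while staying well inside
  the 1 kb assignment window;
* untemplated-T runs of length 2 + Geom(0.5); decoy rates of 5% each for
  single-T clips, MAPQ ≤ 10 records, and CDS-internal PAS-like reads;
* a 0.9:0.1 experimental/spike-in chromatin split (`spike_fraction =
  0.1`), a mutant/WT occupancy factor α = 0.4, and a 200 nt read-through
  shift;
* ≥ 1 kb intergenic spacing, so planted sites are always nearest their
  own gene and the four-anchor mode has real intergenic space.

ChIP occupancy is a per-gene trapezoid over the transcribed interval
(linear ramps of up to 100 nt, capped at a quarter of the interval). The
mutant's interval extends `readthrough_shift` nt past the 3′ end and the
whole mutant track is then rescaled so its total is exactly α × the WT
total: the termination-defective condition redistributes polymerase
downstream *and* loses it globally, and the exact rescaling is what makes
noise-free α recovery through the spike-in chain a sharp contract rather
than an approximation. The spike-in chromosome carries a uniform,
condition-independent signal — the constant-chromatin assumption that
spike-in normalization relies on. Poisson noise, when enabled, rescales a
sample's expected signal to `depth` coverage-bases (10⁶ by default) and
replaces each 10 nt bin with a Poisson draw; at that depth the relative
sampling error of the four totals entering α̂ is ~0.1–0.3%, comfortably
within the 2% recovery contract.

What the generator does **not** emulate: sequence-level
ligation/reverse-transcription artifacts, internal priming on genomic A
runs, fragment-length and GC effects, mappability structure, replicate
variability, and overlapping/nested gene architectures beyond CDS overlap.
Passing tests therefore demonstrate the correctness of the computational
contracts (detection rules, normalization algebra, layout arithmetic,
statistics), not robustness to every artifact of real libraries.

## Problem sizes and determinism

Tests and the acceptance script run on single chromosomes of 60–300 kb
with 8–54 genes, chosen so the whole suite completes in well under a
minute while every stage still runs end to end; the statistics that
matter (exact recovery, α̂, half-maximum shifts) are invariant to genome
size. All simulators are pure functions of their inputs and a seed (the
caller's RNG state is saved and restored), and the full demo pipeline is
byte-reproducible under a fixed seed; sub-stage seeds are derived from the
user's seed by small offsets.

## Known limitations

* GTF records with non-positive width raise a parse error instead of
  being skipped-and-logged; the import path validates widths before
  per-record recovery is possible.
* The PAS caller consumes single-end alignment records only, and only the
  SAM fields it needs (position, strand, MAPQ, CIGAR soft clips, SEQ).
* The metagene module implements absolute layouts only; length-scaled
  (relative) profiles and heatmaps are out of scope.
* bigWig encoding is out of scope; tracks are exchanged as bedGraph and
  fixed-step WIG.
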