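---
title: "Processing multi-contact concatemer 3C reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing multi-contact concatemer 3C reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(concatemeR)
```

## The problem

Chromosome conformation capture (3C) crosslinks spatially proximal genomic
loci, digests the genome with a restriction enzyme, and religates free ends
so that interacting fragments become covalently joined. Long-read
sequencing of these ligation products yields *concatemer reads*: a single
read carries many ligated restriction fragments ("segments"), each one a
participant in the same spatial neighbourhood. Turning such reads into
usable chromatin-contact data requires a chain of small, exacting steps —
splitting reads at the enzyme's recognition sites, aligning the pieces,
expanding each read's n segments into all n(n−1)/2 pairwise contacts,
filtering and de-duplicating, imputing haplotype phase within reads, and
binning contacts into balanced matrices that can be compared across
protocols and used for TAD analysis. This package implements that chain,
plus a ground-truth simulator that makes every step testable end to end.

## In silico digestion

A restriction enzyme is modelled as an IUPAC motif plus a cut offset from
the motif start on the top strand: DpnII cuts `^GATC` (offset 0), HindIII
`A^AGCTT` (offset 1), NlaIII `CATG^` (offset 4). Cut positions are
`motif start + offset`; every motif occurrence counts, including
overlapping ones (the scan advances one base at a time, which matters for
motifs that overlap themselves). Ambiguity codes in the *motif* match their
IUPAC sets, but ambiguous bases in the *sequence* (N and friends) never
satisfy any motif code — a deliberate conservative choice that avoids
spurious cuts inside masked or low-quality stretches. The two main enzymes
are palindromic, so top-strand scanning suffices; for a non-palindromic
custom motif the reverse complement is also scanned and its cuts mapped to
top-strand coordinates (`s + motif_length − offset` for a bottom-strand
match starting at `s`).

Cut positions at 0 or at the sequence end are dropped because they delimit
empty segments; a read with k interior cuts therefore yields exactly k+1
segments that tile it byte-for-byte. No minimum segment length is imposed
by default (`min_length = 0`); the flag exists because some pipelines
discard tiny fragments, but discarding breaks the exact-tiling identity
that the tests rely on.

All internal coordinates are 0-based half-open. Conversions to 1-based
conventions happen only at serialization boundaries (pairs files, SAM),
which keeps off-by-one reasoning localized to the writers.

## From segments to contacts

Each read's aligned segments expand to all unordered pairs. The
representative position of a segment is its 5′-most mapped coordinate,
strand-aware (`ref_start` on `+`, `ref_end − 1` on `−`), matching common
pairs-format practice. Mates are normalized to the upper-triangle
convention (chrom1 ≤ chrom2 by name order, pos1 ≤ pos2 within a
chromosome) so that binning and deduplication are deterministic.

Unmapped segments are *not* dropped during expansion: the pairs they form
carry an unmapped flag and are removed by `filter_pairs()`, whose tally
(`input = retained + unmapped_mate + low_mapq`) is the observable record of
what the filter did. A pair is retained iff both mates are mapped and
`min(mapq1, mapq2)` clears the threshold; the package default threshold is
1, the convention for contact matrices. The filter is monotone by
construction: raising the threshold can only shrink the retained set.

PCR duplicates are detected on alignment fingerprints — the ordered tuple
of (chrom, start, strand) over a read's segments. Two reads from the same
original molecule produce identical fingerprints; the first read id in
sort order is kept as representative, which makes the operation idempotent
and independent of input order.

`emit_mock_pairs()` converts each contact into an Illumina-like paired-end
template (mate 1 from the segment's 5′ end, mate 2 reverse-complemented —
FR orientation, 150 bp by default), so scaffolders and other pair-based
consumers can run on concatemer data; a 17-segment read becomes 136 pairs
and hence 272 mates.

## Haplotype phase imputation

Concatemer reads derive almost entirely from a single chromosomal copy, so
phased segments within one read that map to the same chromosome should
agree. `read_concordance()` reports that agreement two ways — a per-read
boolean (all same-chromosome phased segments share one haplotype) and a
per-pair fraction — because the natural denominator of an aggregate
"percent concordant" is ambiguous, and both views are cheap to carry.

`impute_phase()` assigns a haplotype to an unphased mapped segment when
the *originally* phased segments on its chromosome within a 30-Mbp window
(inclusive) around its representative position are non-empty and unanimous.
Three conservative rules follow from that definition:

* original tags are never modified;
* only original tags count as evidence — imputed tags do not chain within
  the pass, so the result is independent of processing order;
* any in-window conflict blocks imputation entirely.

The window is anchored at each unphased segment, not at the read span.
The minimum evidence count is 1 (configurable); requiring 2 would trade
coverage for robustness against single mis-tagged segments.

## Contact matrices and balancing

`bin_contacts()` assigns each retained pair to one (i, j) cell with i ≤ j
over genome-wide fixed-width bins (2.5 Mbp and 50 kbp are the conventional
resolutions and the pipeline presets); storage is symmetric sparse and
total mass equals the number of binned pairs, a conservation law the tests
assert on every fixture.

Balancing uses the Knight–Ruiz inner-outer Newton iteration with
conjugate-gradient inner solves, written from the published algorithm:
find positive `w` with `diag(w) · M · diag(w)` having equal row sums
(scaled to 1). All-zero rows are masked first. The stopping rule bounds the
2-norm of the row-sum residual at one fifth of `tol` (default 1e-6), which
keeps the max/min row-sum dispersion below `tol` on convergence. Two
failure modes are explicit rather than silent, because real data produce
them (pericentromeric satellite arrays are the classic case): exceeding
`max_iter` returns a flagged status, and an unmasked submatrix whose
contact graph splits into two or more interacting blocks is refused as
degenerate — when blocks do not interact, the equal-row-sum problem
decouples and the common-value convention becomes arbitrary per block, so
weights from such an input are not comparable across the matrix. Isolated
bins whose only entry is their own diagonal are trivially balanced and do
not trigger the check.

Matrix comparison reports squared Pearson correlation over upper-triangle
cells defined in both matrices. Zero cells are *included* by default (the
conservative rule, since the inclusion convention is rarely stated in the
literature); `nonzero_only = TRUE` exposes the alternative so the
sensitivity of a comparison to that convention can be measured.

## TAD-set concordance

Two TAD partitions are compared on their domain-labeled intervals only
(boundary and gap labels are excluded — the measure is defined over
domain partitions). The measure of concordance is

$$\mathrm{MoC}(A,B) = \frac{1}{\sqrt{N_A N_B}-1}\left(\sum_{i,j}
\frac{|A_i \cap B_j|^2}{|A_i|\,|B_j|}-1\right),$$

with MoC = 1 when both partitions consist of a single domain (the formula
is otherwise undefined there; the convention follows the metric's source).
Self-concordance is identically 1. The Jaccard comparison comes in two
modes mirroring standard practice: plain basepair Jaccard of domain
territory, and a matched variant in which two domains count only if each
overlaps the other by at least 25% of its own length. `gap_fraction()`
reports, per annotation class, the percentage of class basepairs that a
TAD caller labeled gap — the readout used to ask whether hard-to-map
genome classes are systematically unassigned.

MAPQ profiles per annotation class use the any-overlap rule (≥ 1 bp) at
cutoffs {1, 10, 20, 30, 60}; segments, not reads, are the counting unit,
and a segment overlapping several classes counts in each.

## The simulator

The simulator exists so that every operation above can be tested against
ground truth without external data. It emulates, in order: a diploid
genome (haplotype 2 differs from haplotype 1 by substitutions at the SNV
rate, coordinates shared); restriction-fragment concatemers whose cis
partners decay as a power law; a configurable trans rate; a per-read
segment-count distribution; and PCR duplicates with provenance.

Defaults are the package's reference conditions, chosen once:

* **enzyme DpnII**, the 4-cutter that yields the richest multi-contact
  data;
* **segments per read** `1 + NB(size 8, mu 16.5)`, giving median 17 — the
  observed median for DpnII concatemer libraries;
* **duplicate rate 0.018**, the PCR duplication level typical of
  amplification-based library preparation;
* **SNV rate 1e-3**, the scale of human heterozygosity;
* **decay exponent α = 1**, the canonical intra-chromosomal contact decay;
* **trans probability 0.05**, consistent with the observation that the
  large majority of homolog-mapping pairs are cis;
* **chromosomes 1.5 Mb + 1.0 Mb**, a desk-scale genome: large enough for
  ~10,000 DpnII fragments and three decades of distance decay, small
  enough that the full suite runs in about a minute and a half.

Reads are assembled by a sticky-end religation model: fragment cores are
joined with exactly one copy of the recognition motif reconstituted at
each junction, and truth segment boundaries are placed at
`junction + cut_offset`. Because cores are interiors of restriction
fragments they contain no motif, so digestion of an error-free read
recovers the truth boundaries *exactly* — a sharp oracle rather than an
approximate one. The coordinate arithmetic for minus-strand segments
relies on the motif being palindromic (all presets are); non-palindromic
custom enzymes are rejected with a clear error. Partner fragments are
sampled around a per-read anchor with probability ∝ d^−α over fragment
midpoints, excluding the anchor and its immediate neighbours (a
one-fragment minimum-distance floor standing in for self-ligation
removal). Each read draws one haplotype, so within-read phase is
perfectly concordant by construction — which is what makes zero-error
imputation a meaningful requirement rather than a statistical accident.

What the simulator does *not* model: sequencing errors beyond optional
uniform substitutions (default 0), chimeric junctions, TAD or compartment
structure in the decay (one global exponent), amplification bias, or
mapping ambiguity (truth alignments carry MAPQ 60 unless degraded
explicitly). Passing tests therefore demonstrate correctness of the
processing arithmetic under a clean generative model, not robustness to
real-world alignment noise.

### Estimating the decay exponent

Only anchor–partner distances follow the generative d^−α law. The
all-pairs expansion also produces partner–partner pairs, whose distance is
the difference or sum of two independent power-law draws; mixing them
flattens the apparent decay (measured fit ≈ 0.79 for α = 1). The estimator
`fit_decay_exponent(..., anchor_only = TRUE)` therefore conditions on
pairs involving segment 0 and recovers the configured exponent to within
a few percent across α ∈ [0.7, 1.5]. The fit itself is a log–log
regression of log-binned frequencies (counts divided by bin width) against
bin-centre distance over 2 kb–150 kb — a range well inside the simulated
chromosome, where edge effects do not bend the curve.

## Problem sizes and numerical choices

The test suite and the acceptance script run the simulator at 120–1000
reads (≈ 2,000–17,000 segments, up to ≈ 340,000 pairs), balance matrices
up to 500×500, and scan 1,000 random 1-kbp sequences per enzyme against a
naive position-by-position IUPAC oracle. These sizes were chosen as the
smallest at which every distributional check (binomial SNV and duplicate
counts within 3σ, decay recovery within ±15%) is comfortably stable.

Ties and degenerate inputs are resolved explicitly: lower-median and
smallest-mode conventions in `segment_stats()`; empty intrachromosomal
input yields an empty histogram, not a division error; empty segment
tables flow through the whole pipeline producing zero-count summaries;
duplicate representatives are the lexicographically first read id. The
pipeline writes no timestamps, so identical inputs give byte-identical
outputs.

## Limitations

The package consumes alignments; it does not align (minimap2 or
equivalent is the upstream tool) and does not call variants, haplotag
reads, or call TADs — those are consumed as inputs in their standard
formats. The balancing failure contract is intentionally stricter than a
bare Newton iteration: inputs a practitioner should inspect (disconnected
maps) are refused rather than silently scaled per block.
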