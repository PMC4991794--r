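---
title: "Methods: differential transcription, operator scanning and qPCR reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential transcription, operator scanning and qPCR reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scostress)
```

This vignette is the package's own account of its methods: the models and
conventions each stage uses, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the design choices made where the procedure was genuinely
open.

## Fragment assembly

The counting unit is the sequenced insert, not the individual mate. Mates
sharing a `read_id` on the same reference whose outer span
(max end − min start) is at most `max_distance` (default 1000 bp) are
combined into one fragment over that span; wider pairs — and pairs on
different references, which the assembler treats the same way — are
discarded and counted; a lone mate is kept as a single-mapping fragment.
"Distance" is the outer span because the combined fragment is meant to
*contain the insert*: an inner-distance convention would shift the limit
by two read lengths.

Strand bookkeeping assumes a forward-stranded library: a fragment takes
the strand of its first mate, and a lone *second* mate is flipped so all
fragments sit in transcript orientation. Multi-mapped `read_id`s are
dropped whole by default (configurable to keep-first): with duplicate
mappings present, any assignment double-counts, and dropping is the
conservative choice.

Every run satisfies the conservation identity
`2·combined + 2·discarded + singles = accepted reads`, which the tests
assert on randomised inputs; assembly is also invariant to input record
order because decisions are made per `read_id` group.

## Counting and RPKM

A fragment is assigned to the unique CDS containing its midpoint
`floor((start + end − 1)/2)`, on the matching strand when counting is
stranded. Midpoint assignment was chosen over any-overlap because
*Streptomyces* genomes are operon-dense: a fragment straddling two
adjacent CDSs must not count twice. Fragments whose midpoint lands in an
ambiguous overlap of two CDSs are left unassigned rather than arbitrarily
attributed.

The library size is the number of *all* assembled fragments, assigned or
not — "per million mapped" refers to mapping, not feature assignment.
With one pseudo read added per gene,

$$\mathrm{RPKM} = \frac{(c + 1)\cdot 10^9}{L \cdot N},$$

so RPKM is strictly positive and the log-ratio statistics below are always
defined. The pseudocount matters only for weakly covered genes; for a
gene with count ≫ 1 it vanishes asymptotically (a tested property).

## Differential-transcription calling

Replicate RPKMs are combined by arithmetic mean per condition *before*
taking logs; `M = log2(mean_trt) − log2(mean_ref)` and
`A` is the mean of the two log means. Mean-then-log keeps `2^M` equal to
the ratio of condition means, which is how the reported fold changes are
defined; log-then-mean would report a geometric-mean fold instead.

Filtering and calling use four thresholds (`de_config()`):

* `rpkm_min = 30` — at least **one** of the two condition means must reach
  30 RPKM. Requiring both would discard exactly the most interesting
  genes, those silent in one condition and strong in the other.
* `a_min = 2.0` — strict A-value cutoff; removes genes whose average
  expression is too low for a stable ratio.
* `z_coeff = 2.58` — the two-sided 1 % standard-normal quantile. Under
  the assumption that most genes are unchanged, the standard deviation of
  all filter-passing M-values estimates the null spread, and
  `m_min = 2.58·STDEV` leaves ≈1 % of null genes outside the band (a
  Monte-Carlo–tested property: for M ~ N(0,1), n = 10⁴, between 0.5 % and
  2 % fall outside across seeds). The sample (n−1) estimator is used; at
  these gene counts the choice is immaterial, but it is the documented one.
* `m_floor = 1.5` — the reporting bound (fold changes 2.8 and 0.4 at
  1-decimal rounding). The effective cutoff is
  `max(m_floor, 2.58·STDEV)`; both values are surfaced in the output so a
  user can see when calibration, not the floor, is binding.

The calibration is deliberately computed on the same filter-passing gene
set that is then classified, and planted differential genes inflate
`STDEV(M)`. In the default synthetic world (6 % of genes at |log₂FC| = 3)
this raises the cutoff from ≈0.6 (mutant contrast, no signal) to ≈2.0
(wild-type contrast) — an honest property of self-calibration that users
should be aware of: with a large regulon the method grows conservative.

No variance model, no p-values, no multiple-testing correction: with two
biological replicates the empirical-cutoff approach is the method; the
package does not pretend otherwise.

## Operator-site scanning

Identity between a candidate and the reference site is **ungapped**: the
shorter sequence slides along the longer over all full-overlap offsets,
identity is `100·matches/len(shorter)` at the best offset (ties to the
smallest offset), reported rounded half-up to an integer. This exactly
reproduces the published identities of the candidate sites that were
derived without internal gaps (91, 90, 87, 73, 73, 71 and the 100 %
self-match); candidates originally aligned with internal gaps are out of
scope, since the original alignment parameters are unavailable. Non-ACGT
characters never match but count in the length, so Ns degrade identity
rather than inflate it.

`scan_upstream()` scores every window with length in `len_range`
(default 10–20 bp) of a region oriented 5'→3' on the coding strand ending
at the base before the start codon, and resolves overlapping hits greedily
by (identity desc, length desc, leftmost). One consequence worth knowing:
any window that fully contains the reference (or a high-identity core)
scores the same 100·matches/len(shorter), so the winner among tied windows
is the longest, leftmost one. `distance_to_start` counts the bases
strictly between the site's 3' end and the start codon; the published
distance convention could not be verified against the genome, so this one
is fixed and documented. Scanning is forward-strand by default with an
optional reverse-complement pass.

The empirical null matters here: random 72 %-GC sequence resembles a
GC-rich operator often enough that ≈20 % of 200-bp regions contain a
window at ≥85 % identity (measured, seed-fixed, with this generator),
though perfect matches essentially never occur. Identity thresholds in
the 50–70 % range therefore say little by themselves in high-GC genomes;
the scanner reports them because the published table does, but the
vignette's advice is to treat sub-85 % hits as hypotheses for EMSA-style
validation, not findings.

Per-position conservation of equal-length aligned sites is
`bits = 2 − H(column)` with frequencies over non-gap characters, with an
optional small-sample correction `−3/(2·ln2·n)`. Alignment of
unequal-length sites is the caller's responsibility — the package
deliberately does not re-implement a multiple aligner.

## qRT-PCR reduction

Crossing points are averaged technical-replicates-first, then across
biological replicates; the standard deviation is computed across the
biological-replicate means only, so technical noise is absorbed rather
than double-counted. For a contrast,
`ΔCP = mean_b − mean_a`, `sd(ΔCP) = sqrt(sd_a² + sd_b²)` (uncorrelated
errors), and the relative amount is `2^(−ΔCP)` with amplification
efficiency fixed at 2 (configurable; no dilution-series estimation). No
reference-gene normalisation is applied: the emulated assay compares CPs
directly on fixed RNA input. Because it is not stated whether reported
relative amounts were normalised within strain or to the unstressed wild
type, the reducer reports both (`rel_amount` and `rel_amount_vs_wt`).

## The synthetic world

`sim_config()` defaults state the world the tests run in; they were chosen
once and are not tuned to outcomes:

* 1000 CDSs of 300–3000 bp at 72 % GC on one replicon — the genome size is
  scaled down ~8-fold from a real *Streptomyces* chromosome to keep test
  runtimes in seconds, while GC is kept realistic because it drives the
  motif-scan null.
* 30 up- and 30 down-regulated genes at |log₂FC| = 3, wild type only; the
  mutant is fully deregulated (log₂FC = 0 everywhere), the qualitative
  behaviour the design is meant to detect.
* 2 biological replicates per strain/condition, negative-binomial counts
  with dispersion 0.01 — typical of low-variance bacterial cultures and
  the knob that keeps recovery tests honest.
* 200,000 fragments per library (scaled down from millions of reads for
  the same runtime reason), 75-bp mates, inserts ~N(200, 30²) bp.
* 5 % orphaned mates and 1 % wide (>1 kb) pairs, so the single-read and
  discard paths are exercised in every end-to-end run.

What the generator does **not** emulate: sequencing errors and quality
scores, rRNA contamination, coverage bias along transcripts, operon
structure (each CDS is transcribed independently), or genuine promoter
architecture in the upstream regions. A green end-to-end test therefore
establishes that the pipeline's arithmetic and bookkeeping are correct and
that the calling procedure recovers a planted regulon of realistic effect
size under realistic count noise — not that it would match any particular
real study's gene lists.

qPCR simulation plants a true fold as a CP shift of −log₂(fold) with
0.15-cycle biological and 0.05-cycle technical Gaussian noise
(3 biological × 2 technical replicates). With these defaults the true
fold lies within 2 propagated standard deviations of the estimate in
≥95 % of simulations — the tested coverage property.

## Numerical and degenerate-input choices

* Reported identities round **half-up** (base R's `round()` is
  half-to-even and would turn 78.5 into 78).
* All-identical M-values give `STDEV = 0` and the cutoff falls back to the
  ±1.5 floor.
* `fold_change = 2^M` holds to machine precision in output tables;
  printing is 2-decimal.
* Empty mapped-read files, header-only tables and empty scan results are
  returned as empty typed objects, not errors; malformed coordinates
  (end ≤ start), unknown mate labels and inverted length ranges are hard
  errors naming the offender.
* The GFF3→internal→GFF3 coordinate conversion is an identity on
  coordinates (0-based half-open internally, converted at the boundary),
  a tested round-trip.

## Known limitations

* The calling procedure has no variance model; with two replicates its
  error control rests entirely on the empirical-cutoff assumption that
  most genes are unchanged. Large regulons inflate the cutoff (see above).
* Ungapped identity cannot reproduce sites originally derived from gapped
  alignments; such candidates need a proper aligner upstream.
* The scanner's identity score ignores base composition; in 72 %-GC
  genomes the null rate at moderate identity is high, and no significance
  is attached to hits.
* Efficiency-2 amplification is an idealisation; real assays on GC-rich
  templates often run below 2, biasing `2^(−ΔCP)` upward.
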