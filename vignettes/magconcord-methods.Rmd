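---
title: "Methods: concordance, quality and triage for long-read metagenome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance, quality and triage for long-read metagenome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magconcord)
```

## Setting

Long-read metagenome assembly can recover contigs the size of whole
bacterial chromosomes directly from a community. Because neither the
long-read nor the short-read assembly of the same community can be assumed
to be a correct reference, the package treats validation as a problem of
*agreement*: quantify how well an independent short-read assembly, grouped
into bins (MAGs), recapitulates each chromosome-scale long-read contig
(LRAC), and screen each LRAC for internal evidence of mis-assembly. The
two data types are kept strictly separate throughout, so no statistic is
biased by using one to polish the other.

## The concordance statistic

Input is BLASTN tabular output (`-outfmt 6`, optionally extended with
`qlen`/`slen`) with short-read contigs as queries and LRACs as subjects.
From all HSPs, exactly one alignment is retained per unique (query,
subject) pair — the one with the maximum bit-score. For a bin $B$ and an
LRAC $S$ of length $L_S$, over the $n$ retained alignments of $B$'s
contigs against $S$:

$$\widehat{pid} = \frac{1}{n}\sum_i \frac{PID_i}{100}, \qquad
\widehat{al2ql} = \frac{1}{n}\sum_i \frac{len_i}{qlen_i}, \qquad
p_{srac} = \frac{|\{\text{aligned contigs of } B\}|}{|B|}, \qquad
p_{aln} = \frac{|\bigcup_i [s^{start}_i, s^{end}_i]|}{L_S}$$

$$\kappa = (\widehat{pid} + \widehat{al2ql} + p_{srac} + p_{aln})/4$$

$p_{srac}$ and $p_{aln}$ capture completeness of the tiling;
$\widehat{pid}$ and $\widehat{al2ql}$ its quality. If most of a bin's
contigs cover an LRAC end-to-end with high-quality alignments, all four
approach unity, and the maximum-κ bin is the cognate candidate
(`rank_cognates()`).

Decisions embedded in the implementation:

- **Unweighted means.** Components average equally across retained
  alignments, with no length weighting; one alignment, one vote.
- **$\widehat{al2ql}$ is not capped at 1** — a query aligning with gaps
  can produce an alignment longer than itself, and that excess is
  informative. $\widehat{pid}$ is divided by 100 so all components share
  the proportion scale.
- **Interval union.** $p_{aln}$ merges subject intervals (via IRanges)
  after normalizing reverse-strand coordinates to (min, max); a base
  covered by many alignments counts once. The test suite checks this
  against a per-base marking oracle.
- **Absent pairs are absent.** A (bin, LRAC) pair with no retained
  alignment yields no row rather than κ = 0: in real data κ is only
  defined for the subset of bins producing alignments, and a
  structural zero would distort downstream summaries of κ
  distributions.
- **The near-full-length variant** keeps alignments with
  $len/qlen \ge 0.95$ and then recomputes *all four* components on the
  filtered set, so $p_{srac}$ and $p_{aln}$ drop along with the discarded
  partial alignments. The boundary is inclusive ($\ge$); a record at
  exactly 0.95 is kept. Descriptions of this filter sometimes write the
  threshold as a strict inequality — with continuous-valued ratios the
  distinction is immaterial except for engineered fixtures, and the
  inclusive reading is the one implemented and documented here.
- **Deterministic tie-breaks.** Best-hit retention resolves bit-score
  ties by larger alignment length, then first occurrence; cognate ranking
  resolves κ ties by higher $p_{aln}$, then lexicographic bin id. Equal
  inputs therefore always give byte-identical outputs.
- **$p_{aln}$ uses the retained best-hit alignments only**, not all HSPs.
  Using every HSP could only enlarge the union, and with one HSP retained
  per contig the union already reflects the tiling structure; consistency
  with the other three components (all defined on the retained set) was
  judged more important.

## Genome quality

`classify_quality()` applies the single-copy-marker-gene convention:
HIGH requires completeness strictly above 90% *and* contamination
strictly below 5%; MEDIUM requires completeness ≥ 50% and contamination
< 10%; everything else is LOW. The strict/non-strict mix is read
literally from the rule's standard statement, so a genome at exactly 90%
completeness is MEDIUM. The three classes partition the plane (a
property test asserts this on a grid).

`check_mimag_high()` adds the annotation half of the full MIMAG
high-quality standard: at least one complete rRNA operon (5S + 16S + 23S)
and at least `min_trna` tRNAs. The standard's threshold of 18 tRNAs is
the default; the parameter is exposed because practice varies.

`summarize_quality_table()` reports unweighted arithmetic means, minima
and maxima of completeness and contamination plus HIGH counts, optionally
per correction method. Rounding to two decimals happens only in
`write_report()`; internal values keep full precision.

### Gene length ratios

To compare sequence-correction procedures without a ground-truth genome,
each predicted gene from a corrected (or uncorrected) assembly is searched
against predicted genes of the cognate short-read assembly, and the ratio
query length / subject length is taken at the best hit (maximum
bit-score per query). Intact genes sit at ratio ≈ 1; frame-shift
truncations pile up well below 1. `summarize_ratio_distribution()` bins
ratios over [0, 2.5] (overflow pooled into the last bin — the display
range of interest; ratios beyond 2.5 are rare pathological hits) and
reports the fraction inside a near-unity band, default [0.95, 1.05].
Queries with no hit are counted separately and never enter the histogram
as zeros, since "no orthologue found" is not evidence of truncation.

## Coverage-based mis-assembly screening

`flag_anomalous_intervals()` flags maximal runs of at least 10 bp where
per-base depth is strictly above 1.5× or strictly below 0.5× the
replicon median. Choices:

- the median is computed over **all** positions, zeros included — the
  conservative reading of "the median coverage", and robust since the
  median of a deeply covered replicon is unmoved by short anomalies;
- inequalities are strict; depth exactly at a threshold is background;
- HIGH and LOW runs are merged separately, and adjacency between a HIGH
  and a LOW position terminates both runs;
- an all-zero profile is rejected as unusable (a zero median makes the
  HIGH threshold degenerate).

A profile from a single read type should be screened at a time; the
caller chooses which (long-read coverage is the usual screen, since the
long reads produced the assembly under examination).

`compute_gc_windows()` computes GC in adjacent windows (default width in
the CLI: 46,700 bp, a round ~1% of a typical 4–5 Mb chromosome that keeps
per-window sampling error near 0.2%). The terminal partial window is kept
with its true length rather than dropped — discarding up to a window of
sequence would blind the track to terminal anomalies, which is where
artefactual concatenations often sit. `N` bases are excluded from both
numerator and denominator; an all-`N` window is omitted with a warning.

## Replicon triage

Circular contigs below 1 Mbp are classified by an ordered evidence
cascade: (R1) ≥ 1 Mbp → putative chromosome; (R2) rRNA operon and ≥ 20
tRNAs → small genome; (R3) rRNA operon and < 20 tRNAs → chromid; (R4)
≤ 20 kb, every gene hypothetical, no external viral call → artefactual
fragment; (R5) external viral classifier verdict → virus/phage or
prophage host; (R6) T4SS plus plasmid-replication markers → conjugative
plasmid; (R7) otherwise → plasmid.

Two defaults deserve justification. The tRNA threshold of 20 sits in the
wide gap between observed exemplars — a ~848 kb Patescibacteria genome
with 46 tRNAs versus chromid candidates with 8 and 3 — and is a
parameter, not a constant. "Extremely short" for the artefact rule is
likewise undefined in the field; 20 kb is the default because known
artefactual circularised fragments are a few kb while genuine phage and
plasmid replicons commonly exceed 20 kb, and it too is exposed as a
parameter. The deliberate ordering of R3 before R5 encodes a
domain judgement: a replicon carrying an rRNA operon alongside a viral
verdict is better read as a cellular replicon hosting a prophage than as
a free virus. The cascade is total and order-deterministic, and gene
order never affects a verdict.

Marker screening (`marker_gene_screen()`) is exact string membership
against editable one-identifier-per-line text files shipped under
`inst/extdata/markers/`; no annotation database is bundled.

## The synthetic generator

`build_scenario()` emulates the data shapes of a bioreactor-community
study at desk scale: one circular 50 kb LRAC (GC 0.55); a cognate bin of
20 contigs tiling 90% of it at 99% identity (plus one unalignable contig,
so $p_{srac} < 1$ as in real bins); three decoy bins with 20% coverage at
80% identity and six unalignable contigs each; a 20 kb coverage profile,
Poisson background at mean depth 50 — Poisson being the minimal model of
sequencing depth — with one planted 50 bp LOW and one 120 bp HIGH
anomaly forced strictly beyond the screening thresholds; a 2,000-gene
best-hit table with 30% truncations at severity 0.7; and an eight-replicon
feature panel, one per triage class. Alignment tables are generated
directly from the known fragment placements — coordinates, realized
identity and a bit-score increasing in length × identity — rather than by
running an aligner, which removes the external-tool dependency while
preserving the exact input schema; the emitted percent identity is
verifiable by re-extracting each genome span and comparing it to the
mutated contig (a test does exactly that).

What the generator does **not** emulate: indels and structural error
(substitutions only, so `al2ql` is exactly 1 by construction for
generated fragments), repeat-induced multi-mapping, chimeric contigs,
uneven strain abundance, and GC-coverage bias. Passing the recovery tests
therefore shows the statistics behave correctly on data matching their
assumptions — it does not certify performance on real communities, where
the discriminating margin between cognate and decoy κ is narrower.

Determinism is strict: every generator takes an explicit seed, scopes the
RNG state with `withr::with_seed` (restoring the caller's state), and
identical (parameters, seed) give byte-identical fixture directories.
Scenario sub-seeds are derived from the master seed by a fixed affine map
modulo $2^{31}-1$.

## Problem sizes and test strategy

The suite runs the hand-computed worked example exactly (components
0.94 / 0.875 / 0.5 / 0.625, κ = 0.735); checks $p_{aln}$ against a
per-base oracle on 100 randomized instances up to 100 kb; requires the
cognate bin to win in ≥ 95 of 100 seeded default scenarios; recovers
planted ≥ 10 bp anomalies interval-for-interval over 50 seeded profiles
while never flagging 9 bp plants; and verifies the published 22-genome
quality-table roll-ups (means to two decimals, HIGH counts exactly) from
the transcriptions shipped in `inst/extdata/`. These sizes keep the full
suite under a minute while leaving the statistics' sampling error far
below the tested tolerances.

## Known limitations

- κ presumes meaningful bins; it ranks candidates but does not test
  absolute cognacy (no null distribution is derived). A κ of 0.3 for the
  best bin means "no cognate MAG", but the package sets no hard cut-off.
- Anomalous-coverage screening finds *candidates* for mis-assembly;
  confirming a chimeric join requires read-level inspection, which is out
  of scope.
- The triage cascade consumes external annotation (operon/tRNA counts,
  viral verdicts, marker flags) as given and is only as good as they are.
- Near-duplicate replicons are not collapsed before triage; if ANI-based
  dereplication is wanted it must precede `classify_all()`.
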