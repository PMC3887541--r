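---
title: "Tandem repeat landscapes: models, parameters and design choices"
author: "trscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem repeat landscapes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscape)
```

## The problem

Tandem repeats (TRs) — stretches of at least two adjacent copies of a 1–50 bp
unit — are unevenly distributed across genomes: in land plants they
concentrate in 5′-UTRs and the promoter-proximal intergenic window, while in
green algae they concentrate in introns and coding sequence. Quantifying this
requires four coupled pieces: a detector for perfect *and* imperfect repeats,
a motif algebra that collapses equivalent repeat units into classes, a
gene-anchored region schema, and normalized density/positional statistics
that are comparable across regions and species. `trscape` implements all
four, plus a synthetic-genome generator that provides ground truth at desk
scale, so that every stage can be tested without multi-gigabyte downloads.

## Repeat model and detector

A **perfect TR** is a maximal run `u^k p` (`u` a primitive unit, `p` a proper
prefix of `u`) with at least two full copies; maximal means not extendable by
a single base on either side, and runs never cross non-ACGT residues (N and
ambiguity codes are "invalid" everywhere in this package — they are also
excluded from every density denominator). Enumeration is exact: for each unit
size `u`, positions with `s[i] == s[i+u]` form runs that map one-to-one onto
maximal tandem spans; a brute-force oracle with the same definition backs
this in the tests.

An **imperfect TR** is scored by optimal global alignment of a window against
indefinite repetitions of a unit (wraparound dynamic programming over
|window| × |unit| with column-wrap transitions, free start and end phase).
Detection is seed-and-extend: maximal perfect runs with at least two exact
copies seed an extension in both directions, stopped when the running score
drops more than a fixed drop-off below its maximum; the arg-max window is
re-scored with free phases and reported when it passes the thresholds.

Thresholds (all configurable, defaults per the published protocol):

| parameter    | default | meaning |
|--------------|---------|---------|
| `max_unit`   | 50      | largest unit size considered (nt) |
| `min_length` | 12      | minimum total repeat length (nt) |
| `min_score`  | 12      | minimum alignment score |
| `match`      | +1      | per-base match reward |
| `mismatch`   | −4      | substitution penalty |
| `indel`      | −4      | gap penalty |
| `dropoff`    | 16      | extension termination (score units) |
| `seed_floor` | 5       | minimum seed length (nt), besides 2 copies |

The alignment scheme is not printed in the original protocol, which fixes
only "score ≥ 12"; the +1/−4/−4 default makes a perfect repeat's score equal
its length, so the 12-nt and score-12 thresholds coincide on perfect repeats.
Two internal search parameters deliberately deviate from the first-cut values
suggested during design:

* **Seed floor 5 nt instead of 8 nt.** An imperfect array whose best
  alignment still scores ≥ 12 can have its longest clean stretch below 8 nt
  (a 21-nt trinucleotide array with two substitutions can be cut into
  7/7/5-nt pieces while scoring 21 − 8 = 13). With an 8-nt floor such arrays
  are unseedable and undetectable; with `max(2·unit, 5)` every array passing
  the score threshold retains a seed. Extensions are drop-off-limited, so the
  extra seeds cost little.
* **Drop-off 4×|mismatch| instead of 2×.** Two clustered substitutions
  already cost −8; a 2× drop-off truncates near-threshold alignments mid-dip.
  4× tolerates three clustered substitutions, which is the worst case a
  score-12 array can contain.

Both choices are validated by the oracle-equivalence and thresholding
acceptance tests rather than by fiat: any search strategy that reproduces the
brute-force enumeration and the exhaustive-DP scores is conformant.

**Reported unit.** For imperfect repeats the unit is the per-column majority
consensus across aligned copies (ties go to the seed base), rotated to the
phase observed at the repeat start — stable under which copy happens to be
mutated. The motif *class* is the lexicographically least cyclic rotation
(ASCII order A < C < G < T) of the primitive reduction, so `(AAG)n`,
`(AGA)n`, `(GAA)n` all report class `AAG`. A motif and its reverse complement
are deliberately **not** merged (genes are annotated on both strands);
`motif_pair_label()` produces the conventional joint "AAG/CTT" display.

**Overlap resolution.** The published protocol reports non-redundant repeat
sets without stating a rule. Here, candidates overlapping ≥ 50% of the
shorter span compete; the higher score wins, ties prefer the smaller unit and
then the leftmost start. The output is pairwise below the threshold.

## Region schema

Per mRNA, ten region classes are materialized: the annotated 5′-UTR, CDS and
3′-UTR intervals, introns (gaps between consecutive exons), and six
intergenic windows tiled in transcription orientation from the transcript
ends: UI200 (1–200 nt upstream of the 5′-UTR), UI500 (201–700), UI1000
(701–1700), and the mirrored DI200/DI500/DI1000 downstream of the 3′-UTR.
For a minus-strand gene "upstream" is rightward in assembly coordinates.
When UTRs are unannotated the windows anchor on the gene start/end and the
UTR classes are skipped for that mRNA — exactly the fallback used for
UTR-less annotations in practice.

Windows are clipped at sequence ends only; overlap with neighboring genes is
allowed (no truncation rule was published). To keep density denominators
honest, per-class intervals are unioned before counting, so bases shared by
two mRNAs of one gene — or by windows of adjacent genes — count once. All
internal coordinates are 0-based half-open; GFF3 (1-based inclusive) is
converted at the I/O boundary only, which keeps the off-by-one surface to two
inverse functions.

## Densities, profiles, frequency tables

* **Density** = TR base pairs per megabase of *valid* (A/C/G/T) nucleotides.
  TRs crossing a region boundary contribute their clipped overlap, which
  makes per-class totals exactly additive over disjoint partitions.
* **Relative density** = 100 × region density / whole-genome density, so the
  genome is exactly 100 and values are comparable across species.
* **Positional profiles** normalize each region to a 0–99 scale with ten
  equal deciles and report the percentage of TR occurrences per decile,
  oriented 5′→3′ in the region's sense. A TR is assigned one decile by its
  **midpoint** — the unique anchor invariant to repeat length (start-based
  assignment is available behind a flag for sensitivity analysis). TRs are
  counted, not bp-weighted. Multi-interval regions (a spliced CDS, a
  multi-exon UTR) are profiled along the concatenated sense axis. A boundary
  note: a TR crossing a region edge contributes clipped bp to density but is
  binned only in the region holding its midpoint, keeping profiles
  single-counted; and exact bin-vector reversal under orientation flips holds
  when the region length is a multiple of ten (integer decile edges),
  otherwise the center decile maps to itself.
* **Frequency tables**: unit-size occurrence percentages over 1–50 nt, motif
  class counts, top-k motifs (ties broken alphabetically), and per-mRNA TR
  presence fractions (an mRNA counts once per class no matter how many TRs
  hit it).

## Comparative statistics

`pearson_test()` (two-sided p from *t* = *r*√((n−2)/(1−r²))),
`anova_oneway()` (F = MS_between/MS_within) and `tukey_hsd()`
(studentized-range q with the Tukey–Kramer form for unbalanced groups) are
implemented from the formulas; base R's `aov`, `TukeyHSD` and `cor.test`
serve as independent references in the tests (agreement to 1e-8). Groups are
intended to be region classes with one relative-density value per species or
replicate; relative (not raw) densities are the intended input, since that is
what the cross-species comparisons use. No correction beyond Tukey's own
family-wise control is applied. One numerical note: for two groups Tukey's
q equals |t|·√2 exactly, but R's `ptukey` is itself accurate only to ~1e-6,
so adjusted p-values agree with the pooled t-test to ~1e-6, with identical
decisions.

## The synthetic world

`simulate_genome()` draws iid background at a stated GC (the simplest null
under which planted enrichment is interpretable), lays out non-overlapping
gene models whose window stacks never collide (genes are spaced at least
2×1700 nt apart), and plants repeat arrays into designated region classes
until per-class target densities (or counts) are met. Defaults describe a
compact plant-like chromosome: 4 exons × 250 nt CDS, 350 nt introns,
250/350 nt UTRs, one gene per ~10 kb. Planted arrays:

* are pairwise disjoint and separated by at least 12 background bases
  (`plant_gap`), so seed extension cannot bridge two plants;
* never cross region boundaries, keeping truth-table accounting exact
  (clipped-overlap logic is exercised by handcrafted fixtures instead);
* satisfy the detector thresholds (≥ 12 nt, ≥ 2 copies) before mutation;
* have their two flanking background bases adjusted, when needed, to break
  the repeat period, so the planted span is exactly the maximal detectable
  span — this is what makes "exact span + unit" recall a meaningful metric;
* draw motifs from a GC-matched pool (all primitive canonical units of size
  1–3 by default, weighted by a Gaussian in motif GC around the background
  GC, sd 12 percentage points), emulating the observed coupling between
  regional GC and top motifs.

Mutations are applied per copy: substitution with probability
`imperfection_rate` (position uniform in the copy, base uniform over the
three alternatives), optional single-base indels. The mutation log is
sufficient to reconstruct the planted sequence, and the tests replay it.

For the qualitative two-regime contrast the plant-like plan uses the target
densities stated at design time (FIVE_UTR 30,000; UI200 25,000; CDS 5,000
bp/Mbp). No numeric alga-like targets were stated, so this package fixes
INTRON 30,000 / CDS 20,000 bp/Mbp once — intron above CDS above everything
else, matching the reported ordering of relative densities in algae — and
does not revisit it.

**What a green test does and does not establish.** The background is iid:
no isochores, no transposable elements, no centromeric satellites, no
mutation–drift repeat dynamics. Background-born repeats exist (an iid genome
at 40% GC carries a few thousand bp/Mbp of mostly A/T-rich repeats) and are
*quantified* via a no-planting control run on the same background stream
rather than excluded. Recovery of planted truth therefore validates the
machinery — coordinates, scoring, normalization, strand handling — not any
claim about real genome composition.

## Numerical and degenerate-input choices

* Integer scores throughout; alignment ties in the traceback prefer
  match > gap-in-reference > gap-in-window, and consensus ties keep the seed
  base, making detection deterministic and strand-symmetric.
* Sequences shorter than `min_length`, all-N sequences, and empty inputs
  yield empty (not missing) results; zero valid nucleotides in a density
  denominator, constant vectors in correlations, and groups without
  replication raise typed errors rather than NaNs.
* The whole-genome profile orientation is the forward strand; intragenic and
  UI/DI profiles follow gene strand.
* `simulate_genome(spec, seed)` is a pure function of its arguments; the
  caller's RNG state is saved and restored.

## Known limitations

Unit sizes above 50 nt are out of scope (as in the protocol this follows);
no probabilistic/HMM repeat models; no masking of low-complexity sequence
before detection; GFF3 support targets canonical files (ID/Parent links,
gene → mRNA → exon/CDS/UTR); the CLI config mirror is JSON, not YAML, since
no YAML parser is available in the supported dependency set.
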