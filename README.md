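# trscape

Tandem repeat (TR) landscapes in genomes and gene regions.

Tandem repeats — at least two adjacent copies of a 1–50 bp unit, perfect or
degenerate — are strongly and non-randomly enriched in particular parts of
genes: land plants concentrate them in 5′-UTRs and the promoter-proximal
UI200 window, green algae in introns and CDS. `trscape` is an R package for
quantifying that landscape from a genome FASTA and a GFF3 annotation:

* **Detection** — perfect TRs as maximal primitive tandem runs; imperfect TRs
  by seed-and-extend with wraparound dynamic programming against `u^∞`
  (defaults: unit 1–50 bp, length ≥ 12 nt, alignment score ≥ 12 under
  +1/−4/−4), with score-based resolution of overlapping calls. The hot loops
  are compiled (Rcpp).
* **Motif algebra** — canonical cyclic rotation (class `AAG` for
  {AAG, AGA, GAA}), primitive-unit reduction, reverse complements (tracked as
  separate classes, displayed jointly as "AAG/CTT"), GC content over valid
  nucleotides only.
* **Region schema** — 5′-UTR, CDS, intron, 3′-UTR plus strand-aware
  intergenic windows UI200/UI500/UI1000 (1–200, 201–700, 701–1700 nt upstream
  of the 5′-UTR) and their DI mirrors downstream, with gene-end fallback when
  UTRs are unannotated.
* **Statistics** — densities in bp/Mbp of valid sequence; relative densities
  normalized so the whole genome is 100; decile positional profiles on a 0–99
  scale; unit-size and top-motif tables; per-mRNA TR presence; Pearson *r*,
  one-way ANOVA F, and Tukey HSD for cross-region/cross-species comparisons.
* **Synthetic genomes** — `simulate_genome()` plants TR arrays with known
  coordinates, motifs (GC-matched pools) and mutations into chosen region
  classes of a generated genome, so the entire pipeline is testable against
  ground truth.

## Worked example

Simulate a plant-like 200 kb chromosome (20 genes, 40% GC) with TRs planted
at 30,000 bp/Mbp in 5′-UTRs, 25,000 in UI200 and 5,000 in CDS, then recover
the landscape:

```r
library(trscape)

spec <- simulation_spec(
  sequence_length = 200000, genes_per_sequence = 20, background_gc = 40,
  plan = list(FIVE_UTR = 30000, UI200 = 25000, CDS = 5000))
sim <- simulate_genome(spec, seed = 42)

trs <- detect(sim$sequences)       # 102 TRs (planted + background-born)
head(trs[, 1:9], 3)
#>   seq_id start  end    unit canonical_unit unit_len copies score perfect
#> 1   chr1  2863 2875  CGGTTC         CCGGTT        6      2    12    TRUE
#> 2   chr1  4959 4973 CAAAGCG        AAAGCGC        7      2    14    TRUE
#> 3   chr1  6268 6280      AC             AC        2      6    12    TRUE

regions <- extract_all_regions(sim$models, sim$sequences)
compute_density(trs, regions, sim$sequences)
#>    region_class total_valid_nt tr_bp density relative_density gc_percent
#> 1        GENOME         200000  1403    7015            100.0       39.9
#> 2        UI1000          20000    72    3600             51.3       39.8
#> 3         UI500          10000    70    7000             99.8       39.8
#> 4         UI200           4000   115   28750            409.8       40.1
#> 5      FIVE_UTR           5000   172   34400            490.4       39.1
#> 6           CDS          20000   197    9850            140.4       40.0
#> 7        INTRON          21000   144    6857             97.7       40.2
#> 8     THREE_UTR           7000    27    3857             55.0       39.4
#> 9         DI200           4000    12    3000             42.8       41.4
#> 10        DI500          10000    77    7700            109.8       40.2
#> 11       DI1000          20000   124    6200             88.4       39.4
```

Reading the table: the planted 5′-UTR and UI200 enrichments are recovered as
the two highest relative densities (490 and 410 vs genome = 100 — i.e. 4.9×
and 4.1× the genome-wide density of 7,015 bp/Mbp); the unplanted classes sit
near or below 100, reflecting background-born repeats only. Every planted
array is recovered with exact span and motif class:

```r
key <- function(d) paste(d$seq_id, d$start, d$end, d$canonical_unit)
mean(key(sim$truth) %in% key(trs))
#> [1] 1
```

Cross-species style comparison of relative densities (one value per
replicate/species per region class):

```r
groups <- list(
  FIVE_UTR = c(590, 612, 488, 705), UI200 = c(464, 512, 377, 506),
  INTRON = c(57, 81, 66, 49))
anova_oneway(groups)
#> anova: statistic = 77.6396, p = 2.108e-06
tukey_hsd(groups)$pairwise
#>    group_i group_j diff     q    p_adj significant
#> 1 FIVE_UTR   UI200 -134  4.24 3.64e-02        TRUE
#> 2 FIVE_UTR  INTRON -536 16.93 2.11e-06        TRUE
#> 3    UI200  INTRON -402 12.70 2.33e-05        TRUE
```

So all three regions differ in mean relative density (F = 77.6,
p = 2.1e-06), and every pairwise contrast survives Tukey's family-wise
control at α = 0.05.

## Command line

```sh
trscape simulate  --spec spec.json --seed 1 --out sim/
trscape detect    --fasta genome.fa --out trs.tsv --bed trs.bed \
                  --max-unit 50 --min-length 12 --min-score 12
trscape regions   --fasta genome.fa --gff3 genes.gff3 --out regions.bed
trscape densities --fasta genome.fa --gff3 genes.gff3 --trs trs.tsv --out dens.tsv
trscape profiles  --fasta genome.fa --gff3 genes.gff3 --trs trs.tsv --out prof.tsv
trscape stats     --densities groups.tsv --test tukey --alpha 0.05 --out out.tsv
```

The wrapper script is installed at `inst/cli/trscape`
(`system.file("cli", "trscape", package = "trscape")`); `--config file.json`
supplies any flag as a default.

## Documentation

The methods vignette (`vignettes/tandem-repeat-landscapes.Rmd`) documents the
repeat and scoring model, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, numerical
tie-breaking choices, and known limitations.
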