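# todcourse

Time-of-day (TOD) expression analysis over developmental time courses.

Plants partition the expression of most genes to specific hours of the
day, and under field conditions that partitioning drifts over the growing
season with temperature, day length and plant age. The classic design for
measuring this samples the transcriptome every 2 h over two days
(Zeitgeber time ZT6–ZT54, 25 samples) at a series of developmental stages
— for example, field-grown rice leaf and root profiled at eleven stages
across a season. `todcourse` provides the full analysis stack for such
data, plus a seeded synthetic-data generator so every stage is testable
by parameter recovery without any download.

## What it computes

- **Rhythmicity detection** (HAYSTACK-style): each expressed gene's
  `log2(x + 1)` profile is correlated against a library of period-24 h
  templates — six shapes (cosine, sharpened cosine, box, spike, rising
  and falling ramps) at each of 24 hourly phase offsets, standardized on
  the sampling grid. A gene is rhythmic when its best correlation
  satisfies `R >= 0.8`, and its phase is the best template's offset: the
  time of day of peak expression. Summaries follow the conventional
  mixed-denominator table (not-expressed and not-rhythmic as % of total,
  rhythmic as % of expressed).
- **Quantile normalization** per condition (via limma).
- **Circular phase-shift analyses** between stages: baseline (every
  stage vs. a fixed anchor) and incremental (consecutive stages), with
  forward shifts `(φ_t − φ_r) mod 24` as the primary statistic,
  histograms, same-phase fractions, and shift-window gene selection.
- **Promoter element discovery** (ELEMENT-style): presence counts of all
  87,360 DNA words of length 3–8 in fixed 500 bp promoters;
  hypergeometric overrepresentation of each word in each phase-binned
  gene list against the promoter universe, BH-corrected within each list
  (`q < 0.05`); significant words clustered into motifs with
  position-frequency matrices and per-(condition, hour) TOD significance
  profiles. With 11 conditions and the 23-bin option this is the
  canonical 253-list schedule.
- **GO-by-phase enrichment** with the same hypergeometric/BH machinery
  against a per-condition expressed-gene universe, occurrences-per-day
  ranking, and cross-stage overlap summaries.
- **Sample similarity QC**: all-sample correlation matrix, classical MDS
  on `1 − r`, and exact cycling-set overlaps.
- **A pipeline driver** (`runPipeline()`) orchestrating all stages from
  either the synthetic generator or TSV/FASTA inputs on disk, writing
  tab-delimited outputs and a manifest (parameters + md5 checksums) that
  makes runs reproducible and auditable.

## Worked example

```r
library(todcourse)

sim <- simulateTimecourses(simConfig(seed = 42))   # 1000 genes, 3 stages,
tcs <- lapply(sim$timecourses, quantileNormalize)  # planted drifts 0/+2/+6 h
lib <- buildModelLibrary(ztGrid(tcs[[1]]))
css <- lapply(tcs, detectCycling, lib = lib)
css[[1]]
#> CyclingCallSet: leaf_15d
#>   total 1000 | not expressed 200 (20%) | not rhythmic 241 (24%) |
#>   rhythmic 559 (70% of expressed)

inc <- incrementalAnalysis(css)
names(which.max(shiftHistogram(inc[[1]])))   # "2"  (planted +2 h drift)
names(which.max(shiftHistogram(inc[[2]])))   # "4"  (+6 − +2 h)

prom <- simulatePromoters(sim$truth, seed = 42)
enr  <- runElement(css[1], prom)
sig  <- unique(enrichmentTable(enr)$kmer[enrichmentTable(enr)$significant])
head(summarizeClusters(clusterKmers(sig), enr), 1)
#>   cluster  consensus nMembers         minQ bestCondition bestBin
#> 1       1 CAAATATCTC       20 2.541569e-34      leaf_15d      12
```

Reading the output: 20% of genes were simulated at background and are
called not expressed; 70% of the expressed genes are rhythmic at
`R >= 0.8`. The incremental phase analysis recovers the planted
developmental drifts as modal shifts of +2 h and +4 h. The element scan
finds the planted Evening Element (`AAATATCT`, inserted into 80% of the
promoters of genes peaking at ZT12): its motif cluster ranks first, with
its strongest overrepresentation exactly in phase bin 12.

File-mode works the same way on your own data: per-condition TSV
matrices (gene × ZT columns), a promoter FASTA and a two-column gene→GO
map, via `pipelineConfig(inputFiles = ...)`.

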