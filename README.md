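# tagcount

Transcript counting from 3'-tagged RNA-seq read pairs.

## The problem

Shallow, highly multiplexed expression profiling can be done by
sequencing a single tagged fragment from the 3' end of every
polyadenylated molecule instead of sampling whole transcripts.  In
such a library, read 1 starts with a 12-base unique molecular
identifier (UMI), an 8-base inline sample index and an anchored polyT,
then reads antisense into the transcript — so the first aligned base
past the trimmed polyT pins the transcript's 3' terminus to a single
genomic base (a *transcript-counting 3' end*, TC 3' end).  Read 2
samples the sense strand and is what gets counted.  The UMI separates
PCR copies from independent molecules: a pair is a duplicate when it
shares outer mapping coordinates *and* UMI with another pair.

`tagcount` implements the full analysis for this design, for anyone
running two-condition comparisons (mutant vs sibling, treated vs
control) across many small samples:

1. **detag** — parse and validate the read-1 tag structure,
   demultiplex by index, carry UMI + index in the read name;
2. **dedup** — UMI-aware duplicate marking on
   (reference, outer start, outer end, orientation, UMI) keys;
3. **peaks** — pool all read 2s into 100-bp bins and call regions with
   a two-state Poisson-emission HMM (posterior ≥ 0.5, adjacent peak
   bins merged);
4. **TC 3' ends** — candidate ends per region from paired read 1s;
   ends with < 3 supporting pairs are dropped, and ends whose 10-base
   downstream context is A-enriched (4 leading As, > 6 As in total, or
   one of 12 empirical A/B patterns with B ∈ {C,G,T}) are flagged as
   internal oligo-dT mispriming artifacts;
5. **annotate** — nearest same-strand annotated transcript 3' end,
   signed distance, stringent (−100..+100) or relaxed (−100..+5000)
   proximity windows, transcript blacklist, 150-base
   region-consistency rule;
6. **quant/DE** — per-region, per-sample counts; median-of-ratios size
   factors; per-region negative-binomial Wald test (moment dispersion
   shrunk toward a mean–dispersion trend); independent filtering of
   low-mean regions; Benjamini–Hochberg adjustment; a gene-list table
   in CSV/TSV/HTML;
7. **permute** — the replicates-versus-depth experiment: split merged
   condition pools into k pseudo-samples at constant total reads and
   rerun the pipeline over k;
8. **simulate** — a truth-annotated generator for the whole stack: toy
   genome, tagged FASTQ/pre-aligned SAM reads with PCR duplicates and
   planted misprime sites, and NB count matrices including a
   ×5/×1/×0.2/×0.1 spike-tier design.

For a region with normalised counts K_gs, condition effect β_g is
estimated by the NB GLM `K_gs ~ condition + offset(log s_s)` with
dispersion α_g fixed at a trend-shrunken moment estimate; the reported
log2 fold change is β_g/log 2 (second condition over the first) and
the Wald statistic is referred to a t distribution on n − 2 degrees of
freedom.

## Worked example

Everything below is simulated, so it runs anywhere in a few seconds
and the truth is known:

```r
library(tagcount)

cfg <- simConfig(seed = 12, nTranscripts = 20,
                 exprMeanlog = log(120), nPerCondition = 4)
sr  <- simulateReads(cfg)              # FASTQ + pre-aligned SAM + truth
run <- runPipeline(sr$sam, sr$sim$genome, sr$sim$annotation, sr$samples,
                   sampleMap = sr$layout@indexWhitelist)

nrow(sr$fastq)                         # 32794 read pairs
duplicateRate(run$pairs)               # 0.0198  (UMI-aware)
duplicateRate(run$pairs, "coords_only")# 0.846   (coordinates alone)
run$model
#> PeakModel (2-state Poisson HMM)
#>   background mean 1.152, peak mean 499.9
#>   logLik -13739.07 after 11 EM iterations (converged)

run$hits[, c("gene_name", "tc_position", "tc_strand", "tc_support",
             "distance", "log2_fold_change", "adjusted_p")]
#>  gene_name tc_position tc_strand tc_support distance log2_fold_change  adjusted_p
#>       g011        2113         +        495        0        -2.086798 0.003223209
#>       g017       22019         +         85        0        -2.299829 0.003223209
#>       g006       15450         -        907        0         1.563995 0.004651144
#>       g007       18766         +       1360        0         2.168784 0.007034791
```

The simulation planted 4-fold changes on tx006 and tx007 (up) and
tx011 and tx017 (down); the pipeline reports exactly those four genes
— TC 3' ends at distance 0 from the annotated termini, log2 fold
changes near ±2 with the right signs — and nothing else.  The
coordinate-only duplicate rate (0.85) versus the UMI-aware rate
(0.020) shows why the UMI matters: at a single 3' position almost all
coordinate collisions are independent molecules.
`run$tce` is a `TagCountExperiment` (a `RangedSummarizedExperiment`
of regions × samples), `run$geneList` the full output table, and
`writeGeneList(run$geneList, "out.tsv", "tsv")` writes it.

A thin CLI over the same functions is in
`inst/scripts/tagcount.R` (subcommands `detag`, `dedup`, `peaks`,
`run`, `simulate`).

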