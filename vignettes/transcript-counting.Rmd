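---
title: "Transcript counting from 3'-tagged read pairs: methods and design"
author: "tagcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript counting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagcount)
```

# The measurement

A transcript-counting library samples one fragment per polyadenylated
molecule at its 3' end.  Read 1 is primed off the polyA tail through an
anchored oligo-dT primer that carries, 5' to 3', a 12-base unique
molecular identifier (UMI), an 8-base inline sample index, a short
fixed spacer and an anchored polyT stretch; the sequence 3' of the
polyT reads antisense into the transcript, so the aligned base of the
trimmed read closest to the former polyT junction marks the
transcript's 3' terminus to single-base resolution.  Read 2 samples
the sense strand at the other end of the fragment (insert sizes of
70–270 bases) and is what gets counted.  Because every molecule is
tagged before amplification, PCR duplicates can be recognised as read
pairs sharing both their outer mapping coordinates and their UMI, and
abundance estimates are per-molecule rather than per-read.

The pipeline turns duplicate-marked paired alignments into a table of
transcript-counting 3' ends (TC 3' ends) with per-sample counts,
distances to annotated transcript ends, and negative-binomial
differential-abundance statistics between two conditions.

# Stages and their assumptions

## Tag parsing and demultiplexing

`parseRead1()` requires the UMI, index, optional spacer and a polyT
run of at least `minPolyT` bases (default 10), in that order.  The
polyT run is the maximal T-stretch allowing one non-T base per ten Ts,
each absorbed miscall having to be followed by another T; the anchor
is nominally 14 Ts, and the tolerance keeps reads with a single
sequencing miscall inside the run without ever swallowing the first
transcript base.  The spacer is matched greedily and is optional (0 up
to its full length is consumed), since earlier primer designs omit it.
Index assignment is exact by default (`maxIndexMismatches = 0`):
without knowledge of the pairwise distances of a concrete index set,
exact matching is the safe default, and the whitelist validity check
enforces separability whenever a tolerance is raised.  UMIs are
accepted with any base including `N`, but an `N`-containing UMI never
matches another UMI during duplicate marking — ambiguity is resolved
toward keeping molecules distinct.  Reads with an empty insert after
trimming are rejected as unmappable.

## UMI-aware duplicate marking

A pair's duplicate key is (reference, outer start, outer end, pair
orientation, UMI).  Within a key group exactly one representative
stays unflagged: the pair with the highest summed base quality, ties
broken by lexicographically smallest read name — a deterministic
convention in the style of standard duplicate markers, which do not
publish their exact rule.  UMI comparison is exact; no error-network
collapsing is attempted, mirroring the method's own accounting of UMI
alteration during amplification as a residual limitation.  Pairs with
an unmapped mate have undefined outer coordinates and are never
flagged.

## Peak regions

All read 2s of the experiment — samples pooled — are placed into
100-bp bins by leftmost mapped base; duplicate-flagged reads and reads
with more than two mismatches are ignored.  A two-state hidden Markov
model (background/peak) with Poisson emissions per state is fitted to
the binned counts by Baum–Welch EM, each reference being an
independent chain.  Poisson emissions are the simplest adequate
family for sparse tag coverage and are a documented swap point.
Initialization is deterministic and data-driven (background mean from
the lower 95% of bins, peak mean from the top 5%) with a
background-favouring transition prior (0.999 background
self-transition, 0.9 peak self-transition), reflecting the expectation
that peaks are rare.  EM runs to an absolute log-likelihood tolerance
of 1e-6 with a 200-iteration cap; states are relabeled afterwards so
the background mean is the smaller one.  Bins with posterior peak
probability ≥ 0.5 are selected and maximal runs of adjacent selected
bins merge into regions.  Degenerate tracks (constant counts) yield a
flagged model from which no peaks are called; an all-zero track is an
error.  Posteriors are clamped to [0, 1] to guard floating-point ulps.

## TC 3' ends and the mispriming filter

For each region, the read 1 paired with every in-region read 2
contributes a candidate end at its junction-proximal aligned base
(soft-clipped bases do not count); the transcript strand is the
opposite of the read-1 alignment strand, because read 1 reads
antisense off the tail.  Candidates supported by fewer than 3
non-duplicate pairs are dropped.  The remaining candidates are tested
on the 10 genomic bases immediately 3' of the end in transcript
orientation: the end is an internal-polyA mispriming artifact when the
first four bases are all A, when more than six of the ten are A, or
when the context matches one of twelve empirically determined A/B
patterns with B read as IUPAC "not A" ({C, G, T}), consistent with the
primer legend that uses the same symbol.  `N` counts as non-A in all
three rules — conservative toward retention.  At a contig edge the
truncated context is tested with whichever rules still apply.  An
optional known-false-ends list removes recurrently artifactual
positions (such as A-rich mitochondrial rRNA stretches that escape the
sequence rules) before selection.  The surviving candidate with the
highest support represents the region; ties break to the smallest
genomic position for determinism.

## Annotation association

Each selected end is matched to the nearest annotated transcript 3'
end on the same chromosome and strand, after removing blacklisted
transcripts; search is per transcript, with gene fields carried along,
so genes with several 3' ends compete by proximity.  The distance is
signed in transcript orientation — negative when the annotated end
lies 5' of the TC end — which lets the asymmetric windows read
directly: stringent passes [-100, +100], relaxed [-100, +5000], bounds
inclusive.  Direction is constrained only by the window, since the
windows themselves are asymmetric.  Equidistant transcripts resolve to
the lexicographically smallest ID.  A region supports its end only if
its 3'-most coordinate is at most 150 bases upstream of the end.

## Quantification and differential abundance

Counts are non-duplicate read 2s per region and sample.  Size factors
are classic median-of-ratios: per sample, the median over
all-positive-count regions of the ratio to the row geometric mean,
rescaled so the factors have unit geometric mean; rows with a zero are
excluded from the median, with a positive-subset fallback when no
all-positive row exists.  Each region is then tested with a
negative-binomial GLM of counts on the two-level condition, log size
factors as offset.  The dispersion is a per-region method-of-moments
estimate pooled within condition, shrunk on the log scale (weight 0.8)
toward a fitted mean–dispersion trend of the form a0 + a1/mean — a
deliberately simple stand-in for heavier empirical-Bayes machinery,
and a documented swap point for delegating to a dedicated engine.  The
Wald statistic on the condition coefficient is referred to a t
distribution on (samples − 2) degrees of freedom, a small-sample
calibration in the spirit of quasi-likelihood pipelines; the package's
validation checks that this combination holds the nominal type-I rate
on a 10,000-region null.  Fold changes are reported as the second
condition level over the first.  Independent filtering scans 40
base-mean quantile cutoffs, BH-adjusts above each, and keeps the
cutoff maximising rejections at the chosen level (ties to the least
filtering); censored regions get a missing adjusted p-value, which the
writers serialize as `NA`.  The final hit filter applies adjusted
p ≤ 0.05, |fold change| ≥ 2 — both inclusive, since the printed
threshold appears both as strict and non-strict and a parameterised
inclusive default covers both — the chosen proximity window, and
region consistency.

## Replicates versus depth

`runPermutationExperiment()` downsamples each condition pool to a
common size, assigns each pair independently and uniformly to one of k
pseudo-samples per condition (a multinomial split — the simplest
faithful reading of assigning reads at random), re-marks duplicates
within each merged pool (duplicates are a property of the pool, not of
the pseudo-labels), reruns the entire pipeline per (k, repetition),
and records the number of ends with adjusted p ≤ 0.05 under the
relaxed window.  Because pseudo-replicates are Poisson splits of one
pool, the between-replicate variance of the original biological
libraries is absent, so absolute significant-end counts are optimistic;
the meaningful output is the trend in k, which the validation asserts
as mean significant ends at k = 11 being at least those at k = 2.

# The simulator

`simConfig()` fixes the study conditions the package is validated
under: 50 transcripts on 2 contigs, 6 samples per condition, baseline
expression log-normal with median 260 read pairs per transcript per
sample (about 200k pairs in total), NB dispersion 0.1 (typical of
biological replicates of whole animals), a 2% PCR duplication rate in
the range reported for well-behaved libraries of this type, 5 planted
misprime sites, a 0.001 substitution error rate, fragment lengths
uniform on 70–270 bases matching the library's size selection, read
lengths 75/54, and a 20% fraction of transcripts with a true 4-fold
change split between directions.

The generator writes A-poor ({C, G, T}) contexts 3' of every true end,
so no artifact rule can fire on a truth position, and rule-matching
A-rich contexts at misprime sites (cycling through the
leading-A, total-A and pattern rules), so every planted artifact is
filterable in principle; reads from misprime sites are generated by
the same fragment machinery as true ends.  Duplicates are exact copies
sharing the UMI (one extra copy with the probability that yields the
configured duplicate fraction); errors are i.i.d. substitutions
applied per molecule before copying, so copies stay exact, and they
hit the tag prefix as well as the insert.  Reads are emitted both as
FASTQ and as pre-aligned SAM whose names already carry UMI and index,
so the alignment step can be bypassed; a spike mode adds 92
single-transcript contigs on a descending abundance ladder with the
four concentration tiers (×5, ×1, ×0.2, ×0.1) in triplicate as sample
conditions.  The count-level shortcut `simulateCounts()` /
`simulateSpikeCounts()` feeds the differential stage directly; the
spike design includes a constant host background because
median-of-ratios normalisation would otherwise absorb the global tier
multiplier — the same reason the real assay measures spikes against a
fixed total-RNA pool.

What the simulator does not emulate: realistic error profiles and
quality strings, indels, GC and positional coverage bias, multimapping
and alignment ambiguity, annotation incompleteness, or UMI errors
arising during amplification.  Passing the validation therefore shows
the pipeline's logic is correct under its own model of the data, not
that real libraries are free of those effects.

# Validation scale

The checked-in validation runs at desk scale, chosen to exercise every
stage meaningfully: the full-pipeline closure uses the default
configuration above (~200k read pairs, about 75 s end to end); peak
recovery uses 20 seeded 2000-bin tracks with background mean 0.5 and
planted 4-bin intervals at mean 10; duplicate-marking equivalence uses
100 seeded libraries of up to 200 pairs against an exhaustive pairwise
oracle; the null calibration uses 10,000 NB regions at 6 + 6; and the
replicates-versus-depth trend uses two ~40k-pair pools scanned at
k = 2 and k = 11 with three repetitions.  Published experiments at
hundreds of millions of reads are outside the scope of these checks.

# Known limitations

* Poisson emissions understate overdispersion in real coverage; a
  negative-binomial emission family is the natural extension.
* The dispersion trend is a two-parameter curve without empirical-Bayes
  weighting; borderline regions inherit its bias.
* Duplicate marking does not correct UMI sequencing errors, so the
  duplicate rate is a slight underestimate when UMIs mutate.
* Single-end and multi-factor designs are out of scope; the test is
  strictly two-condition.
* SAM is consumed as text; BAM inputs should be converted upstream
  (e.g. `samtools view -h`).
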