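---
title: "Detecting tumor-specific splice-junction outliers"
author: "spliceOutliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-specific splice-junction outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceOutliers)
```

# The problem and the model

Alternative splicing in tumors is often *private*: a splice form may be
strongly expressed in a subset of patients and silent in the rest, together
with the matched normals. Differential methods that compare group means are
poorly matched to this structure — averaging over the non-carrier tumors
washes the signal out. This package instead asks, for every splice junction
and every individual tumor sample, "is this sample an outlier relative to
the distribution of the normal panel?", and then asks, per junction,
whether outliers accumulate among tumors more than chance allows.

The unit of observation is a splice junction: the intron removed by a
splicing event, recorded by spliced aligners (STAR's `SJ.out.tab`) as a
1-based inclusive interval with a unique-read count. Because junction reads
are specific to one exon–exon join, they pinpoint the event more sharply
than exon coverage does. Only uniquely mapping reads are counted, both per
junction and in the library size; multi-mapping counts are ignored
throughout.

## Normalization

Raw counts are not comparable across samples or genes. Two divisions make
them so:

1. **Library size**: counts are divided by the sample's total uniquely
   mapped reads and expressed per million (RPM). The scale is configurable
   (`normParams(scale=)`); on the proportion scale the expression floor
   (below) is rescaled by $10^{-6}$ so that the two scales call identical
   outliers. Per-million is the default because the floor parameter is
   conventionally stated on that scale.
2. **Host-gene expression**: junction RPM is divided by the gene's
   expression after per-sample upper-quartile normalization (each sample is
   rescaled so the 75th percentile of its *expressed* genes equals
   `uqTarget`, default 1000, the convention of the widely used
   upper-quartile utilities). This separates *splicing* changes from
   *transcription* changes: a junction in a uniformly up-regulated gene is
   not an outlier after this division.

Two deliberate edge rules: junctions inside no annotated gene are kept with
divisor 1 and flagged `no_gene`, because novel unannotated junctions are a
primary discovery target; and cells whose gene expression is zero while the
junction has reads are marked *undefined* rather than infinite — they are
excluded from both the fences and the Fisher table (they reduce the
effective group sizes for that junction).

## Outlier calls

For each junction the normal panel's defined values define a reference
distribution summarized by robust fences:

$$\mathrm{upper} = Q_{1-q} + m \cdot \mathrm{IQR}, \qquad
  \mathrm{lower} = Q_{q} - m \cdot \mathrm{IQR}$$

with tail quantile $q = 0.25$ and multiplier $m = 1.5$ by default (both
exposed in `outlierParams()` so other fence rules can be substituted). A
tumor cell $x$ is an **over** outlier when all of:

* $x$ strictly exceeds the upper fence (strict, so constant junctions can
  never produce outliers);
* $x \ge$ `minNormExpr` (default $10^{-5}$ on the RPM-over-gene scale) —
  the absolute expression floor that removes biologically negligible
  events;
* $x \ge F \cdot \max(\mathrm{median_{normal}}, \varepsilon)$ with
  fold-change cutoff $F$ (default 10) and $\varepsilon = 10^{-12}$ guarding
  the ratio when the normal median is 0 (any tumor expression above the
  floor over an all-zero normal background qualifies).

**Under** is symmetric: $x$ strictly below the lower fence, both $x$ and
the normal median at or above the floor (a cell below the floor is never an
outlier in either direction), and the normal median at least $F$ times $x$.
A consequence worth knowing: a junction completely silenced in a tumor
($x = 0$) is *not* an under outlier — the method is oriented toward
expressed aberrant events, not loss calls.

Normal samples receive calls too, against leave-one-out fences: a normal
compared to a panel containing itself can never be extreme, and the Fisher
test below needs honest normal outlier counts. Junctions with fewer than
two defined normal values are wholly undefined.

The default fold-change cutoff of 10 reflects the intended use on real
tumor cohorts, where interesting events differ by an order of magnitude
from normal; the simulation benchmark lowers it to 2 because the simulated
expression design varies only 1–5x.

## Junction-level inference

Per junction and per direction, a one-sided Fisher's exact test compares
outlier counts: $[[a, n_T - a], [b, n_N - b]]$ with the alternative "more
outliers among tumors" (the hypergeometric upper tail, computed exactly).
Two one-sided tests per junction, rather than one two-sided test, because
over- and under-expressed events are biologically distinct findings; the
Benjamini–Hochberg correction is pooled across *all* (junction, direction)
pairs so the FDR guarantee covers everything reported. Junctions on chrX
and chrY are removed before testing by default — tumor/normal cohorts are
rarely sex-matched, and sex-linked expression differences masquerade as
splicing signal.

## Gene mapping and event classification

A junction maps to the gene whose span contains its intron on a compatible
strand (undetermined-strand junctions may match either strand). When
several genes qualify, the gene sharing an annotated splice site with the
junction wins, then the smaller span, then the lexicographically first id —
deterministic and documented, and `tieBreak = FALSE` leaves ambiguous
junctions unassigned instead. Event types are assigned by boundary
placement against the exon model, in a fixed priority order:

* **annotated** — the junction equals an annotated intron;
* **skipping** — both boundaries are annotated splice sites of one
  transcript and the intron swallows at least one of its exons whole;
* **deletion** — a boundary falls strictly inside an annotated exon (part
  of the exon is spliced away);
* **insertion** — boundaries in annotated intronic sequence matching no
  annotated site (novel exonic sequence implied).

Frame information is not used — a junction-count data model has none — so
insertion/deletion here describe boundary geometry, not reading-frame
effects. Retained introns are invisible to junction counts and are not a
class.

# The simulator: what it emulates, what it does not

`simulateCohort()` reproduces the *statistical design* of a read-level
benchmark at the junction-count level. It lays out `nGenes` (default 1000)
non-overlapping multi-exon genes (3–8 exons, exon lengths 100–300 bp,
intron lengths 500–2000 bp — unremarkable compact-gene dimensions chosen
once) on one autosome, each with a canonical transcript; `nAltGenes`
(default 200) genes additionally carry an alternative transcript skipping
one internal exon. Expression multipliers are drawn per transcript *and*
sample: canonical uniform 1–2x of the 600-read baseline everywhere; the
alternative transcript at exactly 1x in the 20 normals, uniform 1–2x in 20
"low" tumors and uniform 4–5x in 20 "high" tumors — the heterogeneous
tumor-cohort design the method targets. Per-sample draws (rather than one
draw per transcript) were chosen because heterogeneity across samples is
the stated point of the design; this is documented as a choice, not a
reconstruction.

Each junction's count is a noise draw around the summed expected reads of
the transcripts containing it (Poisson by default; negative binomial with
configurable dispersion, or `"none"` for the noiseless closed-form limit);
gene expression is the summed expected reads of the gene's transcripts with
the same noise family; the library size is the sample's total simulated
reads. All randomness flows through one seed, and the caller's RNG state is
restored.

What this deliberately does **not** emulate: read-level artifacts.
A FASTQ → aligner → quantifier pipeline produces junction counts that are
sparse subsets of transcript reads (only reads spanning the junction
count), plus misalignments, spurious novel junctions and multi-mapper
misassignment. Those artifacts are precisely what makes real benchmarks
report imperfect sensitivity and substantial false discovery. Under clean
Poisson counts at a 600-read baseline the coefficient of variation is a few
percent, so a 2-fold deviation from the normal median — the outlier
requirement at the benchmark cutoff — essentially never happens by chance,
and every alternative gene depresses its two flanking junctions by 2.3–6x
in the high tumors. The benchmark (`runSimulationBenchmark()`, and
`scripts/acceptance.R`) therefore shows near-perfect recovery: passing it
demonstrates that the statistical machinery is implemented correctly and
that the design is detectable *in principle*; it does not demonstrate
robustness to aligner noise, and results on real data should be expected to
be substantially noisier.

```{r benchmark, eval = FALSE}
# the full benchmark: ten replicate seeds, fold-change cutoff 2
out <- runSimulationBenchmark(simParams(), seeds = 1:10,
                              foldChangeCutoff = 2)
out[is.na(out$seed), ]   # mean metrics per call level
```

Evaluation uses two nested gene-level call sets: *identified* (any gene
with at least one junction having at least one tumor outlier call that
survived the floor and fold-change filters) and *identified + significant*
(a junction at BH-FDR ≤ 0.05). "Identified" is defined through surviving
outlier calls rather than through every tested junction; the alternative is
available via the events table directly.

# Numerical conventions

* **Percentile rule, upper-quartile normalization**: the $(n+1)p$
  linear-interpolation quantile (R's type 6), computed over *nonzero*
  values per sample; e.g. the q75 of expressed values {10, 20, 30, 40} is
  37.5. Both the interpolation rule and nonzero-only are configurable
  conventions, fixed and tested rather than left implicit.
* **Percentile rule, fences**: R's default type 7. The fence rule is a
  documented reconstruction — the modified outlier-sum statistic this
  reimplements is not printed in full anywhere — so `tailQuantile` and
  `iqrMultiplier` are exposed to swap alternatives in.
* **Ties**: outliers require *strict* fence crossings; waterfall ordering
  is a stable sort; duplicate metadata lines take the first occurrence with
  a warning.
* **Degenerate inputs**: empty junction files parse to empty cohorts;
  all-zero samples get library size 1 with a warning in the Firebrowse
  reader and an error in upper-quartile normalization (no expressed
  genes); junctions with fewer than two defined normals are undefined, and
  directions with an empty group are skipped rather than tested.
* **Coordinates**: junction keys are 1-based inclusive intron intervals
  (STAR's native convention). Firebrowse donor/acceptor positions are the
  flanking exon bases and are converted by +1/−1, so both input routes
  share one key space.
* **Serialization**: results and burden tables are plain TSV, numerics at
  full precision; undefined cells export as `NA`.

# Known limitations

* Percent-spliced-in is out of scope: outlier calls are on normalized
  junction expression, not inclusion ratios.
* Under-expression calls require the tumor cell itself to reach the
  expression floor, so complete silencing is invisible (see above).
* A single gene assignment per junction; fusion-spanning or antisense
  events are not modeled.
* The rare-disease single-outlier setting (one affected sample, no tumor
  group) is a different problem and is not addressed.
* Statistical power is bounded by panel sizes: with 20 normals and 40
  tumors the smallest attainable Fisher p is about $2 \times 10^{-16}$,
  and pooled BH correction means isolated weak events (a handful of
  outlier tumors) will not reach significance — by design.
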