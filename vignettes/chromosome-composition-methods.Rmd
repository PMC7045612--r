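---
title: "Methods: chromosome-scale composition and comparative genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-scale composition and comparative genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcomp)
```

## Scope

`chromcomp` asks a single question in many forms: does one chromosome stand
out from the rest of its genome, and is that outlier status conserved
across species?  The package provides the per-chromosome statistics, the
between-assembly interval mapping, and a seeded synthetic-data generator
that plants every analyzed signal with truth tables, so the full pipeline
is verifiable at desk scale.  Chromosome sizes in the default study
conditions (0.5–1 Mbp) are deliberately small — a package-level choice that
keeps simulation plus analysis under a minute per species while leaving
every statistic's estimator in its asymptotic regime; nothing in the code
assumes these sizes.

## Coordinate conventions

Intervals are `GenomicRanges::GRanges`, 1-based and closed in memory — the
Bioconductor convention — and converted at the I/O boundary: BED and chain
files are 0-based half-open on disk, VCF and MAF positions are converted on
read.  This is a deliberate deviation from implementing a bespoke 0-based
interval type: reusing `GRanges` buys the audited interval algebra
(`reduce`, `setdiff`, `findOverlaps`) and interoperability with
`rtracklayer`, at the cost of one well-defined conversion per file format.

## Sequence composition

GC content is `(N_C + N_G)` over the unambiguous bases; `N` is excluded
from numerator and denominator.  The CpG observed/expected ratio is the
Gardiner-Garden–Frommer form

$$\mathrm{obs/exp} = \frac{N_{CpG} \cdot L}{N_C \cdot N_G}$$

with `L` the effective (non-N) length.  A CpG straddling a region boundary
is attributed to the region containing its C.  Islands are called with the
classic sliding-window scheme: 200-bp windows must satisfy GC ≥ 0.5 and
obs/exp ≥ 0.6 (defaults; both configurable), passing windows are merged,
candidates are split at N runs, then trimmed one base at a time — dropping
a non-G/C edge base preferentially — until the reported region itself
passes.  Consequently every reported island satisfies the thresholds,
which the test suite verifies directly.

## liftOver and the reciprocal filter

The chain parser is hand-rolled because the analysis needs the chain score
and per-block gap structure to implement `minMatch` semantics (the fraction
of an interval's bases falling in aligned blocks), which the available R
importers do not expose; results are cross-checked against
`rtracklayer::liftOver` in the tests.  Without `allow_multiple`, only the
best-scoring acceptable chain is used and a mapping broken into several
target pieces is reported as `split` with no targets; with it, all
acceptable chains contribute.  Negative-strand query coordinates are
converted to forward coordinates.  The reciprocal filter lifts A→B with
multiple mappings allowed (repeat-rich intervals genuinely map multiply),
lifts each piece back, and keeps a source interval only when a round trip
returns exactly to its original coordinates; a 95%-reciprocal-overlap mode
is available for noisier assemblies.

## Variants and substitutions

SNP density is variants per kbp with either the full region length or the
effective non-N length as denominator.  The common filter keeps
MAF ≥ 0.01 with the boundary included.  CpG context uses the both-position
rule by default: a variant is "in a CpG" when its reference base is the C
*or* the G of a reference CpG, because deamination mutates the methyl-C of
either strand and the plus-strand G marks the minus-strand C.

Substitutions between two aligned species are extracted column-wise from
MAF blocks (both bases unambiguous and different).  CpG context is
evaluated on each species' own gap-stripped block sequence; the default
`either` rule flags a site in CpG context in at least one species, since a
deamination event destroys the CpG in exactly one of them and a
reference-only rule systematically undercounts.  The generator's truth
tables use the `reference` rule, under which recovery is exact.

## Conservation, expression, methylation

Interval means of score tracks follow missing-data semantics: uncovered
bases are excluded from numerator and denominator, never zero-filled.  A
negative mean is flagged as accelerated.  The expression index of
dispersion is the chromosome's median per-gene variance (unbiased, n−1)
over its mean TPM; a `per_gene` mode averaging per-gene variance/mean
ratios is provided for comparison.  Methylation summaries are CpG-weighted
means over a feature set, contrasting a target chromosome against the
other chromosomes (`rest_mean`).  The contrast deliberately excludes the
target from the baseline: in a real genome the target carries a few
percent of all CpGs and the distinction is negligible, but in a compact
synthetic genome the target's own CpGs would dilute its planted signal.

Spearman's rho is the Pearson correlation of mid-ranks (tie-corrected),
with a two-sided t-approximation p-value, or an exact permutation p-value
for n ≤ 8.

## The synthetic generator

Sequences come from a first-order Markov chain over {A,C,G,T} with a
single CpG-depletion knob: rows start from the stationary marginals
implied by a GC parameter, the C→G transition is scaled by a factor, and
the row renormalized.  Because renormalization perturbs the stationary
distribution, both parameters are calibrated against the analytic
stationary distribution (fixed-point iteration on the GC input and the
scale) so the chain's *expected* GC and obs/exp hit their targets; at 1
Mbp the realized values land within ±0.01 (GC) and ±0.03 (obs/exp).  The
inner sampling loop is a small C++ kernel driven by R's own RNG, so
`set.seed` fully determines the output.

The generators plant, with exact truth tables: SNPs with a controlled
CpG-context fraction; an alignment partner with per-site substitution rate
`rate` multiplied by `kappa` at CpG sites (MAF block boundaries are nudged
so no CpG is split, keeping block-local context identical to genome-wide
context and making round-trips exact); regulatory feature classes with
Gaussian score tracks around planted class means (negative means for
enhancer and promoter-flanking classes emulate acceleration); a
hypomethylated target chromosome (0.66 vs 0.75); a doubled log-sigma
expression chromosome; and a rearranged partner assembly with reciprocal
chain files, one deletion and shuffled segment order.

Default study conditions (`default_study_spec()`): 12 species × (4
background chromosomes + 1 chr19-like outlier), GC 0.48/obs-exp 0.34
against 0.41/0.25, SNP density 5 vs 3 per kbp, CpG-SNP fraction 0.25 vs
0.18.  These contrasts are the planted analogue of the compositional
outlier the pipeline is designed to detect; `simulate_study(seed)` is
byte-deterministic in the seed.

## What the generator does and does not emulate

It emulates the *signals* the statistics measure: compositional contrast,
CpG-biased mutation and substitution, accelerated regulatory classes,
hypomethylation, expression dispersion, assembly rearrangement.  It does
not emulate isochore structure, recombination-driven GC-biased gene
conversion, repeat families (soft-masking is random intervals), indel
processes in alignments (blocks are gap-free), linkage between variants,
or realistic gene-length/expression distributions.  Conclusions about
method behavior transfer; conclusions about biology require real data.

## Numerical choices

Window statistics use cumulative sums (O(L) per chromosome); island
trimming re-tests with exact integer counts.  Variance uses the n−1
denominator.  Rank ties use mid-ranks; ranking tables break ties
deterministically by chromosome name and flag them.  Mean-score
aggregation is exact rational arithmetic in doubles (sums of
score × width), not per-base expansion.

## Pipeline and reproducibility

`run_pipeline()` validates all configured inputs before computing, logs
MD5 hashes of every input and the recorded seed, and writes per-chromosome
`report.tsv`, `feature_classes.tsv` and optional compartment contrasts;
identical inputs give identical outputs.  `scripts/acceptance.R --seed S
--out F` reproduces the headline study quantities as JSON, and the
command-line wrapper `inst/cli/chromcomp` exposes `simulate` and `report`
subcommands.
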