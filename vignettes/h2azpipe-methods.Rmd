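---
title: "Methods: genic H2A.Z deposition analysis and its coupling to transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genic H2A.Z deposition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`h2azpipe` analyses the genic distribution of the histone variant H2A.Z
from binned ChIP coverage and links its condition-dependent changes to
transcriptome changes. The analysis universe is a gene-centric partition:
for each gene the *TSS region* runs from 250 bp upstream to 500 bp
downstream of the transcription start site, and the *gene body* (GB) from
500 bp downstream of the TSS to 250 bp downstream of the termination
site, strand-aware. Genes of length at most 500 bp have an empty gene
body and their TSS region absorbs the whole gene ± 250 bp envelope, so
TSS and GB always partition the envelope exactly; this closure rule keeps
every overlap statistic well defined for degenerate gene models.

The pipeline stages are: broad-island calling against an input control;
differential islands between two conditions over the union of their
islands; assignment of (differential) islands to genes and
classification into `tss/gb × increase/decrease` categories; metagene
profiling with expression-quintile stratification and k-means
deposition-pattern clustering; a negative-binomial differential
expression (DE) test; a bootstrap overlap-enrichment statistic connecting
DEG sets to differential-H2A.Z categories; hypergeometric term
enrichment; and fuzzy k-means clustering of DE genes across the
four-group design (control wild type, treated wild type, remodeler
knockdown under both treatments).

## Island calling

Coverage is modelled as counts per 200 bp window. Per window, the chip
count is scored against a Poisson rate equal to the library-scaled
control count, floored at the genome-average chip rate over the
*effective* (mappable) genome — `library / (windows × fraction)`, with
fraction 0.8 by default. Windows with one-sided `p < 0.2` (a deliberately
permissive eligibility screen, as in the SICER family) are merged into
islands across gaps of up to `G = 200` bp; each island is then tested as
a whole (Poisson upper tail of total chip count against total control
expectation) and Benjamini–Hochberg adjusted with the multiplicity set to
the **total window count**, not the island count. Two of these choices
are load-bearing for error control and were fixed by simulation under the
null (chip and control drawn from the same Poisson rate):

* adjusting only over surviving islands ignores that islands are the
  extreme members of the window family; measured on 200 null
  simulations this yields a ~37% probability of at least one island at
  `q < 0.01`. Using the window-family multiplicity is the analogue of
  SICER's genome-wide E-value correction.
* the effective-genome fraction must *divide* the average rate (a less
  mappable genome concentrates the same library into fewer usable
  windows). With the floor understated, plug-in noise in the per-window
  control aggregates across multi-window islands and leaves a ~10% null
  false-run rate; with the divided floor the measured rate is 0/1000.

The island-score recursion and E-value of the original SICER are
deliberately not reproduced; the island FDR (default 0.01) does the
filtering. Replicates are called separately or pooled (the pipeline pools
by summing window counts and reports Pearson replicate concordance as
QC); joint multi-replicate calling is out of scope.

Differential islands are tested on the union of the two conditions'
islands with the exact conditional binomial form of the two-sample
Poisson rate test (the b-count against the library-size ratio), BH over
the union islands — here the islands *are* the pre-registered tests, so
no family enlargement is needed. A pre-immune track, when supplied, is
used as an optional flag (islands overlapping pre-immune islands are
marked, not removed), since subtractive use is not well defined for a
negative-control ChIP.

## Gene assignment and categories

A gene carries H2A.Z enrichment when any island overlaps its ± 250 bp
envelope by at least 1 bp; no minimum-fraction rule is applied. A
differential category (`tss_increase`, `tss_decrease`, `gb_increase`,
`gb_decrease`) is present when at least one differential island of that
direction overlaps that region by ≥ 1 bp. Islands straddling the TSS/GB
boundary set both regions' categories, and genes containing both an
increase and a decrease appear in both summaries — the source analyses
count "genes containing" each change type without resolving straddles,
so these permissive choices are made explicit here and in the output.

## Metagene profiling

Profiles are genes × 200 bins: 50 fixed 20 bp bins over 1 kb upstream,
100 bins of `length/100` bp over the gene body, 50 bins over 1 kb
downstream (minus-strand rows reversed). The bin counts are compared as
`log2((chip + c)/(control + c) × lib_control/lib_chip)` with pseudocount
`c = 0.5` per bin; the ratio (rather than subtraction) form of input
normalisation was chosen and is flagged here because the upstream
tooling's normalisation is ambiguous. The bin grid (50/100/50) is finer
than the 250/500 bp region structure it must resolve; the upstream
tool's exact bin counts are not documented.

Expression quintiles are computed per condition from replicate-mean
FPKM; "expressed" means mean FPKM > 0 with no higher floor, Q1 is the
highest quintile, bins differ in size by at most one with the earliest
bins taking the remainder, and Q0 (FPKM exactly 0 in all replicates) is
sub-split by 2-means on the metagene rows into Q0a (retains signal) and
Q0b (depleted).

Deposition patterns use Euclidean k-means with k-means++ seeding and 25
restarts (best inertia kept). Semantic labels are a centroid-shape
heuristic standing in for visual assignment: the centroid with the
largest mean |signal| over gene-body bins is `k1` (broad, stress-
related); among the rest the largest TSS-peak-minus-body contrast is
`k2` (sharp TSS, housekeeping); the remainder `k3` (depleted).

## Expression analysis

Size factors are median-of-ratios over genes positive in every sample,
rescaled to geometric mean 1. FPKM is `count/(kb × millions mapped)`.
The "regularized log" used for clustering is approximated by
`log2(count/size_factor + 1)`: the clustering consumer only needs
variance-stabilised-ish values, and an empirical-Bayes rlog is out of
scope.

The DE stage is a self-contained stand-in for a full NB GLM package
call. Per gene: normalized group means, `log2fc` with a 0.5 moderation
pseudocount, method-of-moments NB dispersion pooled across groups, and a
delta-method Wald test against a normal reference. The dispersion is
taken as the **maximum** of the gene-wise estimate and a fitted
`a0 + a1/mu` trend. This conservative combination was selected by
simulation at the design's 2 vs 2 scale: averaging gene-wise and trend
estimates 50/50 leaves the test slightly anti-conservative (type-I
0.06–0.07 at nominal 0.05), while a t reference with 2 degrees of
freedom makes `q < 0.001` unreachable regardless of effect size. The
adopted form measures type-I ≈ 0.033 and power ≈ 0.85–0.91 at
`q < 0.001` for |log2FC| = 2 at baselines ≥ 100. Genes all-zero in both
groups report `p = 1`.

Interaction clustering is fuzzy c-means (fuzzifier 1.2, membership
cutoff 0.5, both configurable) on row-standardised transformed values of
the DE union, with memberships computed in ratio form so near-hard
fuzzifiers cannot underflow. Clusters are size-ordered and named
`C1..Cn`. The function default is k = 14 (the scale the method targets
on full transcriptomes); the pipeline's desk-scale default is k = 4
because simulated runs select only tens of DE genes.

## Overlap enrichment

The bespoke statistic: the observed overlap `x` between a DEG set
(size m) and a differential-H2A.Z category (size K) within a background
of N genes is reported against a resampled null (1000 draws of m genes
without replacement; mean ± SD reproduces the descriptive error bars),
and tested with a one-sided **binomial** test of `x` in `m` trials at
`p0 = K/N`, in the empirical direction — the binomial (not
hypergeometric) test mirrors the source analysis, the direction is
reported because over- and under-representation are reported separately,
and the sidedness/background are explicit configuration since neither is
stated upstream. The default background is expressed protein-coding
genes. Term enrichment is a per-term upper-tail hypergeometric test with
BH adjustment (significance at q < 0.05); ontology graph propagation is
out of scope.

## The synthetic world

The generator states a desk-scale world and every default is part of
that statement, chosen once:

* two 1.2 Mb chromosomes, 300 non-overlapping genes, lengths uniform in
  1–5 kb (so every gene has a non-empty GB under the partition when
  longer than 500 bp), ≥ 1 kb end clearance; biotypes 85% PCG.
* three deposition archetypes in proportions 0.50/0.36/0.14, following
  the relative sizes of the three observed pattern clusters
  (n = 18232/13128/4740): `k1` a gene-body plateau (8 reads/window) with
  1–3 Gaussian sub-peaks, `k2` a Gaussian TSS kernel peaking inside
  TSS−250..TSS+500 (30 reads/window, widened by the 200 bp mean fragment
  length), `k3` background only (2 reads/window). Coverage is generated
  directly as Poisson window counts — the window is the caller's native
  unit and read alignment is out of scope.
* the stress condition multiplies every gene's TSS-region signal by
  `1 − e` and gene-body signal by `1 + e`, `e = 0.3`. The source study
  reports the TSS→GB redistribution qualitatively but gives no effect
  size, so `e` is a free parameter, not an estimate of the rice data.
* RNA counts are NB (dispersion 0.05, two replicates per condition) with
  baselines log-uniform over 1..10^4 expected counts and 10% structural
  zeros (populating Q0); 15% of genes are DE at |log2FC| = 2; nominal
  depth 3e6 (at 1e6 roughly half the planted DE genes fall below the
  detectable baseline at 2 vs 2, which starves the downstream overlap
  statistic of observed DEGs).
* the coupling rule plants the negative GB association: up-regulated
  genes carry a gene-body H2A.Z decrease (their GB signal × 0.25 in
  stress), down-regulated genes a gene-body increase (+ one plateau).
  Up-regulated genes are drawn from the `k1` class only, because a GB
  decrease is unobservable on a gene without GB signal; down-regulated
  genes come from any expressed PCG. Setting the rule to `"none"`
  decouples (negative control); the string sentinel exists because NULL
  elements vanish from R lists and JSON.
* one RNG stream per (purpose, sample, chromosome), derived by hashing
  the names with the master seed, so adding a sample never perturbs
  another sample's draws and a fixed seed reproduces the fixture bundle
  byte for byte.

What the generator does **not** emulate: mappability structure, GC and
fragment-length biases, read-level duplication, isoforms/exon structure,
overdispersed (non-Poisson) ChIP background, and correlated biological
replicate effects. A green recovery test therefore establishes that the
algorithms recover the planted structure under idealised noise, not that
they are robust to real-library artefacts.

## Numerical choices and degenerate inputs

Ties in BH resolve by the standard step-up cumulative minimum. Island
scores cap `-log10(q)` at 300 when q underflows. Zero-variance tracks
make Pearson concordance undefined (reported as NA with a warning).
Quintile ties break by gene id. The 2-means Q0 split requires at least
two profiled Q0 genes, otherwise sub-labels stay NA. All-identical
profile matrices are rejected as a single effective cluster. Bootstrap
degeneracy (category = background) is reported with `degenerate = TRUE`
rather than a significance claim. bedGraph values are interpreted as
counts per window-width attributed uniformly per bp, which makes library
size well defined under re-binning; internal coordinates are 0-based
half-open everywhere with GFF3 converting at the boundary.

## Known limitations

The island caller is a documented simplification of the SICER class, not
a reimplementation of its scoring recursion; its q-values are
conservative by construction (window-family multiplicity and
effective-genome floor). The DE stand-in has no GLM machinery
(multi-factor designs, outlier replacement, LFC shrinkage are
non-goals). Desk-scale worlds compress the gene count by two orders of
magnitude relative to a real genome, so category sizes and DEG counts —
and hence the attainable significance of the overlap statistic — are
correspondingly small; conclusions about real libraries require the real
inputs through the same interfaces.
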