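# h2azpipe

A desk-scale R pipeline for analysing genic deposition of the histone
variant **H2A.Z** from ChIP coverage and linking its changes to
transcription. H2A.Z is exchanged into nucleosomes
replication-independently; where it sits on a gene matters: a sharp peak
at the transcription start site (TSS) is the signature of highly
expressed, housekeeping-type genes, while broad gene-body (GB)
deposition marks lowly expressed, stress-responsive genes. Perturbations
such as nutrient starvation or knockdown of the SWR1-complex subunit
ARP6 redistribute H2A.Z from the TSS into gene bodies, and gene-body
H2A.Z changes are negatively coupled to expression changes. This package
provides every statistical stage needed to run that style of analysis on
real or simulated inputs, for chromatin biologists and methods
developers who want a fully specified, testable implementation.

## What it computes

* **Island calling** (SICER-style): per 200 bp window, the chip count is
  tested against a Poisson rate λ = library-scaled input count, floored
  at the effective-genome background rate; eligible windows (p < 0.2)
  merge across gaps ≤ G = 200 bp; each island is tested as a whole,
  `P(Pois(Σλ) ≥ Σx)`, with BH control at FDR < 0.01 over the candidate
  window family.
* **Differential islands** between conditions over the union of their
  islands: exact conditional binomial form of the two-sample Poisson
  rate test, BH at FDR < 0.01, with direction.
* **Gene partition and classification**: TSS region = TSS − 250 .. TSS +
  500, gene body = TSS + 500 .. TTS + 250 (strand-aware); ≥ 1 bp overlap
  assigns islands to genes and fills the four categories
  `tss/gb × increase/decrease`.
* **Metagene profiles**: genes × 200 bins (1 kb flanks + scaled body) of
  input-normalised `log2` ratios; expression quintiles Q1..Q5 (+ Q0 with
  FPKM = 0, split into two sub-groups); k-means (k = 3) deposition
  patterns k1/k2/k3 with shape-based labels.
* **Differential expression**: median-of-ratios normalisation, NB Wald
  test with trend-shrunk method-of-moments dispersion (FDR < 0.001), a
  shifted-log transform, and fuzzy k-means interaction clustering.
* **Overlap enrichment**: the observed DEG/category overlap `x` of m
  DEGs against a category of K genes in a background of N, with a
  1000-iteration resampled null (mean ± SD) and a one-sided binomial
  test of x at p₀ = K/N; plus hypergeometric term enrichment (SEA).
* **Synthetic data**: a generator that states all of the above as a
  truth-tabled world (three deposition archetypes, TSS→GB
  redistribution, NB counts, planted negative coupling), making every
  stage testable without sequencing data.

## Worked example

```r
library(h2azpipe)

cfg <- sim_config(seed = 42)                   # the stated world
world <- generate_annotation(cfg)              # genes + truth table
chip_c  <- generate_chip_coverage(world$genes, world$truth, cfg, "control", "chip")
input_c <- generate_chip_coverage(world$genes, world$truth, cfg, "control", "input")
chip_s  <- generate_chip_coverage(world$genes, world$truth, cfg, "stress", "chip")
input_s <- generate_chip_coverage(world$genes, world$truth, cfg, "stress", "input")

isl_c <- call_islands(chip_c, input_c)         # 270 islands
isl_s <- call_islands(chip_s, input_s)         # 254 islands
head(isl_c, 3)
#>   chrom start   end chip_count control_count     score      p_value      q_value
#> 1  chr1  7400  8600         97      35.59313 16.763918 1.722194e-17 1.148129e-15
#> 2  chr1 18000 18800         71      33.22559  8.070095 8.509509e-09 4.117505e-07
#> 3  chr1 23600 24600         91      32.03737 16.845242 1.428100e-17 9.627638e-16

d   <- call_differential(chip_c, chip_s, island_union(isl_c, isl_s))
cls <- classify_differential(d, compute_gene_regions(world$genes))
round(cls$summary$category_fraction, 2)
#> tss_increase tss_decrease  gb_increase  gb_decrease
#>         0.24         0.27         0.52         0.45

rna <- generate_rna_counts(world$genes, world$truth, cfg)
de  <- de_test(rna$counts, rna$samples$group)  # 13 up, 12 down at q < 0.001

bg    <- intersect(world$genes$gene_id[world$genes$biotype == "PCG"],
                   rownames(rna$counts)[rowSums(rna$counts) > 0])
up    <- intersect(de$gene_id[de$direction == "up"], bg)
gbdec <- intersect(unique(cls$calls$gene_id[cls$calls$category == "gb_decrease"]), bg)
bootstrap_overlap(up, gbdec, bg, seed = 42)
#> <bootstrap_result> x=13 of m=13 (K=28, N=267); null 1.40 +/- 1.07 (1000 iter);
#>   over, binomial p=1.86e-13
```

Reading the last result: all 13 up-regulated DEGs fall among the 28
genes with a gene-body H2A.Z decrease, where 13 random genes would
overlap 1.4 ± 1.1 — the planted negative GB coupling, recovered at
binomial p ≈ 2e-13. The stress condition's genome-wide TSS→GB
redistribution also shows up in the category fractions (increases
concentrate in gene bodies).

The full four-group design (WTC/WTP/arp6C/arp6P analogues, three
contrasts, profiles, SEA, interaction clustering, JSON manifest) runs as

```r
res <- run_pipeline(run_config(simulate = list(seed = 1), out_dir = "run1"))
```

or from the command line via `inst/cli/h2azpipe`
(`simulate`, `call`, `assign`, `de`, `enrich`, `run-all`).

## Vignette

`vignettes/h2azpipe-methods.Rmd` documents the model and every
non-obvious choice: the island-caller's error-control corrections, the
DE dispersion shrinkage selected by calibration simulation, the
partition closure rule for short genes, what the synthetic world does
and does not emulate, and known limitations.
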