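# Synthetic data with a recorded truth table. The generator emulates the
# statistical structure the downstream analysis assumes: three genic H2A.Z
# deposition archetypes (k1 broad gene-body, k2 sharp TSS peak, k3
# depleted), a stress condition that redistributes signal from the TSS to
# the gene body, NB-distributed RNA counts in a replicated two-condition
# design, and a configurable coupling between expression change and
# gene-body H2A.Z change.

H2AZ_CLASSES <- c("k1_broad", "k2_tss", "k3_depleted")
TSS_UP <- 250   # TSS region: 250 bp upstream ...
TSS_DOWN <- 500 # ... to 500 bp downstream of the TSS
TTS_DOWN <- 250 # gene body ends 250 bp downstream of the TTS

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome: two 1.2 Mb chromosomes carrying
#' 300 non-overlapping genes of 1-5 kb, coverage as Poisson counts per
#' 200 bp window, and NB RNA counts with two replicates per condition.
#' Expected window counts are set directly by `tss_peak_height`,
#' `gb_level` and `background_level`; `chip_depth`/`rna_depth` act as
#' multipliers relative to a nominal 1e6-read library.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes total genes, distributed round-robin over chromosomes.
#' @param class_proportions named fractions over the three deposition
#'   archetypes; defaults follow the relative sizes of the three observed
#'   pattern clusters (roughly 0.50/0.36/0.14).
#' @param biotype_proportions named fractions over PCG/PG/TE/TEG.
#' @param fragment_mean mean ChIP fragment length (bp); widens the TSS
#'   kernel only.
#' @param chip_depth,rna_depth nominal library sizes (reads).
#' @param n_replicates replicates per condition (>= 2 for RNA).
#' @param tss_peak_height,gb_level,background_level expected reads per
#'   200 bp window for the TSS kernel peak, the broad gene-body plateau,
#'   and the genomic background.
#' @param redistribution_effect multiplicative TSS decrease / gene-body
#'   increase applied genome-wide under the stress condition.
#' @param de_fraction fraction of genes differentially expressed.
#' @param lfc_magnitude planted |log2 fold change|.
#' @param nb_dispersion NB dispersion (var = mu + disp * mu^2).
#' @param zero_fraction fraction of genes with baseline 0 in all samples
#'   (populates the unexpressed Q0 class).
#' @param coupling_rule named character vector mapping DE direction to a
#'   planted H2A.Z change (default `c(up = "gb_down", down = "gb_up")`,
#'   the negative gene-body coupling); `NULL` or the string `"none"`
#'   decouples (negative control; the string form survives list and JSON
#'   round-trips, where NULL elements vanish).
#' @param n_terms,term_odds_ratio,term_base_prob term-annotation fixture:
#'   number of terms, odds ratio of the two class-enriched terms, and the
#'   background membership probability.
#' @param seed integer RNG seed; all generator randomness derives from it
#'   via named substreams.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 1.2e6,
                       n_genes = 300,
                       class_proportions = c(k1_broad = 0.50, k2_tss = 0.36,
                                             k3_depleted = 0.14),
                       biotype_proportions = c(PCG = 0.85, PG = 0.05,
                                               TE = 0.05, TEG = 0.05),
                       fragment_mean = 200,
                       chip_depth = 1e6,
                       rna_depth = 3e6,
                       n_replicates = 2,
                       tss_peak_height = 30,
                       gb_level = 8,
                       background_level = 2,
                       redistribution_effect = 0.3,
                       de_fraction = 0.15,
                       lfc_magnitude = 2,
                       nb_dispersion = 0.05,
                       zero_fraction = 0.1,
                       coupling_rule = c(up = "gb_down", down = "gb_up"),
                       n_terms = 10,
                       term_odds_ratio = 8,
                       term_base_prob = 0.15,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.null(cfg$coupling_rule) &&
      identical(unname(cfg$coupling_rule), "none")) {
    cfg$coupling_rule <- NULL
  }
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9 ||
      !setequal(names(cfg$class_proportions), H2AZ_CLASSES)) {
    stop("class_proportions must be named over ",
         paste(H2AZ_CLASSES, collapse = ", "), " and sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$biotype_proportions) - 1) > 1e-9 ||
      !setequal(names(cfg$biotype_proportions), BIOTYPES)) {
    stop("biotype_proportions must be named over ",
         paste(BIOTYPES, collapse = ", "), " and sum to 1", call. = FALSE)
  }
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 0, cfg$n_genes >= 0,
            cfg$n_replicates >= 1, cfg$fragment_mean > 0,
            cfg$tss_peak_height >= 0, cfg$gb_level >= 0,
            cfg$background_level >= 0,
            cfg$redistribution_effect >= 0, cfg$redistribution_effect < 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$zero_fraction >= 0, cfg$zero_fraction < 1,
            cfg$nb_dispersion > 0)
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  # genes up to 5 kb plus a 200 bp minimum gap, 1 kb clearance at each end
  need <- per_chrom * (MAX_GENE_LEN + MIN_GENE_GAP) + 2 * FLANK_CLEAR
  if (cfg$n_genes > 0 && need > cfg$chrom_length) {
    stop(sprintf(
      "config infeasible: %d genes/chromosome need %g bp but chrom_length is %g",
      per_chrom, need, cfg$chrom_length), call. = FALSE)
  }
  cfg
}

MIN_GENE_LEN <- 1000
MAX_GENE_LEN <- 5000
MIN_GENE_GAP <- 200
FLANK_CLEAR <- 1000

sim_chrom_lengths <- function(config) {
  setNames(rep(config$chrom_length, config$n_chromosomes),
           sprintf("chr%d", seq_len(config$n_chromosomes)))
}

#' Generate a gene annotation and its truth table
#'
#' Genes are non-overlapping, on both strands, with lengths uniform in
#' 1-5 kb and at least 1 kb clearance from chromosome ends so 1 kb flanks
#' stay in range. Deposition class, biotype, zero-expression status,
#' DE status and the coupled H2A.Z change are drawn once and recorded in
#' the truth table. Under the default coupling rule, up-regulated genes
#' (which carry a planted gene-body H2A.Z decrease) are drawn from the k1
#' broad class only, because a gene-body decrease is unobservable on a
#' gene without gene-body signal; down-regulated genes come from any
#' expressed PCG.
#'
#' @param config `sim_config`.
#' @return list with `genes` (a [gene_model] with a `chrom_lengths`
#'   attribute) and `truth` (data.frame: gene_id, planted_class,
#'   planted_biotype, planted_zero, planted_de, planted_h2az_change).
#' @export
generate_annotation <- function(config) {
  config <- validate_sim_config(config)
  lens <- sim_chrom_lengths(config)
  empty <- function() {
    g <- gene_model(character(), character(), numeric(), numeric(),
                    character(), character())
    attr(g, "chrom_lengths") <- lens
    list(genes = g, truth = data.frame(
      gene_id = character(), planted_class = character(),
      planted_biotype = character(), planted_zero = logical(),
      planted_de = character(), planted_h2az_change = character(),
      stringsAsFactors = FALSE))
  }
  if (config$n_genes == 0) return(empty())

  per_chrom <- diff(floor(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  rows <- list()
  gid <- 0
  for (ci in seq_along(lens)) {
    nc <- per_chrom[ci]
    if (nc == 0) next
    rows[[ci]] <- with_stream(config$seed, "annotation", names(lens)[ci],
                              expr = {
      gene_len <- floor(runif(nc, MIN_GENE_LEN, MAX_GENE_LEN + 1))
      usable <- lens[ci] - 2 * FLANK_CLEAR
      free <- usable - sum(gene_len) - nc * MIN_GENE_GAP
      stopifnot(free >= 0)
      extra <- as.vector(stats::rmultinom(1, size = floor(free),
                                          prob = rep(1, nc)))
      gaps <- MIN_GENE_GAP + extra
      # cumulative layout: gap_i then gene_i
      starts <- FLANK_CLEAR + cumsum(gaps + gene_len) - gene_len
      data.frame(
        chrom = names(lens)[ci], start = starts, end = starts + gene_len,
        strand = sample(c("+", "-"), nc, replace = TRUE),
        stringsAsFactors = FALSE
      )
    })
    gid <- gid + nc
  }
  df <- do.call(rbind, rows)
  df$gene_id <- sprintf("g%04d", seq_len(nrow(df)))
  genes <- gene_model(df$gene_id, df$chrom, df$start, df$end, df$strand,
                      "PCG")
  attr(genes, "chrom_lengths") <- lens

  n <- nrow(genes)
  truth <- with_stream(config$seed, "truth", expr = {
    planted_class <- sample(names(config$class_proportions), n,
                            replace = TRUE, prob = config$class_proportions)
    planted_biotype <- sample(names(config$biotype_proportions), n,
                              replace = TRUE,
                              prob = config$biotype_proportions)
    planted_zero <- runif(n) < config$zero_fraction
    planted_de <- rep("null", n)
    n_de <- round(config$de_fraction * n)
    n_up <- floor(n_de / 2)
    n_down <- n_de - n_up
    expressed_pcg <- which(planted_biotype == "PCG" & !planted_zero)
    up_pool <- if (!is.null(config$coupling_rule)) {
      intersect(expressed_pcg, which(planted_class == "k1_broad"))
    } else {
      expressed_pcg
    }
    up_idx <- sample(up_pool, min(n_up, length(up_pool)))
    down_pool <- setdiff(expressed_pcg, up_idx)
    down_idx <- sample(down_pool, min(n_down, length(down_pool)))
    planted_de[up_idx] <- "up"
    planted_de[down_idx] <- "down"
    change <- rep("none", n)
    if (!is.null(config$coupling_rule)) {
      for (dir in names(config$coupling_rule)) {
        change[planted_de == dir] <- config$coupling_rule[[dir]]
      }
    }
    data.frame(gene_id = genes$gene_id, planted_class, planted_biotype,
               planted_zero, planted_de, planted_h2az_change = change,
               stringsAsFactors = FALSE)
  })
  list(genes = genes, truth = truth)
}

# Per-gene expected extra window counts (over background) for one
# chromosome, split into a TSS-region component and a gene-body component
# so condition effects can scale them independently. `mids` are window
# midpoints in bp.
gene_signal_components <- function(gene, class, mids, config) {
  tss <- if (gene$strand == "+") gene$start else gene$end
  sig_tss <- numeric(length(mids))
  sig_gb <- numeric(length(mids))
  tss_lo <- if (gene$strand == "+") tss - TSS_UP else tss - TSS_DOWN
  tss_hi <- if (gene$strand == "+") tss + TSS_DOWN else tss + TSS_UP
  gb_lo <- if (gene$strand == "+") gene$start + TSS_DOWN else gene$start
  gb_hi <- if (gene$strand == "+") gene$end else gene$end - TSS_DOWN
  in_tss <- mids >= tss_lo & mids < tss_hi
  in_gb <- mids >= gb_lo & mids < gb_hi & !in_tss

  tss_kernel <- function(height) {
    centre <- if (gene$strand == "+") tss + 125 else tss - 125
    sigma <- (TSS_UP + TSS_DOWN + config$fragment_mean) / 4
    height * exp(-0.5 * ((mids - centre) / sigma)^2) *
      (mids >= tss_lo - config$fragment_mean &
         mids < tss_hi + config$fragment_mean)
  }
  if (class == "k2_tss") {
    k <- tss_kernel(config$tss_peak_height)
    sig_tss <- sig_tss + k * in_tss
    sig_gb <- sig_gb + k * in_gb
  } else if (class == "k1_broad") {
    body <- numeric(length(mids))
    body[in_gb] <- config$gb_level
    n_sub <- sample(1:3, 1)
    span <- c(gb_lo, gb_hi)
    for (s in seq_len(n_sub)) {
      centre <- runif(1, span[1], span[2])
      body <- body + config$gb_level *
        exp(-0.5 * ((mids - centre) / 300)^2) * in_gb
    }
    sig_gb <- sig_gb + body
    sig_tss[in_tss] <- sig_tss[in_tss] + config$gb_level / 2
  }
  list(tss = sig_tss, gb = sig_gb, in_tss = in_tss, in_gb = in_gb)
}

#' Generate a binned ChIP/input/pre-immune coverage track
#'
#' Window counts are Poisson draws around class-specific expectations:
#' k2 genes carry a Gaussian TSS kernel (peak inside TSS-250..TSS+500),
#' k1 genes an elevated gene body with 1-3 sub-peaks, k3 genes background
#' only. Input and pre-immune libraries are uniform background. Under
#' `condition = "stress"` the TSS-region component of every gene's signal
#' is multiplied by `1 - redistribution_effect` and the gene-body
#' component by `1 + redistribution_effect`, and each gene's planted
#' H2A.Z change is applied on top (gb_down/tss_down scale the component by
#' 0.25; gb_up/tss_up add one extra plateau/kernel). The replicate index
#' selects the RNG substream only, never the expectation.
#'
#' @param genes,truth from [generate_annotation()].
#' @param config `sim_config`.
#' @param condition `"control"` or `"stress"`.
#' @param library_role `"chip"`, `"input"` or `"preimmune"`.
#' @param replicate replicate index (>= 1).
#' @param sample_id label; default derived from the arguments.
#' @param return_expected if TRUE, also attach the per-chromosome expected
#'   (noise-free) window means as attribute `expected`.
#' @return `coverage_track` on a 200 bp window grid.
#' @export
generate_chip_coverage <- function(genes, truth, config,
                                   condition = c("control", "stress"),
                                   library_role = c("chip", "input",
                                                    "preimmune"),
                                   replicate = 1,
                                   sample_id = NULL,
                                   return_expected = FALSE) {
  condition <- match.arg(condition)
  library_role <- match.arg(library_role)
  config <- validate_sim_config(config)
  stopifnot(nrow(genes) == nrow(truth),
            all(genes$gene_id == truth$gene_id))
  W <- 200
  lens <- attr(genes, "chrom_lengths") %||% sim_chrom_lengths(config)
  depth <- config$chip_depth / 1e6
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_%s_r%d", condition, library_role, replicate)
  }
  counts <- list()
  expected <- list()
  for (ch in names(lens)) {
    nw <- ceiling(lens[[ch]] / W)
    mids <- (seq_len(nw) - 0.5) * W
    mu <- rep(config$background_level, nw)
    if (library_role == "chip") {
      idx <- which(genes$chrom == ch)
      for (i in idx) {
        comp <- with_stream(config$seed, "genesignal", genes$gene_id[i],
                            expr = gene_signal_components(
                              genes[i, ], truth$planted_class[i], mids,
                              config))
        f_tss <- 1
        f_gb <- 1
        add_tss <- 0
        add_gb <- 0
        if (condition == "stress") {
          f_tss <- 1 - config$redistribution_effect
          f_gb <- 1 + config$redistribution_effect
          changes <- strsplit(truth$planted_h2az_change[i], ",")[[1]]
          if ("gb_down" %in% changes) f_gb <- f_gb * 0.25
          if ("tss_down" %in% changes) f_tss <- f_tss * 0.25
          if ("gb_up" %in% changes) add_gb <- config$gb_level
          if ("tss_up" %in% changes) add_tss <- config$tss_peak_height / 2
        }
        mu <- mu + comp$tss * f_tss + comp$gb * f_gb +
          add_gb * comp$in_gb + add_tss * comp$in_tss
      }
    }
    mu <- mu * depth
    expected[[ch]] <- mu
    counts[[ch]] <- with_stream(
      config$seed, "coverage", sample_id, ch,
      expr = rpois(nw, mu)
    )
  }
  track <- coverage_track(counts, W, sample_id)
  if (return_expected) attr(track, "expected") <- expected
  track
}

#' Generate an NB RNA count table
#'
#' Gene baselines are log-uniform over four orders of magnitude
#' (1..10^4 expected counts); genes flagged `planted_zero` have baseline 0
#' in every sample. Planted DE genes get a `±lfc_magnitude` log2 shift in
#' every stress-type group. Counts are NB with the configured dispersion.
#'
#' @param genes,truth from [generate_annotation()].
#' @param config `sim_config` (requires `n_replicates >= 2`).
#' @param groups named character vector mapping sample-group name to
#'   condition type (`"control"` or `"stress"`); default the plain
#'   two-condition design.
#' @return list: `counts` (integer matrix gene x sample), `samples`
#'   (data.frame sample_id, group, condition, replicate), `baseline`
#'   (expected control-condition mean per gene).
#' @export
generate_rna_counts <- function(genes, truth, config,
                                groups = c(control = "control",
                                           stress = "stress")) {
  config <- validate_sim_config(config)
  if (config$n_replicates < 2) {
    stop("n_replicates must be >= 2", call. = FALSE)
  }
  stopifnot(all(groups %in% c("control", "stress")))
  n <- nrow(genes)
  depth <- config$rna_depth / 1e6
  baseline <- with_stream(config$seed, "rna_baseline", expr = {
    b <- 10^runif(n, 0, 4)
    b[truth$planted_zero] <- 0
    b
  })
  shift <- ifelse(truth$planted_de == "up", 2^config$lfc_magnitude,
                  ifelse(truth$planted_de == "down",
                         2^(-config$lfc_magnitude), 1))
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         group = names(groups), stringsAsFactors = FALSE)
  samples$condition <- unname(groups[samples$group])
  samples$sample_id <- sprintf("%s_%d", samples$group, samples$replicate)
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * depth
    if (samples$condition[j] == "stress") mu <- mu * shift
    counts[, j] <- with_stream(
      config$seed, "rna", samples$group[j], samples$replicate[j],
      expr = {
        x <- integer(n)
        pos <- mu > 0
        x[pos] <- rnbinom(sum(pos), mu = mu[pos],
                          size = 1 / config$nb_dispersion)
        x
      })
  }
  list(counts = counts,
       samples = samples[, c("sample_id", "group", "condition", "replicate")],
       baseline = setNames(baseline, genes$gene_id))
}

#' Generate a term annotation fixture
#'
#' Terms are assigned per gene as independent Bernoulli memberships at the
#' background probability, except the first term, which is enriched in k1
#' genes at the configured odds ratio, and the second, enriched in k2
#' genes. With `term_odds_ratio = 1` all terms are null.
#'
#' @param truth truth table from [generate_annotation()].
#' @param config `sim_config`.
#' @return data.frame (`term_id`, `gene_id`), long format; zero rows when
#'   `n_terms = 0`.
#' @export
generate_term_annotation <- function(truth, config) {
  config <- validate_sim_config(config)
  if (config$n_terms == 0 || nrow(truth) == 0) {
    return(data.frame(term_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  p0 <- config$term_base_prob
  odds0 <- p0 / (1 - p0)
  p_enr <- config$term_odds_ratio * odds0 /
    (1 + config$term_odds_ratio * odds0)
  enriched_in <- c(TERM01 = "k1_broad", TERM02 = "k2_tss")
  with_stream(config$seed, "terms", expr = {
    out <- list()
    for (t in seq_len(config$n_terms)) {
      tid <- sprintf("TERM%02d", t)
      p <- rep(p0, nrow(truth))
      if (tid %in% names(enriched_in) && config$term_odds_ratio != 1) {
        p[truth$planted_class == enriched_in[[tid]]] <- p_enr
      }
      member <- runif(nrow(truth)) < p
      if (any(member)) {
        out[[tid]] <- data.frame(term_id = tid,
                                 gene_id = truth$gene_id[member],
                                 stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0) {
      data.frame(term_id = character(), gene_id = character(),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, c(out, list(make.row.names = FALSE)))
    }
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' Bundles annotation, truth table, per-group ChIP + input coverage
#' tracks, RNA counts and term annotation; optionally writes everything
#' to disk (GFF3, bedGraph, TSV, JSON config echo) through the package's
#' own readers/writers so files round-trip.
#'
#' @param config `sim_config`.
#' @param groups named map of sample group -> condition type; the default
#'   mirrors a two-genotype x two-treatment design in which both the
#'   treated wild type and the remodeler knockdown behave as "stress".
#' @param out_dir optional output directory.
#' @return list: `config`, `genes`, `truth`, `tracks` (per group: list of
#'   `chip` replicate tracks and one `input`), `rna` (counts + samples),
#'   `terms`, and `files` when written.
#' @export
simulate_dataset <- function(config = sim_config(),
                             groups = c(WTC = "control", WTP = "stress",
                                        arp6C = "stress", arp6P = "stress"),
                             out_dir = NULL) {
  config <- validate_sim_config(config)
  ann <- generate_annotation(config)
  tracks <- list()
  for (g in names(groups)) {
    chips <- lapply(seq_len(config$n_replicates), function(r) {
      generate_chip_coverage(ann$genes, ann$truth, config,
                             condition = groups[[g]], library_role = "chip",
                             replicate = r,
                             sample_id = sprintf("%s_chip_r%d", g, r))
    })
    input <- generate_chip_coverage(ann$genes, ann$truth, config,
                                    condition = groups[[g]],
                                    library_role = "input", replicate = 1,
                                    sample_id = sprintf("%s_input", g))
    tracks[[g]] <- list(chip = chips, input = input)
  }
  rna <- generate_rna_counts(ann$genes, ann$truth, config, groups = groups)
  terms <- generate_term_annotation(ann$truth, config)
  bundle <- list(config = config, genes = ann$genes, truth = ann$truth,
                 tracks = tracks, rna = rna, terms = terms)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(annotation = file.path(out_dir, "annotation.gff3"))
    write_gff3(ann$genes, files[["annotation"]])
    for (g in names(tracks)) {
      for (r in seq_along(tracks[[g]]$chip)) {
        f <- file.path(out_dir, sprintf("%s_chip_r%d.bedgraph", g, r))
        write_bedgraph(tracks[[g]]$chip[[r]], f)
        files[[sprintf("%s_chip_r%d", g, r)]] <- f
      }
      f <- file.path(out_dir, sprintf("%s_input.bedgraph", g))
      write_bedgraph(tracks[[g]]$input, f)
      files[[sprintf("%s_input", g)]] <- f
    }
    files[["counts"]] <- file.path(out_dir, "counts.tsv")
    write_counts_tsv(rna$counts, files[["counts"]])
    files[["samples"]] <- file.path(out_dir, "samples.tsv")
    write.table(rna$samples, files[["samples"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[["truth"]] <- file.path(out_dir, "truth.tsv")
    write.table(ann$truth, files[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[["terms"]] <- file.path(out_dir, "terms.tsv")
    write.table(terms, files[["terms"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[["config"]] <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), files[["config"]],
                         auto_unbox = TRUE, digits = NA, null = "null")
    bundle$files <- files
  }
  bundle
}
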