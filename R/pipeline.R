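# Orchestration of the full four-group design (control wild type, treated
# wild type, remodeler knockdown under both treatments): island calling,
# differential islands per contrast, gene assignment/classification,
# metagene profiling with quintiles and pattern clusters, differential
# expression, bootstrap overlap matrices, term enrichment, and interaction
# clustering, with a machine-readable manifest.

#' Pipeline run configuration
#'
#' Either a `simulate` block (arguments to [sim_config()]) or a `paths`
#' block naming real input files must be given, not neither.
#'
#' @param simulate named list of [sim_config()] arguments, or NULL.
#' @param paths named list with `annotation` (GFF3), `tracks` (per group:
#'   list with `chip` = character vector of bedGraph paths and `input` =
#'   one path), `counts` (TSV), `samples` (TSV with sample_id/group),
#'   `terms` (TSV term_id/gene_id); or NULL.
#' @param groups named map group -> condition type for simulation.
#' @param contrasts list of length-2 character vectors (reference,
#'   condition) over group names.
#' @param island_fdr,de_fdr,sea_alpha significance thresholds.
#' @param bootstrap_iters bootstrap iterations for the overlap matrix.
#' @param k_patterns deposition-pattern clusters (default 3).
#' @param k_interaction fuzzy interaction clusters (desk-scale default 4).
#' @param seed master seed; every stage derives its stream from it.
#' @param out_dir output directory for artifacts and the manifest.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(simulate = list(), paths = NULL,
                       groups = c(WTC = "control", WTP = "stress",
                                  arp6C = "stress", arp6P = "stress"),
                       contrasts = list(c("WTC", "WTP"), c("WTC", "arp6C"),
                                        c("arp6C", "arp6P")),
                       island_fdr = 0.01, de_fdr = 0.001, sea_alpha = 0.05,
                       bootstrap_iters = 1000, k_patterns = 3,
                       k_interaction = 4, seed = 1, out_dir = tempfile()) {
  if (is.null(simulate) && is.null(paths)) {
    stop("config must provide a simulate block or input paths",
         call. = FALSE)
  }
  if (!is.null(paths)) {
    req <- c("annotation", "tracks", "counts", "samples")
    missing <- setdiff(req, names(paths))
    if (length(missing) > 0) {
      stop("paths block missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  check_probability(island_fdr, "island_fdr")
  check_probability(de_fdr, "de_fdr")
  check_probability(sea_alpha, "sea_alpha")
  structure(list(simulate = simulate, paths = paths, groups = groups,
                 contrasts = contrasts, island_fdr = island_fdr,
                 de_fdr = de_fdr, sea_alpha = sea_alpha,
                 bootstrap_iters = bootstrap_iters,
                 k_patterns = k_patterns, k_interaction = k_interaction,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys mirror [run_config()] arguments.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$contrasts) && is.matrix(raw$contrasts)) {
    raw$contrasts <- lapply(seq_len(nrow(raw$contrasts)),
                            function(i) raw$contrasts[i, ])
  }
  if (!is.null(raw$groups)) raw$groups <- unlist(raw$groups)
  do.call(run_config, raw)
}

pool_tracks <- function(tracks) {
  counts <- tracks[[1]]$counts
  if (length(tracks) > 1) {
    for (t in tracks[-1]) {
      for (ch in names(counts)) counts[[ch]] <- counts[[ch]] + t$counts[[ch]]
    }
  }
  coverage_track(counts, tracks[[1]]$window_size,
                 sample_id = paste0(tracks[[1]]$sample_id, "_pooled"))
}

load_real_inputs <- function(config) {
  p <- config$paths
  genes <- read_gff3(p$annotation)
  tracks <- lapply(p$tracks, function(tr) {
    list(chip = lapply(tr$chip, read_bedgraph, window_size = 200),
         input = read_bedgraph(tr$input, window_size = 200))
  })
  counts <- read_counts_tsv(p$counts)
  samples <- read.delim(p$samples, stringsAsFactors = FALSE)
  terms <- if (!is.null(p$terms)) {
    read.delim(p$terms, stringsAsFactors = FALSE)
  } else {
    data.frame(term_id = character(), gene_id = character())
  }
  list(genes = genes, truth = NULL, tracks = tracks,
       rna = list(counts = counts, samples = samples), terms = terms)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> island calling per group (replicate chip
#' tracks pooled; concordance QC recorded) -> differential islands per
#' contrast on the union of each pair's islands -> gene classification
#' -> metagene matrix, expression quintiles and pattern clusters ->
#' differential expression per contrast -> bootstrap overlap matrix per
#' contrast -> term enrichment per DEG list -> fuzzy interaction
#' clustering of the DE union. All artifacts are written under
#' `config$out_dir` together with a JSON manifest (parameter echo,
#' per-stage log, md5 checksums).
#'
#' @param config `run_config`.
#' @return invisible list with all in-memory results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  stage <- function(name, expr) {
    log_lines <<- c(log_lines, sprintf("stage %s: start", name))
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: done", name))
    res
  }
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  data <- stage("inputs", {
    if (!is.null(config$paths)) {
      load_real_inputs(config)
    } else {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      cfg <- do.call(sim_config, sim_args)
      simulate_dataset(cfg, groups = config$groups)
    }
  })
  genes <- data$genes
  params <- island_params(island_fdr = config$island_fdr)
  regions <- compute_gene_regions(genes)

  islands <- stage("islands", {
    lapply(names(data$tracks), function(g) {
      tr <- data$tracks[[g]]
      pooled <- pool_tracks(tr$chip)
      conc <- if (length(tr$chip) >= 2) {
        replicate_concordance(tr$chip[[1]], tr$chip[[2]])
      } else {
        NA_real_
      }
      isl <- call_islands(pooled, tr$input, params)
      emit(sprintf("islands_%s.bed", g), function(p) write_bed(isl, p))
      list(group = g, pooled = pooled, islands = isl, concordance = conc)
    }) |> setNames(names(data$tracks))
  })

  contrasts <- Filter(function(ct) all(ct %in% names(islands)),
                      config$contrasts)
  diffs <- stage("differential_islands", {
    lapply(contrasts, function(ct) {
      uni <- island_union(islands[[ct[1]]]$islands,
                          islands[[ct[2]]]$islands)
      d <- call_differential(islands[[ct[1]]]$pooled,
                             islands[[ct[2]]]$pooled, uni, params)
      key <- paste(ct, collapse = "_vs_")
      emit(sprintf("diff_islands_%s.bed", key),
           function(p) write_bed(d, p))
      cls <- classify_differential(d, regions)
      write_calls <- function(p) {
        write.table(cls$calls, p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      emit(sprintf("gene_calls_%s.tsv", key), write_calls)
      list(contrast = ct, union = uni, diff = d, classification = cls)
    }) |> setNames(vapply(contrasts, paste, "", collapse = "_vs_"))
  })

  profile <- stage("metaprofile", {
    ref <- names(islands)[1]
    mat <- build_matrix(islands[[ref]]$pooled, data$tracks[[ref]]$input,
                        genes)
    counts <- data$rna$counts
    gl <- setNames(genes$end - genes$start, genes$gene_id)
    fp <- fpkm(counts, gl)
    quint <- assign_quintiles(fp, data$rna$samples, condition = ref,
                              matrix = mat, seed = config$seed)
    pcg <- genes$gene_id[genes$biotype == "PCG"]
    pat <- cluster_patterns(
      structure(list(values = mat$values[intersect(rownames(mat$values),
                                                   pcg), , drop = FALSE],
                     pseudocount = mat$pseudocount,
                     bin_grid = mat$bin_grid),
                class = "metaprofile_matrix"),
      k = config$k_patterns, seed = config$seed)
    emit("quintiles.tsv", function(p)
      write.table(quint, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("pattern_clusters.tsv", function(p)
      write.table(data.frame(gene_id = names(pat$cluster),
                             cluster = pat$cluster,
                             label = unname(pat$labels[pat$cluster])),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("metaprofile_mean.tsv", function(p)
      write.table(average_profile(mat), p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    list(matrix = mat, fpkm = fp, quintiles = quint, patterns = pat)
  })

  de <- stage("differential_expression", {
    counts <- data$rna$counts
    sf <- size_factors(counts)
    lapply(contrasts, function(ct) {
      cols <- data$rna$samples$sample_id[data$rna$samples$group %in% ct]
      grp <- factor(data$rna$samples$group[match(cols,
                                                 data$rna$samples$sample_id)],
                    levels = ct)
      res <- de_test(counts[, cols, drop = FALSE], grp, sf = sf[cols],
                     alpha_fdr = config$de_fdr)
      key <- paste(ct, collapse = "_vs_")
      emit(sprintf("de_%s.tsv", key), function(p)
        write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE))
      res
    }) |> setNames(vapply(contrasts, paste, "", collapse = "_vs_"))
  })

  background <- {
    pcg <- genes$gene_id[genes$biotype == "PCG"]
    expressed <- rownames(data$rna$counts)[rowSums(data$rna$counts) > 0]
    intersect(pcg, expressed)
  }

  overlap <- stage("bootstrap_overlap", {
    lapply(names(diffs), function(key) {
      res <- overlap_summary(de[[key]], diffs[[key]]$classification$calls,
                             background, n_iter = config$bootstrap_iters,
                             seed = stream_seed(config$seed, "overlap", key))
      emit(sprintf("overlap_%s.tsv", key), function(p)
        write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE))
      res
    }) |> setNames(names(diffs))
  })

  sea <- stage("term_enrichment", {
    if (nrow(data$terms) == 0) {
      list()
    } else {
      lapply(names(de), function(key) {
        lapply(c(up = "up", down = "down"), function(dir) {
          q <- intersect(de[[key]]$gene_id[de[[key]]$direction == dir],
                         background)
          if (length(q) == 0) return(NULL)
          res <- sea_enrichment(q, data$terms, background,
                                alpha = config$sea_alpha)
          emit(sprintf("sea_%s_%s.tsv", key, dir), function(p)
            write.table(res, p, sep = "\t", quote = FALSE,
                        row.names = FALSE))
          res
        })
      }) |> setNames(names(de))
    }
  })

  interaction <- stage("interaction_clustering", {
    de_union <- unique(unlist(lapply(de, function(d)
      d$gene_id[d$direction != "ns"])))
    if (length(de_union) <= config$k_interaction) {
      log_lines <<- c(log_lines,
                      "interaction clustering skipped: too few DE genes")
      NULL
    } else {
      sf <- size_factors(data$rna$counts)
      rl <- rlog_like(data$rna$counts, sf)[de_union, , drop = FALSE]
      ic <- cluster_interactions(rl, k = config$k_interaction,
                                 seed = config$seed)
      emit("interaction_clusters.tsv", function(p)
        write.table(data.frame(gene_id = names(ic$assignment),
                               cluster = unname(ic$assignment)),
                    p, sep = "\t", quote = FALSE, row.names = FALSE))
      ic
    }
  })

  manifest <- list(
    package = "h2azpipe",
    parameters = list(island_fdr = config$island_fdr,
                      de_fdr = config$de_fdr,
                      sea_alpha = config$sea_alpha,
                      bootstrap_iters = config$bootstrap_iters,
                      k_patterns = config$k_patterns,
                      k_interaction = config$k_interaction,
                      seed = config$seed,
                      groups = as.list(config$groups),
                      contrasts = lapply(contrasts, identity),
                      simulate = config$simulate),
    concordance = lapply(islands, function(x) x$concordance),
    log = log_lines,
    checksums = as.list(tools::md5sum(unlist(files)))
  )
  names(manifest$checksums) <- names(files)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(data = data, islands = islands, differential = diffs,
                 profile = profile, de = de, overlap = overlap, sea = sea,
                 interaction = interaction, manifest = manifest,
                 manifest_path = manifest_path))
}
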