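# TSS/gene-body genic partition and island-to-gene assignment. The TSS
# region runs from 250 bp upstream to 500 bp downstream of the TSS
# (strand-aware); the gene body from 500 bp downstream of the TSS to
# 250 bp downstream of the TTS. Genes of length <= 500 bp have an empty
# gene body and their TSS region extends to TTS+250, so the two regions
# always partition the gene +/- 250 bp envelope.

#' Compute TSS-proximal and gene-body regions for each gene
#'
#' Strand-aware: for a minus-strand gene the TSS is the right-most
#' coordinate and "upstream" extends rightward. Regions are clipped to
#' chromosome bounds when known. All coordinates 0-based half-open; an
#' empty region has `start == end`.
#'
#' @param genes `gene_model` data.frame.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping (defaults to the `chrom_lengths` attribute of `genes`).
#' @return data.frame: gene_id, chrom, strand, tss_start, tss_end,
#'   gb_start, gb_end, env_start, env_end.
#' @export
compute_gene_regions <- function(genes, chrom_lengths = NULL) {
  chrom_lengths <- chrom_lengths %||% attr(genes, "chrom_lengths")
  n <- nrow(genes)
  plus <- genes$strand == "+"
  len <- genes$end - genes$start
  env_start <- genes$start - TTS_DOWN
  env_end <- genes$end + TTS_DOWN
  tss_start <- tss_end <- gb_start <- gb_end <- numeric(n)
  short <- len <= TSS_DOWN
  # plus strand: TSS at start
  tss_start[plus] <- genes$start[plus] - TSS_UP
  tss_end[plus] <- genes$start[plus] + TSS_DOWN
  gb_start[plus] <- genes$start[plus] + TSS_DOWN
  gb_end[plus] <- genes$end[plus] + TTS_DOWN
  # minus strand: TSS at end, mirror image
  tss_end[!plus] <- genes$end[!plus] + TSS_UP
  tss_start[!plus] <- genes$end[!plus] - TSS_DOWN
  gb_end[!plus] <- genes$end[!plus] - TSS_DOWN
  gb_start[!plus] <- genes$start[!plus] - TTS_DOWN
  # short genes: no gene body, TSS region covers the whole envelope
  tss_start[short] <- env_start[short]
  tss_end[short] <- env_end[short]
  gb_start[short & plus] <- gb_end[short & plus] <- env_end[short & plus]
  gb_end[short & !plus] <- gb_start[short & !plus] <- env_start[short & !plus]
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    tss_start = tss_start, tss_end = tss_end,
                    gb_start = gb_start, gb_end = gb_end,
                    env_start = env_start, env_end = env_end,
                    stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[out$chrom]
    for (col in c("tss_start", "tss_end", "gb_start", "gb_end",
                  "env_start", "env_end")) {
      out[[col]] <- pmin(pmax(out[[col]], 0), lim)
    }
  } else {
    for (col in c("tss_start", "tss_end", "gb_start", "gb_end",
                  "env_start", "env_end")) {
      out[[col]] <- pmax(out[[col]], 0)
    }
  }
  out
}

# >= 1 bp overlaps between interval sets, per chromosome; returns a
# data.frame of (query_idx, subject_idx).
overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  hits <- list()
  for (ch in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == ch & q_end > q_start)
    si <- which(s_chrom == ch & s_end > s_start)
    if (length(qi) == 0 || length(si) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi] + 1, q_end[qi]),
      IRanges::IRanges(s_start[si] + 1, s_end[si])
    )
    if (length(ov) > 0) {
      hits[[ch]] <- data.frame(query = qi[S4Vectors_from(ov)],
                               subject = si[S4Vectors_to(ov)])
    }
  }
  if (length(hits) == 0) return(data.frame(query = integer(),
                                           subject = integer()))
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

S4Vectors_from <- function(ov) methods::slot(ov, "from")
S4Vectors_to <- function(ov) methods::slot(ov, "to")

#' Assign islands to genes by envelope overlap
#'
#' A gene is considered to carry H2A.Z enrichment when any island
#' overlaps the gene extended by 250 bp on both sides, by at least 1 bp.
#' One island may assign to several genes.
#'
#' @param islands island data.frame (chrom/start/end).
#' @param genes `gene_model` data.frame.
#' @param chrom_lengths optional clipping bounds.
#' @return named list: gene_id -> integer vector of island row indices;
#'   genes without islands are absent.
#' @export
assign_islands_to_genes <- function(islands, genes, chrom_lengths = NULL) {
  if (nrow(islands) == 0 || nrow(genes) == 0) return(list())
  reg <- compute_gene_regions(genes, chrom_lengths)
  hits <- overlap_pairs(reg$chrom, reg$env_start, reg$env_end,
                        islands$chrom, islands$start, islands$end)
  split(hits$subject, reg$gene_id[hits$query])
}

#' Classify genes by differential H2A.Z category
#'
#' Each gene receives a subset of the four categories `tss_increase`,
#' `tss_decrease`, `gb_increase`, `gb_decrease`: a category is present
#' iff at least one differential island of that direction overlaps that
#' region by >= 1 bp. Islands straddling the TSS/gene-body boundary set
#' both regions' categories; genes carrying both directions count in
#' both summaries.
#'
#' @param diff_islands data.frame from [call_differential()].
#' @param gene_regions data.frame from [compute_gene_regions()].
#' @return list with `calls` (data.frame gene_id, category, island rows
#'   as a comma-joined string; one row per gene x category) and `summary`
#'   (list: n_genes_with_diff, fraction per category among those genes,
#'   and the region breakdown among decrease-/increase-containing genes;
#'   all empty when there are no differential islands).
#' @export
classify_differential <- function(diff_islands, gene_regions) {
  categories <- c("tss_increase", "tss_decrease", "gb_increase",
                  "gb_decrease")
  empty_calls <- data.frame(gene_id = character(), category = character(),
                            islands = character(), stringsAsFactors = FALSE)
  if (nrow(diff_islands) == 0) {
    return(list(calls = empty_calls,
                summary = list(n_genes_with_diff = 0L,
                               category_fraction = setNames(numeric(0),
                                                            character(0)),
                               decrease_region_breakdown = numeric(0),
                               increase_region_breakdown = numeric(0))))
  }
  rows <- list()
  for (region in c("tss", "gb")) {
    rs <- gene_regions[[paste0(region, "_start")]]
    re <- gene_regions[[paste0(region, "_end")]]
    hits <- overlap_pairs(gene_regions$chrom, rs, re,
                          diff_islands$chrom, diff_islands$start,
                          diff_islands$end)
    if (nrow(hits) == 0) next
    dir <- diff_islands$direction[hits$subject]
    rows[[region]] <- data.frame(
      gene_id = gene_regions$gene_id[hits$query],
      category = paste0(region, "_",
                        ifelse(dir == "increase", "increase", "decrease")),
      island = hits$subject, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    calls <- empty_calls
  } else {
    long <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    agg <- stats::aggregate(island ~ gene_id + category, data = long,
                            FUN = function(x)
                              paste(sort(unique(x)), collapse = ","))
    calls <- data.frame(gene_id = agg$gene_id, category = agg$category,
                        islands = agg$island, stringsAsFactors = FALSE)
    calls <- calls[order(calls$gene_id, calls$category), ]
    rownames(calls) <- NULL
  }
  genes_with <- unique(calls$gene_id)
  n_with <- length(genes_with)
  frac <- vapply(categories, function(cc) {
    if (n_with == 0) return(NA_real_)
    length(unique(calls$gene_id[calls$category == cc])) / n_with
  }, numeric(1))
  breakdown <- function(dir) {
    sub <- calls[grepl(dir, calls$category), ]
    g <- unique(sub$gene_id)
    if (length(g) == 0) return(numeric(0))
    tss <- unique(sub$gene_id[sub$category == paste0("tss_", dir)])
    gb <- unique(sub$gene_id[sub$category == paste0("gb_", dir)])
    c(tss = length(tss) / length(g), gb = length(gb) / length(g))
  }
  list(calls = calls,
       summary = list(
         n_genes_with_diff = n_with,
         category_fraction = if (n_with == 0) numeric(0) else frac,
         decrease_region_breakdown = breakdown("decrease"),
         increase_region_breakdown = breakdown("increase")))
}
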