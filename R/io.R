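# Genomic I/O: GFF3 gene annotation, bedGraph coverage, BED islands, TSV
# tables. Internal coordinates are 0-based half-open everywhere; GFF3
# (1-based inclusive) converts at the boundary; BED/bedGraph are native.

BIOTYPES <- c("PCG", "PG", "TE", "TEG")

#' Construct a gene annotation table
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param biotype one of `"PCG"`, `"PG"`, `"TE"`, `"TEG"`.
#' @return data.frame of class `gene_model`, one row per gene.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       biotype = "PCG") {
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand), biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  validate_genes(df)
}

validate_genes <- function(df) {
  if (nrow(df) > 0) {
    if (anyDuplicated(df$gene_id)) {
      stop("duplicate gene_id: ",
           paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(df$start < 0) || any(df$end <= df$start)) {
      stop("gene coordinates must satisfy 0 <= start < end", call. = FALSE)
    }
    if (!all(df$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'", call. = FALSE)
    }
    if (!all(df$biotype %in% BIOTYPES)) {
      stop("biotype must be one of ", paste(BIOTYPES, collapse = ", "),
           call. = FALSE)
    }
  }
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Read gene features from a GFF3 file
#'
#' Consumes only `gene`-type rows; requires an `ID` attribute; a missing or
#' unknown `biotype` attribute defaults to `"PCG"` with a warning. GFF3's
#' 1-based inclusive coordinates convert to the internal 0-based half-open
#' convention, so a row `start=1001 end=3000` becomes the interval
#' `[1000, 3000)`.
#'
#' @param path GFF3 file (plain or gzip).
#' @return `gene_model` data.frame.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- which(keep)
  recs <- list()
  warned_biotype <- FALSE
  for (ln in rows) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      stop(sprintf("malformed GFF3 row at line %d: expected 9 fields, got %d",
                   ln, length(fields)), call. = FALSE)
    }
    if (fields[3] != "gene") next
    start1 <- suppressWarnings(as.numeric(fields[4]))
    end1 <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(start1) || is.na(end1)) {
      stop(sprintf("malformed GFF3 row at line %d: non-numeric coordinates",
                   ln), call. = FALSE)
    }
    if (end1 < start1) {
      stop(sprintf("malformed GFF3 row at line %d: end < start", ln),
           call. = FALSE)
    }
    attrs <- parse_gff3_attributes(fields[9])
    if (is.na(attrs["ID"])) {
      stop(sprintf("malformed GFF3 row at line %d: missing ID attribute", ln),
           call. = FALSE)
    }
    biotype <- attrs["biotype"]
    if (is.na(biotype) || !(biotype %in% BIOTYPES)) {
      if (!warned_biotype) {
        warning("unknown or missing biotype attribute; defaulting to PCG",
                call. = FALSE)
        warned_biotype <- TRUE
      }
      biotype <- "PCG"
    }
    recs[[length(recs) + 1]] <- data.frame(
      gene_id = unname(attrs["ID"]), chrom = fields[1],
      start = start1 - 1, end = end1,
      strand = fields[7], biotype = unname(biotype),
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0) {
    return(validate_genes(data.frame(
      gene_id = character(), chrom = character(), start = numeric(),
      end = numeric(), strand = character(), biotype = character(),
      stringsAsFactors = FALSE
    )))
  }
  validate_genes(do.call(rbind, recs))
}

parse_gff3_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) >= 2) x[2] else NA_character_,
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals[c("ID", "biotype")]
}

#' Write gene features to GFF3
#'
#' @param genes `gene_model` data.frame.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    ord <- order(genes$chrom, genes$start)
    g <- genes[ord, ]
    writeLines(sprintf(
      "%s\th2azpipe\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
      g$chrom, as.integer(g$start) + 1L, as.integer(g$end), g$strand,
      g$gene_id, g$biotype
    ), con)
  }
  invisible(path)
}

#' Construct a binned coverage track
#'
#' @param counts named list: chromosome -> numeric vector of per-window
#'   counts (window `i` covers bp `[(i-1)*W, i*W)`).
#' @param window_size window width W in bp.
#' @param sample_id library label.
#' @return object of class `coverage_track` with the library size (total
#'   count over all windows) attached.
#' @export
coverage_track <- function(counts, window_size, sample_id = "track") {
  stopifnot(is.list(counts), !is.null(names(counts)) || length(counts) == 0,
            window_size > 0)
  counts <- lapply(counts, as.numeric)
  if (any(vapply(counts, function(x) any(x < 0), logical(1)))) {
    stop("coverage counts must be non-negative", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, window_size = window_size, counts = counts,
         library_size = sum(vapply(counts, sum, numeric(1)))),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d chromosome(s), W=%d bp, library=%g\n",
              x$sample_id, length(x$counts), x$window_size, x$library_size))
  invisible(x)
}

#' Read a bedGraph file into a binned coverage track
#'
#' Interval values carry count mass at a density of `value / window_size`
#' per bp; the mass is re-binned into fixed windows by bp-weighted sums, so
#' an interval spanning a window boundary splits proportionally and a
#' single-window interval contributes its value to that window. Missing
#' intervals are zero. Intervals must be sorted and non-overlapping per
#' chromosome and values non-negative.
#'
#' @param path bedGraph file (plain or gzip); `track`/`#` lines skipped.
#' @param window_size target window width in bp.
#' @param sample_id library label.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to the last covered coordinate rounded up to a whole window.
#' @return `coverage_track`.
#' @export
read_bedgraph <- function(path, window_size, sample_id = "track",
                          chrom_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    counts <- list()
    if (!is.null(chrom_lengths)) {
      counts <- lapply(chrom_lengths,
                       function(L) numeric(ceiling(L / window_size)))
      names(counts) <- names(chrom_lengths)
    }
    return(coverage_track(counts, window_size, sample_id))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4)) {
    stop("malformed bedGraph row: fewer than 4 fields", call. = FALSE)
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[`, character(1), 3)),
    value = as.numeric(vapply(parts, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$value))) {
    stop("malformed bedGraph row: non-numeric field", call. = FALSE)
  }
  if (any(df$value < 0)) stop("negative bedGraph value", call. = FALSE)
  counts <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (is.unsorted(d$start, strictly = FALSE)) {
      stop(sprintf("bedGraph intervals not sorted on %s", ch), call. = FALSE)
    }
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop(sprintf("overlapping bedGraph intervals on %s", ch), call. = FALSE)
    }
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(d$end)
    }
    nw <- ceiling(L / window_size)
    v <- numeric(nw)
    for (i in seq_len(nrow(d))) {
      a <- d$start[i]; b <- d$end[i]
      dens <- d$value[i] / window_size  # count mass per bp
      w0 <- floor(a / window_size) + 1
      w1 <- min(ceiling(b / window_size), nw)
      for (w in w0:w1) {
        lo <- max(a, (w - 1) * window_size)
        hi <- min(b, w * window_size)
        if (hi > lo) v[w] <- v[w] + dens * (hi - lo)
      }
    }
    counts[[ch]] <- v
  }
  coverage_track(counts, window_size, sample_id)
}

#' Write a coverage track as bedGraph
#'
#' One row per non-zero window, value = window count, 0-based half-open.
#'
#' @param track `coverage_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", track$sample_id), con)
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    W <- track$window_size
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, (nz - 1L) * W, nz * W, v[nz]),
               con)
  }
  invisible(path)
}

#' Write islands or differential islands as BED6+
#'
#' Score is `-log10(q)` capped at `max_score`; for differential islands the
#' direction is encoded in the name field. Extra columns carry the raw
#' counts, p and q.
#'
#' @param islands data.frame from [call_islands()] or [call_differential()].
#' @param path output file.
#' @param max_score cap for `-log10(q)` when q underflows (default 300).
#' @export
write_bed <- function(islands, path, max_score = 300) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tp_value\tq_value", con)
  if (nrow(islands) == 0) return(invisible(path))
  ord <- order(islands$chrom, islands$start)
  if (!identical(ord, seq_len(nrow(islands)))) {
    stop("islands must be sorted by chrom, start", call. = FALSE)
  }
  score <- -log10(islands$q_value)
  score[!is.finite(score) | score > max_score] <- max_score
  name <- if ("direction" %in% names(islands)) {
    sprintf("diff_%d_%s", seq_len(nrow(islands)), islands$direction)
  } else {
    sprintf("island_%d", seq_len(nrow(islands)))
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.4g\t.\t%.6g\t%.6g",
                     islands$chrom, as.integer(islands$start),
                     as.integer(islands$end), name, score,
                     islands$p_value, islands$q_value), con)
  invisible(path)
}

#' Read/write a gene-by-sample count table as TSV
#'
#' @param counts integer matrix, rownames = gene ids.
#' @param path TSV file with a header row and a `gene_id` first column.
#' @return `read_counts_tsv` returns the matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}
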