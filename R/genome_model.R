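# Core coordinate model: gene annotations, transcription-oriented intergenic
# intervals, and fixed-width binning. All internal coordinates are 0-based,
# half-open; GFF3 I/O converts to/from 1-based inclusive at the boundary.

#' Construct a genome annotation
#'
#' Bundles an ordered table of gene records with chromosome lengths. The
#' termination site (`tts`) of each gene is the annotated transcript 3' end:
#' `end` for `+` strand genes and `start` for `-` strand genes, under the
#' internal 0-based half-open convention.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param chrom_lengths named numeric vector of chromosome lengths (nt).
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (the validated table, sorted by chromosome and start, with a
#'   `tts` column added) and `chrom_lengths`.
#' @examples
#' gn <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                  start = 100, end = 400)
#' ann <- genome_annotation(gn, c(chr1 = 1000))
#' ann$genes$tts  # 400: the 3' end of a + strand gene
#' @export
genome_annotation <- function(genes, chrom_lengths) {
  required <- c("gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("annotation error: missing gene columns: ",
         paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes)[, required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  if (is.null(names(chrom_lengths)) && length(chrom_lengths) > 0) {
    stop("annotation error: chrom_lengths must be named")
  }
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$gene_id)) {
      stop("annotation error: duplicate gene_id: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "))
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stop("annotation error: strand must be '+' or '-'")
    }
    if (any(genes$start >= genes$end)) {
      stop("coordinate error: gene body must satisfy start < end")
    }
    unknown <- setdiff(genes$chrom, names(chrom_lengths))
    if (length(unknown) > 0) {
      stop("coordinate error: gene on unknown chromosome: ",
           paste(unknown, collapse = ", "))
    }
    len <- chrom_lengths[genes$chrom]
    if (any(genes$start < 0) || any(genes$end > len)) {
      stop("coordinate error: gene outside chromosome bounds")
    }
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  structure(list(genes = genes, chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s) (%s nt)\n",
              nrow(x$genes), length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ",")))
  invisible(x)
}

#' Extract transcription-oriented intergenic intervals
#'
#' Emits one interval per gene, anchored at the gene's termination site and
#' extending in the direction of transcription until the nearest annotated
#' gene boundary on either strand, or the chromosome end. This is the search
#' space in which a 3'UTR extension may be called: a called extension can
#' never enter an annotated gene body. Zero-length intervals (termination
#' site abutting or inside another feature) are retained so every gene has a
#' defined, possibly empty, search space. Convergent gene pairs each receive
#' their own oriented interval over the shared span.
#'
#' @param annotation a [genome_annotation()].
#' @return data.frame with one row per gene: `interval_id`, `gene_id`,
#'   `chrom`, `strand`, `five_prime_pos` (adjacent to the parent tts),
#'   `three_prime_pos` (truncation point), `start`, `end` (the genomic span,
#'   0-based half-open) and `length` in nt. Traversal from `five_prime_pos`
#'   toward `three_prime_pos` follows the parent gene's transcription.
#' @export
extract_intergenic <- function(annotation) {
  if (!inherits(annotation, "genome_annotation")) {
    stop("annotation error: expected a genome_annotation object")
  }
  genes <- annotation$genes
  if (nrow(genes) == 0) {
    return(data.frame(interval_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      five_prime_pos = numeric(), three_prime_pos = numeric(),
                      start = numeric(), end = numeric(), length = numeric(),
                      stringsAsFactors = FALSE))
  }
  same_strand_overlap <- function(g) {
    g <- g[order(g$start), , drop = FALSE]
    any(g$start[-1] < g$end[-nrow(g)])
  }
  for (key in unique(paste(genes$chrom, genes$strand))) {
    sel <- paste(genes$chrom, genes$strand) == key
    if (sum(sel) > 1 && same_strand_overlap(genes[sel, ])) {
      stop("annotation error: overlapping genes on the same strand (", key, ")")
    }
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    others <- genes[genes$chrom == g$chrom & genes$gene_id != g$gene_id, ,
                    drop = FALSE]
    tts <- g$tts
    if (g$strand == "+") {
      bound <- annotation$chrom_lengths[[g$chrom]]
      if (nrow(others) > 0) {
        # a body overlapping the tts closes the interval immediately
        if (any(others$start < tts & others$end > tts)) {
          bound <- tts
        } else {
          nxt <- others$start[others$start >= tts]
          if (length(nxt) > 0) bound <- min(nxt)
        }
      }
      data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                 five_prime_pos = tts, three_prime_pos = bound,
                 start = tts, end = bound, length = bound - tts,
                 stringsAsFactors = FALSE)
    } else {
      bound <- 0
      if (nrow(others) > 0) {
        if (any(others$start < tts & others$end > tts)) {
          bound <- tts
        } else {
          prv <- others$end[others$end <= tts]
          if (length(prv) > 0) bound <- max(prv)
        }
      }
      data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                 five_prime_pos = tts, three_prime_pos = bound,
                 start = bound, end = tts, length = tts - bound,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out <- cbind(interval_id = paste0(out$gene_id, ".ig"), out)
  rownames(out) <- NULL
  out
}

#' Tile intergenic intervals into fixed-width bins
#'
#' Bins are counted from the 5' end of each interval (bin 0 is adjacent to
#' the parent gene's termination site) and tile the interval without gaps or
#' overlap; the last bin may be shorter than `width`.
#'
#' @param intervals data.frame as returned by [extract_intergenic()] (one or
#'   more rows).
#' @param width bin width in nt (default 10).
#' @return data.frame with columns `interval_id`, `gene_id`, `bin_index`
#'   (0-based from the 5' end), `chrom`, `start`, `end` (genomic, 0-based
#'   half-open), `strand`, `width`.
#' @export
bin_intervals <- function(intervals, width = 10) {
  if (!is.numeric(width) || length(width) != 1 || width < 1) {
    stop("parameter error: bin width must be >= 1")
  }
  width <- as.integer(width)
  pieces <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    n_bins <- ceiling(iv$length / width)
    if (n_bins == 0) return(NULL)
    k <- seq_len(n_bins) - 1L
    if (iv$strand == "+") {
      s <- iv$five_prime_pos + k * width
      e <- pmin(s + width, iv$three_prime_pos)
    } else {
      e <- iv$five_prime_pos - k * width
      s <- pmax(e - width, iv$three_prime_pos)
    }
    data.frame(interval_id = iv$interval_id, gene_id = iv$gene_id,
               bin_index = k, chrom = iv$chrom, start = s, end = e,
               strand = iv$strand, width = e - s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(interval_id = character(), gene_id = character(),
                      bin_index = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), width = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @rdname bin_intervals
#' @param interval a single-row interval data.frame.
#' @export
bin_interval <- function(interval, width = 10) {
  stopifnot(nrow(interval) == 1)
  bin_intervals(interval, width = width)
}

#' Map a coding-sequence position to its codon index
#'
#' A 1-based nucleotide position within a CDS falls in codon
#' `ceiling(pos / 3)`; e.g. a substitution at CDS position 116 affects
#' codon 39.
#'
#' @param cds_pos 1-based coding-sequence position(s).
#' @return 1-based codon index (integer), vectorized over `cds_pos`.
#' @export
cds_position_to_codon <- function(cds_pos) {
  if (any(!is.finite(cds_pos)) || any(cds_pos < 1)) {
    stop("parameter error: cds_pos must be >= 1")
  }
  as.integer(ceiling(cds_pos / 3))
}

#' Number of residues in an inclusive residue span
#'
#' A deletion removing residues `first_res` through `last_res` inclusive
#' removes `last_res - first_res + 1` residues; e.g. residues 84 through 114
#' span 31 amino acids.
#'
#' @param first_res,last_res 1-based residue indices, `first_res <= last_res`.
#' @return integer residue count, vectorized.
#' @export
residue_span_length <- function(first_res, last_res) {
  if (any(first_res > last_res)) {
    stop("parameter error: first_res must be <= last_res")
  }
  as.integer(last_res - first_res + 1)
}

# ---- annotation I/O --------------------------------------------------------

#' Read a gene annotation from GFF3
#'
#' Uses `gene` features when present, otherwise falls back to the outermost
#' `mRNA` span per gene. GFF3 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param chrom_lengths optional named vector; when `NULL`, lengths are taken
#'   from the file's `##sequence-region` pragmas (an error if absent).
#' @return a [genome_annotation()].
#' @export
read_gene_annotation <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- gr[gr$type == "gene"]
  if (length(feats) == 0) {
    mr <- gr[gr$type == "mRNA"]
    if (length(mr) == 0) stop("format error: no gene or mRNA features in ", path)
    # outermost span per parent gene id
    key <- vapply(mr$ID, function(x) x[1], character(1))
    spl <- split(mr, key)
    feats <- unlist(GenomicRanges::GRangesList(lapply(spl, range)))
    feats$ID <- names(feats)
  }
  ids <- if (!is.null(feats$ID)) as.character(feats$ID) else
    as.character(feats$Name)
  if (is.null(chrom_lengths)) {
    pragmas <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(pragmas) == 0) {
      stop("format error: no ##sequence-region pragmas; supply chrom_lengths")
    }
    parts <- strsplit(trimws(pragmas), "\\s+")
    chrom_lengths <- stats::setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, function(p) p[2], character(1)))
  }
  genome_annotation(
    data.frame(gene_id = ids,
               chrom = as.character(GenomicRanges::seqnames(feats)),
               strand = as.character(GenomicRanges::strand(feats)),
               start = GenomicRanges::start(feats) - 1,
               end = GenomicRanges::end(feats),
               stringsAsFactors = FALSE),
    chrom_lengths)
}

#' Write a gene annotation to GFF3
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  genes <- annotation$genes
  sl <- annotation$chrom_lengths
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(sl)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch, as.integer(sl[[ch]])),
               con)
  }
  if (nrow(genes) > 0) {
    writeLines(sprintf("%s\tutrx\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, as.integer(genes$start + 1),
                       as.integer(genes$end), genes$strand, genes$gene_id),
               con)
  }
  invisible(path)
}

#' Write intervals or extensions as BED6
#'
#' Converts from the internal 0-based half-open convention (identical to
#' BED). The `name` column is the gene id and `score` the interval length.
#'
#' @param x data.frame with `chrom`, `start`, `end`, `gene_id`, `strand`,
#'   `length` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), x$gene_id, as.integer(x$length),
                   x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write bin definitions as TSV
#'
#' @param bins data.frame from [bin_intervals()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(bins, path) {
  utils::write.table(
    bins[, c("interval_id", "bin_index", "chrom", "start", "end", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
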