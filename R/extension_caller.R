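# 3'UTR extension calling: median-of-ratios normalization of bin counts,
# contiguous assembly of extensions from each termination site until a bin's
# normalized readcount drops below the stop threshold, then a strict length
# filter.

#' Caller configuration
#'
#' @param bin_width bin width in nt.
#' @param stop_threshold normalized readcount below which assembly stops
#'   (the failing bin is excluded from the extension).
#' @param min_length length filter: only extensions strictly longer than
#'   this many nt are retained.
#' @param statistic replicate summary used during assembly: `"mean"`
#'   (default) or `"median"` of normalized counts across the genotype's
#'   samples, or `"intersection"` (every sample must individually pass,
#'   i.e. the per-bin minimum).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(bin_width = 10, stop_threshold = 1,
                          min_length = 200,
                          statistic = c("mean", "median", "intersection")) {
  statistic <- match.arg(statistic)
  if (bin_width < 1) stop("parameter error: bin_width must be >= 1")
  if (stop_threshold <= 0) stop("parameter error: stop_threshold must be > 0")
  if (min_length < 0) stop("parameter error: min_length must be >= 0")
  structure(list(bin_width = bin_width, stop_threshold = stop_threshold,
                 min_length = min_length, statistic = statistic),
            class = "caller_config")
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed from gene-body counts: each sample's
#' factor is the median, over genes with nonzero counts in every sample, of
#' the ratio of that sample's count to the gene's geometric mean across
#' samples; factors are then rescaled so their geometric mean is 1. Size
#' factors are computed from gene-body counts rather than intergenic bins
#' because bins are mostly near-zero and the median-of-ratios degenerates on
#' sparse rows.
#'
#' @param gene_counts genes x samples matrix of raw counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(gene_counts) {
  gene_counts <- as.matrix(gene_counts)
  keep <- rowSums(gene_counts > 0) == ncol(gene_counts)
  if (!any(keep)) {
    stop("normalization error: no gene has nonzero counts in all samples; ",
         "consider a pseudo-reference fallback")
  }
  lc <- log(gene_counts[keep, , drop = FALSE])
  log_ratios <- lc - rowMeans(lc)
  s <- exp(apply(log_ratios, 2, stats::median))
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(gene_counts))
}

#' Normalize bin counts by size factors
#'
#' @param bin_counts bins x samples matrix.
#' @param s named size factors from [size_factors()].
#' @return matrix of normalized counts, `count / s_j` per sample column.
#' @export
normalize_bins <- function(bin_counts, s) {
  bin_counts <- as.matrix(bin_counts)
  missing <- setdiff(colnames(bin_counts), names(s))
  if (length(missing) > 0) {
    stop("key error: no size factor for sample(s): ",
         paste(missing, collapse = ", "))
  }
  sweep(bin_counts, 2, s[colnames(bin_counts)], "/")
}

# replicate summary of normalized counts used as the assembly statistic
.assembly_stat <- function(norm, statistic) {
  switch(statistic,
         mean = rowMeans(norm),
         median = apply(norm, 1, stats::median),
         intersection = apply(norm, 1, min))
}

#' Assemble 3'UTR extensions from binned coverage
#'
#' Walks each intergenic interval's bins from the 5' end (bin 0, adjacent to
#' the parent gene's termination site) and extends the call over the maximal
#' prefix of bins whose assembly statistic is at or above the stop
#' threshold; the first failing bin ends assembly and is excluded, even if a
#' later bin would pass again (contiguity). An interval whose bin 0 fails
#' yields no call. A call that exhausts its interval is flagged truncated.
#'
#' @param intervals interval table from [extract_intergenic()].
#' @param bins bin table from [bin_intervals()], tiling `intervals`.
#' @param norm_bins normalized bins x samples matrix with rownames
#'   `interval_id:bin_index` (from [normalize_bins()]).
#' @param samples character vector: the samples (one genotype) whose
#'   normalized counts are summarized during assembly.
#' @param config a [caller_config()].
#' @param genotype label stored with each call.
#' @return data.frame of calls (pre length filter): `gene_id`, `genotype`,
#'   `chrom`, `strand`, `start`, `end`, `length`, `n_bins`, `truncated`,
#'   `next_bin_stat` (assembly statistic of the first bin past the call;
#'   `NA` when truncated).
#' @export
assemble_extensions <- function(intervals, bins, norm_bins, samples, config,
                                genotype = NA_character_) {
  if (length(samples) == 0) stop("parameter error: sample set is empty")
  missing <- setdiff(samples, colnames(norm_bins))
  if (length(missing) > 0) {
    stop("key error: samples not in normalized matrix: ",
         paste(missing, collapse = ", "))
  }
  stat <- .assembly_stat(norm_bins[, samples, drop = FALSE], config$statistic)
  names(stat) <- rownames(norm_bins)
  bin_ids <- paste(bins$interval_id, bins$bin_index, sep = ":")
  if (!all(bin_ids %in% names(stat))) {
    stop("coverage error: normalized matrix does not cover all bins")
  }
  bstat <- stat[bin_ids]

  calls <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    sel <- which(bins$interval_id == iv$interval_id)
    if (length(sel) == 0) return(NULL)
    sel <- sel[order(bins$bin_index[sel])]
    v <- bstat[sel]
    fail <- which(v < config$stop_threshold)
    k <- if (length(fail) == 0) length(sel) else fail[1] - 1L
    if (k == 0) return(NULL)
    used <- sel[seq_len(k)]
    truncated <- k == length(sel)
    data.frame(gene_id = iv$gene_id, genotype = genotype, chrom = iv$chrom,
               strand = iv$strand, start = min(bins$start[used]),
               end = max(bins$end[used]), length = sum(bins$width[used]),
               n_bins = k, truncated = truncated,
               next_bin_stat = if (truncated) NA_real_ else
                 unname(v[k + 1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), genotype = character(),
                      chrom = character(), strand = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_bins = integer(), truncated = logical(),
                      next_bin_stat = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Filter extensions by length
#'
#' Retains calls strictly longer than `config$min_length` nt (a 200-nt call
#' is removed under the default threshold of 200).
#'
#' @param calls data.frame from [assemble_extensions()].
#' @param config a [caller_config()].
#' @return the retained subset of `calls`.
#' @export
filter_extensions <- function(calls, config) {
  out <- calls[calls$length > config$min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sum raw counts over an extension's bins, per sample
#'
#' @param calls data.frame of calls with `gene_id` and `n_bins` (bins 0 to
#'   `n_bins - 1` of the gene's interval make up the call).
#' @param bins bin table from [bin_intervals()].
#' @param bin_counts raw bins x samples matrix with rownames
#'   `interval_id:bin_index`.
#' @return integer matrix, one row per call (rownames = gene_id), one column
#'   per sample.
#' @export
quantify_extensions <- function(calls, bins, bin_counts) {
  bin_ids <- paste(bins$interval_id, bins$bin_index, sep = ":")
  out <- matrix(0L, nrow(calls), ncol(bin_counts),
                dimnames = list(calls$gene_id, colnames(bin_counts)))
  for (i in seq_len(nrow(calls))) {
    sel <- bins$gene_id == calls$gene_id[i] &
      bins$bin_index < calls$n_bins[i]
    ids <- bin_ids[sel]
    if (sum(sel) != calls$n_bins[i] || !all(ids %in% rownames(bin_counts))) {
      stop("coverage error: bins missing for extension of ",
           calls$gene_id[i])
    }
    out[i, ] <- as.integer(round(colSums(
      bin_counts[ids, , drop = FALSE])))
  }
  out
}

#' Call 3'UTR extensions per genotype
#'
#' Convenience wrapper running normalization, per-genotype assembly and the
#' length filter, and quantifying each extended gene over the union of its
#' per-genotype call regions (the longest called prefix), across all samples.
#' Assembly is run per genotype so genotype-specific extension sets (and
#' their overlaps) are well defined; the union region puts both genotypes'
#' counts on the same footing for differential testing.
#'
#' @param intervals,bins interval and bin tables.
#' @param bin_counts raw bins x samples matrix.
#' @param gene_counts raw genes x samples matrix (for size factors).
#' @param sample_sheet data.frame with `sample` and `genotype` columns.
#' @param config a [caller_config()].
#' @return list with `size_factors`, `calls` (filtered calls, all genotypes),
#'   `regions` (per-gene union region), and `extension_counts` (union-region
#'   raw counts, genes x samples).
#' @export
call_extensions <- function(intervals, bins, bin_counts, gene_counts,
                            sample_sheet, config = caller_config()) {
  s <- size_factors(gene_counts)
  norm <- normalize_bins(bin_counts, s)
  genos <- unique(sample_sheet$genotype)
  calls <- do.call(rbind, lapply(genos, function(g) {
    smp <- sample_sheet$sample[sample_sheet$genotype == g]
    filter_extensions(
      assemble_extensions(intervals, bins, norm, smp, config, genotype = g),
      config)
  }))
  if (is.null(calls) || nrow(calls) == 0) {
    return(list(size_factors = s, calls = calls, regions = NULL,
                extension_counts = NULL))
  }
  # union region per gene: calls share the 5' anchor, so the union is the
  # call with the most bins
  regions <- do.call(rbind, lapply(split(calls, calls$gene_id), function(d) {
    d[which.max(d$n_bins), c("gene_id", "chrom", "strand", "start", "end",
                             "length", "n_bins", "truncated")]
  }))
  rownames(regions) <- NULL
  ext_counts <- quantify_extensions(regions, bins, bin_counts)
  list(size_factors = s, calls = calls, regions = regions,
       extension_counts = ext_counts)
}
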