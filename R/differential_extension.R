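# Differential read-through between genotypes. The decision rule keeps the
# two published thresholds (FDR-adjusted p < 0.1 and extension/gene-body
# ratio fold change > 2) and tests per-sample log2 extension/body ratios
# with a Welch t-test; the ratio construction makes the test independent of
# the gene-body expression level.

#' Differential-testing configuration
#'
#' @param alpha_adj FDR-adjusted p-value threshold.
#' @param fc_min fold-change threshold on the ratio of extension/gene-body
#'   ratios between genotypes (applied symmetrically: `> fc_min` or
#'   `< 1/fc_min`).
#' @param pseudocount added to normalized counts before forming ratios, so a
#'   zero extension or body count never divides by zero.
#' @param p_adjust_method multiple-testing method (Benjamini-Hochberg).
#' @param var_floor floor on group variances, avoiding zero-variance
#'   degeneracy in the t statistic.
#' @return list of class `diff_config`.
#' @export
diff_config <- function(alpha_adj = 0.1, fc_min = 2, pseudocount = 0.5,
                        p_adjust_method = "BH", var_floor = 1e-8) {
  if (alpha_adj <= 0 || alpha_adj >= 1) {
    stop("parameter error: alpha_adj must lie in (0, 1)")
  }
  if (fc_min < 1) stop("parameter error: fc_min must be >= 1")
  if (pseudocount <= 0) stop("parameter error: pseudocount must be > 0")
  structure(list(alpha_adj = alpha_adj, fc_min = fc_min,
                 pseudocount = pseudocount,
                 p_adjust_method = p_adjust_method, var_floor = var_floor),
            class = "diff_config")
}

#' Extension/gene-body ratios per sample and per genotype
#'
#' Per-sample ratio for gene g, sample j:
#' `r_gj = (ext_gj / s_j + pc) / (body_gj / s_j + pc)`; per-genotype ratio
#' `R_g = (mean normalized extension + pc) / (mean normalized body + pc)`,
#' with `pc` the pseudocount.
#'
#' @param ext_counts extensions x samples raw count matrix (rownames =
#'   gene_id).
#' @param body_counts genes x samples raw count matrix.
#' @param s named size factors.
#' @param sample_sheet data.frame with `sample` and `genotype`.
#' @param pseudocount see [diff_config()].
#' @return list with `per_sample` (genes x samples ratio matrix),
#'   `per_genotype` (genes x genotypes ratio matrix), and `dropped`
#'   (gene ids excluded for all-zero body counts, with a reason).
#' @export
ratio_table <- function(ext_counts, body_counts, s, sample_sheet,
                        pseudocount = 0.5) {
  genes <- rownames(ext_counts)
  missing <- setdiff(genes, rownames(body_counts))
  if (length(missing) > 0) {
    stop("key error: extensions without gene-body counts: ",
         paste(missing, collapse = ", "))
  }
  samples <- sample_sheet$sample
  body <- body_counts[genes, samples, drop = FALSE]
  ext <- ext_counts[genes, samples, drop = FALSE]
  all_zero <- rowSums(body) == 0
  dropped <- data.frame(
    gene_id = genes[all_zero],
    reason = rep("zero gene-body counts in all samples", sum(all_zero)),
    stringsAsFactors = FALSE)
  if (any(all_zero)) {
    message("ratio_table: excluding ", sum(all_zero),
            " gene(s) with zero body counts in all samples")
    body <- body[!all_zero, , drop = FALSE]
    ext <- ext[!all_zero, , drop = FALSE]
    genes <- genes[!all_zero]
  }
  sf <- s[samples]
  norm_ext <- sweep(ext, 2, sf, "/")
  norm_body <- sweep(body, 2, sf, "/")
  per_sample <- (norm_ext + pseudocount) / (norm_body + pseudocount)
  genos <- unique(sample_sheet$genotype)
  per_genotype <- vapply(genos, function(g) {
    smp <- sample_sheet$sample[sample_sheet$genotype == g]
    (rowMeans(norm_ext[, smp, drop = FALSE]) + pseudocount) /
      (rowMeans(norm_body[, smp, drop = FALSE]) + pseudocount)
  }, numeric(length(genes)))
  per_genotype <- matrix(per_genotype, nrow = length(genes),
                         dimnames = list(genes, genos))
  list(per_sample = per_sample, per_genotype = per_genotype,
       dropped = dropped)
}

# Welch t-test with floored variances; identical groups (t = 0) give p = 1
.welch_p <- function(x, y, var_floor) {
  nx <- length(x); ny <- length(y)
  vx <- max(stats::var(x), var_floor)
  vy <- max(stats::var(y), var_floor)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t_stat), df)
}

#' Test extensions for differential read-through between two genotypes
#'
#' Welch two-sample t-test on per-sample log2 extension/gene-body ratios.
#'
#' @param per_sample_ratios genes x samples ratio matrix from
#'   [ratio_table()].
#' @param sample_sheet data.frame with `sample` and `genotype`.
#' @param contrast length-2 character: `c(test, reference)` genotypes.
#' @param config a [diff_config()].
#' @return numeric vector of raw two-sided p-values, one per gene.
#' @export
test_extension <- function(per_sample_ratios, sample_sheet,
                           contrast, config = diff_config()) {
  stopifnot(length(contrast) == 2)
  smp_test <- sample_sheet$sample[sample_sheet$genotype == contrast[1]]
  smp_ref <- sample_sheet$sample[sample_sheet$genotype == contrast[2]]
  if (length(smp_test) < 2 || length(smp_ref) < 2) {
    stop("statistics error: need >= 2 samples per genotype")
  }
  lr <- log2(per_sample_ratios)
  apply(lr, 1, function(row) {
    .welch_p(row[smp_test], row[smp_ref], config$var_floor)
  })
}

#' Adjust p-values and classify extensions as significantly differential
#'
#' Benjamini-Hochberg adjustment; an extension is significant when the
#' adjusted p-value is below `alpha_adj` and the fold change of the
#' extension/gene-body ratios between genotypes exceeds `fc_min` in either
#' direction (`fold_change > fc_min` or `< 1/fc_min`).
#'
#' @param p raw p-values.
#' @param fold_change per-gene ratio of per-genotype ratios
#'   (test / reference).
#' @param config a [diff_config()].
#' @param gene_id optional gene ids.
#' @return data.frame: `gene_id`, `fold_change`, `p`, `padj`, `significant`.
#' @export
adjust_and_classify <- function(p, fold_change, config = diff_config(),
                                gene_id = names(p)) {
  if (length(p) != length(fold_change)) {
    stop("validation error: p and fold_change lengths differ")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("validation error: p-values outside [0, 1]")
  }
  padj <- stats::p.adjust(p, method = config$p_adjust_method)
  sig <- padj < config$alpha_adj &
    (fold_change > config$fc_min | fold_change < 1 / config$fc_min)
  data.frame(gene_id = if (is.null(gene_id)) seq_along(p) else gene_id,
             fold_change = unname(fold_change), p = unname(p),
             padj = unname(padj), significant = unname(sig),
             stringsAsFactors = FALSE)
}

#' Full differential-extension analysis for one contrast
#'
#' @param ext_counts,body_counts raw count matrices (see [ratio_table()]).
#' @param s named size factors.
#' @param sample_sheet data.frame with `sample` and `genotype`.
#' @param contrast `c(test, reference)` genotype labels.
#' @param config a [diff_config()].
#' @return data.frame with per-genotype ratios (`R_<genotype>`),
#'   `fold_change`, `p`, `padj`, `significant`.
#' @export
differential_extension <- function(ext_counts, body_counts, s, sample_sheet,
                                   contrast, config = diff_config()) {
  rt <- ratio_table(ext_counts, body_counts, s, sample_sheet,
                    pseudocount = config$pseudocount)
  p <- test_extension(rt$per_sample, sample_sheet, contrast, config)
  fc <- rt$per_genotype[, contrast[1]] / rt$per_genotype[, contrast[2]]
  res <- adjust_and_classify(p, fc, config,
                             gene_id = rownames(rt$per_genotype))
  r <- as.data.frame(rt$per_genotype)
  names(r) <- paste0("R_", colnames(rt$per_genotype))
  cbind(res[, "gene_id", drop = FALSE], r,
        res[, c("fold_change", "p", "padj", "significant")])
}

#' Overlap summary of significant gene sets
#'
#' Sizes of each set, every pairwise (and higher-order) intersection, and
#' the union, for Venn-style reporting of extension sets across contrasts.
#'
#' @param sets named list of character vectors (e.g. significant gene ids
#'   per genotype contrast).
#' @return data.frame with columns `sets` (labels joined by `&`, or
#'   `"union"`) and `n`.
#' @export
venn_summary <- function(sets) {
  if (length(sets) < 2) stop("parameter error: need >= 2 sets")
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(nm, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(combos, function(cc) {
    data.frame(sets = paste(cc, collapse = " & "),
               n = length(Reduce(intersect, sets[cc])),
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1]] <- data.frame(
    sets = "union", n = length(unique(unlist(sets))),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
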