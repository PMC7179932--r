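# Seeded generator for toy genomes, strand-specific coverage with
# genotype-dependent transcriptional read-through, and cleavage-site
# sequences with planted NUE hexamers. Counts are generated directly at bin
# resolution (no read-level simulation): the caller consumes binned counts,
# so read-level detail would add cost without exercising more of the method.

#' Simulation configuration
#'
#' Defines the geometry of a toy genome and the count model for
#' strand-specific polyA+ coverage in a two-genotype read-through study.
#'
#' Gene-body and intergenic bin counts are negative binomial with a single
#' shared dispersion `phi` (`phi = 0` gives Poisson). For gene g with
#' expression rate `e_g` (expected reads per `bin_width`-nt gene-body bin,
#' drawn log-uniform within `expression_bounds`), sample s with library-size
#' multiplier `depth_s`, the intergenic bin at 0-based distance d from the
#' termination site has mean
#' `depth_s * (e_g * f * S(d) + background)`, where `f` is the genotype's
#' read-through fraction and the survival term is `S(d) = (1 - q)^d` for
#' geometric decay or a step function for fixed-length read-through
#' (`S(d) = 1` for `d < L_true / bin_width`, else 0).
#'
#' @param n_chroms number of chromosomes.
#' @param n_genes total number of genes (spread evenly over chromosomes).
#' @param chrom_length chromosome length in nt; `NULL` sizes each chromosome
#'   to fit its genes plus one trailing gap.
#' @param gene_length_range,intergenic_gap_range uniform bounds (nt).
#' @param strand_mode `"alternate"` (convergent/divergent pairs), `"random"`,
#'   or `"plus"`.
#' @param n_replicates replicates per genotype.
#' @param genotypes labels; first is the reference/control.
#' @param expression_bounds log-uniform bounds for `e_g` (reads per body bin).
#' @param dispersion negative-binomial dispersion `phi` (>= 0).
#' @param readthrough_fraction named numeric, read-through fraction `f` per
#'   genotype for affected genes (each in [0, 1]).
#' @param affected_fraction fraction of genes carrying read-through in the
#'   non-reference genotype(s).
#' @param decay `"geometric"` or `"fixed"`.
#' @param q per-bin stopping probability for geometric decay, in (0, 1].
#' @param L_true fixed read-through length(s) in nt (recycled over affected
#'   genes) when `decay = "fixed"`.
#' @param background expected noise reads per intergenic bin.
#' @param depth per-sample library-size multipliers (recycled), or `NULL`
#'   for 1 everywhere.
#' @param antisense_rate fraction of a convergent neighbour's read-through
#'   signal leaking onto the opposite strand (0 disables; strand-specific
#'   libraries by construction).
#' @param bin_width bin width in nt.
#' @param seed integer; fixes every draw of the generator.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 1,
                              n_genes = 50,
                              chrom_length = NULL,
                              gene_length_range = c(600, 2000),
                              intergenic_gap_range = c(2000, 4000),
                              strand_mode = c("alternate", "random", "plus"),
                              n_replicates = 3,
                              genotypes = c("control", "mutant"),
                              expression_bounds = c(5, 50),
                              dispersion = 0.05,
                              readthrough_fraction = c(control = 0, mutant = 0.8),
                              affected_fraction = 0.5,
                              decay = c("geometric", "fixed"),
                              q = 0.05,
                              L_true = 400,
                              background = 0.1,
                              depth = NULL,
                              antisense_rate = 0,
                              bin_width = 10,
                              seed = 1) {
  strand_mode <- match.arg(strand_mode)
  decay <- match.arg(decay)
  if (any(readthrough_fraction < 0) || any(readthrough_fraction > 1)) {
    stop("configuration error: read-through fractions must lie in [0, 1]")
  }
  if (decay == "geometric" && (q <= 0 || q > 1)) {
    stop("configuration error: q must lie in (0, 1]")
  }
  if (dispersion < 0 || background < 0 || any(expression_bounds <= 0)) {
    stop("configuration error: rates must be non-negative")
  }
  if (!all(genotypes %in% names(readthrough_fraction))) {
    stop("configuration error: readthrough_fraction must name every genotype")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# one RNG substream per generator stage so stages stay independently
# reproducible; offsets keep derived seeds within 32-bit range
.stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + stage
}

#' Build a toy annotated genome
#'
#' Lays out non-overlapping genes separated by uniform random gaps, with a
#' uniform random DNA sequence. Deterministic for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return list with `annotation` (a [genome_annotation()]) and `genome`
#'   (a [Biostrings::DNAStringSet]).
#' @export
build_toy_genome <- function(config) {
  set.seed(.stage_seed(config$seed, 1L))
  n_per <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  if (config$n_chroms > 0 && config$n_genes %% config$n_chroms > 0) {
    n_per[seq_len(config$n_genes %% config$n_chroms)] <-
      n_per[seq_len(config$n_genes %% config$n_chroms)] + 1
  }
  genes <- list()
  chrom_lengths <- numeric(0)
  gid <- 0
  for (ci in seq_len(config$n_chroms)) {
    ch <- sprintf("chr%d", ci)
    pos <- 0
    rows <- list()
    for (i in seq_len(n_per[ci])) {
      gap <- round(stats::runif(1, config$intergenic_gap_range[1],
                                config$intergenic_gap_range[2]))
      len <- round(stats::runif(1, config$gene_length_range[1],
                                config$gene_length_range[2]))
      strand <- switch(config$strand_mode,
                       alternate = if (i %% 2 == 1) "+" else "-",
                       random = sample(c("+", "-"), 1),
                       plus = "+")
      gid <- gid + 1
      rows[[i]] <- data.frame(gene_id = sprintf("g%03d", gid), chrom = ch,
                              strand = strand, start = pos + gap,
                              end = pos + gap + len, stringsAsFactors = FALSE)
      pos <- pos + gap + len
    }
    tail_gap <- round(stats::runif(1, config$intergenic_gap_range[1],
                                   config$intergenic_gap_range[2]))
    needed <- pos + tail_gap
    clen <- if (is.null(config$chrom_length)) needed else config$chrom_length
    if (clen < needed) {
      stop("configuration error: genes and gaps (", needed,
           " nt) do not fit chrom_length ", clen)
    }
    chrom_lengths[ch] <- clen
    genes <- c(genes, rows)
  }
  gene_df <- if (length(genes) > 0) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = numeric(), end = numeric())
  if (config$n_chroms > 0 && length(chrom_lengths) == 0) {
    chrom_lengths <- stats::setNames(
      rep(if (is.null(config$chrom_length)) 10000 else config$chrom_length,
          config$n_chroms),
      sprintf("chr%d", seq_len(config$n_chroms)))
  }
  seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- names(chrom_lengths)
  list(annotation = genome_annotation(gene_df, chrom_lengths), genome = seqs)
}

# survival term S(d) of the read-through signal at bin distance d
.survival <- function(d, config, L_true) {
  if (config$decay == "geometric") {
    (1 - config$q)^d
  } else {
    as.numeric(d < L_true / config$bin_width)
  }
}

.rcounts <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate gene-body and intergenic bin counts
#'
#' Draws negative-binomial counts under the model described in
#' [simulation_config()], per sample of a two-genotype design. The returned
#' truth table records every gene's expression rate, read-through fraction
#' and (fixed-mode) read-through length per genotype, so downstream callers
#' can be scored without hard-coded effect sizes.
#'
#' @param annotation a [genome_annotation()] (typically from
#'   [build_toy_genome()]).
#' @param config a [simulation_config()].
#' @return list of class `simulated_dataset` with elements `annotation`,
#'   `intervals`, `bins`, `gene_counts` (genes x samples integer matrix),
#'   `bin_counts` (bins x samples; rownames `interval_id:bin_index`),
#'   `sample_sheet` (sample, genotype, depth), `truth` (gene_id, genotype,
#'   e, f, L_true) and `config`.
#' @export
simulate_counts <- function(annotation, config) {
  set.seed(.stage_seed(config$seed, 2L))
  genes <- annotation$genes
  n_genes <- nrow(genes)
  intervals <- extract_intergenic(annotation)
  bins <- bin_intervals(intervals, width = config$bin_width)

  samples <- unlist(lapply(config$genotypes, function(g) {
    sprintf("%s_%d", g, seq_len(config$n_replicates))
  }))
  genotype_of <- rep(config$genotypes, each = config$n_replicates)
  depth <- if (is.null(config$depth)) rep(1, length(samples)) else
    rep_len(config$depth, length(samples))
  sample_sheet <- data.frame(sample = samples, genotype = genotype_of,
                             depth = depth, stringsAsFactors = FALSE)

  # per-gene truth
  e_g <- exp(stats::runif(n_genes, log(config$expression_bounds[1]),
                          log(config$expression_bounds[2])))
  n_affected <- round(config$affected_fraction * n_genes)
  affected <- rep(FALSE, n_genes)
  if (n_affected > 0) affected[sample.int(n_genes, n_affected)] <- TRUE
  L_gene <- rep_len(config$L_true, n_genes)
  # the reference genotype keeps its configured fraction at every gene;
  # other genotypes carry their own fraction only at affected genes and the
  # reference fraction elsewhere
  ref_f <- config$readthrough_fraction[[config$genotypes[1]]]
  truth <- do.call(rbind, lapply(config$genotypes, function(geno) {
    base_f <- config$readthrough_fraction[[geno]]
    f <- if (geno == config$genotypes[1]) rep(base_f, n_genes) else
      ifelse(affected, base_f, ref_f)
    data.frame(gene_id = genes$gene_id, genotype = geno, e = e_g, f = f,
               L_true = ifelse(config$decay == "fixed", L_gene, NA_real_),
               affected = affected, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  # gene-body counts
  n_body_bins <- ceiling((genes$end - genes$start) / config$bin_width)
  gene_counts <- matrix(0L, n_genes, length(samples),
                        dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    mu <- e_g * n_body_bins * depth[j]
    gene_counts[, j] <- .rcounts(n_genes, mu, config$dispersion)
  }

  # intergenic bin means: own read-through + background (+ antisense leak)
  f_tab <- matrix(truth$f, n_genes, length(config$genotypes),
                  dimnames = list(genes$gene_id, config$genotypes))
  gene_ix <- match(bins$gene_id, genes$gene_id)
  signal_base <- matrix(0, nrow(bins), length(config$genotypes),
                        dimnames = list(NULL, config$genotypes))
  for (geno in config$genotypes) {
    signal_base[, geno] <- e_g[gene_ix] * f_tab[gene_ix, geno] *
      .survival(bins$bin_index, config, L_gene[gene_ix])
  }
  if (config$antisense_rate > 0) {
    signal_base <- signal_base +
      config$antisense_rate *
      .antisense_signal(bins, intervals, genes, e_g, f_tab, L_gene, config)
  }

  bin_ids <- paste(bins$interval_id, bins$bin_index, sep = ":")
  bin_counts <- matrix(0L, nrow(bins), length(samples),
                       dimnames = list(bin_ids, samples))
  for (j in seq_along(samples)) {
    mu <- depth[j] * (signal_base[, genotype_of[j]] + config$background)
    bin_counts[, j] <- .rcounts(nrow(bins), mu, config$dispersion)
  }

  structure(list(annotation = annotation, intervals = intervals, bins = bins,
                 gene_counts = gene_counts, bin_counts = bin_counts,
                 sample_sheet = sample_sheet, truth = truth, config = config),
            class = "simulated_dataset")
}

# read-through of a convergent neighbour measured on this gene's strand:
# for each bin, find opposite-strand intervals overlapping its span and add
# their survival-weighted signal at the distance from the neighbour's tts
.antisense_signal <- function(bins, intervals, genes, e_g, f_tab, L_gene,
                              config) {
  out <- matrix(0, nrow(bins), ncol(f_tab), dimnames = list(NULL, colnames(f_tab)))
  for (b in seq_len(nrow(bins))) {
    opp <- intervals[intervals$chrom == bins$chrom[b] &
                       intervals$strand != bins$strand[b] &
                       intervals$start < bins$end[b] &
                       intervals$end > bins$start[b], , drop = FALSE]
    for (k in seq_len(nrow(opp))) {
      gi <- match(opp$gene_id[k], genes$gene_id)
      mid <- (bins$start[b] + bins$end[b]) / 2
      d <- floor(abs(mid - opp$five_prime_pos[k]) / config$bin_width)
      out[b, ] <- out[b, ] + e_g[gi] * f_tab[gi, ] *
        .survival(d, config, L_gene[gi])
    }
  }
  out
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d genes, %d bins, %d samples (%s)\n",
    nrow(x$gene_counts), nrow(x$bin_counts), ncol(x$bin_counts),
    paste(unique(x$sample_sheet$genotype), collapse = " vs ")))
  invisible(x)
}

#' Generate cleavage-site-centered sequences with a planted NUE hexamer
#'
#' Each sequence covers positions `-window..-1` and `+1..+window` around a
#' cleavage site (position -1 is the last transcribed base; there is no
#' position 0). Bases are i.i.d. uniform over A/C/G/T except, when
#' `planted = TRUE`, a hexamer whose last base sits at `center_offset`
#' (default -20, the canonical NUE location).
#'
#' @param n number of sequences.
#' @param nue hexamer to plant (RNA or DNA alphabet; stored as DNA).
#' @param center_offset position of the hexamer's 3' base (negative).
#' @param window half-width in nt (sequence length is `2 * window`).
#' @param planted logical; `FALSE` gives pure background.
#' @param seed integer seed.
#' @return list of class `cleavage_seq_set`: `sequences` (character, DNA),
#'   `cleavage_index` (index of position -1 within each sequence), `window`,
#'   `nue`, `center_offset`, `planted`.
#' @export
make_cleavage_sequences <- function(n, nue = "AATAAA", center_offset = -20,
                                    window = 200, planted = TRUE, seed = 1) {
  nue <- toupper(gsub("U", "T", nue))
  if (nchar(nue) != 6 || grepl("[^ACGT]", nue)) {
    stop("parameter error: nue must be a hexamer over A/C/G/T/U")
  }
  if (center_offset > -1 || center_offset - 5 < -window) {
    stop("parameter error: planted hexamer must lie within -window..-1")
  }
  set.seed(.stage_seed(seed, 3L))
  L <- 2L * window
  ci <- window  # index (1-based) of position -1
  plant_at <- ci + center_offset + 1 - 5  # 1-based start index of the hexamer
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (planted) s[plant_at:(plant_at + 5)] <- strsplit(nue, "")[[1]]
    paste(s, collapse = "")
  }, character(1))
  structure(list(sequences = seqs, cleavage_index = ci, window = window,
                 nue = nue, center_offset = center_offset, planted = planted),
            class = "cleavage_seq_set")
}

# ---- writers ---------------------------------------------------------------

#' Write simulator outputs to a directory
#'
#' Writes GFF3 annotation, FASTA genome (if supplied), gene and bin count
#' TSVs, sample sheet, truth table, and per-strand bedGraphs of one sample's
#' binned coverage.
#'
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @param genome optional `DNAStringSet` from [build_toy_genome()].
#' @param bedgraph_sample sample whose coverage is exported as bedGraph
#'   (default: first sample); `NULL` skips bedGraph output.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir, genome = NULL,
                                    bedgraph_sample = sim$sample_sheet$sample[1]) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_annotation(sim$annotation, file.path(dir, "annotation.gff3"))
  if (!is.null(genome)) {
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  }
  write_count_table(sim$gene_counts, file.path(dir, "gene_counts.tsv"), "gene_id")
  write_bin_counts(sim$bins, sim$bin_counts, file.path(dir, "bin_counts.tsv"))
  utils::write.table(sim$sample_sheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedgraph_sample)) {
    write_coverage_bedgraph(sim$bins, sim$bin_counts[, bedgraph_sample],
                            file.path(dir, "coverage_plus.bedgraph"),
                            file.path(dir, "coverage_minus.bedgraph"))
  }
  invisible(dir)
}

#' Write a counts matrix as TSV with an id column
#' @param counts matrix with rownames.
#' @param path output file.
#' @param id_col name of the first column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_col = "id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write bin counts as TSV (interval_id, bin_index, one column per sample)
#' @param bins bin table from [bin_intervals()].
#' @param bin_counts bins x samples matrix, rows aligned with `bins`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(bins, bin_counts, path) {
  df <- data.frame(interval_id = bins$interval_id, bin_index = bins$bin_index,
                   bin_counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one sample's binned coverage as per-strand bedGraph
#'
#' The bedGraph value is the per-base read density (bin count / bin width) so
#' that summing values over a bin's span recovers the bin count. Coordinates
#' are 0-based half-open per the UCSC convention.
#'
#' @param bins bin table from [bin_intervals()].
#' @param counts numeric vector of counts aligned with `bins` rows.
#' @param path_plus,path_minus output files for the two strands.
#' @return invisibly, the two paths.
#' @export
write_coverage_bedgraph <- function(bins, counts, path_plus, path_minus) {
  for (st in c("+", "-")) {
    sel <- bins$strand == st & counts > 0
    b <- bins[sel, , drop = FALSE]
    v <- counts[sel] / b$width
    ord <- order(b$chrom, b$start)
    lines <- sprintf("%s\t%d\t%d\t%s", b$chrom[ord], as.integer(b$start[ord]),
                     as.integer(b$end[ord]), format(v[ord], trim = TRUE))
    writeLines(lines, if (st == "+") path_plus else path_minus)
  }
  invisible(c(path_plus, path_minus))
}
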