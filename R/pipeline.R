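# Orchestration and file-format plumbing: one reproducible run from
# annotation + counts (or a seeded simulation) through extension calling,
# differential testing and, when a genome is available, cleavage-site
# composition profiling. bedGraph is 0-based half-open (UCSC); GFF3 is
# 1-based inclusive; everything internal is 0-based half-open.

#' Pipeline configuration
#'
#' Every field may be an in-memory object or a file path; paths are read
#' with the package's parsers. Exactly one of `simulate` (a
#' [simulation_config()]) or the input tables must be supplied.
#'
#' @param annotation [genome_annotation()] or GFF3 path.
#' @param gene_counts genes x samples matrix or TSV path.
#' @param bin_counts bins x samples matrix (rownames `interval_id:bin_index`)
#'   or TSV path (`interval_id`, `bin_index`, one column per sample).
#' @param sample_sheet data.frame or TSV path with `sample`, `genotype`.
#' @param genome optional `DNAStringSet` or FASTA path (enables the
#'   composition-profile stage).
#' @param simulate optional [simulation_config()]; when set, inputs are
#'   generated in memory and the other input fields are ignored.
#' @param contrast `c(test, reference)` genotype labels.
#' @param caller a [caller_config()].
#' @param diff a [diff_config()].
#' @param signal_window composition-profile half-width (nt).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (simulation seeds come
#'   from `simulate$seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation = NULL, gene_counts = NULL,
                            bin_counts = NULL, sample_sheet = NULL,
                            genome = NULL, simulate = NULL,
                            contrast = c("mutant", "control"),
                            caller = caller_config(), diff = diff_config(),
                            signal_window = 200, out_dir = tempfile("utrx_"),
                            seed = 1) {
  if (is.null(simulate)) {
    for (nm in c("annotation", "gene_counts", "bin_counts", "sample_sheet")) {
      v <- get(nm)
      if (is.null(v)) {
        stop("validation error: missing input '", nm,
             "' (and no simulation configured)")
      }
      if (is.character(v) && length(v) == 1 && !file.exists(v)) {
        stop("validation error: input file for '", nm, "' not found: ", v)
      }
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a sample sheet TSV
#' @param path TSV with at least `sample` and `genotype` columns.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("sample", "genotype"), names(df))
  if (length(missing) > 0) {
    stop("validation error: sample sheet ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) {
    stop("validation error: duplicate sample ids in ", path)
  }
  df
}

#' Read a counts TSV into a matrix (first column = row ids)
#' @param path TSV file.
#' @return integer matrix with rownames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a bin-count TSV and validate it against a bin inventory
#'
#' @param path TSV with `interval_id`, `bin_index`, then one column per
#'   sample.
#' @param bins bin table from [bin_intervals()]; when supplied, the file must
#'   cover exactly this inventory, and rows are returned in its order.
#' @return bins x samples matrix with rownames `interval_id:bin_index`.
#' @export
read_bin_counts <- function(path, bins = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("interval_id", "bin_index"), names(df))
  if (length(missing) > 0) {
    stop("format error: ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ids <- paste(df$interval_id, df$bin_index, sep = ":")
  m <- as.matrix(df[, setdiff(names(df), c("interval_id", "bin_index")),
                    drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (!is.null(bins)) {
    want <- paste(bins$interval_id, bins$bin_index, sep = ":")
    absent <- setdiff(want, ids)
    if (length(absent) > 0) {
      stop("format error: ", path, " missing ", length(absent),
           " bin row(s), first: ", absent[1])
    }
    m <- m[want, , drop = FALSE]
  }
  m
}

#' Bin strand-specific bedGraph coverage onto an interval's bins
#'
#' Per-base bedGraph values are summed into the bins (a record's value is
#' its per-base read density, so a record contributes
#' `value * overlap_width` to each bin it overlaps). Records on each strand
#' file are matched against bins of that strand only.
#'
#' @param path_plus,path_minus bedGraph files for `+` and `-` strand
#'   coverage (either may be `NULL` / missing for an empty strand).
#' @param bins bin table from [bin_intervals()].
#' @return numeric vector of binned counts aligned with `bins` rows.
#' @export
read_coverage <- function(path_plus, path_minus, bins) {
  out <- numeric(nrow(bins))
  for (st in c("+", "-")) {
    path <- if (st == "+") path_plus else path_minus
    if (is.null(path) || !file.exists(path)) next
    gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                   error = function(e) {
                     stop("format error in ", path, ": ",
                          conditionMessage(e))
                   })
    if (length(gr) == 0) next
    red <- GenomicRanges::reduce(gr)
    if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(gr))) {
      stop("format error: overlapping bedGraph records in ", path)
    }
    sel <- which(bins$strand == st)
    if (length(sel) == 0) next
    bgr <- GenomicRanges::GRanges(bins$chrom[sel],
                                  IRanges::IRanges(bins$start[sel] + 1,
                                                   bins$end[sel]))
    ov <- GenomicRanges::findOverlaps(bgr, gr)
    if (length(ov) > 0) {
      inter_w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(bgr)[S4Vectors::queryHits(ov)],
        GenomicRanges::ranges(gr)[S4Vectors::subjectHits(ov)]))
      contrib <- inter_w * gr$score[S4Vectors::subjectHits(ov)]
      agg <- tapply(contrib, S4Vectors::queryHits(ov), sum)
      out[sel[as.integer(names(agg))]] <- as.numeric(agg)
    }
  }
  out
}

.checksum <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    NA_character_
  }
}

#' Run the full read-through analysis pipeline
#'
#' Stage order: intergenic extraction, binning, size-factor normalization,
#' per-genotype extension assembly, length filter, union-region
#' quantification, differential testing, and (when a genome is available)
#' cleavage-site composition profiling. Writes BED/TSV outputs and a JSON
#' run manifest to `config$out_dir`; any stage failure aborts with the
#' failing stage named.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `intervals`, `bins`,
#'   `size_factors`, `calls`, `regions`, `extension_counts`, `differential`,
#'   `profile` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  checksums <- list(annotation = .checksum(config$annotation),
                    gene_counts = .checksum(config$gene_counts),
                    bin_counts = .checksum(config$bin_counts),
                    sample_sheet = .checksum(config$sample_sheet))

  genome <- NULL
  if (!is.null(config$simulate)) {
    sim_in <- stage("simulate", {
      toy <- build_toy_genome(config$simulate)
      genome <- toy$genome
      list(sim = simulate_counts(toy$annotation, config$simulate),
           genome = toy$genome)
    })
    genome <- sim_in$genome
    sim <- sim_in$sim
    annotation <- sim$annotation
    gene_counts <- sim$gene_counts
    bin_counts <- sim$bin_counts
    sample_sheet <- sim$sample_sheet
  } else {
    annotation <- stage("read_annotation", {
      if (is.character(config$annotation)) {
        read_gene_annotation(config$annotation)
      } else config$annotation
    })
    gene_counts <- stage("read_gene_counts", {
      if (is.character(config$gene_counts)) {
        read_count_table(config$gene_counts)
      } else config$gene_counts
    })
    sample_sheet <- stage("read_sample_sheet", {
      if (is.character(config$sample_sheet)) {
        read_sample_sheet(config$sample_sheet)
      } else config$sample_sheet
    })
    if (!is.null(config$genome)) {
      genome <- stage("read_genome", {
        if (is.character(config$genome)) {
          Biostrings::readDNAStringSet(config$genome)
        } else config$genome
      })
    }
  }
  if (!all(config$contrast %in% sample_sheet$genotype)) {
    stop("validation error: contrast genotype(s) absent from sample sheet: ",
         paste(setdiff(config$contrast, sample_sheet$genotype),
               collapse = ", "))
  }

  intervals <- stage("extract_intergenic", extract_intergenic(annotation))
  bins <- stage("bin_intervals",
                bin_intervals(intervals, config$caller$bin_width))
  if (is.null(config$simulate)) {
    bin_counts <- stage("read_bin_counts", {
      if (is.character(config$bin_counts)) {
        read_bin_counts(config$bin_counts, bins)
      } else config$bin_counts
    })
  }

  called <- stage("call_extensions",
                  call_extensions(intervals, bins, bin_counts, gene_counts,
                                  sample_sheet, config$caller))

  differential <- NULL
  if (!is.null(called$extension_counts) &&
      nrow(called$extension_counts) > 0) {
    differential <- stage("differential_extension",
      differential_extension(called$extension_counts, gene_counts,
                             called$size_factors, sample_sheet,
                             config$contrast, config$diff))
  }

  profile <- NULL
  if (!is.null(genome)) {
    profile <- stage("composition_profile", {
      g <- annotation$genes
      sites <- data.frame(chrom = g$chrom,
                          pos = ifelse(g$strand == "+", g$tts - 1, g$tts),
                          strand = g$strand, stringsAsFactors = FALSE)
      composition_profile_genome(genome, sites, W = config$signal_window)
    })
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage("write_outputs", {
    write_bed6(intervals, file.path(config$out_dir, "intervals.bed"))
    if (!is.null(called$calls) && nrow(called$calls) > 0) {
      for (g in unique(called$calls$genotype)) {
        write_bed6(called$calls[called$calls$genotype == g, ],
                   file.path(config$out_dir,
                             sprintf("extensions_%s.bed", g)))
      }
      write_count_table(called$extension_counts,
                        file.path(config$out_dir, "extension_counts.tsv"),
                        "gene_id")
    }
    if (!is.null(differential)) {
      utils::write.table(differential,
                         file.path(config$out_dir, "differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(profile)) {
      write_profile(profile, file.path(config$out_dir, "profile.tsv"))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("utrx")),
    seed = config$seed,
    contrast = config$contrast,
    thresholds = list(bin_width = config$caller$bin_width,
                      stop_threshold = config$caller$stop_threshold,
                      min_length = config$caller$min_length,
                      statistic = config$caller$statistic,
                      alpha_adj = config$diff$alpha_adj,
                      fc_min = config$diff$fc_min,
                      pseudocount = config$diff$pseudocount),
    input_checksums = checksums,
    row_counts = list(genes = nrow(annotation$genes),
                      intervals = nrow(intervals), bins = nrow(bins),
                      calls = if (is.null(called$calls)) 0 else
                        nrow(called$calls),
                      differential = if (is.null(differential)) 0 else
                        nrow(differential)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  # atomic manifest write: temp file then rename
  tmp <- file.path(config$out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(config$out_dir, "manifest.json"))

  structure(list(intervals = intervals, bins = bins,
                 size_factors = called$size_factors, calls = called$calls,
                 regions = called$regions,
                 extension_counts = called$extension_counts,
                 differential = differential, profile = profile,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d intervals, %d calls, %d differential rows\n",
              x$manifest$row_counts$intervals, x$manifest$row_counts$calls,
              x$manifest$row_counts$differential))
  invisible(x)
}
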