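# Independent oracles and tiny fixture builders shared across tests.

# brute-force prefix scan: number of leading values >= tau
oracle_prefix_len <- function(v, tau) {
  k <- 0L
  for (x in v) {
    if (x >= tau) k <- k + 1L else break
  }
  k
}

# brute-force best-NUE search: all offsets, minimal Hamming distance,
# ties to the most 3' occurrence
oracle_find_nue <- function(sequence, cleavage_index, canonical = "AAUAAA",
                            search_window = c(-35, -10)) {
  s <- strsplit(toupper(chartr("T", "U", sequence)), "")[[1]]
  canon <- strsplit(canonical, "")[[1]]
  best <- NULL
  for (end_off in seq(min(search_window) + 5, max(search_window))) {
    idx_end <- cleavage_index + end_off + 1
    idx_start <- idx_end - 5
    if (idx_start < 1 || idx_end > length(s)) next
    hex <- s[idx_start:idx_end]
    d <- sum(hex != canon)
    if (is.null(best) || d < best$distance ||
        (d == best$distance && end_off > best$offset_end)) {
      best <- list(hexamer = paste(hex, collapse = ""), distance = d,
                   offset_end = end_off)
    }
  }
  best
}

# single-gene annotation on one chromosome
tiny_annotation <- function(genes, chrom_len = 1000) {
  genome_annotation(genes, c(chr1 = chrom_len))
}

# build an interval table + aligned bins + a one-sample normalized matrix
# directly from a vector of per-bin values (bin 0 first)
fabricate_bins <- function(values, width = 10, strand = "+",
                           five_prime = 1000, interval_len = NULL,
                           samples = "s1") {
  if (is.null(interval_len)) interval_len <- length(values) * width
  iv <- if (strand == "+") {
    data.frame(interval_id = "gA.ig", gene_id = "gA", chrom = "chr1",
               strand = strand, five_prime_pos = five_prime,
               three_prime_pos = five_prime + interval_len,
               start = five_prime, end = five_prime + interval_len,
               length = interval_len, stringsAsFactors = FALSE)
  } else {
    data.frame(interval_id = "gA.ig", gene_id = "gA", chrom = "chr1",
               strand = strand, five_prime_pos = five_prime,
               three_prime_pos = five_prime - interval_len,
               start = five_prime - interval_len, end = five_prime,
               length = interval_len, stringsAsFactors = FALSE)
  }
  bins <- bin_intervals(iv, width = width)
  stopifnot(nrow(bins) == length(values))
  m <- matrix(rep(values, length(samples)), ncol = length(samples),
              dimnames = list(paste(bins$interval_id, bins$bin_index,
                                    sep = ":"), samples))
  list(intervals = iv, bins = bins, norm = m)
}

# simulated dataset under the default two-genotype study conditions,
# small enough for test-time use
quick_sim <- function(seed = 11, n_genes = 20, ...) {
  cfg <- simulation_config(n_genes = n_genes, seed = seed, ...)
  toy <- build_toy_genome(cfg)
  list(cfg = cfg, toy = toy, sim = simulate_counts(toy$annotation, cfg))
}
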