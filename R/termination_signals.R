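# Sequence analysis around cleavage sites: per-position base-composition
# profiles, best-match NUE hexamer search upstream of the cleavage site, and
# a chi-square comparison of NUE base frequencies between gene sets.
# Position convention: -1 is the last transcribed base before the polyA
# tail; there is no position 0.

.profile_positions <- function(W) c(-W:-1, 1:W)

#' Base-composition profile around cleavage sites
#'
#' Computes per-position proportions of A, C, G, U in a window of `W` nt on
#' each side of each cleavage site. Input DNA is reported in the RNA
#' alphabet (T as U). Sites too close to a sequence end contribute only
#' their existing positions.
#'
#' @param x a `cleavage_seq_set` (from [make_cleavage_sequences()]), or a
#'   character vector of sequences with `cleavage_index` supplied.
#' @param cleavage_index 1-based index of position -1 within each sequence
#'   (scalar or vector; ignored when `x` is a `cleavage_seq_set`).
#' @param W window half-width in nt (default 200).
#' @return data.frame with columns `position` (-W..-1, 1..W), `pA`, `pC`,
#'   `pG`, `pU` and `n` (sequences contributing at that position).
#' @export
composition_profile <- function(x, cleavage_index = NULL, W = 200) {
  if (W < 1) stop("parameter error: W must be >= 1")
  if (inherits(x, "cleavage_seq_set")) {
    cleavage_index <- x$cleavage_index
    x <- x$sequences
  }
  if (is.null(cleavage_index)) {
    stop("parameter error: cleavage_index required for plain sequences")
  }
  ci <- rep_len(cleavage_index, length(x))
  positions <- .profile_positions(W)
  counts <- matrix(0L, length(positions), 4,
                   dimnames = list(NULL, c("A", "C", "G", "U")))
  n <- integer(length(positions))
  for (i in seq_along(x)) {
    chars <- strsplit(toupper(chartr("T", "U", x[i])), "")[[1]]
    idx <- ifelse(positions < 0, ci[i] + positions + 1, ci[i] + positions)
    ok <- idx >= 1 & idx <= length(chars)
    b <- chars[idx[ok]]
    valid <- b %in% c("A", "C", "G", "U")
    rows <- which(ok)[valid]
    for (base in c("A", "C", "G", "U")) {
      hit <- rows[b[valid] == base]
      counts[hit, base] <- counts[hit, base] + 1L
    }
    n[rows] <- n[rows] + 1L
  }
  prop <- counts / ifelse(n > 0, n, 1)
  data.frame(position = positions, pA = prop[, "A"], pC = prop[, "C"],
             pG = prop[, "G"], pU = prop[, "U"], n = n)
}

#' Base-composition profile from a genome and cleavage-site coordinates
#'
#' Extracts strand-aware windows around each site (minus-strand windows are
#' reverse-complemented before profiling) and delegates to
#' [composition_profile()]. Sites whose window would leave the chromosome
#' are trimmed to the available bases; sites outside the sequence are
#' skipped with a warning.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param sites data.frame with `chrom`, `pos` (0-based coordinate of the
#'   last transcribed base, position -1) and `strand`.
#' @param W window half-width in nt.
#' @return as [composition_profile()].
#' @export
composition_profile_genome <- function(genome, sites, W = 200) {
  seqs <- character(0)
  cis <- integer(0)
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    if (!ch %in% names(genome)) {
      warning("site ", i, " on unknown chromosome ", ch, "; skipped")
      next
    }
    L <- length(genome[[ch]])
    p <- sites$pos[i]  # 0-based
    if (p < 0 || p >= L) {
      warning("site ", i, " outside sequence bounds; skipped")
      next
    }
    if (sites$strand[i] == "+") {
      from <- max(1, p + 1 - W + 1)        # 1-based
      to <- min(L, p + 1 + W)
      s <- as.character(Biostrings::subseq(genome[[ch]], from, to))
      ci <- p + 1 - from + 1
    } else {
      from <- max(1, p + 1 - W)
      to <- min(L, p + 1 + W - 1)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[ch]], from, to)))
      ci <- to - (p + 1) + 1
    }
    seqs <- c(seqs, s)
    cis <- c(cis, ci)
  }
  composition_profile(seqs, cleavage_index = cis, W = W)
}

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Find the best-matching NUE hexamer upstream of a cleavage site
#'
#' Scans all hexamers lying fully inside the search window (offsets relative
#' to the cleavage site; default -35..-10) and returns the one minimizing
#' Hamming distance to the canonical polyadenylation signal; ties are broken
#' by the most 3' occurrence (closest to the cleavage site).
#'
#' @param sequence one sequence (DNA or RNA alphabet).
#' @param cleavage_index 1-based index of position -1 in `sequence`.
#' @param canonical reference hexamer (default AAUAAA).
#' @param search_window length-2 integer, most 5' and most 3' offsets of the
#'   window (negative, inclusive).
#' @return list: `hexamer` (RNA alphabet), `distance`, `offset_start`,
#'   `offset_end` (positions of its first and last base).
#' @export
find_nue <- function(sequence, cleavage_index, canonical = "AAUAAA",
                     search_window = c(-35, -10)) {
  canonical <- toupper(chartr("T", "U", canonical))
  if (nchar(canonical) != 6) stop("parameter error: canonical must be a hexamer")
  win_lo <- min(search_window); win_hi <- max(search_window)
  if (win_hi - win_lo + 1 < 6) {
    stop("parameter error: search window shorter than 6 nt")
  }
  s <- toupper(chartr("T", "U", sequence))
  best <- NULL
  # end offsets from most 3' to most 5'; first strict improvement wins, so
  # ties resolve to the most 3' occurrence
  for (end_off in seq(win_hi, win_lo + 5)) {
    start_off <- end_off - 5
    idx_end <- cleavage_index + end_off + 1
    idx_start <- idx_end - 5
    if (idx_start < 1 || idx_end > nchar(s)) next
    hex <- substr(s, idx_start, idx_end)
    d <- .hamming(hex, canonical)
    if (is.null(best) || d < best$distance) {
      best <- list(hexamer = hex, distance = d, offset_start = start_off,
                   offset_end = end_off)
    }
  }
  if (is.null(best)) stop("parameter error: window outside sequence")
  best
}

#' Per-set NUE table: best hexamer per gene and aggregated base counts
#'
#' @param x a `cleavage_seq_set` or character vector of sequences.
#' @param cleavage_index as in [composition_profile()].
#' @param canonical,search_window as in [find_nue()].
#' @return list of class `nue_table`: `per_gene` (data.frame hexamer,
#'   distance, offsets), `base_counts` (4 x 6 matrix, bases x hexamer
#'   positions), `base_totals` (length-4 vector aggregated over the six
#'   positions), `canonical`.
#' @export
nue_table <- function(x, cleavage_index = NULL, canonical = "AAUAAA",
                      search_window = c(-35, -10)) {
  if (inherits(x, "cleavage_seq_set")) {
    cleavage_index <- x$cleavage_index
    x <- x$sequences
  }
  ci <- rep_len(cleavage_index, length(x))
  hits <- lapply(seq_along(x), function(i) {
    find_nue(x[i], ci[i], canonical, search_window)
  })
  per_gene <- data.frame(
    hexamer = vapply(hits, `[[`, character(1), "hexamer"),
    distance = vapply(hits, `[[`, numeric(1), "distance"),
    offset_start = vapply(hits, `[[`, numeric(1), "offset_start"),
    offset_end = vapply(hits, `[[`, numeric(1), "offset_end"),
    stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "U")
  base_counts <- matrix(0L, 4, 6, dimnames = list(bases, paste0("p", 1:6)))
  for (h in per_gene$hexamer) {
    ch <- strsplit(h, "")[[1]]
    for (k in 1:6) base_counts[ch[k], k] <- base_counts[ch[k], k] + 1L
  }
  structure(list(per_gene = per_gene, base_counts = base_counts,
                 base_totals = rowSums(base_counts),
                 canonical = toupper(chartr("T", "U", canonical))),
            class = "nue_table")
}

#' Chi-square comparison of NUE base frequencies between two gene sets
#'
#' Aggregates base counts over the six positions of each gene's best NUE
#' hexamer into a 4 x 2 (base x set) contingency table and applies a Pearson
#' chi-square test with 3 degrees of freedom. `mode = "per_position"`
#' instead stacks the per-position base counts into a 24 x 2 table.
#'
#' @param table_a,table_b `nue_table` objects for the two gene sets.
#' @param mode `"pooled"` (default) or `"per_position"`.
#' @return list: `statistic`, `df`, `p_value`, `table` (the contingency
#'   table) and `low_expected` (TRUE when any expected cell < 1, in which
#'   case an exact test is advisable and a warning is emitted).
#' @export
nue_chi_square <- function(table_a, table_b,
                           mode = c("pooled", "per_position")) {
  mode <- match.arg(mode)
  if (sum(table_a$base_totals) == 0 || sum(table_b$base_totals) == 0) {
    stop("parameter error: both gene sets must be non-empty")
  }
  tab <- if (mode == "pooled") {
    cbind(setA = table_a$base_totals, setB = table_b$base_totals)
  } else {
    cbind(setA = as.vector(table_a$base_counts),
          setB = as.vector(table_b$base_counts))
  }
  keep <- rowSums(tab) > 0
  tab <- tab[keep, , drop = FALSE]
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  low <- any(expected < 1)
  if (low) {
    warning("statistics warning: expected cell < 1; ",
            "consider an exact test")
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab, low_expected = low)
}

#' Write a composition profile as TSV
#' @param profile data.frame from [composition_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
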