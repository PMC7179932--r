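test_that("composition profiles report per-position proportions in RNA alphabet", {
  # constant input: all A everywhere
  seqs <- rep(strrep("A", 60), 5)
  pr <- composition_profile(seqs, cleavage_index = 30, W = 30)
  expect_true(all(pr$pA == 1))
  expect_true(all(pr$n == 5))
  # positions span -W..-1 and +1..+W with no position 0
  expect_equal(pr$position, c(-30:-1, 1:30))
  # T is reported as U
  pr2 <- composition_profile(rep(strrep("T", 20), 3), cleavage_index = 10,
                             W = 10)
  expect_true(all(pr2$pU == 1))
  # proportions sum to 1 wherever n > 0
  cs <- make_cleavage_sequences(20, seed = 41, window = 50)
  pr3 <- composition_profile(cs, W = 50)
  sums <- pr3$pA + pr3$pC + pr3$pG + pr3$pU
  expect_true(all(abs(sums[pr3$n > 0] - 1) < 1e-12))
})

test_that("planted hexamers force the expected profile positions", {
  cs <- make_cleavage_sequences(100, nue = "AATAAA", center_offset = -20,
                                seed = 43)
  pr <- composition_profile(cs)
  at <- function(p, col) pr[pr$position == p, col]
  for (p in c(-25, -24, -22, -21, -20)) expect_equal(at(p, "pA"), 1)
  expect_equal(at(-23, "pU"), 1)
  # planted-signal recovery: A-content over the NUE window beats background
  a_nue <- mean(pr$pA[pr$position %in% -25:-20])
  a_bg <- mean(pr$pA[pr$position %in% 50:200])
  expect_gt(a_nue, a_bg)
})

test_that("sites near sequence ends contribute only existing positions", {
  pr <- composition_profile("ACGT", cleavage_index = 2, W = 10)
  expect_equal(sum(pr$n > 0), 4)
  expect_equal(pr$n[pr$position == -1], 1)
  expect_equal(pr$n[pr$position == -5], 0)
})

test_that("minus-strand genome profiling equals reverse-complement profiling", {
  set.seed(45)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  W <- 50
  # a minus-strand site at 0-based coordinate p: last transcribed base = p
  p <- 199
  pr_minus <- composition_profile_genome(
    genome, data.frame(chrom = "chr1", pos = p, strand = "-"), W = W)
  rc <- as.character(Biostrings::reverseComplement(genome[[1]]))
  # in the reverse-complemented sequence, coordinate p maps to 400 - 1 - p
  pr_plus <- composition_profile_genome(
    Biostrings::DNAStringSet(c(chr1 = rc)),
    data.frame(chrom = "chr1", pos = 400 - 1 - p, strand = "+"), W = W)
  expect_equal(pr_minus, pr_plus)
  expect_warning(composition_profile_genome(
    genome, data.frame(chrom = "chr1", pos = 500, strand = "+"), W = W),
    "skipped")
})

test_that("NUE search minimizes Hamming distance with 3'-most tie-break", {
  # exact canonical match
  s <- paste0(strrep("C", 165), "AATAAA", strrep("C", 29), "GGGG")
  found <- find_nue(s, cleavage_index = 200)
  expect_equal(found$hexamer, "AAUAAA")
  expect_equal(found$distance, 0)
  expect_equal(found$offset_end, -30)
  # one-off variant AAUGAA when nothing better exists
  s2 <- paste0(strrep("C", 165), "AATGAA", strrep("C", 29), "GGGG")
  found2 <- find_nue(s2, cleavage_index = 200)
  expect_equal(found2$hexamer, "AAUGAA")
  expect_equal(found2$distance, 1)
  # two equally good hits (ends at -30 and -20): the 3'-most wins
  s3 <- paste0(strrep("C", 165), "AATAAA", "CCCC", "AATAAA", strrep("C", 19))
  found3 <- find_nue(s3, cleavage_index = 200)
  expect_equal(found3$offset_end, -20)
  expect_error(find_nue(s, 200, search_window = c(-14, -10)),
               "parameter error")
})

test_that("NUE search agrees with the brute-force all-offsets oracle", {
  set.seed(47)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    got <- find_nue(s, cleavage_index = 100)
    want <- oracle_find_nue(s, cleavage_index = 100)
    expect_equal(got$hexamer, want$hexamer)
    expect_equal(got$distance, want$distance)
    expect_equal(got$offset_end, want$offset_end)
  }
})

test_that("NUE tables aggregate per-gene hexamer base counts", {
  cs <- make_cleavage_sequences(40, nue = "AATAAA", center_offset = -20,
                                seed = 49)
  nt <- nue_table(cs)
  expect_equal(nrow(nt$per_gene), 40)
  expect_true(all(nt$per_gene$distance == 0))
  expect_true(all(nt$per_gene$offset_end >= -35 &
                    nt$per_gene$offset_end <= -10))
  # counts per hexamer position sum to the set size
  expect_true(all(colSums(nt$base_counts) == 40))
  expect_equal(unname(nt$base_totals["A"]), 200)
  expect_equal(unname(nt$base_totals["U"]), 40)
})

test_that("chi-square comparison behaves on known tables", {
  # identical sets: statistic 0, p = 1
  cs <- make_cleavage_sequences(30, planted = FALSE, seed = 51, window = 50)
  nt <- nue_table(cs)
  res <- nue_chi_square(nt, nt)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 3)
  # hand-built 4 x 2 table vs the textbook sum((O - E)^2 / E)
  ta <- list(base_totals = c(A = 90, C = 2, G = 3, U = 5),
             base_counts = NULL)
  tb <- list(base_totals = c(A = 60, C = 12, G = 13, U = 15),
             base_counts = NULL)
  class(ta) <- class(tb) <- "nue_table"
  res2 <- nue_chi_square(ta, tb)
  tab <- cbind(ta$base_totals, tb$base_totals)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$statistic, sum((tab - E)^2 / E))
  expect_equal(res2$p_value,
               pchisq(res2$statistic, 3, lower.tail = FALSE))
  # permuting set labels leaves the statistic unchanged
  res3 <- nue_chi_square(tb, ta)
  expect_equal(res3$statistic, res2$statistic)
  # near-empty cells trigger the exact-test advisory
  tc <- list(base_totals = c(A = 3, C = 0, G = 0, U = 1), base_counts = NULL)
  td <- list(base_totals = c(A = 1, C = 0, G = 0, U = 0), base_counts = NULL)
  class(tc) <- class(td) <- "nue_table"
  expect_warning(r <- nue_chi_square(tc, td), "exact test")
  expect_true(r$low_expected)
})

test_that("chi-square p-values are uniform under a multinomial null", {
  # calibration of the hand-computed Pearson statistic: two independent
  # same-probability base-count tables per replicate
  set.seed(55)
  pr <- c(0.4, 0.2, 0.2, 0.2)
  draw <- function() {
    structure(list(base_totals = stats::setNames(
      as.numeric(stats::rmultinom(1, 150, pr)), c("A", "C", "G", "U"))),
      class = "nue_table")
  }
  ps <- vapply(1:200, function(i) {
    suppressWarnings(nue_chi_square(draw(), draw())$p_value)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.05)
})

test_that("gene-subset comparisons of one population are not anti-conservative", {
  # aggregating the six bases of each gene's best hexamer is a cluster
  # sample: within-gene composition is nearly constant, so resampling genes
  # gives a conservative (never inflated) chi-square
  cs <- make_cleavage_sequences(60, planted = FALSE, seed = 53, window = 50)
  nt <- nue_table(cs)
  per_gene_counts <- t(vapply(nt$per_gene$hexamer, function(h) {
    ch <- strsplit(h, "")[[1]]
    vapply(c("A", "C", "G", "U"), function(b) sum(ch == b), numeric(1))
  }, numeric(4)))
  set.seed(55)
  ps <- vapply(1:200, function(i) {
    pick <- sample(60, 30)
    ta <- structure(list(base_totals = colSums(per_gene_counts[pick, ])),
                    class = "nue_table")
    tb <- structure(list(base_totals = colSums(per_gene_counts[-pick, ])),
                    class = "nue_table")
    suppressWarnings(nue_chi_square(ta, tb)$p_value)
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.05)
})
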