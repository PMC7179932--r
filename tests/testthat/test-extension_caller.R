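test_that("median-of-ratios size factors behave on known inputs", {
  # identical samples: both factors 1
  m <- matrix(c(10, 30, 50, 10, 30, 50), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # hand computation: counts [[10,20],[30,60],[50,100]] -> s = (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # permutation invariance over gene rows
  expect_equal(size_factors(m2[c(3, 1, 2), ]), size_factors(m2))
  # no gene nonzero everywhere
  m3 <- matrix(c(0, 5, 5, 0), ncol = 2)
  expect_error(size_factors(m3), "normalization error")
})

test_that("size factors agree with the reference median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  m <- matrix(rnbinom(300, mu = 50 * rep(runif(6, 0.5, 2), each = 50),
                      size = 10), ncol = 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same up to the geometric-mean-1 rescaling convention
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("bin normalization divides by the sample's size factor", {
  m <- matrix(c(10, 4, 10, 4), ncol = 2,
              dimnames = list(c("b1", "b2"), c("a", "b")))
  expect_equal(normalize_bins(m, c(a = 1, b = 1)), m)
  expect_equal(normalize_bins(m, c(a = 2, b = 2))[1, 1], 5)
  # scale invariance: doubling counts and size factors changes nothing
  s <- c(a = 0.8, b = 1.3)
  expect_equal(normalize_bins(2 * m, 2 * s), normalize_bins(m, s))
  expect_error(normalize_bins(m, c(a = 1)), "key error")
})

test_that("assembly walks the maximal contiguous prefix above threshold", {
  cfg <- caller_config()
  # a bin below threshold stops assembly even if a later bin passes again
  fb <- fabricate_bins(c(5.0, 3.2, 1.4, 0.8, 2.0))
  calls <- assemble_extensions(fb$intervals, fb$bins, fb$norm, "s1", cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$length, 30)
  expect_equal(calls$n_bins, 3)
  expect_false(calls$truncated)
  expect_equal(calls$next_bin_stat, 0.8)
  # bin 0 below threshold: no call at all
  fb2 <- fabricate_bins(c(0.4, 9.9, 9.9))
  expect_equal(nrow(assemble_extensions(fb2$intervals, fb2$bins, fb2$norm,
                                        "s1", cfg)), 0)
  # exhausting the interval sets the truncated flag
  fb3 <- fabricate_bins(c(2, 2, 2))
  c3 <- assemble_extensions(fb3$intervals, fb3$bins, fb3$norm, "s1", cfg)
  expect_true(c3$truncated)
  expect_true(is.na(c3$next_bin_stat))
  expect_error(assemble_extensions(fb$intervals, fb$bins, fb$norm,
                                   character(0), cfg), "parameter error")
})

test_that("assembly equals the brute-force prefix oracle on random bins", {
  cfg <- caller_config()
  set.seed(13)
  for (rep in 1:50) {
    v <- round(runif(sample(1:30, 1), 0, 3), 2)
    fb <- fabricate_bins(v)
    calls <- assemble_extensions(fb$intervals, fb$bins, fb$norm, "s1", cfg)
    k <- oracle_prefix_len(v, cfg$stop_threshold)
    if (k == 0) {
      expect_equal(nrow(calls), 0)
    } else {
      expect_equal(calls$length, 10 * k)
    }
  }
})

test_that("raising the stop threshold never lengthens a call", {
  set.seed(14)
  for (rep in 1:20) {
    v <- runif(20, 0, 3)
    fb <- fabricate_bins(v)
    lens <- vapply(c(0.5, 1, 1.5, 2), function(tau) {
      cfg <- caller_config(stop_threshold = tau)
      calls <- assemble_extensions(fb$intervals, fb$bins, fb$norm, "s1", cfg)
      if (nrow(calls) == 0) 0 else calls$length
    }, numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("a larger read-through fraction never shortens the expected call", {
  mean_len <- vapply(c(0.2, 0.9), function(f) {
    lens <- vapply(1:10, function(seed) {
      cfg <- simulation_config(
        n_genes = 10, seed = seed, decay = "fixed", L_true = 400,
        background = 0.05, expression_bounds = c(20, 40),
        affected_fraction = 1,
        readthrough_fraction = c(control = 0, mutant = f))
      toy <- build_toy_genome(cfg)
      sim <- simulate_counts(toy$annotation, cfg)
      res <- call_extensions(sim$intervals, sim$bins, sim$bin_counts,
                             sim$gene_counts, sim$sample_sheet,
                             caller_config(min_length = 0))
      if (is.null(res$calls) || nrow(res$calls) == 0) 0 else
        mean(res$calls$length[res$calls$genotype == "mutant"])
    }, numeric(1))
    mean(lens)
  }, numeric(1))
  expect_gte(mean_len[2], mean_len[1])
})

test_that("the length filter is strictly greater-than", {
  calls <- data.frame(gene_id = paste0("g", 1:4),
                      length = c(50, 200, 250, 600))
  kept <- filter_extensions(calls, caller_config())
  expect_equal(kept$length, c(250, 600))
  expect_equal(nrow(filter_extensions(calls, caller_config(min_length = 0))),
               4)
})

test_that("extension quantification sums raw bin counts per sample", {
  fb <- fabricate_bins(c(2, 2, 2, 0.5))
  raw <- matrix(c(4, 5, 6, 1, 0, 0, 0, 0), ncol = 2,
                dimnames = list(rownames(fb$norm), c("s1", "s2")))
  calls <- assemble_extensions(fb$intervals, fb$bins, fb$norm, "s1",
                               caller_config())
  q <- quantify_extensions(calls, fb$bins, raw)
  expect_equal(unname(q["gA", ]), c(15, 0))
  bad <- calls
  bad$n_bins <- 10
  expect_error(quantify_extensions(bad, fb$bins, raw), "coverage error")
})

test_that("fixed-length read-through is recovered to within one bin", {
  cfg <- simulation_config(
    n_genes = 50, seed = 17, decay = "fixed", L_true = 400,
    background = 0.02, expression_bounds = c(30, 60),
    affected_fraction = 1,
    readthrough_fraction = c(control = 0, mutant = 1))
  toy <- build_toy_genome(cfg)
  sim <- simulate_counts(toy$annotation, cfg)
  res <- call_extensions(sim$intervals, sim$bins, sim$bin_counts,
                         sim$gene_counts, sim$sample_sheet)
  mut <- res$calls[res$calls$genotype == "mutant", ]
  hit <- abs(mut$length - 400) <= 10
  expect_gte(mean(hit), 0.95)
  expect_gte(nrow(mut), 45)
})

test_that("zero intergenic coverage yields zero calls genome-wide", {
  cfg <- simulation_config(n_genes = 10, seed = 19, background = 0,
                           readthrough_fraction = c(control = 0, mutant = 0))
  toy <- build_toy_genome(cfg)
  sim <- simulate_counts(toy$annotation, cfg)
  res <- call_extensions(sim$intervals, sim$bins, sim$bin_counts,
                         sim$gene_counts, sim$sample_sheet,
                         caller_config(min_length = 0))
  expect_true(is.null(res$calls) || nrow(res$calls) == 0)
})
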