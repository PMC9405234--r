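test_that("r2 from haplotype frequencies follows the two-locus formula", {
  expect_equal(r2_from_haplotype_freqs(0.5, 0, 0, 0.5), 1)
  expect_equal(r2_from_haplotype_freqs(0.25, 0.25, 0.25, 0.25), 0)
  # D = 0.5*0.3 - 0.1*0.1 = 0.14; denom = 0.6*0.4*0.6*0.4 = 0.0576
  expect_equal(r2_from_haplotype_freqs(0.5, 0.1, 0.1, 0.3),
               0.14^2 / 0.0576, tolerance = 1e-12)
  expect_true(is.na(r2_from_haplotype_freqs(0.5, 0.5, 0, 0)))  # monomorphic B
  expect_error(r2_from_haplotype_freqs(0.5, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("composite r2 is squared dosage correlation; EM matches truth", {
  gi <- c(0L, 1L, 2L, 2L, 0L, 1L)
  expect_equal(r2_unphased(gi, gi, "composite"), 1)
  expect_true(is.na(r2_unphased(gi, rep(1L, 6), "composite")))
  # genotypes collapsed from known phase with no double heterozygotes:
  # individuals (AB,AB), (ab,ab), (AB,Ab), (aB,ab) -> haplotype counts
  # AB:3 Ab:1 aB:1 ab:3, and no (1,1) genotype cell to leave phase ambiguous
  gi2 <- c(2L, 0L, 2L, 0L)
  gj2 <- c(2L, 0L, 1L, 1L)
  truth <- r2_from_haplotype_freqs(3 / 8, 1 / 8, 1 / 8, 3 / 8)
  expect_equal(r2_unphased(gi2, gj2, "em"), truth, tolerance = 1e-6)
})

test_that("EM r2 approaches the phased truth as samples grow", {
  set.seed(12)
  hap_freqs <- c(AB = 0.4, Ab = 0.2, aB = 0.1, ab = 0.3)
  draw <- function(n) {
    idx <- sample(4, 2 * n, replace = TRUE, prob = hap_freqs)
    a <- c(1, 1, 0, 0)[idx]; b <- c(1, 0, 1, 0)[idx]
    # r2 of the realized (sample) haplotype frequencies: the phased truth
    # the EM should recover up to phase ambiguity, free of sampling error
    f <- tabulate(idx, 4) / (2 * n)
    list(gi = a[seq(1, 2 * n, 2)] + a[seq(2, 2 * n, 2)],
         gj = b[seq(1, 2 * n, 2)] + b[seq(2, 2 * n, 2)],
         truth = r2_from_haplotype_freqs(f[1], f[2], f[3], f[4]))
  }
  d200 <- draw(200)
  expect_lt(abs(r2_unphased(d200$gi, d200$gj, "em") - d200$truth), 0.05)
  d1000 <- draw(1000)
  expect_lt(abs(r2_unphased(d1000$gi, d1000$gj, "em") - d1000$truth), 0.02)
})

test_that("r2 is symmetric and invariant to allele-label swaps", {
  set.seed(13)
  gi <- rbinom(40, 2, 0.4); gj <- rbinom(40, 2, 0.6)
  for (est in c("composite", "em")) {
    expect_equal(r2_unphased(gi, gj, est), r2_unphased(gj, gi, est))
    expect_equal(r2_unphased(2L - gi, gj, est), r2_unphased(gi, gj, est),
                 tolerance = 1e-9)
  }
})

test_that("windowed pair formation honours index, distance and r2 filters", {
  set.seed(14)
  g3 <- geno_from_freqs(rep(0.5, 3), 40)
  g3$variants$pos <- c(1000L, 2000L, 3000L)
  cfg <- ld_window_config(report_r2_min = NULL)
  expect_identical(nrow(pairwise_ld(g3, cfg)), 3L)
  g2 <- geno_from_freqs(rep(0.5, 2), 40)
  g2$variants$pos <- c(1L, 1500001L)
  expect_identical(nrow(pairwise_ld(g2, cfg)), 0L)
  # reporting threshold omits pairs and counts them
  p <- pairwise_ld(g3, ld_window_config(report_r2_min = 0.99))
  expect_identical(nrow(p) + attr(p, "n_omitted"), attr(p, "n_pairs_formed"))
})

test_that("pairwise_ld equals the brute-force all-pairs oracle", {
  set.seed(15)
  g <- geno_from_freqs(runif(50, 0.1, 0.9), 60)
  g$variants$pos <- sort(sample.int(3e6, 50))
  # sprinkle missingness to exercise pairwise-complete handling
  g$dosages[sample(length(g$dosages), 100)] <- NA
  g <- genotype_matrix(g$dosages, g$variants, g$samples)
  pairs <- pairwise_ld(g, ld_window_config(max_kb = 1500, report_r2_min = NULL))
  oracle <- r2_oracle_all_pairs(g$dosages, g$variants$pos, max_kb = 1500)
  expect_identical(nrow(pairs), nrow(oracle))
  expect_equal(pairs$r2, oracle$r2, tolerance = 1e-12)
  # and with no missing data through the fast path
  g2 <- geno_from_freqs(runif(50, 0.1, 0.9), 60)
  g2$variants$pos <- sort(sample.int(3e6, 50))
  pairs2 <- pairwise_ld(g2, ld_window_config(max_kb = 1500, report_r2_min = NULL))
  oracle2 <- r2_oracle_all_pairs(g2$dosages, g2$variants$pos, max_kb = 1500)
  expect_equal(pairs2$r2, oracle2$r2, tolerance = 1e-12)
})

test_that("chromosome summaries aggregate mean, sd and median", {
  pairs <- data.frame(chrom = "1", vid_i = "a", vid_j = "b",
                      pos_i = 1L, pos_j = 2L, distance_bp = 1L,
                      r2 = c(0.2, 0.4, 0.6))
  sm <- chromosome_ld_summary(pairs)
  gw <- sm[sm$chrom == "genome", ]
  expect_equal(gw$mean_r2, 0.4)
  expect_equal(gw$median_r2, 0.4)
  expect_equal(gw$sd_r2, 0.2)
  one <- chromosome_ld_summary(pairs[1, ])
  expect_true(is.na(one$sd_r2[1]))
  expect_equal(one$mean_r2[1], 0.2)
})

test_that("decay bins are half-open with pairs placed by distance", {
  pairs <- data.frame(chrom = "1", vid_i = "a", vid_j = "b",
                      pos_i = 0L, pos_j = 0L,
                      distance_bp = c(500L, 1000L, 9999L, 995000L),
                      r2 = c(0.8, 0.6, 0.5, 0.1))
  d <- ld_decay(pairs)
  d10 <- d[d$max_kb == 10, ]
  expect_identical(d10$n_pairs[1], 1L)      # 0.5 kb -> [0,1) bin
  expect_identical(d10$n_pairs[2], 1L)      # 1.0 kb -> [1,2) bin
  expect_identical(d10$n_pairs[10], 1L)     # 9.999 kb -> [9,10] bin
  d1000 <- d[d$max_kb == 1000, ]
  expect_identical(d1000$n_pairs[10], 1L)   # 995 kb in [900,1000]
  expect_true(all(is.na(d1000$mean_r2[d1000$n_pairs == 0])))
})

test_that("simulated LD decays with distance", {
  sim <- shared_sim()
  g <- as_genotypes(sim$pops$pop1)
  pairs <- pairwise_ld(g, ld_window_config(report_r2_min = NULL))
  near <- pairs$r2[pairs$distance_bp <= 1e4]
  far <- pairs$r2[pairs$distance_bp >= 5e5 & pairs$distance_bp <= 1e6]
  expect_gt(mean(near), mean(far))
})
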