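test_that("D' CI concentrates for coupled loci and stays low for independent", {
  set.seed(16)
  # perfectly coupled haplotypes, n = 100 diploids
  hap <- rbinom(200, 1, 0.4)
  gi <- hap[1:100] + hap[101:200]
  ci <- dprime_ci(gi, gi)
  expect_gt(ci$ci_lo, 0.9)
  expect_equal(ci$dprime, 1, tolerance = 1e-6)
  # independent loci
  gj <- rbinom(100, 2, 0.5)
  gk <- rbinom(100, 2, 0.5)
  ci2 <- dprime_ci(gj, gk)
  expect_lt(ci2$ci_lo, 0.2)
  # allele-label swap leaves the CI unchanged (sign normalization)
  ci3 <- dprime_ci(gj, 2L - gk)
  expect_equal(ci2[c("ci_lo", "ci_hi")], ci3[c("ci_lo", "ci_hi")])
  # bounds are ordered and bracket the point estimate on the grid
  expect_true(ci$ci_lo <= ci$ci_hi)
  expect_true(is.na(dprime_ci(gj, rep(0L, 100))$dprime))
})

test_that("phased and unphased D' CIs agree on double-het-free data", {
  set.seed(17)
  h1 <- rbinom(300, 1, 0.5)
  h2 <- ifelse(runif(300) < 0.9, h1, 1 - h1)   # strong coupling
  ci_p <- dprime_ci(h1, h2, phased = TRUE)
  expect_true(ci_p$ci_lo <= ci_p$dprime + 0.01)
  expect_gt(ci_p$dprime, 0.6)
})

test_that("three tightly linked SNPs form one block; independent SNPs none", {
  set.seed(18)
  fx <- island_haps(200, list(list(n_snps = 3, n_templates = 2,
                                   spacing_bp = 2000, gap_bp = 0)))
  h <- haplotype_matrix(fx$haps,
                        variant_table("1", fx$pos,
                                      vid = paste0("v", seq_along(fx$pos))),
                        sample_table(paste0("s", 1:100)))
  bl <- gabriel_blocks(h)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$n_snps, 3L)
  # independent SNPs: fresh random columns, no LD
  ind <- matrix(rbinom(200 * 3, 1, 0.5), 200, 3)
  h2 <- haplotype_matrix(ind, h$variants, h$samples)
  expect_identical(nrow(gabriel_blocks(h2)), 0L)
})

test_that("two planted LD islands across a recombination break are recovered", {
  set.seed(19)
  fx <- island_haps(240, list(
    list(n_snps = 6, n_templates = 3, spacing_bp = 3000, gap_bp = 50000),
    list(n_snps = 7, n_templates = 3, spacing_bp = 3000, gap_bp = 0)))
  h <- haplotype_matrix(fx$haps,
                        variant_table("1", fx$pos,
                                      vid = paste0("v", seq_along(fx$pos))),
                        sample_table(paste0("s", 1:120)))
  bl <- gabriel_blocks(h)
  expect_identical(nrow(bl), 2L)
  # planted boundaries recovered within one SNP
  expect_lte(abs(bl$n_snps[1] - 6), 1)
  expect_lte(abs(bl$n_snps[2] - 7), 1)
  expect_lt(bl$end_bp[1], fx$pos[7])
  # haplotype frequencies within a block sum to 1
  expect_equal(sum(bl$haplotypes[[1]]), 1)
  # blocks never overlap and never hold < 3 SNPs
  expect_true(all(bl$n_snps >= 3))
  expect_true(all(utils::head(bl$end_bp, -1) < utils::tail(bl$start_bp, -1)))
})

test_that("detection matches the exhaustive span-enumeration oracle", {
  for (seed in 20:22) {
    set.seed(seed)
    fx <- island_haps(160, list(
      list(n_snps = 4, n_templates = 2, spacing_bp = 4000, gap_bp = 40000),
      list(n_snps = 5, n_templates = 4, spacing_bp = 4000, gap_bp = 0)))
    v <- variant_table("1", fx$pos, vid = paste0("v", seq_along(fx$pos)))
    h <- haplotype_matrix(fx$haps, v, sample_table(paste0("s", 1:80)))
    bl <- gabriel_blocks(h)
    # oracle works on the same usable-marker set (MAF >= 0.05)
    fr <- allele_frequencies(as_genotypes(h))
    usable <- which(!is.na(fr$maf) & fr$maf >= 0.05)
    orc <- gabriel_oracle(fx$haps[, usable, drop = FALSE], fx$pos[usable],
                          phased = TRUE)
    expect_identical(nrow(bl), nrow(orc))
    if (nrow(orc)) {
      expect_identical(bl$start_bp, as.integer(fx$pos[usable][orc$first]))
      expect_identical(bl$end_bp, as.integer(fx$pos[usable][orc$last]))
    }
  }
})

test_that("block detection is invariant to sample order and label swaps", {
  set.seed(23)
  fx <- island_haps(160, list(list(n_snps = 5, n_templates = 3,
                                   spacing_bp = 3000, gap_bp = 0)))
  v <- variant_table("1", fx$pos, vid = paste0("v", seq_along(fx$pos)))
  h <- haplotype_matrix(fx$haps, v, sample_table(paste0("s", 1:80)))
  bl <- gabriel_blocks(h)
  perm <- sample(80)
  h2 <- keep_samples(h, perm)
  bl2 <- gabriel_blocks(h2)
  expect_identical(bl[c("start_bp", "end_bp", "n_snps")],
                   bl2[c("start_bp", "end_bp", "n_snps")])
  flip <- fx$haps
  flip[, 2] <- 1L - flip[, 2]
  bl3 <- gabriel_blocks(haplotype_matrix(flip, v, h$samples))
  expect_identical(bl[c("start_bp", "end_bp", "n_snps")],
                   bl3[c("start_bp", "end_bp", "n_snps")])
})

test_that("block summaries compute lengths, coverage and SNP shares", {
  blocks <- data.frame(chrom = "1",
                       start_bp = c(100000, 400000),
                       end_bp = c(110000, 430000),
                       n_snps = c(4L, 6L))
  blocks$haplotypes <- list(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.75))
  ext <- data.frame(chrom = "1", start_bp = 1, end_bp = 1e6)
  bs <- block_summary(blocks, ext, n_snps_total = 100L)
  expect_equal(bs$n_blocks, 2)
  expect_equal(bs$total_length_mb, 0.04)
  expect_equal(bs$pct_genome_coverage, 100 * 40000 / 999999, tolerance = 1e-6)
  expect_equal(bs$mean_length_kb, 20)
  expect_equal(bs$median_length_kb, 20)
  expect_equal(bs$max_length_kb, 30)
  expect_equal(bs$pct_snps_in_blocks, 10)
  expect_equal(bs$haplotype_frequency_mean, 0.5)
  # one 10-kb block on a 1-Mb extent ~ 1% coverage
  bs1 <- block_summary(blocks[1, ], ext)
  expect_equal(bs1$pct_genome_coverage, 1, tolerance = 0.01)
  empty <- block_summary(blocks[0, ], ext)
  expect_equal(empty$n_blocks, 0)
})

test_that("shared/unique block comparison uses >= 1 bp overlap", {
  a <- data.frame(chrom = "1", start_bp = 100L, end_bp = 200L, n_snps = 3L)
  b <- data.frame(chrom = "1", start_bp = 150L, end_bp = 250L, n_snps = 3L)
  sh <- shared_unique_blocks(a, b)
  expect_identical(sh$shared_a, 1L)
  expect_identical(sh$shared_b, 1L)
  expect_identical(sh$unique_a, 0L)
  # identical lists: all shared; disjoint: none
  expect_identical(shared_unique_blocks(a, a)$unique_a, 0L)
  c2 <- data.frame(chrom = "1", start_bp = 300L, end_bp = 400L, n_snps = 3L)
  expect_identical(shared_unique_blocks(a, c2)$shared_a, 0L)
  # different chromosome never shares (GRanges warns about disjoint
  # sequence levels, which is exactly the situation under test)
  d2 <- data.frame(chrom = "2", start_bp = 100L, end_bp = 200L, n_snps = 3L)
  expect_identical(suppressWarnings(shared_unique_blocks(a, d2)$shared_a), 0L)
})
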