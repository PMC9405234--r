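test_that("exact HWE test matches enumeration for every table with n <= 20", {
  for (n in 1:20) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_exact_pvalue(n_AA, n_Aa, n_aa),
                   hwe_oracle(n_AA, n_Aa, n_aa), tolerance = 1e-12,
                   label = sprintf("table (%d,%d,%d)", n_AA, n_Aa, n_aa))
    }
  }
})

test_that("HWE conventions: monomorphic tables give p = 1", {
  expect_equal(hwe_exact_pvalue(5, 0, 0), 1)
  expect_equal(hwe_exact_pvalue(0, 0, 7), 1)
  expect_equal(hwe_exact_pvalue(0, 2, 0), 1)  # modal class at nA = na = 2
})

test_that("MAF spectrum uses the five half-open bins with closed top", {
  sp <- maf_spectrum(c(0.02, 0.1, 0.5))
  expect_identical(sp$n, c(1L, 1L, 0L, 0L, 1L))
  expect_identical(maf_spectrum(0.0999999)$n[1], 1L)
  expect_identical(sum(maf_spectrum(c(0.01, 0.019))$n), 0L)
  set.seed(42)
  u <- runif(20000, 0.02, 0.5)
  sp <- maf_spectrum(u)
  widths <- sp$bin_hi - sp$bin_lo
  expect_equal(sp$proportion, widths / 0.48, tolerance = 0.03)
  expect_equal(sum(sp$proportion), 1)
})

test_that("pi-hat recovers duplicate, unrelated and parent-offspring pairs", {
  set.seed(7)
  p <- runif(1000, 0.1, 0.9)
  hap <- function() rbinom(length(p), 1, p)
  mk_ind <- function(h1, h2) h1 + h2
  a1 <- hap(); a2 <- hap(); b1 <- hap(); b2 <- hap()
  child <- mk_ind(a1, hap())                # shares haplotype a1 with parent A
  d <- rbind(parentA = mk_ind(a1, a2), dupA = mk_ind(a1, a2),
             unrel = mk_ind(b1, b2), child = child)
  g <- genotype_matrix(d, variant_table("1", seq_along(p) * 100,
                                        vid = paste0("v", seq_along(p))),
                       sample_table(rownames(d)))
  ph <- ibd_pihat(g)
  expect_equal(diag(ph), rep(1, 4), ignore_attr = TRUE)
  expect_equal(ph["parentA", "dupA"], 1, tolerance = 0.05)
  expect_equal(ph["parentA", "unrel"], 0, tolerance = 0.05)
  expect_equal(ph["parentA", "child"], 0.5, tolerance = 0.05)
})

test_that("relatedness pruning is greedy, deterministic and minimal here", {
  set.seed(8)
  p <- runif(600, 0.2, 0.8)
  base <- rbinom(length(p), 2, p)
  noisy <- function() { x <- base; i <- sample(length(p), 30)
                        x[i] <- rbinom(30, 2, p[i]); x }
  d <- rbind(t1 = noisy(), t2 = noisy(), t3 = noisy(),
             u1 = rbinom(length(p), 2, p), u2 = rbinom(length(p), 2, p))
  g <- genotype_matrix(d, variant_table("1", seq_along(p) * 50,
                                        vid = paste0("v", seq_along(p))),
                       sample_table(rownames(d)))
  pr <- prune_related(g, 0.45)
  # the related triangle loses exactly 2 members; unrelated pair untouched
  expect_length(pr$removed, 2)
  expect_true(all(pr$removed %in% c("t1", "t2", "t3")))
  expect_true(all(c("u1", "u2") %in% pr$genotypes$samples$sid))
  # no pair above threshold -> identity
  pr2 <- prune_related(keep_samples(g, g$samples$sid %in% c("u1", "u2")), 0.45)
  expect_length(pr2$removed, 0)
  # duplicate pair -> exactly one removed
  gd <- keep_samples(g, g$samples$sid %in% c("t1", "t2", "u1"))
  pr3 <- prune_related(gd, 0.45)
  expect_length(pr3$removed, 1)
})

test_that("QC cascade attributes one failure per filter and is idempotent", {
  set.seed(9)
  n <- 60
  freqs <- runif(120, 0.25, 0.75)   # enough variants for stable pi-hat
  g0 <- geno_from_freqs(freqs, n)
  d <- g0$dosages
  d[, 1] <- c(rep(NA, 10), rbinom(n - 10, 2, 0.5))       # call rate 83%
  d[, 2] <- rbinom(n, 1, 0.01)                           # MAF ~ 0.005
  d[, 3] <- rep(1L, n)                                   # all-het: HWE blowup
  v <- g0$variants
  v$chrom[4] <- "X"                                      # non-autosomal
  g <- genotype_matrix(d, v, g0$samples)
  res <- apply_qc(g, qc_config())
  expect_identical(res$report$n_snps_post, ncol(d) - 4L)
  expect_identical(res$report$removed_snps$nonautosomal, 1L)
  expect_identical(res$report$removed_snps$call_rate, 1L)
  expect_identical(res$report$removed_snps$maf, 1L)
  expect_identical(res$report$removed_snps$hwe, 1L)
  # idempotence
  res2 <- apply_qc(res$genotypes, qc_config())
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
  expect_identical(res2$report$n_snps_post, res$report$n_snps_post)
  # all-pass fixture is the identity
  res3 <- apply_qc(g0, qc_config())
  expect_identical(res3$genotypes$dosages, g0$dosages)
})

test_that("PCA separates two drifted populations and respects duplicates", {
  set.seed(10)
  p_anc <- runif(300, 0.2, 0.8)
  # FST ~ 0.05 via beta-distributed per-population frequencies
  drift <- function(p) rbeta(length(p), p * 19, (1 - p) * 19)
  pa <- drift(p_anc); pb <- drift(p_anc)
  da <- vapply(pa, function(q) rbinom(30, 2, q), integer(30))
  db <- vapply(pb, function(q) rbinom(30, 2, q), integer(30))
  g <- genotype_matrix(rbind(da, db),
                       variant_table("1", seq_along(p_anc) * 100,
                                     vid = paste0("v", seq_along(p_anc))),
                       sample_table(paste0("s", 1:60),
                                    rep(c("A", "B"), each = 30)))
  pc <- pca_structure(g, k = 2)
  lab <- rep(c(1, -1), each = 30)
  # PC1 separates labels: same-sign projection within groups (silhouette > 0)
  x <- pc$coordinates[, 1]
  expect_true(abs(mean(x[1:30]) - mean(x[31:60])) >
                2 * (sd(x[1:30]) + sd(x[31:60])) / sqrt(30))
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  # duplicated rows get identical coordinates
  g2 <- keep_samples(g, c(1, 1, 2:10))
  pc2 <- pca_structure(g2, k = 2)
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ])
})

test_that("panmictic data shows no dominant PCA axis", {
  set.seed(11)
  g <- geno_from_freqs(runif(400, 0.2, 0.8), 50)
  pc <- pca_structure(g, k = 5)
  # top eigenvalue close to the bulk: ratio of PC1 to PC5 stays small
  expect_lt(pc$variance_explained[1] / pc$variance_explained[5], 1.6)
})
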