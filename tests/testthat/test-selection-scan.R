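make_h <- function(haps, pos, ancestral = "ref") {
  haplotype_matrix(haps,
                   variant_table("1", pos, vid = paste0("v", seq_along(pos)),
                                 ancestral = ancestral),
                   sample_table(paste0("s", seq_len(nrow(haps) / 2))))
}

test_that("EHH is 1 at the core, non-increasing, with hand-checked splits", {
  # 6 derived carriers splitting 4/2 at the first flank:
  # EHH = (C(4,2)+C(2,2)) / C(6,2) = 7/15
  haps <- rbind(
    cbind(1L, 0L, 1L), cbind(1L, 0L, 1L), cbind(1L, 0L, 1L),
    cbind(1L, 0L, 0L),
    cbind(1L, 1L, 1L), cbind(1L, 1L, 0L),
    cbind(0L, 0L, 0L), cbind(0L, 1L, 1L))
  h <- make_h(haps, c(5000L, 10000L, 15000L))
  # ancestral = ref so the derived allele is coded 1; core at v1
  pr <- ehh(h, "v1", allele = "derived")
  right <- pr$raw$ehh_right
  expect_equal(right[1], 1)
  expect_equal(right[2], 7 / 15)
  expect_true(all(diff(pr$raw$ehh_right) <= 1e-12))
  expect_true(all(diff(pr$raw$ehh_left) <= 1e-12))
  # identical carriers: EHH stays 1 across the region
  same <- matrix(1L, 8, 3); same[7:8, 1] <- 0L
  h2 <- make_h(same, c(5000L, 10000L, 15000L))
  pr2 <- ehh(h2, "v1", allele = "derived")
  expect_true(all(pr2$raw$ehh_right == 1))
  # carriers split 2/2 at the first flank -> EHH = (C(2,2)+C(2,2))/C(4,2)
  h3 <- make_h(rbind(c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 0L, 0L),
                     c(1L, 1L, 1L), c(0L, 0L, 0L), c(0L, 1L, 1L)),
               c(5000L, 10000L, 15000L))
  pr3 <- ehh(h3, "v1", allele = "derived")
  expect_equal(pr3$raw$ehh_right[2], 2 / 6)
})

test_that("EHH truncates at the floor and at large gaps", {
  set.seed(25)
  haps <- matrix(rbinom(60 * 10, 1, 0.5), 60, 10)
  haps[, 5] <- 1L
  pos <- c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6, 1.45e6, 2.2e6, 2.25e6, 2.3e6, 2.35e6)
  h <- make_h(haps, as.integer(pos))
  pr <- ehh(h, "v5", allele = "derived")
  # the 750-kb gap between v6 and v7 stops the rightward extension
  expect_lte(max(pr$raw$pos_right), 1.45e6)
  # values below the floor end the profile
  below <- which(pr$raw$ehh_right < 0.05)
  if (length(below)) expect_identical(below, length(pr$raw$ehh_right))
})

test_that("EHH agrees with the brute-force substring oracle", {
  set.seed(26)
  haps <- matrix(rbinom(40 * 30, 1, 0.5), 40, 30)
  pos <- sort(sample.int(2e6, 30))
  h <- make_h(haps, pos)
  for (core in c(1L, 7L, 30L)) {
    for (al in c("derived", "ancestral", "all")) {
      pr <- ehh(h, paste0("v", core), allele = al)
      carriers <- switch(al,
        derived = which(haps[, core] == 1L),
        ancestral = which(haps[, core] == 0L),
        all = seq_len(nrow(haps)))
      if (length(carriers) < 2) { expect_null(pr); next }
      orc <- ehh_oracle(haps, pos, core, carriers, split_core = al == "all")
      expect_equal(pr$raw$pos_left, orc$pos_left)
      expect_equal(pr$raw$ehh_left, orc$ehh_left)
      expect_equal(pr$raw$pos_right, orc$pos_right)
      expect_equal(pr$raw$ehh_right, orc$ehh_right)
    }
  }
})

test_that("iHH integrates rectangles, triangles and arbitrary profiles", {
  mk <- function(pl, el, pr, er) {
    structure(list(raw = list(pos_left = pl, ehh_left = el,
                              pos_right = pr, ehh_right = er)),
              class = "ehh_profile")
  }
  # EHH = 1 over exactly 10 kb each side -> 20,000
  expect_equal(ihh(mk(c(50000, 40000), c(1, 1), c(50000, 60000), c(1, 1))),
               20000)
  # linear decay 1 -> 0 over 10 kb one side only -> 5,000
  expect_equal(ihh(mk(50000, 1, c(50000, 60000), c(1, 0))), 5000)
  # arbitrary 5-point profile vs numeric integration oracle
  px <- c(0, 1000, 2500, 4000, 7000)
  ex <- c(1, 0.8, 0.55, 0.2, 0.07)
  # dense-grid numeric integration including the knots
  xx <- sort(unique(c(seq(0, 7000, by = 0.5), px)))
  yy <- approx(px, ex, xx)$y
  oracle <- sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
  expect_equal(ihh(mk(0, 1, px, ex)), oracle, tolerance = 1e-9)
})

test_that("piHS transform matches the normal-CDF equivalences", {
  expect_equal(pihs(0), 0)
  expect_equal(pihs(3.2905), 3, tolerance = 1e-3)   # two-sided p = 0.001
  expect_equal(pihs(-3.2905), 3, tolerance = 1e-3)  # even function
  z <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(pihs(z)) > 0))               # increasing in |iHS|
  expect_equal(pihs(-z), pihs(z))
})

test_that("symmetric allele classes give uniHS = 0", {
  # derived and ancestral carrier sets with mirrored extension patterns
  blk <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(0L, 0L, 0L), c(0L, 0L, 1L))
  h <- make_h(rbind(blk, blk), c(10000L, 20000L, 30000L))
  sc <- ihs_scan(h, scan_config(min_maf = 0.05))
  core <- sc[sc$vid == "v1", ]
  expect_equal(core$unihs, 0)
})

test_that("neutral iHS standardization is calibrated within bins", {
  sim <- shared_sim()
  sc <- ihs_scan(sim$pops$pop1)
  grp <- attr(sc, "standardization_groups")
  ok <- !is.na(sc$ihs)
  z <- sc$ihs[ok]
  for (b in unique(grp)) {
    zb <- z[grp == b]
    if (length(zb) >= 20) {
      expect_lt(abs(mean(zb)), 0.05)
      expect_lt(abs(sd(zb) - 1), 0.05)
    }
  }
})

test_that("candidate windows tile with the 990-kb step and rank by density", {
  set.seed(27)
  pos <- sort(sample.int(2.98e6, 120))
  scores <- data.frame(chrom = "1", pos = pos, vid = paste0("v", 1:120),
                       freq_derived = 0.5, ihh_a = 1, ihh_d = 1,
                       unihs = 0, ihs = rnorm(120, 0, 0.5))
  scores$pihs <- pihs(scores$ihs)
  w <- candidate_windows(scores, scan_config(window_min_snps = 5L))
  expect_identical(sort(unique(w$start_bp)), c(1, 990001, 1980001))
  # plant all extreme SNPs inside one window
  scores$ihs[scores$pos > 990000 & scores$pos <= 1980000] <- 4
  scores$pihs <- pihs(scores$ihs)
  w2 <- candidate_windows(scores, scan_config(window_min_snps = 5L))
  cand <- w2[w2$candidate, ]
  expect_identical(cand$start_bp, 990001)
  # all scores sub-threshold: densities zero, candidate set still returned
  scores$ihs <- rnorm(120, 0, 0.1)
  scores$pihs <- pihs(scores$ihs)
  w3 <- candidate_windows(scores, scan_config(window_min_snps = 5L))
  expect_identical(attr(w3, "n_extreme_total"), 0L)
  expect_identical(sum(w3$candidate), 1L)
  # windows below the SNP floor are dropped
  expect_true(all(w3$n_snps >= 5))
})

test_that("XP-EHH is zero on identical inputs and antisymmetric on swap", {
  sim <- shared_sim()
  h1 <- sim$pops$pop1
  h2 <- sim$pops$pop2
  same <- xpehh_scan(h1, h1)
  expect_true(all(abs(same$scores$raw) < 1e-12, na.rm = TRUE))
  expect_identical(nrow(same$runs), 0L)
  ab <- xpehh_scan(h1, h2)
  ba <- xpehh_scan(h2, h1)
  ok <- !is.na(ab$scores$xpehh)
  expect_equal(ab$scores$xpehh[ok], -ba$scores$xpehh[ok], tolerance = 1e-9)
  expect_error(xpehh_scan(h1, keep_variants(h2, 1:10)), "identical variant")
})

test_that("run calling needs the minimum consecutive span", {
  scores <- data.frame(chrom = "1", pos = (1:10) * 1000,
                       vid = paste0("v", 1:10))
  scores$xpehh <- c(5, 5, 1, 5, 5, 5, 1, 5, 1, 5)
  runs <- ldsweep:::.score_runs(scores, scores$xpehh >= 4, 3L, "pop1")
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$start_bp, 4000)
  expect_identical(runs$end_bp, 6000)
  expect_identical(runs$n_snps, 3L)
})
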