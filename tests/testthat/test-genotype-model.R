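test_that("PLINK bed/bim/fam round-trips, including missing calls", {
  d <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 3)
  g <- genotype_matrix(d, variant_table("1", c(100L, 200L), c("v1", "v2")),
                       sample_table(c("a", "b", "c")))
  prefix <- file.path(withr::local_tempdir(), "fix")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$variants$pos, g$variants$pos)
  expect_identical(g2$samples$sid, g$samples$sid)
  # byte-identical genotype payload on rewrite
  write_plink(g2, paste0(prefix, "_2"))
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 100),
                   readBin(paste0(prefix, "_2.bed"), "raw", 100))
})

test_that("bed decoding matches a hand-packed 2-bit fixture", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  # 3 samples, 2 variants; SNP-major v1: 00=hom A1(dosage 2), 01=missing,
  # 10=het, 11=hom A2 (dosage 0). Pack sample bits little-endian per byte.
  # variant 1: dosages (2, 1, 0)  -> codes 00,10,11 -> byte 00 11 10 00 = 0x38
  # variant 2: dosages (NA, 0, 2) -> codes 01,11,00 -> byte 00 00 11 01 = 0x0D
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x0d)), paste0(prefix, ".bed"))
  writeLines(c("1\tv1\t0\t100\tA\tG", "1\tv2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("f\ta\t0\t0\t0\t-9", "f\tb\t0\t0\t0\t-9", "f\tc\t0\t0\t0\t-9"),
             paste0(prefix, ".fam"))
  g <- read_plink(prefix)
  expect_identical(unname(g$dosages),
                   matrix(c(2L, 1L, 0L, NA, 0L, 2L), nrow = 3))
})

test_that("bad magic bytes and dimension mismatches are format errors", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(prefix, ".bed"))
  writeLines("1\tv1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines("f\ta\t0\t0\t0\t-9", paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "inconsistent")
})

test_that("VCF genotypes and phased haplotypes transcribe exactly", {
  vcf <- file.path(withr::local_tempdir(), "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\tv1\tA\tG\t.\tPASS\tAA=G\tGT\t0|1",
    "1\t200\tv2\tC\tT\t.\tPASS\tAA=C\tGT\t1|1"), vcf)
  h <- read_vcf(vcf, phased = TRUE)
  expect_s3_class(h, "haplo_matrix")
  expect_identical(unname(h$haps), matrix(c(0L, 1L, 1L, 1L), nrow = 2))
  expect_identical(h$variants$ancestral, c("alt", "ref"))
  g <- read_vcf(vcf, phased = FALSE)
  expect_identical(unname(g$dosages), matrix(c(1L, 2L), nrow = 1))
})

test_that("unphased GT under phased reading is an error; multiallelic skipped", {
  vcf <- file.path(withr::local_tempdir(), "u.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\tv2\tC\tT,G\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_vcf(vcf, phased = TRUE), "unphased")
  expect_message(g <- read_vcf(vcf, phased = FALSE), "skipped")
  expect_identical(g$variants$vid, "v1")
})

test_that("simulator-exported VCF round-trips the in-memory haplotypes", {
  sim <- shared_sim()
  dir <- withr::local_tempdir()
  paths <- export_simulation(sim, dir)
  h <- read_vcf(paths$vcf, phased = TRUE)
  combined <- do.call(rbind, lapply(sim$pops, function(p) p$haps))
  expect_identical(unname(h$haps), unname(combined))
  expect_true(all(h$variants$ancestral == "ref"))
  g <- read_plink(paths$plink)
  expect_identical(unname(g$dosages), unname(as_genotypes(h)$dosages))
  map <- read_population_map(paths$map)
  expect_identical(sort(unique(unname(map))), c("pop1", "pop2"))
})

test_that("split_by_population partitions rows and keeps all variants", {
  set.seed(1)
  g <- geno_from_freqs(runif(10, 0.2, 0.8), 127)
  map <- setNames(rep(c("BartlowCombine", "Kokstad"), c(85, 42)),
                  g$samples$sid)
  sp <- split_by_population(g, map)
  expect_identical(vapply(sp, function(x) nrow(x$samples), 0L),
                   c(BartlowCombine = 85L, Kokstad = 42L))
  expect_identical(sp[[1]]$variants, g$variants)
  # single label: identity on rows
  one <- split_by_population(g, setNames(rep("all", 127), g$samples$sid))
  expect_identical(one$all$dosages, g$dosages)
  # empty group keeps full variant metadata
  map2 <- setNames(c(rep("a", 127)), g$samples$sid)
  sp2 <- split_by_population(keep_samples(g, 1:5),
                             setNames(rep("a", 5), g$samples$sid[1:5]))
  expect_identical(nrow(sp2$a$samples), 5L)
  expect_error(split_by_population(g, map[-1]), "unmapped")
})

test_that("allele frequencies count alt copies over non-missing calls", {
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA,
                                2L, 2L, 1L, NA,
                                0L, 0L, 0L, 0L,
                                NA, NA, NA, NA), nrow = 4),
                       variant_table("1", c(1, 2, 3, 4) * 100,
                                     vid = paste0("v", 1:4)),
                       sample_table(paste0("s", 1:4)))
  fr <- allele_frequencies(g)
  expect_equal(fr$freq_alt, c(0.5, 5 / 6, 0, NA))
  expect_equal(fr$maf, c(0.5, 1 / 6, 0, NA))
  expect_true(all(fr$maf >= 0 & fr$maf <= 0.5, na.rm = TRUE))
})

test_that("haplotype collapse reproduces haplotype-level frequencies", {
  sim <- shared_sim()
  h <- sim$pops$pop1
  f_hap <- colMeans(h$haps)
  f_geno <- allele_frequencies(as_genotypes(h))$freq_alt
  expect_equal(unname(f_hap), f_geno)
})

test_that("variant constructor enforces ordering, dedup and filters", {
  v <- suppressMessages(variant_table(c("1", "1", "2", "1"),
                                      c(500, 100, 50, 100),
                                      vid = c("a", "b", "c", "d")))
  expect_identical(v$vid, c("b", "a", "c"))   # sorted, duplicate pos dropped
  expect_error(variant_table("1", 100, ref = "A", alt = "A"), "differ")
  expect_message(variant_table("1", c(100, NA), vid = c("a", "b")), "unknown")
})
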