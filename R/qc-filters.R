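#' Quality-control configuration
#'
#' Thresholds for per-population SNP and sample quality control. Defaults
#' mirror routine SNP-array practice in livestock genomics: an exact
#' Hardy-Weinberg test at p < 1e-6, minor allele frequency >= 0.02, call
#' rate >= 90%, and removal of close relatives at pi-hat > 0.45.
#'
#' @param hwe_p_min exact HWE p-value below which a SNP is removed.
#' @param maf_min SNPs with MAF strictly below this are removed.
#' @param call_rate_min minimum fraction of non-missing calls per SNP.
#' @param pihat_max pairs above this pi-hat are considered close relatives.
#' @param drop_nonautosomal drop variants whose chromosome label is not in
#'   `autosomes`.
#' @param autosomes chromosome labels treated as autosomes (default
#'   `"1"`..`"29"`, the cattle autosomes; set `NULL` to accept every label).
#' @return a `qc_config` list.
#' @export
qc_config <- function(hwe_p_min = 1e-6, maf_min = 0.02, call_rate_min = 0.90,
                      pihat_max = 0.45, drop_nonautosomal = TRUE,
                      autosomes = as.character(1:29)) {
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5,
            call_rate_min >= 0, call_rate_min <= 1,
            pihat_max >= 0, pihat_max <= 1)
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 call_rate_min = call_rate_min, pihat_max = pihat_max,
                 drop_nonautosomal = drop_nonautosomal, autosomes = autosomes),
            class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions for one biallelic
#' SNP. Given the observed allele counts, the p-value is the summed
#' probability of all heterozygote counts whose conditional probability does
#' not exceed that of the observed count (two-sided "as or less probable"
#' definition). A monomorphic SNP returns 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  # heterozygote count shares the parity of the rare allele count
  h <- seq(rare %% 2L, rare, by = 2L)
  # log P(h | n, nA) = log [ n! / (nAA! h! naa!) * 2^h ] + const
  logp <- h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' MAF spectrum over the standard five bins
#'
#' Counts retained SNPs in the five conventional MAF bins
#' `[0.02, 0.1)`, `[0.1, 0.2)`, `[0.2, 0.3)`, `[0.3, 0.4)`, `[0.4, 0.5]`.
#' SNPs with MAF < 0.02 (or `NA`) are excluded from the spectrum.
#'
#' @param maf numeric vector of minor allele frequencies, or a `geno_matrix`.
#' @return data.frame `bin_lo, bin_hi, n, proportion` (proportions sum to 1
#'   over the binned SNPs).
#' @export
maf_spectrum <- function(maf) {
  if (inherits(maf, "geno_matrix")) maf <- allele_frequencies(maf)$maf
  maf <- maf[!is.na(maf) & maf >= 0.02]
  edges <- c(0.02, 0.1, 0.2, 0.3, 0.4, 0.5)
  idx <- findInterval(maf, edges, rightmost.closed = TRUE)
  n <- tabulate(idx, nbins = 5L)
  data.frame(bin_lo = edges[1:5], bin_hi = edges[2:6], n = n,
             proportion = if (sum(n)) n / sum(n) else rep(NA_real_, 5L))
}

#' Pairwise IBD sharing (pi-hat)
#'
#' Method-of-moments estimate of the proportion of the genome shared
#' identical-by-descent for every sample pair, from identity-by-state counts
#' and sample allele frequencies (the approach behind PLINK's `--genome`).
#' pi-hat = P(IBD=1)/2 + P(IBD=2), with state probabilities clamped to
#' [0, 1]. Missing genotypes are dropped pairwise.
#'
#' @param g `geno_matrix`; variants should already be MAF-filtered
#'   (uninformative frequencies make the moments unstable). Fewer than 50
#'   usable variants triggers a warning.
#' @return symmetric samples x samples matrix of pi-hat (diagonal 1).
#' @export
ibd_pihat <- function(g) {
  d <- g$dosages
  if (ncol(d) < 50L) warning("fewer than 50 variants; pi-hat estimates unstable")
  fr <- allele_frequencies(g)
  p <- fr$freq_alt
  usable <- !is.na(p) & p > 0 & p < 1
  d <- d[, usable, drop = FALSE]
  p <- p[usable]
  q <- 1 - p
  # expected per-SNP P(IBS = s | IBD = k)
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  n <- nrow(d)
  pihat <- matrix(1, n, n, dimnames = list(g$samples$sid, g$samples$sid))
  if (n < 2L) return(pihat)
  for (i in seq_len(n - 1L)) {
    di <- d[i, ]
    for (j in seq((i + 1L), n)) {
      dj <- d[j, ]
      ok <- !is.na(di) & !is.na(dj)
      m <- sum(ok)
      if (m == 0L) { pihat[i, j] <- pihat[j, i] <- NA_real_; next }
      ibs <- 2L - abs(di[ok] - dj[ok])
      n_ibs0 <- sum(ibs == 0L); n_ibs1 <- sum(ibs == 1L)
      E0_0 <- sum(e0_ibs0[ok]); E1_0 <- sum(e0_ibs1[ok]); E1_1 <- sum(e1_ibs1[ok])
      p0 <- if (E0_0 > 0) n_ibs0 / E0_0 else 0
      p1 <- if (E1_1 > 0) (n_ibs1 - p0 * E1_0) / E1_1 else 0
      p0 <- min(max(p0, 0), 1)
      p1 <- min(max(p1, 0), 1 - p0)
      p2 <- max(0, 1 - p0 - p1)
      pihat[i, j] <- pihat[j, i] <- min(1, p1 / 2 + p2)
    }
  }
  pihat
}

#' Greedy removal of close relatives
#'
#' While any pair exceeds `pihat_max`, the member of the currently worst
#' (highest pi-hat) pair with the higher mean pi-hat to all other samples is
#' removed; ties are broken by lexicographic sample id. The retained set
#' contains no pair above the threshold. The procedure is deterministic.
#'
#' @param g `geno_matrix`.
#' @param pihat_max relatedness threshold.
#' @param pihat optional precomputed pi-hat matrix from [ibd_pihat()].
#' @return list with `genotypes` (pruned `geno_matrix`), `removed`
#'   (character vector of sample ids) and `pihat` (the input matrix).
#' @export
prune_related <- function(g, pihat_max = 0.45, pihat = NULL) {
  if (is.null(pihat)) pihat <- ibd_pihat(g)
  m <- pihat
  diag(m) <- 0
  active <- rownames(m)
  removed <- character(0)
  repeat {
    sub <- m[active, active, drop = FALSE]
    if (!length(sub) || all(sub <= pihat_max, na.rm = TRUE)) break
    worst <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pair <- active[worst]
    means <- rowMeans(sub[pair, , drop = FALSE], na.rm = TRUE)
    drop_id <- pair[order(-means, pair)][1L]
    removed <- c(removed, drop_id)
    active <- setdiff(active, drop_id)
  }
  list(genotypes = keep_samples(g, g$samples$sid %in% active),
       removed = removed, pihat = pihat)
}

#' Apply the full SNP and sample QC cascade
#'
#' Filters a genotype matrix in a fixed, logged order:
#' (1) drop non-autosomal / unknown-position variants, (2) call rate,
#' (3) minor allele frequency, (4) exact Hardy-Weinberg test,
#' (5) relatedness pruning. SNP-level statistics are recomputed after sample
#' removal only for the report's genotyping rate; filters use the entry
#' sample set. Each SNP is attributed to the first filter it fails; the
#' report also carries the total unique removals.
#'
#' @param g `geno_matrix`.
#' @param cfg a [qc_config()].
#' @return list with `genotypes` (filtered matrix), `report` (a `qc_report`
#'   list with pre/post counts, per-filter removals, genotyping rate, mean
#'   pi-hat over retained pairs and mean/sd MAF) and `removed_samples`.
#' @export
apply_qc <- function(g, cfg = qc_config()) {
  rep0 <- list(n_samples_pre = nrow(g$samples), n_snps_pre = nrow(g$variants))
  removed <- c(nonautosomal = 0L, call_rate = 0L, maf = 0L, hwe = 0L)

  if (cfg$drop_nonautosomal && !is.null(cfg$autosomes)) {
    keep <- g$variants$chrom %in% cfg$autosomes
    removed["nonautosomal"] <- sum(!keep)
    g <- keep_variants(g, keep)
  }
  d <- g$dosages
  call_rate <- colMeans(!is.na(d))
  keep <- call_rate >= cfg$call_rate_min
  removed["call_rate"] <- sum(!keep)
  g <- keep_variants(g, keep)

  fr <- allele_frequencies(g)
  keep <- !is.na(fr$maf) & fr$maf >= cfg$maf_min
  removed["maf"] <- sum(!keep)
  g <- keep_variants(g, keep)

  d <- g$dosages
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_pvalue(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                     sum(x == 0L, na.rm = TRUE))
  }, numeric(1))
  keep <- hwe_p >= cfg$hwe_p_min
  removed["hwe"] <- sum(!keep)
  g <- keep_variants(g, keep)

  pr <- prune_related(g, cfg$pihat_max)
  g <- pr$genotypes

  if (nrow(g$variants) == 0L || nrow(g$samples) == 0L) {
    warning("QC removed every SNP or sample")
  }
  fr <- allele_frequencies(g)
  kept <- setdiff(rownames(pr$pihat), pr$removed)
  ut <- pr$pihat[kept, kept, drop = FALSE][upper.tri(diag(length(kept)))]
  report <- structure(list(
    n_samples_pre = rep0$n_samples_pre, n_samples_post = nrow(g$samples),
    n_snps_pre = rep0$n_snps_pre, n_snps_post = nrow(g$variants),
    removed_snps = as.list(removed),
    removed_snps_total = rep0$n_snps_pre - nrow(g$variants),
    removed_samples = pr$removed,
    genotyping_rate = mean(!is.na(g$dosages)),
    mean_ibd = if (length(ut)) mean(ut, na.rm = TRUE) else NA_real_,
    mean_maf = mean(fr$maf, na.rm = TRUE),
    sd_maf = stats::sd(fr$maf, na.rm = TRUE)
  ), class = "qc_report")
  list(genotypes = g, report = report, removed_samples = pr$removed)
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n",
      sprintf("  samples: %d -> %d (removed: %s)\n", x$n_samples_pre,
              x$n_samples_post,
              if (length(x$removed_samples)) length(x$removed_samples) else 0),
      sprintf("  SNPs:    %d -> %d\n", x$n_snps_pre, x$n_snps_post),
      sprintf("  per-filter (first failure): nonautosomal %d, call rate %d, MAF %d, HWE %d\n",
              x$removed_snps$nonautosomal, x$removed_snps$call_rate,
              x$removed_snps$maf, x$removed_snps$hwe),
      sprintf("  genotyping rate %.4f, mean IBD %.3f, MAF %.3f +/- %.3f\n",
              x$genotyping_rate, x$mean_ibd, x$mean_maf, x$sd_maf), sep = "")
  invisible(x)
}

#' Write a QC report as JSON and plain text
#' @param report a `qc_report`.
#' @param prefix output path prefix (`<prefix>.json`, `<prefix>.txt`,
#'   `<prefix>.removed_samples.txt`).
#' @return `prefix`, invisibly.
#' @export
write_qc_report <- function(report, prefix) {
  jsonlite::write_json(unclass(report), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::capture.output(print(report), file = paste0(prefix, ".txt"))
  writeLines(report$removed_samples, paste0(prefix, ".removed_samples.txt"))
  invisible(prefix)
}

#' Principal component analysis of genotype structure
#'
#' Standard chip-data PCA: missing dosages are mean-imputed per variant,
#' variants are centred and scaled by `sqrt(2 p (1 - p))`, and the sample
#' covariance of the standardized matrix is eigendecomposed.
#' `variance_explained` is each eigenvalue over the covariance trace.
#' Zero-variance variants are dropped with a message.
#'
#' @param g `geno_matrix`.
#' @param k number of components to return.
#' @return list with `coordinates` (samples x k score matrix),
#'   `variance_explained` (length-k fractions) and `k`.
#' @export
pca_structure <- function(g, k = 2L) {
  d <- g$dosages
  p <- allele_frequencies(g)$freq_alt
  ok <- !is.na(p) & p > 0 & p < 1
  if (any(!ok)) message(sum(!ok), " zero-variance/all-missing variant(s) dropped from PCA")
  d <- d[, ok, drop = FALSE]
  p <- p[ok]
  mu <- 2 * p
  sc <- sqrt(2 * p * (1 - p))
  x <- sweep(d, 2L, mu)
  x[is.na(x)] <- 0                       # mean imputation after centring
  x <- sweep(x, 2L, sc, "/")
  k <- min(k, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = (pc$sdev^2 / total_var)[seq_len(k)],
       k = k)
}
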