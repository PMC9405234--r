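#' r-squared from two-locus haplotype frequencies
#'
#' The squared correlation of allelic states,
#' `r2 = (P_AB * P_ab - P_Ab * P_aB)^2 / (P_A * P_a * P_B * P_b)`,
#' where the haplotype frequencies must sum to 1 and the allele frequencies
#' are their margins. A monomorphic locus makes r2 undefined (`NA`), never 0.
#'
#' @param p_AB,p_Ab,p_aB,p_ab haplotype frequencies (must sum to 1 within
#'   1e-9).
#' @return r-squared in [0, 1], or `NA` if a margin is 0 or 1.
#' @export
r2_from_haplotype_freqs <- function(p_AB, p_Ab, p_aB, p_ab) {
  tot <- p_AB + p_Ab + p_aB + p_ab
  if (abs(tot - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  pA <- p_AB + p_Ab; pB <- p_AB + p_aB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(NA_real_)
  d <- p_AB * p_ab - p_Ab * p_aB
  min(1, d * d / denom)
}

# Two-locus haplotype-frequency EM from diploid dosage vectors.
# Returns c(p_AB, p_Ab, p_aB, p_ab) with A/B = alt alleles at locus 1/2.
# Only double heterozygotes are phase-ambiguous; everything else contributes
# fixed haplotype counts.
em_two_locus <- function(gi, gj, max_iter = 100L, tol = 1e-10) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  if (n < 2L) return(rep(NA_real_, 4L))
  # fixed haplotype counts from unambiguous genotypes (per chromosome)
  # counts in order AB, Ab, aB, ab where A=alt@i, B=alt@j
  tab <- table(factor(gi, 0:2), factor(gj, 0:2))
  fixed <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  ndh <- tab[2, 2]                       # double heterozygotes
  h <- rep(0.25, 4L)
  for (iter in seq_len(max_iter)) {
    coup <- h[1] * h[4]
    repl <- h[2] * h[3]
    w <- if (coup + repl > 0) coup / (coup + repl) else 0.5
    counts <- fixed + ndh * c(w, 1 - w, 1 - w, w)
    h_new <- counts / sum(counts)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  h
}

#' r-squared between two loci from unphased genotypes
#'
#' Two estimators: `"composite"` is the squared Pearson correlation of the
#' dosage vectors over pairwise-complete samples (the usual PLINK `--r2`
#' behaviour for unphased data); `"em"` resolves double-heterozygote phase
#' with a two-locus EM and applies [r2_from_haplotype_freqs()] to the
#' estimated haplotype frequencies.
#'
#' @param gi,gj dosage vectors (0/1/2/NA) of equal length.
#' @param estimator `"composite"` or `"em"`.
#' @return r-squared in [0, 1]; `NA` when either locus is monomorphic among
#'   complete pairs or fewer than 2 complete pairs exist.
#' @export
r2_unphased <- function(gi, gj, estimator = c("composite", "em")) {
  estimator <- match.arg(estimator)
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2L) return(NA_real_)
  gi <- gi[ok]; gj <- gj[ok]
  if (stats::var(gi) == 0 || stats::var(gj) == 0) return(NA_real_)
  if (estimator == "composite") {
    min(1, stats::cor(gi, gj)^2)
  } else {
    h <- em_two_locus(gi, gj)
    r2_from_haplotype_freqs(h[1], h[2], h[3], h[4])
  }
}

#' LD window configuration
#'
#' Mirrors the windowed pairwise-r2 parameters of a PLINK `--r2` run:
#' pairs further apart than `max_snps_apart` variants or `max_kb` kilobases
#' are never formed, and when `report_r2_min` is non-`NULL` pairs with r2
#' below it are omitted from the output (this reporting filter conditions
#' any downstream mean r2 upward; disable it for unbiased decay or Ne work).
#'
#' @param max_snps_apart maximum index separation (default 99999).
#' @param max_kb maximum distance in kb (default 1000).
#' @param report_r2_min reporting threshold (default 0.2); `NULL` or `NA`
#'   disables it.
#' @param estimator unphased r2 estimator, `"composite"` or `"em"`.
#' @return an `ld_window_config` list.
#' @export
ld_window_config <- function(max_snps_apart = 99999L, max_kb = 1000,
                             report_r2_min = 0.2,
                             estimator = c("composite", "em")) {
  structure(list(max_snps_apart = as.integer(max_snps_apart),
                 max_kb = max_kb,
                 report_r2_min = if (is.null(report_r2_min) ||
                                     is.na(report_r2_min)) NULL
                                 else report_r2_min,
                 estimator = match.arg(estimator)),
            class = "ld_window_config")
}

#' Windowed pairwise r-squared
#'
#' Emits every intra-chromosomal SNP pair within the index and distance
#' windows of `cfg`, with its r2. Pairs whose r2 is undefined (monomorphic
#' locus) are dropped; when the reporting threshold is active, pairs with
#' r2 below it are omitted and counted.
#'
#' @param g `geno_matrix` (variants sorted by chrom, pos — guaranteed by the
#'   constructor).
#' @param cfg an [ld_window_config()].
#' @return data.frame with columns `chrom, vid_i, vid_j, pos_i, pos_j,
#'   distance_bp, r2`, plus attributes `n_pairs_formed` and `n_omitted`
#'   (below-threshold count).
#' @export
pairwise_ld <- function(g, cfg = ld_window_config()) {
  out <- list()
  n_formed <- 0L
  v <- g$variants
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    l <- length(idx)
    if (l < 2L) next
    pos <- v$pos[idx]
    d <- g$dosages[, idx, drop = FALSE]
    if (cfg$estimator == "composite" && !anyNA(d)) {
      # fast path: standardized crossproduct
      x <- scale(d)
      sd0 <- attr(x, "scaled:scale") == 0
      ii <- jj <- integer(0); rr <- numeric(0)
      for (i in seq_len(l - 1L)) {
        jmax <- i
        while (jmax < l && jmax - i < cfg$max_snps_apart &&
               pos[jmax + 1L] - pos[i] <= cfg$max_kb * 1000) jmax <- jmax + 1L
        if (jmax == i) next
        js <- seq(i + 1L, jmax)
        if (sd0[i]) next
        js <- js[!sd0[js]]
        if (!length(js)) next
        r <- crossprod(x[, i], x[, js, drop = FALSE])[1L, ] / (nrow(x) - 1L)
        ii <- c(ii, rep.int(i, length(js))); jj <- c(jj, js)
        rr <- c(rr, pmin(1, r * r))
      }
    } else {
      ii <- jj <- integer(0); rr <- numeric(0)
      for (i in seq_len(l - 1L)) {
        jmax <- i
        while (jmax < l && jmax - i < cfg$max_snps_apart &&
               pos[jmax + 1L] - pos[i] <= cfg$max_kb * 1000) jmax <- jmax + 1L
        if (jmax == i) next
        for (j in seq(i + 1L, jmax)) {
          r2 <- r2_unphased(d[, i], d[, j], cfg$estimator)
          if (is.na(r2)) next
          ii <- c(ii, i); jj <- c(jj, j); rr <- c(rr, r2)
        }
      }
    }
    if (!length(ii)) next
    n_formed <- n_formed + length(ii)
    out[[chr]] <- data.frame(
      chrom = chr,
      vid_i = v$vid[idx[ii]], vid_j = v$vid[idx[jj]],
      pos_i = pos[ii], pos_j = pos[jj],
      distance_bp = pos[jj] - pos[ii],
      r2 = rr, stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
           else data.frame(chrom = character(), vid_i = character(),
                           vid_j = character(), pos_i = integer(),
                           pos_j = integer(), distance_bp = integer(),
                           r2 = numeric())
  n_omitted <- 0L
  if (!is.null(cfg$report_r2_min)) {
    keep <- pairs$r2 >= cfg$report_r2_min
    n_omitted <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "n_pairs_formed") <- n_formed
  attr(pairs, "n_omitted") <- n_omitted
  pairs
}

#' Per-chromosome and genome-wide r-squared summary
#'
#' @param pairs data.frame from [pairwise_ld()].
#' @return data.frame `chrom, n_pairs, mean_r2, sd_r2, median_r2` with a
#'   final `"genome"` row over all pairs.
#' @export
chromosome_ld_summary <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(chrom = character(), n_pairs = integer(),
                      mean_r2 = numeric(), sd_r2 = numeric(),
                      median_r2 = numeric()))
  }
  one <- function(r2, label) {
    data.frame(chrom = label, n_pairs = length(r2), mean_r2 = mean(r2),
               sd_r2 = if (length(r2) >= 2L) stats::sd(r2) else NA_real_,
               median_r2 = stats::median(r2))
  }
  by_chr <- split(pairs$r2, pairs$chrom)
  rows <- Map(one, by_chr, names(by_chr))
  rbind(do.call(rbind, c(rows, make.row.names = FALSE)),
        one(pairs$r2, "genome"))
}

#' Distance-binned LD decay
#'
#' Bins SNP pairs by physical distance and reports mean and sd of r2 per
#' half-open bin `[lo, hi)` kb (last bin closed). The default granularities
#' are the conventional decay panels: 0-10 kb in 1-kb bins, 0-100 kb in
#' 10-kb bins and 0-1000 kb in 100-kb bins.
#'
#' @param pairs data.frame from [pairwise_ld()].
#' @param granularities list of `c(max_kb, bin_kb)` pairs.
#' @return data.frame `max_kb, bin_lo_kb, bin_hi_kb, n_pairs, mean_r2,
#'   sd_r2` (empty bins keep `n_pairs = 0` and `NA` statistics).
#' @export
ld_decay <- function(pairs,
                     granularities = list(c(10, 1), c(100, 10), c(1000, 100))) {
  res <- lapply(granularities, function(gr) {
    max_kb <- gr[1]; bin_kb <- gr[2]
    edges <- seq(0, max_kb, by = bin_kb)
    d_kb <- pairs$distance_bp / 1000
    sel <- d_kb <= max_kb
    idx <- findInterval(d_kb[sel], edges, rightmost.closed = TRUE)
    r2 <- pairs$r2[sel]
    nb <- length(edges) - 1L
    data.frame(
      max_kb = max_kb,
      bin_lo_kb = edges[-length(edges)],
      bin_hi_kb = edges[-1],
      n_pairs = tabulate(idx, nb),
      mean_r2 = vapply(seq_len(nb), function(b) {
        x <- r2[idx == b]; if (length(x)) mean(x) else NA_real_ }, numeric(1)),
      sd_r2 = vapply(seq_len(nb), function(b) {
        x <- r2[idx == b]
        if (length(x) >= 2L) stats::sd(x) else NA_real_ }, numeric(1)))
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Write an LD pair stream in the PLINK .ld column layout
#' @param pairs data.frame from [pairwise_ld()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_pairs <- function(pairs, path) {
  chr_i <- pairs$chrom
  utils::write.table(
    data.frame(CHR_A = chr_i, BP_A = pairs$pos_i, SNP_A = pairs$vid_i,
               CHR_B = chr_i, BP_B = pairs$pos_j, SNP_B = pairs$vid_j,
               R2 = pairs$r2),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an LD decay curve
#' @param decay data.frame from [ld_decay()] (one granularity recommended).
#' @return a ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  decay$mid_kb <- (decay$bin_lo_kb + decay$bin_hi_kb) / 2
  ggplot2::ggplot(decay[!is.na(decay$mean_r2), ],
                  ggplot2::aes(x = .data$mid_kb, y = .data$mean_r2,
                               colour = factor(.data$max_kb))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  colour = "panel (kb)") +
    ggplot2::theme_minimal()
}
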