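#' D-prime point estimate and likelihood-based confidence interval
#'
#' Computes |D'| for a pair of biallelic loci together with a 95% confidence
#' interval obtained by profiling the data likelihood over |D'| on a grid
#' (step 0.01), with allele frequencies fixed at their sample estimates and
#' the sign of D normalized to positive by relabelling one locus. For
#' unphased input the likelihood is over the nine genotype cells with the
#' double-heterozygote cell summing both phases (the Haploview approach);
#' for phased input it is multinomial over the four haplotype classes.
#' The CI bounds are the 5th and 95th percentiles of the normalized
#' likelihood mass on the grid.
#'
#' @param gi,gj dosage vectors (unphased) or haplotype 0/1 vectors
#'   (`phased = TRUE`).
#' @param phased whether `gi`/`gj` are per-haplotype alleles.
#' @return list `dprime, ci_lo, ci_hi` (all `NA` if a locus is monomorphic).
#' @export
dprime_ci <- function(gi, gj, phased = FALSE) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  und <- list(dprime = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  if (length(gi) < 2L) return(und)
  if (phased) {
    pA <- mean(gi); pB <- mean(gj)
  } else {
    pA <- mean(gi) / 2; pB <- mean(gj) / 2
  }
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(und)
  # point estimate of D
  if (phased) {
    pAB <- mean(gi == 1L & gj == 1L)
    D <- pAB - pA * pB
  } else {
    h <- em_two_locus(gi, gj)
    D <- h[1] - pA * pB
  }
  flip <- D < 0
  if (flip) { pB <- 1 - pB; D <- -D }    # relabel locus j alleles
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  if (dmax <= 0) return(und)
  grid <- seq(0, 1, by = 0.01)
  eps <- 1e-12
  hAB <- pA * pB + grid * dmax
  hAb <- pA * (1 - pB) - grid * dmax
  haB <- (1 - pA) * pB - grid * dmax
  hab <- (1 - pA) * (1 - pB) + grid * dmax
  hAB <- pmax(hAB, eps); hAb <- pmax(hAb, eps)
  haB <- pmax(haB, eps); hab <- pmax(hab, eps)
  if (phased) {
    b <- if (flip) 1L - gj else gj
    nAB <- sum(gi == 1L & b == 1L); nAb <- sum(gi == 1L & b == 0L)
    naB <- sum(gi == 0L & b == 1L); nab <- sum(gi == 0L & b == 0L)
    ll <- nAB * log(hAB) + nAb * log(hAb) + naB * log(haB) + nab * log(hab)
  } else {
    b <- if (flip) 2L - gj else gj
    tab <- table(factor(gi, 0:2), factor(b, 0:2))
    cell <- array(dim = c(3, 3, length(grid)))
    cell[3, 3, ] <- hAB^2;            cell[3, 2, ] <- 2 * hAB * hAb
    cell[3, 1, ] <- hAb^2
    cell[2, 3, ] <- 2 * hAB * haB
    cell[2, 2, ] <- 2 * (hAB * hab + hAb * haB)
    cell[2, 1, ] <- 2 * hAb * hab
    cell[1, 3, ] <- haB^2;            cell[1, 2, ] <- 2 * haB * hab
    cell[1, 1, ] <- hab^2
    ll <- numeric(length(grid))
    for (a in 1:3) for (bb in 1:3) {
      if (tab[a, bb] > 0) ll <- ll + tab[a, bb] * log(cell[a, bb, ])
    }
  }
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  list(dprime = min(1, D / dmax),
       ci_lo = grid[which(cum >= 0.05)[1L]],
       ci_hi = grid[which(cum >= 0.95)[1L]])
}

# Gabriel pair classification from a dprime_ci result.
# strong LD: ci_lo >= 0.70 and ci_hi >= 0.98; strong recombination:
# ci_hi < 0.90; anything else is uninformative.
.gabriel_class <- function(ci_lo, ci_hi,
                           strong_lo = 0.70, strong_hi = 0.98,
                           rec_hi = 0.90) {
  ifelse(is.na(ci_hi), NA_character_,
         ifelse(ci_hi < rec_hi, "rec",
                ifelse(ci_lo >= strong_lo & ci_hi >= strong_hi,
                       "strong", "uninf")))
}

#' Gabriel-definition haplotype block detection
#'
#' Detects haplotype blocks with the confidence-interval definition of
#' Gabriel et al. as implemented (with default constants) in Haploview:
#' markers with MAF < `search_maf_min` are excluded from the search; a pair
#' is in "strong LD" when its |D'| 95% CI has lower bound >= 0.70 and upper
#' bound >= 0.98, and shows "strong recombination" when the upper bound is
#' < 0.90. A marker span is a candidate block when its end-point pair is in
#' strong LD, it holds at least 3 usable markers, spans at most
#' `max_span_kb`, and at least 95% of its informative pairs (80% for
#' 3-marker spans) are strong-LD. Overlapping candidates are resolved
#' greedily by descending bp span (ties to the leftmost start). Blocks of
#' fewer than `min_snps` markers are discarded.
#'
#' @param x `haplo_matrix` (phased likelihood, exact block haplotype counts)
#'   or `geno_matrix` (EM-based).
#' @param max_span_kb maximum block span in kb (default 1000).
#' @param search_maf_min marker MAF floor inside the search (default 0.05,
#'   the Haploview default).
#' @param min_snps minimum markers per reported block (default 3; spurious
#'   2-SNP blocks are conventionally removed).
#' @param informative_frac strong-LD fraction required among informative
#'   pairs (default 0.95; 3-marker spans use `frac3`).
#' @param frac3 relaxation for 3-marker spans (default 0.80).
#' @return data.frame with one row per block: `chrom, start_bp, end_bp,
#'   n_snps, length_kb, vids` (comma-joined marker ids), plus a
#'   `haplotypes` list-column of per-block haplotype frequency tables.
#' @export
gabriel_blocks <- function(x, max_span_kb = 1000, search_maf_min = 0.05,
                           min_snps = 3L, informative_frac = 0.95,
                           frac3 = 0.80) {
  phased <- inherits(x, "haplo_matrix")
  g <- if (phased) as_genotypes(x) else x
  fr <- allele_frequencies(g)
  usable <- !is.na(fr$maf) & fr$maf >= search_maf_min
  blocks <- list()
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr & usable)
    l <- length(idx)
    if (l < min_snps) next
    pos <- g$variants$pos[idx]
    mat <- if (phased) x$haps[, idx, drop = FALSE]
           else g$dosages[, idx, drop = FALSE]
    # pairwise CI cache within the span window
    lo <- hi <- matrix(NA_real_, l, l)
    for (i in seq_len(l - 1L)) {
      for (j in seq(i + 1L, l)) {
        if (pos[j] - pos[i] > max_span_kb * 1000) break
        ci <- dprime_ci(mat[, i], mat[, j], phased = phased)
        lo[i, j] <- ci$ci_lo; hi[i, j] <- ci$ci_hi
      }
    }
    cls <- matrix(.gabriel_class(lo, hi), l, l)
    strong <- !is.na(cls) & cls == "strong"
    informative <- !is.na(cls) & cls != "uninf"
    # candidate end-point pairs
    cand <- which(strong, arr.ind = TRUE)
    cand <- cand[cand[, 2L] - cand[, 1L] >= min_snps - 1L, , drop = FALSE]
    if (!nrow(cand)) next
    span_bp <- pos[cand[, 2L]] - pos[cand[, 1L]]
    ord <- order(-span_bp, cand[, 1L])
    cand <- cand[ord, , drop = FALSE]
    taken <- rep(FALSE, l)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (any(taken[i:j])) next
      sub <- i:j
      ns <- sum(strong[sub, sub], na.rm = TRUE)
      ni <- sum(informative[sub, sub], na.rm = TRUE)
      if (ni == 0L) next
      need <- if (length(sub) == 3L) frac3 else informative_frac
      if (ns / ni < need) next
      taken[sub] <- TRUE
      hfreq <- block_haplotype_freqs(mat[, sub, drop = FALSE], phased = phased)
      blocks[[length(blocks) + 1L]] <- list(
        chrom = chr, start_bp = pos[i], end_bp = pos[j],
        n_snps = length(sub),
        vids = paste(g$variants$vid[idx[sub]], collapse = ","),
        haplotypes = hfreq)
    }
  }
  if (!length(blocks)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      length_kb = numeric(), vids = character()))
  }
  out <- data.frame(
    chrom = vapply(blocks, `[[`, "", "chrom"),
    start_bp = as.integer(vapply(blocks, `[[`, 0, "start_bp")),
    end_bp = as.integer(vapply(blocks, `[[`, 0, "end_bp")),
    n_snps = vapply(blocks, `[[`, 0L, "n_snps"),
    vids = vapply(blocks, `[[`, "", "vids"),
    stringsAsFactors = FALSE)
  out$length_kb <- (out$end_bp - out$start_bp) / 1000
  out$haplotypes <- lapply(blocks, `[[`, "haplotypes")
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-block haplotype frequencies
#'
#' For phased input, observed haplotype strings are counted directly. For
#' unphased input a full-enumeration multi-locus EM over phase-consistent
#' haplotype pairs is run (50 iterations or log-likelihood change < 1e-6);
#' blocks wider than `max_em_snps` markers return `NULL` because the
#' enumeration grows exponentially.
#'
#' @param mat haplotypes x markers (phased) or samples x markers (dosages).
#' @param phased interpretation of `mat`.
#' @param max_em_snps widest unphased block the EM will attempt.
#' @return named numeric vector of haplotype frequencies (names are allele
#'   strings), or `NULL` when not computable.
#' @export
block_haplotype_freqs <- function(mat, phased, max_em_snps = 10L) {
  if (phased) {
    s <- apply(mat, 1L, paste, collapse = "")
    tab <- sort(table(s), decreasing = TRUE)
    return(tab / sum(tab))
  }
  k <- ncol(mat)
  if (k > max_em_snps) return(NULL)
  cc <- stats::complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  if (!nrow(mat)) return(NULL)
  # enumerate compatible ordered haplotype pairs per individual
  pair_list <- apply(mat, 1L, function(gen) {
    het <- which(gen == 1L)
    base <- ifelse(gen == 2L, 1L, 0L)
    if (!length(het)) return(matrix(c(base, base), nrow = 1L,
                                    dimnames = NULL, byrow = TRUE))
    combos <- as.matrix(expand.grid(rep(list(0:1), length(het))))
    t(apply(combos, 1L, function(cmb) {
      h1 <- base; h1[het] <- cmb
      h2 <- base; h2[het] <- 1L - cmb
      c(h1, h2)
    }))
  }, simplify = FALSE)
  key <- function(h) apply(h, 1L, paste, collapse = "")
  all_h <- unique(unlist(lapply(pair_list, function(p)
    c(key(p[, 1:k, drop = FALSE]), key(p[, (k + 1):(2 * k), drop = FALSE])))))
  f <- stats::setNames(rep(1 / length(all_h), length(all_h)), all_h)
  ll_old <- -Inf
  for (iter in 1:50) {
    cnt <- stats::setNames(numeric(length(all_h)), all_h)
    ll <- 0
    for (p in pair_list) {
      k1 <- key(p[, 1:k, drop = FALSE]); k2 <- key(p[, (k + 1):(2 * k), drop = FALSE])
      w <- f[k1] * f[k2]
      sw <- sum(w)
      ll <- ll + log(max(sw, 1e-300))
      w <- w / max(sw, 1e-300)
      for (q in seq_along(w)) {
        cnt[k1[q]] <- cnt[k1[q]] + w[q]
        cnt[k2[q]] <- cnt[k2[q]] + w[q]
      }
    }
    f <- cnt / sum(cnt)
    if (abs(ll - ll_old) < 1e-6) break
    ll_old <- ll
  }
  sort(f[f > 1e-6], decreasing = TRUE) / sum(f[f > 1e-6])
}

#' Block-set summary statistics
#'
#' @param blocks data.frame from [gabriel_blocks()].
#' @param genome_extent data.frame `chrom, start_bp, end_bp` giving the
#'   analyzed span per chromosome (conventionally first to last retained
#'   SNP), the denominator of the genome-coverage percentage.
#' @param n_snps_total total retained SNPs, for the percent-in-blocks
#'   statistic (optional).
#' @return one-row data.frame with block counts, total length (Mb), percent
#'   genome coverage, length and SNP-count summaries, and
#'   `haplotype_frequency_mean` (mean over blocks of the mean frequency of
#'   that block's observed haplotypes; reported for convention, no single
#'   standard definition exists).
#' @export
block_summary <- function(blocks, genome_extent, n_snps_total = NA_integer_) {
  extent_bp <- sum(genome_extent$end_bp - genome_extent$start_bp)
  if (!nrow(blocks)) {
    return(data.frame(n_blocks = 0L, total_length_mb = 0,
                      pct_genome_coverage = 0, mean_length_kb = NA_real_,
                      median_length_kb = NA_real_, max_length_kb = NA_real_,
                      n_snps_in_blocks = 0L, pct_snps_in_blocks = NA_real_,
                      mean_snps_per_block = NA_real_,
                      max_snps_per_block = NA_integer_,
                      haplotype_frequency_mean = NA_real_))
  }
  len_bp <- blocks$end_bp - blocks$start_bp
  hmean <- vapply(blocks$haplotypes %||% list(), function(h)
    if (is.null(h)) NA_real_ else mean(h), numeric(1))
  data.frame(
    n_blocks = nrow(blocks),
    total_length_mb = sum(len_bp) / 1e6,
    pct_genome_coverage = 100 * sum(len_bp) / extent_bp,
    mean_length_kb = mean(len_bp) / 1000,
    median_length_kb = stats::median(len_bp) / 1000,
    max_length_kb = max(len_bp) / 1000,
    n_snps_in_blocks = sum(blocks$n_snps),
    pct_snps_in_blocks = if (is.na(n_snps_total)) NA_real_
                         else 100 * sum(blocks$n_snps) / n_snps_total,
    mean_snps_per_block = mean(blocks$n_snps),
    max_snps_per_block = max(blocks$n_snps),
    haplotype_frequency_mean = mean(hmean, na.rm = TRUE))
}

#' Shared and unique blocks between two populations
#'
#' A block is "shared" when it overlaps a block of the other population on
#' the same chromosome by at least `min_overlap_bp` base pairs (optionally
#' also by a minimum fraction of its own length); otherwise it is unique to
#' its population.
#'
#' @param blocks_a,blocks_b block data.frames from [gabriel_blocks()].
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param min_overlap_frac optional minimum overlap as a fraction of the
#'   query block's length (default 0 = any).
#' @return list with counts `shared_a, shared_b, unique_a, unique_b` and the
#'   corresponding interval data.frames.
#' @export
shared_unique_blocks <- function(blocks_a, blocks_b, min_overlap_bp = 1L,
                                 min_overlap_frac = 0) {
  gr <- function(b) GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start_bp, b$end_bp))
  if (!nrow(blocks_a) || !nrow(blocks_b)) {
    return(list(shared_a = 0L, shared_b = 0L,
                unique_a = nrow(blocks_a), unique_b = nrow(blocks_b),
                shared_a_blocks = blocks_a[0, ], shared_b_blocks = blocks_b[0, ],
                unique_a_blocks = blocks_a, unique_b_blocks = blocks_b))
  }
  ga <- gr(blocks_a); gb <- gr(blocks_b)
  ov <- GenomicRanges::findOverlaps(ga, gb,
                                    minoverlap = as.integer(min_overlap_bp))
  if (min_overlap_frac > 0 && length(ov)) {
    w <- IRanges::width(IRanges::pintersect(ga[S4Vectors::queryHits(ov)],
                                            gb[S4Vectors::subjectHits(ov)]))
    keep <- w / IRanges::width(ga[S4Vectors::queryHits(ov)]) >= min_overlap_frac
    ov <- ov[keep]
  }
  sa <- unique(S4Vectors::queryHits(ov))
  sb <- unique(S4Vectors::subjectHits(ov))
  list(shared_a = length(sa), shared_b = length(sb),
       unique_a = nrow(blocks_a) - length(sa),
       unique_b = nrow(blocks_b) - length(sb),
       shared_a_blocks = blocks_a[sa, , drop = FALSE],
       shared_b_blocks = blocks_b[sb, , drop = FALSE],
       unique_a_blocks = blocks_a[setdiff(seq_len(nrow(blocks_a)), sa), , drop = FALSE],
       unique_b_blocks = blocks_b[setdiff(seq_len(nrow(blocks_b)), sb), , drop = FALSE])
}

#' Export blocks as BED (0-based half-open)
#' @param blocks data.frame from [gabriel_blocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  utils::write.table(
    data.frame(blocks$chrom, blocks$start_bp - 1L, blocks$end_bp,
               paste0("block_", seq_len(nrow(blocks))), blocks$n_snps),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
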