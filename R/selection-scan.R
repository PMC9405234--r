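#' Selection-scan configuration
#'
#' Parameters shared by the EHH, iHS and XP-EHH machinery.
#'
#' @param min_ehh truncation floor: EHH integration stops after the first
#'   point below this value (default 0.05).
#' @param max_gap_kb maximum allowed gap between adjacent SNPs; integration
#'   stops (hard) before a larger gap (default 500).
#' @param min_maf derived-allele frequency window for iHS cores is
#'   `[min_maf, 1 - min_maf]` (default 0.05).
#' @param freq_bins number of equal-width derived-allele-frequency bins for
#'   iHS standardization (default 50, width 0.02).
#' @param min_bin_snps adjacent frequency bins are merged until each
#'   standardization group holds at least this many scored SNPs (default
#'   20); sparse bins would otherwise standardize a SNP against only its
#'   own close neighbours and erase real signal.
#' @param window_kb candidate-window width (default 1000).
#' @param window_step_kb window step; the default 990 makes adjacent 1-Mb
#'   windows overlap by 10 kb.
#' @param window_min_snps windows with fewer scored SNPs are dropped
#'   (default 10).
#' @param extreme_rule how a SNP qualifies as "extreme" for window
#'   density: `"pihs"` (piHS at or above `extreme_pihs_min`; default),
#'   `"abs"` (|iHS| at or above `extreme_abs_ihs`) or `"top_pct"` (the
#'   genome-wide top `extreme_top_snp_pct` percent of |iHS|, the SNP-level
#'   candidate convention for chip scans).
#' @param extreme_pihs_min piHS cutoff for `extreme_rule = "pihs"`
#'   (default 3, i.e. two-sided p <= 0.001).
#' @param extreme_abs_ihs |iHS| cutoff for `extreme_rule = "abs"`
#'   (default 3).
#' @param extreme_top_snp_pct percent of scored SNPs flagged under
#'   `extreme_rule = "top_pct"` (default 1).
#' @param window_top_pct percent of windows (by extreme-SNP density) called
#'   candidates (default 1).
#' @param xpehh_min standardized XP-EHH threshold (default 4.0).
#' @param xpehh_min_run minimum consecutive above-threshold SNPs for an
#'   XP-EHH candidate run (default 3).
#' @return a `scan_config` list.
#' @export
scan_config <- function(min_ehh = 0.05, max_gap_kb = 500, min_maf = 0.05,
                        freq_bins = 50L, min_bin_snps = 20L,
                        window_kb = 1000,
                        window_step_kb = 990, window_min_snps = 10L,
                        extreme_rule = c("pihs", "abs", "top_pct"),
                        extreme_pihs_min = 3, extreme_abs_ihs = 3,
                        extreme_top_snp_pct = 1,
                        window_top_pct = 1, xpehh_min = 4,
                        xpehh_min_run = 3L) {
  structure(list(min_ehh = min_ehh, max_gap_kb = max_gap_kb,
                 min_maf = min_maf, freq_bins = as.integer(freq_bins),
                 min_bin_snps = as.integer(min_bin_snps),
                 window_kb = window_kb, window_step_kb = window_step_kb,
                 window_min_snps = as.integer(window_min_snps),
                 extreme_rule = match.arg(extreme_rule),
                 extreme_pihs_min = extreme_pihs_min,
                 extreme_abs_ihs = extreme_abs_ihs,
                 extreme_top_snp_pct = extreme_top_snp_pct,
                 window_top_pct = window_top_pct, xpehh_min = xpehh_min,
                 xpehh_min_run = as.integer(xpehh_min_run)),
            class = "scan_config")
}

# derived allele code (0/1 in the hap matrix) per variant; ancestral
# defaults to ref with a loud warning when unknown
.derived_code <- function(variants) {
  anc <- variants$ancestral
  if (anyNA(anc)) {
    warning("ancestral allele unknown for ", sum(is.na(anc)),
            " variant(s); assuming ref is ancestral")
    anc[is.na(anc)] <- "ref"
  }
  ifelse(anc == "ref", 1L, 0L)           # hap value carrying the derived allele
}

#' Extended haplotype homozygosity profile
#'
#' EHH around a core SNP for the carriers of one core allele: at each SNP
#' moving outward, the probability that two random carrier haplotypes are
#' identical over the whole stretch from the core. EHH equals 1 at the core
#' and is non-increasing outward. Computation truncates after the first
#' point with EHH below `cfg$min_ehh` and stops at gaps larger than
#' `cfg$max_gap_kb`.
#'
#' @param h `haplo_matrix` (single chromosome for the scanned region).
#' @param core_vid core variant id.
#' @param allele `"ancestral"`, `"derived"`, or `"all"` (pooled site EHH:
#'   all haplotypes, partitioned by the core allele itself, so the core
#'   value is the core-site homozygosity rather than 1).
#' @param cfg a [scan_config()].
#' @return list of class `ehh_profile` with `core_vid`, `allele`,
#'   `core_pos`, and data.frame `profile` (`pos`, `ehh`, `side`).
#' @export
ehh <- function(h, core_vid, allele = c("derived", "ancestral", "all"),
                cfg = scan_config()) {
  allele <- match.arg(allele)
  core <- match(core_vid, h$variants$vid)
  if (is.na(core)) stop("unknown core variant ", core_vid)
  chr <- h$variants$chrom[core]
  if (!all(h$variants$chrom == chr)) {
    idx <- which(h$variants$chrom == chr)
    h <- keep_variants(h, idx)
    core <- match(core_vid, h$variants$vid)
  }
  if (allele == "all") {
    carriers <- seq_len(nrow(h$haps))
    split_core <- TRUE
  } else {
    der <- .derived_code(h$variants)[core]
    want <- if (allele == "derived") der else 1L - der
    carriers <- which(h$haps[, core] == want)
    split_core <- FALSE
  }
  if (length(carriers) < 2L) {
    return(NULL)                         # undefined; caller logs the skip
  }
  pr <- ehh_profile_cpp(h$haps, as.numeric(h$variants$pos), core - 1L,
                        carriers - 1L, cfg$min_ehh, cfg$max_gap_kb * 1000,
                        split_core)
  profile <- rbind(
    data.frame(pos = rev(pr$pos_left), ehh = rev(pr$ehh_left),
               side = "left")[-length(pr$pos_left), , drop = FALSE],
    data.frame(pos = pr$pos_right, ehh = pr$ehh_right, side = "right"))
  structure(list(core_vid = core_vid, allele = allele,
                 core_pos = h$variants$pos[core], profile = profile,
                 raw = pr),
            class = "ehh_profile")
}

#' Integrated EHH
#'
#' Trapezoidal integral of an EHH profile over physical distance (bp),
#' summed over the two directions away from the core. Integration stops at
#' the profile's truncation points. A profile with flanking points on only
#' one side is integrated one-sided.
#'
#' @param profile an `ehh_profile` from [ehh()].
#' @return iHH in bp x homozygosity units.
#' @export
ihh <- function(profile) {
  tr <- function(pos, e) {
    if (length(pos) < 2L) return(0)
    sum(abs(diff(pos)) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
  }
  tr(profile$raw$pos_left, profile$raw$ehh_left) +
    tr(profile$raw$pos_right, profile$raw$ehh_right)
}

#' Two-sided neutrality p transform of iHS
#'
#' `piHS = -log10(1 - 2 |Phi(iHS) - 0.5|) = -log10(2 Phi(-|iHS|))`, the
#' -log10 two-sided p-value of the standardized score under the standard
#' normal neutral reference. Even in iHS and strictly increasing in |iHS|.
#'
#' @param ihs standardized iHS value(s).
#' @return piHS value(s).
#' @export
pihs <- function(ihs) {
  -(log(2) + stats::pnorm(abs(ihs), lower.tail = FALSE, log.p = TRUE)) / log(10)
}

#' Genome-wide iHS scan
#'
#' For every SNP whose derived-allele frequency lies in
#' `[min_maf, 1 - min_maf]`, computes the integrated EHH for the ancestral
#' (`iHH_A`) and derived (`iHH_D`) core alleles and the unstandardized score
#' `uniHS = ln(iHH_A / iHH_D)`. Scores are standardized to mean 0, sd 1
#' within equal-width derived-allele-frequency bins, and transformed to
#' piHS. SNPs with fewer than 2 carriers of either allele, zero iHH on
#' either side, or a standardization bin of fewer than 2 SNPs get `NA`
#' scores and are excluded from standardization.
#'
#' @param h `haplo_matrix` with known (or ref-assumed) ancestral alleles.
#' @param cfg a [scan_config()].
#' @return data.frame `chrom, pos, vid, freq_derived, ihh_a, ihh_d, unihs,
#'   ihs, pihs`.
#' @export
ihs_scan <- function(h, cfg = scan_config()) {
  der <- .derived_code(h$variants)
  n_hap <- nrow(h$haps)
  freq_der <- vapply(seq_len(ncol(h$haps)), function(j)
    mean(h$haps[, j] == der[j]), numeric(1))
  res <- data.frame(chrom = h$variants$chrom, pos = h$variants$pos,
                    vid = h$variants$vid, freq_derived = freq_der,
                    ihh_a = NA_real_, ihh_d = NA_real_, unihs = NA_real_,
                    stringsAsFactors = FALSE)
  eligible <- freq_der >= cfg$min_maf & freq_der <= 1 - cfg$min_maf
  by_chr <- split(which(eligible), h$variants$chrom[eligible])
  for (chr in names(by_chr)) {
    idx_chr <- which(h$variants$chrom == chr)
    hc <- keep_variants(h, idx_chr)
    pos_chr <- as.numeric(hc$variants$pos)
    der_chr <- der[idx_chr]
    for (jj in by_chr[[chr]]) {
      j_loc <- match(jj, idx_chr)
      car_d <- which(hc$haps[, j_loc] == der_chr[j_loc])
      car_a <- setdiff(seq_len(n_hap), car_d)
      if (length(car_d) < 2L || length(car_a) < 2L) next
      pd <- ehh_profile_cpp(hc$haps, pos_chr, j_loc - 1L, car_d - 1L,
                            cfg$min_ehh, cfg$max_gap_kb * 1000, FALSE)
      pa <- ehh_profile_cpp(hc$haps, pos_chr, j_loc - 1L, car_a - 1L,
                            cfg$min_ehh, cfg$max_gap_kb * 1000, FALSE)
      tr <- function(pr) {
        f <- function(pos, e) if (length(pos) < 2L) 0 else
          sum(abs(diff(pos)) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
        f(pr$pos_left, pr$ehh_left) + f(pr$pos_right, pr$ehh_right)
      }
      res$ihh_d[jj] <- tr(pd)
      res$ihh_a[jj] <- tr(pa)
    }
  }
  ok <- !is.na(res$ihh_a) & !is.na(res$ihh_d) & res$ihh_a > 0 & res$ihh_d > 0
  res$unihs[ok] <- log(res$ihh_a[ok] / res$ihh_d[ok])
  # frequency-binned standardization with sparse-bin merging
  edges <- seq(0, 1, length.out = cfg$freq_bins + 1L)
  bin <- findInterval(res$freq_derived, edges, rightmost.closed = TRUE)
  grp <- .merge_sparse_bins(bin[ok], cfg$min_bin_snps)
  res$ihs <- NA_real_
  u <- res$unihs[ok]
  z <- rep(NA_real_, length(u))
  for (b in unique(grp)) {
    in_b <- grp == b
    if (sum(in_b) < 2L) next
    sdv <- stats::sd(u[in_b])
    if (sdv > 0) z[in_b] <- (u[in_b] - mean(u[in_b])) / sdv
  }
  res$ihs[ok] <- z
  res$pihs <- pihs(res$ihs)
  attr(res, "standardization_groups") <- grp
  res
}

# merge adjacent frequency bins (ordered by bin index) until every group
# holds at least min_n SNPs; a trailing short group is merged backwards
.merge_sparse_bins <- function(bin, min_n) {
  ub <- sort(unique(bin))
  counts <- as.integer(table(factor(bin, ub)))
  grp_of <- integer(length(ub))
  g <- 1L; acc <- 0L
  for (i in seq_along(ub)) {
    grp_of[i] <- g
    acc <- acc + counts[i]
    if (acc >= min_n && i < length(ub)) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0L && acc < min_n && g > 1L) {
    grp_of[grp_of == g] <- g - 1L        # fold a short tail into the last group
  }
  grp_of[match(bin, ub)]
}

#' Candidate selection windows from iHS scores
#'
#' Tiles each chromosome with windows of `window_kb` kb starting at 0 and
#' advancing by `window_step_kb` kb (defaults make adjacent 1-Mb windows
#' overlap by 10 kb). Windows with fewer than `window_min_snps` scored SNPs
#' are dropped. A SNP is extreme under `cfg$extreme_rule`: a fixed piHS
#' threshold (default), a fixed |iHS| threshold, or the genome-wide top
#' percentile of |iHS|; windows are ranked by the density of extreme SNPs
#' and the top `window_top_pct` percent (at least one) are flagged
#' candidates.
#'
#' @param scores data.frame from [ihs_scan()].
#' @param cfg a [scan_config()].
#' @return data.frame `chrom, start_bp, end_bp, n_snps, n_extreme, density,
#'   rank_pct, candidate`, with attribute `n_extreme_total` (0 means the
#'   candidate set is only a rank ordering, not evidence of selection).
#' @export
candidate_windows <- function(scores, cfg = scan_config()) {
  scored <- scores[!is.na(scores$ihs), , drop = FALSE]
  extreme <- switch(cfg$extreme_rule,
    pihs = scored$pihs >= cfg$extreme_pihs_min,
    abs = abs(scored$ihs) >= cfg$extreme_abs_ihs,
    top_pct = abs(scored$ihs) >= stats::quantile(
      abs(scored$ihs), 1 - cfg$extreme_top_snp_pct / 100, names = FALSE))
  rows <- list()
  for (chr in unique(scored$chrom)) {
    s <- scored$chrom == chr
    pos <- scored$pos[s]; ext <- extreme[s]
    w_bp <- cfg$window_kb * 1000; step_bp <- cfg$window_step_kb * 1000
    starts <- seq(0, max(pos), by = step_bp)
    for (st in starts) {
      in_w <- pos > st & pos <= st + w_bp
      n <- sum(in_w)
      if (n < cfg$window_min_snps) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start_bp = st + 1, end_bp = st + w_bp,
        n_snps = n, n_extreme = sum(ext[in_w]))
    }
  }
  if (!length(rows)) {
    out <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      n_extreme = integer(), density = numeric(),
                      rank_pct = numeric(), candidate = logical())
    attr(out, "n_extreme_total") <- 0L
    return(out)
  }
  out <- do.call(rbind, rows)
  out$density <- out$n_extreme / out$n_snps
  out$rank_pct <- 100 * rank(-out$density, ties.method = "min") / nrow(out)
  n_cand <- max(1L, ceiling(nrow(out) * cfg$window_top_pct / 100))
  ord <- order(-out$density, out$chrom, out$start_bp)
  out$candidate <- FALSE
  out$candidate[ord[seq_len(n_cand)]] <- TRUE
  attr(out, "n_extreme_total") <- sum(out$n_extreme)
  out
}

#' Cross-population XP-EHH scan
#'
#' For every SNP present in both populations, integrates the allele-pooled
#' site EHHS (all haplotypes, partitioned by the core allele, normalized to
#' 1 at the core site) per population and forms
#' `raw = ln(iHH_pop1 / iHH_pop2)`; raw scores are standardized genome-wide
#' (mean 0, sd 1). The core-site normalization removes core-frequency
#' variance from the raw scores, as in the usual XP-EHH implementations. Positive extremes mark haplotypes unusually
#' extended in population 1. Candidates are runs of at least
#' `xpehh_min_run` consecutive SNPs with standardized score above
#' `xpehh_min`; negative-tail runs (selection in population 2) are reported
#' symmetrically.
#'
#' @param h1,h2 `haplo_matrix` objects with identical variant sets.
#' @param cfg a [scan_config()].
#' @return list with `scores` (data.frame `chrom, pos, vid, ihh_pop1,
#'   ihh_pop2, raw, xpehh`) and `runs` (data.frame `chrom, start_bp, end_bp,
#'   n_snps, direction`).
#' @export
xpehh_scan <- function(h1, h2, cfg = scan_config()) {
  if (!identical(h1$variants$vid, h2$variants$vid)) {
    stop("populations must share an identical variant set")
  }
  v <- h1$variants
  pooled_ihh <- function(h) {
    out <- rep(NA_real_, nrow(v))
    nh <- nrow(h$haps)
    cc2 <- nh * (nh - 1) / 2
    for (chr in unique(v$chrom)) {
      idx <- which(v$chrom == chr)
      hc <- keep_variants(h, idx)
      pos_chr <- as.numeric(hc$variants$pos)
      all_car <- seq_len(nh) - 1L
      for (j in seq_along(idx)) {
        n1 <- sum(hc$haps[, j])
        core_h <- (n1 * (n1 - 1) / 2 + (nh - n1) * (nh - n1 - 1) / 2) / cc2
        # EHHS truncation floor applies to the core-normalized statistic
        pr <- ehh_profile_cpp(hc$haps, pos_chr, j - 1L, all_car,
                              cfg$min_ehh * core_h, cfg$max_gap_kb * 1000,
                              TRUE)
        f <- function(pos, e) if (length(pos) < 2L) 0 else
          sum(abs(diff(pos)) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
        out[idx[j]] <- (f(pr$pos_left, pr$ehh_left) +
                        f(pr$pos_right, pr$ehh_right)) / core_h
      }
    }
    out
  }
  i1 <- pooled_ihh(h1)
  i2 <- pooled_ihh(h2)
  ok <- !is.na(i1) & !is.na(i2) & i1 > 0 & i2 > 0
  raw <- rep(NA_real_, nrow(v))
  raw[ok] <- log(i1[ok] / i2[ok])
  mu <- mean(raw[ok]); sdv <- stats::sd(raw[ok])
  xp <- (raw - mu) / sdv
  scores <- data.frame(chrom = v$chrom, pos = v$pos, vid = v$vid,
                       ihh_pop1 = i1, ihh_pop2 = i2, raw = raw, xpehh = xp,
                       stringsAsFactors = FALSE)
  runs <- rbind(
    .score_runs(scores, scores$xpehh >= cfg$xpehh_min, cfg$xpehh_min_run,
                "pop1"),
    .score_runs(scores, scores$xpehh <= -cfg$xpehh_min, cfg$xpehh_min_run,
                "pop2"))
  list(scores = scores, runs = runs)
}

# consecutive-SNP runs of a logical condition, per chromosome
.score_runs <- function(scores, cond, min_run, direction) {
  cond[is.na(cond)] <- FALSE
  rows <- list()
  for (chr in unique(scores$chrom)) {
    s <- which(scores$chrom == chr)
    r <- rle(cond[s])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      i <- s[starts[k]]; j <- s[ends[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start_bp = scores$pos[i], end_bp = scores$pos[j],
        n_snps = ends[k] - starts[k] + 1L, direction = direction)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      direction = character()))
  }
  do.call(rbind, rows)
}

#' Manhattan-style plot of a per-SNP score
#' @param scores data.frame with `chrom, pos` and the column named in `y`.
#' @param y column to plot (default `"pihs"`).
#' @param threshold optional horizontal reference line.
#' @return a ggplot object.
#' @export
plot_scan <- function(scores, y = "pihs", threshold = NULL) {
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data[[y]],
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = y) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) p <- p + ggplot2::geom_hline(yintercept = threshold,
                                                        linetype = 2)
  p
}
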