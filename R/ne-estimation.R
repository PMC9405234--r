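#' Configuration for LD-based effective population size
#'
#' Parameters of the expected-r2 inversion
#' `Ne(t) = (1 / (4 c)) * (1 / E[r2_adj | c] - alpha)` with the distance of a
#' pair mapped to a recombination fraction `c` and to time
#' `t = 1 / (2 c)` generations ago.
#'
#' @param alpha mutation correction constant; 1 (none, the default), 2 or
#'   2.2 are the conventional choices.
#' @param phase_known if `TRUE` the sample-size correction uses beta = 2
#'   (gametic phase known); default `FALSE` (beta = 1), appropriate for
#'   unphased chip genotypes.
#' @param max_distance_kb pairs beyond this distance are ignored
#'   (default 4000).
#' @param min_distance_kb pairs closer than this are ignored (default 50;
#'   very short ranges reflect mutation-age effects more than drift).
#' @param recomb_rate Morgans per bp (default 1e-8 = 1 cM/Mb).
#' @param n_bins number of log-spaced distance bins (default 30).
#' @param mapping distance-to-c mapping: `"linear"` (c = d * rate) or
#'   `"sved"` (c = d r / (2 (1 - d r))), both capped at 0.5.
#' @param bin_time `"harmonic"` (bin representative distance = harmonic mean
#'   of its pair distances, default) or `"midpoint"`.
#' @param min_maf MAF floor for pairs entering the estimate (default 0.05).
#' @return an `ne_config` list.
#' @export
ne_config <- function(alpha = 1, phase_known = FALSE, max_distance_kb = 4000,
                      min_distance_kb = 50, recomb_rate = 1e-8, n_bins = 30L,
                      mapping = c("linear", "sved"),
                      bin_time = c("harmonic", "midpoint"), min_maf = 0.05) {
  stopifnot(alpha > 0, recomb_rate > 0, max_distance_kb > min_distance_kb)
  structure(list(alpha = alpha, beta = if (phase_known) 2 else 1,
                 max_distance_kb = max_distance_kb,
                 min_distance_kb = min_distance_kb,
                 recomb_rate = recomb_rate, n_bins = as.integer(n_bins),
                 mapping = match.arg(mapping),
                 bin_time = match.arg(bin_time), min_maf = min_maf),
            class = "ne_config")
}

#' Sample-size adjustment of r-squared
#'
#' `r2_adj = r2 - 1 / (beta * n)`, with beta = 2 when the gametic phase is
#' known and beta = 1 when it is not. Negative values are kept; they are
#' averaged away at the bin level.
#'
#' @param r2 raw r-squared value(s).
#' @param n number of diploid individuals.
#' @param beta 1 or 2.
#' @return adjusted r-squared.
#' @export
adjust_r2 <- function(r2, n, beta = 1) {
  stopifnot(n >= 2, beta %in% c(1, 2))
  r2 - 1 / (beta * n)
}

#' Map a physical distance to a recombination fraction
#'
#' @param d_bp distance in bp (> 0).
#' @param recomb_rate Morgans per bp.
#' @param mapping `"linear"`: `c = d * rate`; `"sved"`:
#'   `c = d r / (2 (1 - d r))`. Both capped at 0.5.
#' @return recombination fraction in (0, 0.5].
#' @export
distance_to_c <- function(d_bp, recomb_rate = 1e-8,
                          mapping = c("linear", "sved")) {
  mapping <- match.arg(mapping)
  stopifnot(all(d_bp > 0))
  m <- d_bp * recomb_rate
  c_val <- switch(mapping,
                  linear = m,
                  sved = m / (2 * (1 - pmin(m, 1 - 1e-9))))
  pmin(c_val, 0.5)
}

#' Historical effective population size from binned LD
#'
#' Bins SNP pairs by distance, maps each bin to a recombination fraction
#' `c` and a time `t = 1/(2c)` generations ago, and inverts the drift
#' expectation `E[r2_adj] = 1 / (alpha + 4 Ne c)` to
#' `Ne = (1/(4c)) (1/E[r2_adj] - alpha)`. The pair stream must carry
#' r-squared values computed WITHOUT any reporting threshold: conditioning
#' on large r2 biases E[r2] and hence Ne.
#'
#' @param pairs data.frame from [pairwise_ld()] run with
#'   `report_r2_min = NULL` (the function stops if the threshold attribute
#'   shows omitted pairs); columns `distance_bp` and `r2` are used.
#' @param n number of diploid individuals behind the r2 values.
#' @param cfg an [ne_config()].
#' @return data.frame sorted by `t`: `t` (generations ago), `c_t`,
#'   `mean_r2_adj`, `n_pairs`, `ne`, and a logical `valid` flag
#'   (`FALSE` where `E[r2_adj] <= 1/alpha * (1 + eps)` makes the inversion
#'   non-positive, or where the bin is empty).
#' @export
ne_trajectory <- function(pairs, n, cfg = ne_config()) {
  if (!is.null(attr(pairs, "n_omitted")) && attr(pairs, "n_omitted") > 0L) {
    stop("pair stream was r2-thresholded; recompute with report_r2_min = NULL")
  }
  d <- pairs$distance_bp
  sel <- d >= cfg$min_distance_kb * 1000 & d <= cfg$max_distance_kb * 1000
  d <- d[sel]
  r2a <- adjust_r2(pairs$r2[sel], n, cfg$beta)
  edges <- exp(seq(log(cfg$min_distance_kb * 1000),
                   log(cfg$max_distance_kb * 1000),
                   length.out = cfg$n_bins + 1L))
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(cfg$n_bins), function(b) {
    in_bin <- idx == b
    np <- sum(in_bin)
    if (np == 0L) return(NULL)           # empty bin skipped
    d_rep <- switch(cfg$bin_time,
                    harmonic = 1 / mean(1 / d[in_bin]),
                    midpoint = (edges[b] + edges[b + 1L]) / 2)
    c_t <- distance_to_c(d_rep, cfg$recomb_rate, cfg$mapping)
    m <- mean(r2a[in_bin])
    valid <- is.finite(m) && m > 0 && (1 / m - cfg$alpha) > 0
    data.frame(t = 1 / (2 * c_t), c_t = c_t, mean_r2_adj = m,
               n_pairs = np,
               ne = if (valid) (1 / (4 * c_t)) * (1 / m - cfg$alpha)
                    else NA_real_,
               valid = valid)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot an Ne trajectory
#' @param traj data.frame from [ne_trajectory()].
#' @return a ggplot object.
#' @export
plot_ne_trajectory <- function(traj) {
  ggplot2::ggplot(traj[traj$valid, ],
                  ggplot2::aes(x = .data$t, y = .data$ne)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "generations ago", y = expression(N[e])) +
    ggplot2::theme_minimal()
}
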