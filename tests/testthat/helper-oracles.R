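# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are written from first principles (enumeration, direct
# counting) and never call the code paths they check.

# exact HWE p-value by full enumeration with factorial() arithmetic
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  probs <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hs)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# all-pairs r2 by direct dosage correlation (no windowing machinery)
r2_oracle_all_pairs <- function(dosages, pos, max_kb = Inf) {
  l <- ncol(dosages)
  out <- list()
  for (i in seq_len(l - 1)) {
    for (j in seq(i + 1, l)) {
      if (pos[j] - pos[i] > max_kb * 1000) next
      ok <- !is.na(dosages[, i]) & !is.na(dosages[, j])
      if (sum(ok) < 2) next
      x <- dosages[ok, i]; y <- dosages[ok, j]
      if (var(x) == 0 || var(y) == 0) next
      out[[length(out) + 1]] <- data.frame(i = i, j = j,
                                           r2 = min(1, cor(x, y)^2))
    }
  }
  do.call(rbind, out)
}

# brute-force EHH by substring grouping, straight from the definition
ehh_oracle <- function(haps, pos, core, carriers, min_ehh = 0.05,
                       max_gap = 5e5, split_core = FALSE) {
  m <- length(carriers)
  cc <- function(n) n * (n - 1) / 2
  core_val <- if (split_core)
    sum(cc(table(haps[carriers, core]))) / cc(m) else 1
  one_side <- function(step) {
    L <- ncol(haps)
    out_pos <- pos[core]; out_ehh <- core_val
    j <- core
    repeat {
      j2 <- j + step
      if (j2 < 1 || j2 > L) break
      if (abs(pos[j2] - pos[j]) > max_gap) break
      rng <- seq(core, j2, by = step)
      if (!split_core) rng <- rng[rng != core]
      key <- apply(haps[carriers, rng, drop = FALSE], 1, paste, collapse = "")
      e <- sum(cc(table(key))) / cc(m)
      out_pos <- c(out_pos, pos[j2]); out_ehh <- c(out_ehh, e)
      j <- j2
      if (e < min_ehh) break
    }
    list(pos = out_pos, ehh = out_ehh)
  }
  if (core_val < min_ehh) {
    return(list(pos_left = pos[core], ehh_left = core_val,
                pos_right = pos[core], ehh_right = core_val))
  }
  l <- one_side(-1L); r <- one_side(+1L)
  list(pos_left = l$pos, ehh_left = l$ehh,
       pos_right = r$pos, ehh_right = r$ehh)
}

# quadratic interval-overlap oracle (closed intervals, >= 1 bp)
intersect_oracle <- function(regions, features) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (regions$chrom[i] != features$chrom[j]) next
      lo <- max(regions$start_bp[i], features$start_bp[j])
      hi <- min(regions$end_bp[i], features$end_bp[j])
      if (hi >= lo) {
        hits[[length(hits) + 1]] <- data.frame(
          region_idx = i, name = features$name[j], overlap_bp = hi - lo + 1)
      }
    }
  }
  if (!length(hits)) return(data.frame(region_idx = integer(),
                                       name = character(),
                                       overlap_bp = integer()))
  do.call(rbind, hits)
}

# exhaustive Gabriel-block oracle: enumerate every contiguous span, apply
# the published predicate through the dprime_ci surface, then resolve
# overlaps greedily by descending bp span (leftmost on ties)
gabriel_oracle <- function(mat, pos, phased, max_span_kb = 1000,
                           informative_frac = 0.95, frac3 = 0.80) {
  l <- length(pos)
  cls <- matrix(NA_character_, l, l)
  for (i in seq_len(l - 1)) for (j in seq(i + 1, l)) {
    ci <- dprime_ci(mat[, i], mat[, j], phased = phased)
    cls[i, j] <- if (is.na(ci$ci_hi)) NA_character_
      else if (ci$ci_hi < 0.90) "rec"
      else if (ci$ci_lo >= 0.70 && ci$ci_hi >= 0.98) "strong"
      else "uninf"
  }
  cand <- list()
  for (i in seq_len(l - 2)) for (j in seq(i + 2, l)) {
    if (pos[j] - pos[i] > max_span_kb * 1000) next
    if (is.na(cls[i, j]) || cls[i, j] != "strong") next
    sub <- cls[i:j, i:j]
    ns <- sum(sub == "strong", na.rm = TRUE)
    ni <- sum(sub %in% c("strong", "rec"), na.rm = TRUE)
    if (ni == 0) next
    need <- if (j - i + 1 == 3) frac3 else informative_frac
    if (ns / ni >= need) {
      cand[[length(cand) + 1]] <- c(i = i, j = j, span = pos[j] - pos[i])
    }
  }
  if (!length(cand)) return(data.frame(first = integer(), last = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "span"], cand[, "i"]), , drop = FALSE]
  taken <- rep(FALSE, l)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    out[[length(out) + 1]] <- data.frame(first = i, last = j)
  }
  res <- do.call(rbind, out)
  res[order(res$first), , drop = FALSE]
}

# phased haplotype fixture: islands of tightly linked SNPs; haplotypes are
# drawn from a few island-level templates, islands assigned independently
island_haps <- function(n_hap, islands, seed = 1) {
  set.seed(seed)
  cols <- list()
  pos <- integer(0)
  at <- 10000
  for (isl in islands) {
    k <- isl$n_snps
    templates <- matrix(rbinom(isl$n_templates * k, 1, 0.5),
                        isl$n_templates, k)
    while (any(duplicated(templates)) ||
           any(colSums(templates) %in% c(0, isl$n_templates))) {
      templates <- matrix(rbinom(isl$n_templates * k, 1, 0.5),
                          isl$n_templates, k)
    }
    pick <- sample.int(isl$n_templates, n_hap, replace = TRUE)
    cols[[length(cols) + 1]] <- templates[pick, , drop = FALSE]
    pos <- c(pos, at + cumsum(rep(isl$spacing_bp, k)))
    at <- pos[length(pos)] + isl$gap_bp
  }
  list(haps = do.call(cbind, cols), pos = pos)
}

# small two-population genotype fixture drawn from given allele frequencies
geno_from_freqs <- function(freqs, n, sid_prefix = "s", population = "pop1") {
  d <- vapply(freqs, function(p) rbinom(n, 2, p), integer(n))
  genotype_matrix(d,
                  variant_table("1", seq_along(freqs) * 1000,
                                vid = paste0("v", seq_along(freqs))),
                  sample_table(sprintf("%s%03d", sid_prefix, seq_len(n)),
                               population))
}

# compact simulated dataset reused by several files (cached per session)
.shared_sim_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.shared_sim_env$sim)) {
    .shared_sim_env$sim <- suppressMessages(simulate_population(
      sim_config(seed = 20260929L, n_founders = 150L,
                 ne_schedule = data.frame(generation = 0L, N = 150L),
                 split_generation = 60L, n_generations = 100L,
                 n_snps = 600L, chrom_length_bp = 2e7, n_sample = 40L)))
  }
  .shared_sim_env$sim
}
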