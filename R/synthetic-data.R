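#' Simulation configuration
#'
#' Study conditions for the forward Wright-Fisher generator: two sister
#' subpopulations descended from a common ancestral population with a
#' declining effective size, biallelic SNPs with known ancestral alleles on
#' one autosome, chip-like fixed sites (no new mutations after
#' initialization), and an optional hard selective sweep private to one
#' subpopulation. The defaults are desk-scale (population size a few
#' hundred, a few thousand SNPs, one chromosome) so a full run takes
#' seconds.
#'
#' @param n_founders diploid founder count (ancestral population size at
#'   generation 0).
#' @param ne_schedule data.frame `generation, N`: the population size from
#'   each breakpoint generation onward (step function). The default declines
#'   from 200 founders to 100, echoing the declining-Ne history typical of
#'   closed conservation herds.
#' @param split_generation generation at which the population splits into
#'   two subpopulations (each of the scheduled size N thereafter). `NA`
#'   for a single panmictic population.
#' @param n_generations total generations simulated.
#' @param chrom_length_bp chromosome length (default 50 Mb, so a sweep
#'   footprint of a few Mb stays a small fraction of the genome).
#' @param n_snps segregating sites at initialization.
#' @param founder_freq founder derived-allele frequency model: `"sfs"`
#'   (neutral site-frequency spectrum, P(i copies) proportional to 1/i) or
#'   `"array"` (uniform on 0.05-0.95, emulating the common-variant
#'   ascertainment of genotyping chips).
#' @param recomb_rate Morgans per bp (default 1e-8 = 1 cM/Mb).
#' @param mutation_rate per-site per-generation; default 0 so the SNP set is
#'   fixed, like array data.
#' @param sweep optional list `(pos, s, population, start_generation)` plus
#'   optional `init_freq_range` (default `c(0.005, 0.03)`, i.e. a hard
#'   sweep from a rare standing variant): viability
#'   selection 1 : 1+s : 1+2s on derived-allele count at the segregating
#'   site nearest `pos` whose derived frequency lies in the range, applied
#'   in one subpopulation from `start_generation` on. Selection switches off
#'   once the allele reaches `target_freq` (default 0.8), emulating a sweep
#'   observed in flight rather than after fixation; `min_final_freq`
#'   (default 0.4) is the success criterion for retries.
#' @param n_sample diploid individuals sampled per population at the end.
#' @param sweep_retries if the sweep allele is lost or ends below
#'   `min_final_freq`, rerun the whole simulation (continuing the same
#'   random stream) up to this many times.
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 200L,
                       ne_schedule = data.frame(generation = c(0L, 60L),
                                                N = c(200L, 100L)),
                       split_generation = 80L, n_generations = 150L,
                       chrom_length_bp = 5e7, n_snps = 2500L,
                       founder_freq = c("sfs", "array"),
                       recomb_rate = 1e-8, mutation_rate = 0,
                       sweep = NULL, n_sample = 50L, sweep_retries = 5L,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(all(ne_schedule$N >= 2), n_founders >= 2)
  if (!is.null(sweep)) {
    stopifnot(sweep$pos >= 1, sweep$pos <= chrom_length_bp)
    sweep$init_freq_range <- sweep$init_freq_range %||% c(0.005, 0.03)
    sweep$target_freq <- sweep$target_freq %||% 0.8
    sweep$min_final_freq <- sweep$min_final_freq %||% 0.4
  }
  structure(list(n_founders = as.integer(n_founders),
                 ne_schedule = ne_schedule,
                 split_generation = split_generation,
                 n_generations = as.integer(n_generations),
                 chrom_length_bp = chrom_length_bp,
                 n_snps = as.integer(n_snps),
                 founder_freq = match.arg(founder_freq),
                 recomb_rate = recomb_rate,
                 mutation_rate = mutation_rate, sweep = sweep,
                 n_sample = as.integer(n_sample),
                 sweep_retries = as.integer(sweep_retries),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.schedule_n <- function(schedule, gen) {
  idx <- max(which(schedule$generation <= gen))
  as.integer(schedule$N[idx])
}

#' Forward Wright-Fisher simulation
#'
#' Simulates phased haplotypes under random mating with drift,
#' recombination (Poisson crossovers on the genetic map, no interference)
#' and optional viability selection at one sweep site. Founder haplotypes
#' draw each site independently with derived-allele frequency from the
#' neutral site-frequency spectrum (P(i copies) proportional to 1/i), so the
#' ancestral allele of every SNP is the reference allele by construction.
#' The population follows the size schedule, splits into two subpopulations
#' at `split_generation`, and `n_sample` individuals per population are
#' sampled without replacement from the final generation. A fixed seed gives
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `wf_sim`: `pops` (named list of `haplo_matrix`),
#'   `truth` (realized N per generation and population, per-generation
#'   derived-allele frequency matrices, sweep trajectory and site, seed) and
#'   `config`.
#' @export
simulate_population <- function(cfg) {
  set.seed(cfg$seed)
  for (attempt in seq_len(max(1L, cfg$sweep_retries))) {
    sim <- .simulate_once(cfg)
    if (is.null(cfg$sweep)) break
    final <- utils::tail(sim$truth$sweep$trajectory, 1L)
    if (length(final) && final >= cfg$sweep$min_final_freq) break
    message("sweep failed to establish (attempt ", attempt, ")")
  }
  sim
}

.simulate_once <- function(cfg) {
  L <- cfg$n_snps
  pos <- sort(sample.int(cfg$chrom_length_bp, L))
  n0 <- cfg$n_founders
  if (cfg$founder_freq == "array") {
    p0 <- stats::runif(L, 0.05, 0.95)
  } else {
    sfs_i <- seq_len(2L * n0 - 1L)
    p0 <- sample(sfs_i, L, replace = TRUE, prob = 1 / sfs_i) / (2 * n0)
  }
  # haplotypes stored transposed (sites x haplotypes) for cache-friendly
  # meiosis in the compiled core; transposed back at output
  haps <- matrix(stats::rbinom(2L * n0 * L, 1L, rep(p0, each = 2L * n0)),
                 nrow = 2L * n0, ncol = L)
  haps <- t(haps)
  cummap <- cumsum(c(0, diff(pos))) * cfg$recomb_rate
  split_gen <- cfg$split_generation
  two_pops <- !is.na(split_gen) && !is.null(split_gen)
  pops <- list(anc = haps)
  sweep <- cfg$sweep
  sweep_site <- NA_integer_
  sweep_traj <- numeric(0)
  sweep_started <- FALSE
  n_track <- list()
  freq_track <- list()
  for (gen in seq_len(cfg$n_generations)) {
    n_gen <- .schedule_n(cfg$ne_schedule, gen)
    if (two_pops && gen == split_gen && length(pops) == 1L) {
      pops <- list(pop1 = pops[[1L]], pop2 = pops[[1L]])
    }
    if (!is.null(sweep) && !sweep_started && gen >= sweep$start_generation) {
      target_pop <- if (length(pops) == 1L) 1L
                    else match(sweep$population, names(pops))
      f_now <- rowMeans(pops[[target_pop]])
      in_range <- f_now >= sweep$init_freq_range[1] &
        f_now <= sweep$init_freq_range[2]
      cand <- if (any(in_range)) which(in_range)
              else which(f_now > 0 & f_now < 0.5)
      if (length(cand)) {
        sweep_site <- cand[which.min(abs(pos[cand] - sweep$pos))]
        sweep_started <- TRUE
      }
    }
    for (pi in seq_along(pops)) {
      par <- pops[[pi]]
      np <- ncol(par) / 2L
      fitness <- rep(1, np)
      sel_here <- sweep_started &&
        ((length(pops) == 1L) || names(pops)[pi] == sweep$population)
      if (sel_here && mean(par[sweep_site, ]) < sweep$target_freq) {
        dos <- par[sweep_site, seq(1L, 2L * np, 2L)] +
          par[sweep_site, seq(2L, 2L * np, 2L)]
        fitness <- 1 + sweep$s * dos
      }
      pops[[pi]] <- wf_next_gen_cpp(par, n_gen, fitness, cummap)
      if (cfg$mutation_rate > 0) {
        nmut <- stats::rpois(1L, cfg$mutation_rate * 2 * n_gen * L)
        if (nmut > 0) {
          cells <- cbind(sample.int(L, nmut, replace = TRUE),
                         sample.int(2L * n_gen, nmut, replace = TRUE))
          pops[[pi]][cells] <- 1L - pops[[pi]][cells]
        }
      }
    }
    n_track[[gen]] <- data.frame(generation = gen,
                                 population = names(pops), N = n_gen)
    freq_track[[gen]] <- vapply(pops, rowMeans, numeric(L))
    if (sweep_started) {
      tp <- if (length(pops) == 1L) 1L else match(sweep$population, names(pops))
      sweep_traj <- c(sweep_traj, mean(pops[[tp]][sweep_site, ]))
    }
  }
  variants <- variant_table(chrom = "1", pos = pos,
                            vid = sprintf("snp%05d", seq_len(L)),
                            ref = "A", alt = "G", ancestral = "ref")
  out_pops <- lapply(seq_along(pops), function(pi) {
    n_now <- ncol(pops[[pi]]) / 2L
    take <- sort(sample.int(n_now, min(cfg$n_sample, n_now)))
    hcols <- as.vector(rbind(2L * take - 1L, 2L * take))
    s <- sample_table(sprintf("%s_ind%03d", names(pops)[pi], take),
                      population = names(pops)[pi])
    haplotype_matrix(t(pops[[pi]][, hcols, drop = FALSE]), variants, s)
  })
  names(out_pops) <- names(pops)
  lost <- sweep_started && length(sweep_traj) &&
    sweep_traj[length(sweep_traj)] <= 0
  structure(list(
    pops = out_pops,
    truth = list(
      ne = do.call(rbind, n_track),
      initial_freq = p0,
      freq_by_generation = freq_track,
      ancestral = stats::setNames(rep("ref", L), variants$vid),
      sweep = if (is.null(sweep)) NULL else list(
        vid = if (is.na(sweep_site)) NA_character_ else variants$vid[sweep_site],
        pos = if (is.na(sweep_site)) NA_integer_ else pos[sweep_site],
        s = sweep$s,
        population = sweep$population %||% names(pops)[1L],
        trajectory = sweep_traj, lost = lost),
      seed = cfg$seed),
    config = cfg), class = "wf_sim")
}

#' Export a simulation to standard file formats
#'
#' Writes the pooled samples as a PLINK bed/bim/fam set, a phased VCF with
#' `AA` INFO tags carrying the true ancestral alleles, a TSV
#' sample-to-population map and a ground-truth JSON.
#'
#' @param sim a `wf_sim` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem (default `"sim"`).
#' @return named list of written paths, invisibly.
#' @export
export_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combined <- do.call(rbind, lapply(sim$pops, function(h) h$haps))
  samples <- do.call(rbind, lapply(sim$pops, function(h) h$samples))
  rownames(samples) <- NULL
  h_all <- haplotype_matrix(combined, sim$pops[[1L]]$variants, samples)
  paths <- list(
    plink = file.path(dir, prefix),
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    map = file.path(dir, paste0(prefix, ".popmap.tsv")),
    truth = file.path(dir, paste0(prefix, ".truth.json")))
  write_plink(as_genotypes(h_all), paths$plink)
  write_vcf(h_all, paths$vcf)
  utils::write.table(
    data.frame(sample_id = samples$sid, population = samples$population),
    paths$map, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$freq_by_generation <- NULL       # bulky; regenerate by re-running
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
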