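#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic data.
#
# Two conservation herds ("pop1", "pop2") descended from one ancestral
# population with declining size, genotyped at chip-like biallelic SNPs on
# a single autosome; a second scenario adds a hard selective sweep private
# to pop1 for the selection-scan stages. Everything downstream reads the
# files written here, so the whole workflow is reproducible from this seed.

suppressPackageStartupMessages(library(ldsweep))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

seed <- 20260929L

message("Neutral two-herd scenario (defaults) ...")
neutral <- simulate_population(sim_config(seed = seed))
export_simulation(neutral, "results/data", prefix = "herds_neutral")

message("Sweep scenario: s = 0.1 hard sweep private to pop1 ...")
swept <- simulate_population(sim_config(
  seed = seed + 1L, n_founders = 500L,
  ne_schedule = data.frame(generation = 0L, N = 500L),
  split_generation = 60L, n_generations = 150L,
  n_snps = 5000L, chrom_length_bp = 1e8, n_sample = 75L,
  sweep = list(pos = 5e7, s = 0.1, population = "pop1",
               start_generation = 60L, target_freq = 0.95)))
export_simulation(swept, "results/data", prefix = "herds_sweep")

message("True sweep site: ", swept$truth$sweep$vid, " at ",
        swept$truth$sweep$pos, " bp; final frequency ",
        round(tail(swept$truth$sweep$trajectory, 1), 3))
message("Wrote results/data/herds_neutral.* and results/data/herds_sweep.*")
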