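#!/usr/bin/env Rscript
# Stage 5: historical effective population size from LD.
#
# Bins UNTHRESHOLDED r2 pairs by distance, maps bins to recombination
# fractions (c) and times (t = 1/(2c) generations ago), and inverts the
# drift expectation E[r2_adj] = 1/(alpha + 4 Ne c). The input pairs must
# not carry the 0.2 reporting filter: conditioning on large r2 would bias
# E[r2] and hence Ne.

suppressPackageStartupMessages(library(ldsweep))
dir.create("results/ne", showWarnings = FALSE, recursive = TRUE)

g <- read_plink("results/data/herds_neutral")
map <- read_population_map("results/data/herds_neutral.popmap.tsv")
pops <- split_by_population(g, map)
pops$overall <- g

trajs <- list()
for (nm in names(pops)) {
  kept <- readLines(file.path("results/qc", paste0("kept_snps_", nm, ".txt")))
  samp <- readLines(file.path("results/qc", paste0("kept_samples_", nm, ".txt")))
  gq <- keep_samples(keep_variants(pops[[nm]], pops[[nm]]$variants$vid %in% kept),
                     pops[[nm]]$samples$sid %in% samp)
  fr <- allele_frequencies(gq)
  gq <- keep_variants(gq, !is.na(fr$maf) & fr$maf >= 0.05)
  pairs <- pairwise_ld(gq, ld_window_config(max_kb = 4000,
                                            report_r2_min = NULL))
  traj <- ne_trajectory(pairs, nrow(gq$samples), ne_config())
  traj$population <- nm
  trajs[[nm]] <- traj
  v <- traj[traj$valid, ]
  message(sprintf("%s: Ne %.0f at t ~ %.0f ... %.0f at t ~ %.0f generations",
                  nm, v$ne[1], v$t[1], v$ne[nrow(v)], v$t[nrow(v)]))
}
write.table(do.call(rbind, c(trajs, make.row.names = FALSE)),
            "results/ne/ne_trajectory.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
p <- plot_ne_trajectory(trajs$pop1)
ggplot2::ggsave("results/ne/ne_trajectory_pop1.pdf", p, width = 6, height = 4)
message("wrote results/ne/")
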