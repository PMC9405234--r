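#!/usr/bin/env Rscript
# Stage 6: haplotype-based selection scans on the sweep scenario.
#
# iHS within each herd (frequency-bin standardized log-ratio of integrated
# EHH for ancestral vs derived alleles, piHS significance transform,
# 1-Mb candidate windows ranked by extreme-SNP density) and XP-EHH between
# the herds (standardized log-ratio of pooled site EHHS; candidates are
# >= 3 consecutive SNPs above 4.0). The simulated sweep is private to pop1,
# so the truth file tells us exactly what the scans should find.

suppressPackageStartupMessages(library(ldsweep))
dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)

h <- read_vcf("results/data/herds_sweep.vcf", phased = TRUE)
map <- read_population_map("results/data/herds_sweep.popmap.tsv")
pops <- split_by_population(h, map)
truth <- jsonlite::read_json("results/data/herds_sweep.truth.json",
                             simplifyVector = TRUE)
scfg <- scan_config(extreme_rule = "top_pct")

for (nm in names(pops)) {
  sc <- ihs_scan(pops[[nm]], scfg)
  write.table(sc, file.path("results/selection", paste0("ihs_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  w <- candidate_windows(sc, scfg)
  write.table(w, file.path("results/selection",
                           paste0("ihs_windows_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- w[w$candidate, ]
  message(sprintf("%s: %d scored SNPs; candidate window %s:%d-%d", nm,
                  sum(!is.na(sc$ihs)), cand$chrom[1], cand$start_bp[1],
                  cand$end_bp[1]))
  p <- plot_scan(sc[!is.na(sc$pihs), ], y = "pihs", threshold = 3)
  ggplot2::ggsave(file.path("results/selection",
                            paste0("ihs_manhattan_", nm, ".pdf")),
                  p, width = 8, height = 3)
}

xp <- xpehh_scan(pops$pop1, pops$pop2, scfg)
write.table(xp$scores, "results/selection/xpehh.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(xp$runs, "results/selection/xpehh_runs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
p <- plot_scan(xp$scores[!is.na(xp$scores$xpehh), ], y = "xpehh", threshold = 4)
ggplot2::ggsave("results/selection/xpehh_manhattan.pdf", p,
                width = 8, height = 3)

message(sprintf("true sweep at %s bp; %d XP-EHH candidate run(s)",
                format(truth$sweep$pos, big.mark = ","), nrow(xp$runs)))
if (nrow(xp$runs)) {
  hit <- any(truth$sweep$pos >= xp$runs$start_bp - 2e6 &
               truth$sweep$pos <= xp$runs$end_bp + 2e6)
  message("sweep covered by an XP-EHH run (+-2 Mb): ", hit)
}
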