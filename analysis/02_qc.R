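#!/usr/bin/env Rscript
# Stage 2: per-herd quality control, MAF spectrum and PCA structure.
#
# Reads the PLINK fileset exported by 01_simulate.R the way real chip data
# would arrive, filters each herd separately (call rate, MAF, exact HWE,
# relatedness pruning) and the pooled set, and summarizes allele-frequency
# structure. QC'd sample/variant lists feed every later stage.

suppressPackageStartupMessages(library(ldsweep))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

g <- read_plink("results/data/herds_neutral")
map <- read_population_map("results/data/herds_neutral.popmap.tsv")
pops <- split_by_population(g, map)
pops$overall <- g

for (nm in names(pops)) {
  qc <- apply_qc(pops[[nm]], qc_config(autosomes = "1"))
  write_qc_report(qc$report, file.path("results/qc", paste0("qc_", nm)))
  write.table(maf_spectrum(qc$genotypes),
              file.path("results/qc", paste0("maf_spectrum_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(qc$genotypes$variants$vid,
             file.path("results/qc", paste0("kept_snps_", nm, ".txt")))
  writeLines(qc$genotypes$samples$sid,
             file.path("results/qc", paste0("kept_samples_", nm, ".txt")))
  message(sprintf("%s: %d -> %d SNPs, %d -> %d samples", nm,
                  qc$report$n_snps_pre, qc$report$n_snps_post,
                  qc$report$n_samples_pre, qc$report$n_samples_post))
}

pc <- pca_structure(pops$overall, k = 4)
write.table(data.frame(sid = rownames(pc$coordinates),
                       population = map[rownames(pc$coordinates)],
                       pc$coordinates),
            "results/qc/pca_coordinates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("PCA: PC1 %.2f%%, PC2 %.2f%% of total variance",
                100 * pc$variance_explained[1], 100 * pc$variance_explained[2]))
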