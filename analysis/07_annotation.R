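#!/usr/bin/env Rscript
# Stage 7: candidate-region annotation and gene-set comparison.
#
# Extends the stage-6 candidate regions by 200 kb both ways, merges
# overlaps, and intersects them with a gene annotation. No real bovine
# annotation is bundled, so this stage writes and uses a SYNTHETIC gene
# map (uniformly placed intervals on the simulated chromosome, named
# synthetic_gene_*); swap in a real BED/GFF3 to annotate real scans.

suppressPackageStartupMessages(library(ldsweep))
dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)

set.seed(20260929L)
genes_bed <- "results/annotation/synthetic_genes.bed"
starts <- sort(sample.int(1e8 - 6e4, 2000))
writeLines(sprintf("1\t%d\t%d\tsynthetic_gene_%04d", starts, starts + 4e4,
                   seq_along(starts)), genes_bed)
ann <- read_annotation(genes_bed, source_tag = "synthetic")
bounds <- data.frame(chrom = "1", end_bp = 1e8)

gene_sets <- list()
for (nm in c("pop1", "pop2")) {
  w <- read.delim(file.path("results/selection",
                            paste0("ihs_windows_", nm, ".tsv")))
  regs <- w[w$candidate, c("chrom", "start_bp", "end_bp")]
  regs$chrom <- as.character(regs$chrom)
  ext <- extend_regions(regs, flank_bp = 2e5, chrom_bounds = bounds)
  hits <- intersect_annotations(ext, ann)
  write.table(hits, file.path("results/annotation",
                              paste0("gene_hits_ihs_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gene_sets[[paste0("ihs_", nm)]] <- unique(hits$name)
  message(sprintf("iHS %s: %d extended region(s), %d gene hits", nm,
                  nrow(ext), nrow(hits)))
}

runs <- read.delim("results/selection/xpehh_runs.tsv")
if (nrow(runs)) {
  runs$chrom <- as.character(runs$chrom)
  ext <- extend_regions(runs[, c("chrom", "start_bp", "end_bp")],
                        flank_bp = 2e5, chrom_bounds = bounds)
  hits <- intersect_annotations(ext, ann)
  write.table(hits, "results/annotation/gene_hits_xpehh.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  gene_sets$xpehh <- unique(hits$name)
  message(sprintf("XP-EHH: %d region(s), %d gene hits", nrow(ext), nrow(hits)))
}

gene_sets <- gene_sets[lengths(gene_sets) > 0]
if (length(gene_sets) >= 2) {
  cmp <- compare_gene_sets(gene_sets)
  write_gene_sets(cmp, "results/annotation/gene_sets")
  print(cmp$regions)
} else {
  message("fewer than two non-empty gene sets; no comparison written")
}
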