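#!/usr/bin/env Rscript
# Stage 4: Gabriel haplotype blocks and the cross-herd block comparison.
#
# Detects blocks per herd from the phased haplotypes (D'-CI definition,
# blocks of fewer than 3 SNPs discarded), summarizes counts, lengths and
# genome coverage, and classifies blocks as shared (>= 1 bp overlap with a
# block of the other herd) or unique.

suppressPackageStartupMessages(library(ldsweep))
dir.create("results/blocks", showWarnings = FALSE, recursive = TRUE)

h <- read_vcf("results/data/herds_neutral.vcf", phased = TRUE)
map <- read_population_map("results/data/herds_neutral.popmap.tsv")
pops <- split_by_population(h, map)
pops$overall <- h

blocks <- list(); summaries <- list()
for (nm in names(pops)) {
  kept <- readLines(file.path("results/qc", paste0("kept_snps_", nm, ".txt")))
  samp <- readLines(file.path("results/qc", paste0("kept_samples_", nm, ".txt")))
  hq <- keep_samples(keep_variants(pops[[nm]], pops[[nm]]$variants$vid %in% kept),
                     pops[[nm]]$samples$sid %in% samp)
  bl <- gabriel_blocks(hq)
  blocks[[nm]] <- bl
  write.table(bl[, setdiff(names(bl), "haplotypes")],
              file.path("results/blocks", paste0("blocks_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_blocks_bed(bl, file.path("results/blocks", paste0("blocks_", nm, ".bed")))
  ext <- do.call(rbind, lapply(split(hq$variants, hq$variants$chrom),
    function(v) data.frame(chrom = v$chrom[1], start_bp = min(v$pos),
                           end_bp = max(v$pos))))
  summaries[[nm]] <- cbind(population = nm,
                           block_summary(bl, ext, nrow(hq$variants)))
  message(sprintf("%s: %d blocks, %.2f Mb, %.2f%% of the analysed genome",
                  nm, summaries[[nm]]$n_blocks,
                  summaries[[nm]]$total_length_mb,
                  summaries[[nm]]$pct_genome_coverage))
}
write.table(do.call(rbind, c(summaries, make.row.names = FALSE)),
            "results/blocks/block_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sh <- shared_unique_blocks(blocks$pop1, blocks$pop2)
jsonlite::write_json(sh[c("shared_a", "shared_b", "unique_a", "unique_b")],
                     "results/blocks/shared_unique.json", auto_unbox = TRUE)
write_blocks_bed(sh$shared_a_blocks, "results/blocks/shared_pop1.bed")
write_blocks_bed(sh$unique_a_blocks, "results/blocks/unique_pop1.bed")
write_blocks_bed(sh$unique_b_blocks, "results/blocks/unique_pop2.bed")
message(sprintf("shared: %d of pop1's %d blocks overlap pop2; unique %d / %d",
                sh$shared_a, nrow(blocks$pop1), sh$unique_a, sh$unique_b))
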