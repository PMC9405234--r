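#' Pipeline configuration
#'
#' Bundles the per-stage configurations and input locations of a full run:
#' QC, windowed LD and decay, Gabriel blocks with cross-population
#' comparison, LD-based Ne, iHS and XP-EHH scans, and optional annotation.
#' `replication_mode` switches the LD stage to the thresholded reporting
#' convention (`--ld-window-r2 0.2`-style): pairs with r2 < 0.2 are then
#' omitted from the reported per-chromosome means, which conditions those
#' means upward; the Ne stage always uses an unthresholded stream.
#'
#' @param input either a `wf_sim` / list of `haplo_matrix` objects, or a
#'   list with `plink` (prefix) or `vcf` (path, phased) plus `popmap`
#'   (TSV path).
#' @param outdir output directory.
#' @param qc a [qc_config()].
#' @param ld an [ld_window_config()]; its `report_r2_min` is forced to 0.2
#'   when `replication_mode` and to `NULL` otherwise.
#' @param ne an [ne_config()].
#' @param scan a [scan_config()].
#' @param genes,qtls optional BED/GFF annotation paths.
#' @param flank_bp candidate-region flank before annotation (default 2e5).
#' @param replication_mode apply the thresholded LD reporting convention.
#' @param exclude_samples optional sample ids dropped before the scans
#'   (e.g. an admixed PCA cluster).
#' @param seed integer seed for any stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, outdir, qc = qc_config(),
                            ld = ld_window_config(), ne = ne_config(),
                            scan = scan_config(), genes = NULL, qtls = NULL,
                            flank_bp = 200000, replication_mode = TRUE,
                            exclude_samples = NULL, seed = 1L) {
  structure(list(input = input, outdir = outdir, qc = qc, ld = ld, ne = ne,
                 scan = scan, genes = genes, qtls = qtls,
                 flank_bp = flank_bp, replication_mode = replication_mode,
                 exclude_samples = exclude_samples, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()]; per-stage keys are passed to the matching
#' `*_config()` constructor.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    input = y$input, outdir = y$outdir,
    qc = do.call(qc_config, y$qc %||% list()),
    ld = do.call(ld_window_config, y$ld %||% list()),
    ne = do.call(ne_config, y$ne %||% list()),
    scan = do.call(scan_config, y$scan %||% list()),
    genes = y$genes, qtls = y$qtls,
    flank_bp = y$flank_bp %||% 200000,
    replication_mode = y$replication_mode %||% TRUE,
    exclude_samples = y$exclude_samples,
    seed = y$seed %||% 1L)
}

.load_input <- function(input) {
  if (inherits(input, "wf_sim")) return(input$pops)
  if (is.list(input) && all(vapply(input, inherits, TRUE, "haplo_matrix"))) {
    return(input)
  }
  map <- read_population_map(input$popmap)
  x <- if (!is.null(input$plink)) read_plink(input$plink)
       else read_vcf(input$vcf, phased = isTRUE(input$phased %||% TRUE))
  split_by_population(x, map)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, per population and for the pooled sample ("overall"): QC and
#' the MAF spectrum; PCA on the pooled genotypes; windowed pairwise LD with
#' per-chromosome summaries and decay curves; Gabriel block detection with
#' block summaries and the cross-population shared/unique comparison;
#' LD-based Ne trajectories from an unthresholded pair stream; iHS scans
#' with candidate windows per population and an XP-EHH scan between the
#' first two populations; and, when annotation files are supplied,
#' flank-extended candidate regions intersected with genes/QTLs and a gene
#' set comparison. All tables are written to `cfg$outdir`, and the run is
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [pipeline_config()].
#' @return named list of the main result objects, invisibly writing the
#'   report bundle to `cfg$outdir`.
#' @export
run_pipeline <- function(cfg) {
  set.seed(cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  log <- function(...) message("[pipeline] ", ...)

  pops_h <- .load_input(cfg$input)
  phased <- all(vapply(pops_h, inherits, TRUE, "haplo_matrix"))
  if (!is.null(cfg$exclude_samples)) {
    pops_h <- lapply(pops_h, function(x)
      keep_samples(x, !x$samples$sid %in% cfg$exclude_samples))
  }
  # pooled set analysed with the same code path under a merged label
  pooled <- if (phased) {
    haplotype_matrix(do.call(rbind, lapply(pops_h, function(h) h$haps)),
                     pops_h[[1L]]$variants,
                     do.call(rbind, lapply(pops_h, function(h) h$samples)))
  } else {
    genotype_matrix(do.call(rbind, lapply(pops_h, function(g) g$dosages)),
                    pops_h[[1L]]$variants,
                    do.call(rbind, lapply(pops_h, function(g) g$samples)))
  }
  groups <- c(pops_h, list(overall = pooled))

  qc_out <- list()
  for (nm in names(groups)) {
    g <- if (phased) as_genotypes(groups[[nm]]) else groups[[nm]]
    qc <- apply_qc(g, cfg$qc)
    write_qc_report(qc$report, file.path(cfg$outdir, paste0("qc_", nm)))
    write_tsv(maf_spectrum(qc$genotypes),
              file.path(cfg$outdir, paste0("maf_spectrum_", nm, ".tsv")))
    keep_v <- groups[[nm]]$variants$vid %in% qc$genotypes$variants$vid
    keep_s <- groups[[nm]]$samples$sid %in% qc$genotypes$samples$sid
    groups[[nm]] <- keep_samples(keep_variants(groups[[nm]], keep_v), keep_s)
    qc_out[[nm]] <- qc$report
    log("QC ", nm, ": ", qc$report$n_snps_post, " SNPs, ",
        qc$report$n_samples_post, " samples")
  }
  out$qc <- qc_out

  pca <- pca_structure(if (phased) as_genotypes(groups$overall)
                       else groups$overall, k = 2L)
  write_tsv(data.frame(sid = rownames(pca$coordinates), pca$coordinates),
            file.path(cfg$outdir, "pca_coordinates.tsv"))
  out$pca <- pca

  ld_cfg_rep <- cfg$ld
  ld_cfg_rep$report_r2_min <- if (cfg$replication_mode) 0.2 else NULL
  ld_cfg_free <- cfg$ld
  ld_cfg_free$report_r2_min <- NULL
  ld_summary <- list(); decay_all <- list(); blocks <- list(); ne_all <- list()
  for (nm in names(groups)) {
    g <- if (phased) as_genotypes(groups[[nm]]) else groups[[nm]]
    pairs_rep <- pairwise_ld(g, ld_cfg_rep)
    sm <- chromosome_ld_summary(pairs_rep)
    sm$population <- nm
    ld_summary[[nm]] <- sm
    dc <- ld_decay(pairs_rep)
    dc$population <- nm
    decay_all[[nm]] <- dc
    ne_cfg <- cfg$ne
    ne_pairs <- pairwise_ld(g, ld_window_config(
      max_kb = ne_cfg$max_distance_kb, report_r2_min = NULL))
    traj <- ne_trajectory(ne_pairs, nrow(g$samples), ne_cfg)
    traj$population <- nm
    ne_all[[nm]] <- traj
    blocks[[nm]] <- gabriel_blocks(groups[[nm]])
    write_tsv(blocks[[nm]][, setdiff(names(blocks[[nm]]), "haplotypes")],
              file.path(cfg$outdir, paste0("blocks_", nm, ".tsv")))
    write_blocks_bed(blocks[[nm]],
                     file.path(cfg$outdir, paste0("blocks_", nm, ".bed")))
    log("LD ", nm, ": ", nrow(pairs_rep), " reported pairs; ",
        nrow(blocks[[nm]]), " blocks")
  }
  write_tsv(do.call(rbind, c(ld_summary, make.row.names = FALSE)),
            file.path(cfg$outdir, "ld_summary.tsv"))
  write_tsv(do.call(rbind, c(decay_all, make.row.names = FALSE)),
            file.path(cfg$outdir, "ld_decay.tsv"))
  write_tsv(do.call(rbind, c(ne_all, make.row.names = FALSE)),
            file.path(cfg$outdir, "ne_trajectory.tsv"))
  out$ld_summary <- ld_summary; out$ld_decay <- decay_all
  out$ne <- ne_all; out$blocks <- blocks

  extent <- function(g) do.call(rbind, lapply(split(g$variants, g$variants$chrom),
    function(v) data.frame(chrom = v$chrom[1L], start_bp = min(v$pos),
                           end_bp = max(v$pos))))
  bsum <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    cbind(population = nm,
          block_summary(blocks[[nm]], extent(g), nrow(g$variants)))
  }))
  write_tsv(bsum, file.path(cfg$outdir, "block_summary.tsv"))
  out$block_summary <- bsum

  pop_names <- setdiff(names(groups), "overall")
  if (length(pop_names) >= 2L) {
    sh <- shared_unique_blocks(blocks[[pop_names[1L]]], blocks[[pop_names[2L]]])
    jsonlite::write_json(sh[c("shared_a", "shared_b", "unique_a", "unique_b")],
                         file.path(cfg$outdir, "shared_blocks.json"),
                         auto_unbox = TRUE)
    out$shared_blocks <- sh
  }

  out$ihs <- list(); out$windows <- list()
  if (phased) {
    for (nm in names(groups)) {
      sc <- ihs_scan(groups[[nm]], cfg$scan)
      write_tsv(sc, file.path(cfg$outdir, paste0("ihs_", nm, ".tsv")))
      w <- candidate_windows(sc, cfg$scan)
      write_tsv(w, file.path(cfg$outdir, paste0("ihs_windows_", nm, ".tsv")))
      out$ihs[[nm]] <- sc; out$windows[[nm]] <- w
      log("iHS ", nm, ": ", sum(!is.na(sc$ihs)), " scored SNPs, ",
          sum(w$candidate), " candidate window(s)")
    }
    if (length(pop_names) >= 2L) {
      # XP-EHH needs an identical variant set in both populations
      common <- intersect(groups[[pop_names[1L]]]$variants$vid,
                          groups[[pop_names[2L]]]$variants$vid)
      h1 <- keep_variants(groups[[pop_names[1L]]],
                          groups[[pop_names[1L]]]$variants$vid %in% common)
      h2 <- keep_variants(groups[[pop_names[2L]]],
                          groups[[pop_names[2L]]]$variants$vid %in% common)
      xp <- xpehh_scan(h1, h2, cfg$scan)
      write_tsv(xp$scores, file.path(cfg$outdir, "xpehh.tsv"))
      write_tsv(xp$runs, file.path(cfg$outdir, "xpehh_runs.tsv"))
      out$xpehh <- xp
      log("XP-EHH: ", nrow(xp$runs), " candidate run(s)")
    }
  }

  if (!is.null(cfg$genes)) {
    ann <- read_annotation(cfg$genes, "genes")
    bounds <- do.call(rbind, lapply(split(ann, ann$chrom), function(a)
      data.frame(chrom = a$chrom[1L], end_bp = max(a$end_bp))))
    gene_sets <- list()
    for (nm in names(out$windows)) {
      w <- out$windows[[nm]]
      regs <- w[w$candidate, c("chrom", "start_bp", "end_bp"), drop = FALSE]
      ext <- extend_regions(regs, cfg$flank_bp, bounds)
      hits <- intersect_annotations(ext, ann)
      write_tsv(hits, file.path(cfg$outdir, paste0("gene_hits_", nm, ".tsv")))
      gene_sets[[nm]] <- unique(hits$name)
    }
    if (!is.null(out$xpehh) && nrow(out$xpehh$runs)) {
      ext <- extend_regions(out$xpehh$runs[, c("chrom", "start_bp", "end_bp")],
                            cfg$flank_bp, bounds)
      hits <- intersect_annotations(ext, ann)
      write_tsv(hits, file.path(cfg$outdir, "gene_hits_xpehh.tsv"))
      gene_sets$xpehh <- unique(hits$name)
    }
    gene_sets <- gene_sets[lengths(gene_sets) > 0]
    if (length(gene_sets) >= 2L) {
      cmp <- compare_gene_sets(gene_sets[seq_len(min(4L, length(gene_sets)))])
      write_gene_sets(cmp, file.path(cfg$outdir, "gene_sets"))
      out$gene_sets <- cmp
    }
    if (!is.null(cfg$qtls)) {
      qtl <- read_annotation(cfg$qtls, "qtl")
      for (nm in names(out$windows)) {
        w <- out$windows[[nm]]
        regs <- w[w$candidate, c("chrom", "start_bp", "end_bp"), drop = FALSE]
        ext <- extend_regions(regs, cfg$flank_bp, bounds)
        write_tsv(intersect_annotations(ext, qtl),
                  file.path(cfg$outdir, paste0("qtl_hits_", nm, ".tsv")))
      }
    }
  }

  .write_pipeline_summary(out, cfg)
  invisible(out)
}

.write_pipeline_summary <- function(out, cfg) {
  lines <- c("# Pipeline summary", "")
  for (nm in names(out$qc)) {
    r <- out$qc[[nm]]
    lines <- c(lines, sprintf(
      "- %s: %d/%d SNPs and %d/%d samples retained after QC", nm,
      r$n_snps_post, r$n_snps_pre, r$n_samples_post, r$n_samples_pre))
  }
  if (!is.null(out$pca)) {
    lines <- c(lines, sprintf(
      "- PCA (pooled): PC1 %.2f%%, PC2 %.2f%% of variance",
      100 * out$pca$variance_explained[1L],
      100 * out$pca$variance_explained[2L]))
  }
  for (nm in names(out$ld_summary)) {
    sm <- out$ld_summary[[nm]]
    gw <- sm[sm$chrom == "genome", ]
    if (nrow(gw)) lines <- c(lines, sprintf(
      "- LD %s: genome-wide mean r2 %.3f +/- %.3f over %d reported pairs%s",
      nm, gw$mean_r2, gw$sd_r2, gw$n_pairs,
      if (cfg$replication_mode) " (r2 >= 0.2 reporting filter active)" else ""))
  }
  if (!is.null(out$block_summary)) {
    for (i in seq_len(nrow(out$block_summary))) {
      b <- out$block_summary[i, ]
      lines <- c(lines, sprintf(
        "- Blocks %s: %d blocks, %.2f Mb, %.2f%% coverage",
        b$population, b$n_blocks, b$total_length_mb, b$pct_genome_coverage))
    }
  }
  if (!is.null(out$xpehh)) {
    lines <- c(lines, sprintf("- XP-EHH: %d candidate run(s)",
                              nrow(out$xpehh$runs)))
  }
  writeLines(lines, file.path(cfg$outdir, "summary.md"))
}
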