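#' Read gene/QTL annotation intervals
#'
#' Imports BED (0-based half-open, converted) or GFF3 features as a
#' data.frame of 1-based inclusive intervals. Feature names come from the
#' BED name column or the GFF `Name`/`ID`/`gene_id` attribute.
#'
#' @param path BED or GFF3 file; format inferred from the extension.
#' @param source_tag label recorded in the `source` column.
#' @return data.frame `chrom, start_bp, end_bp, name, source`.
#' @export
read_annotation <- function(path, source_tag = basename(path)) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  fmt <- if (ext %in% c("gff", "gff3", "gtf")) "gff3" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
        else paste0("feature_", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             name = nm, source = source_tag, stringsAsFactors = FALSE)
}

#' Extend and merge candidate regions
#'
#' Adds a flank both upstream and downstream of each region (default
#' 200 kb), clamps at position 1 and at the chromosome end, and merges
#' regions that overlap after extension.
#'
#' @param regions data.frame `chrom, start_bp, end_bp` (1-based inclusive).
#' @param flank_bp flank length (default 200000).
#' @param chrom_bounds data.frame `chrom, end_bp` giving chromosome ends
#'   (e.g. from annotation or the last SNP); regions on chromosomes absent
#'   from it are clamped only at 1.
#' @return data.frame `chrom, start_bp, end_bp` of merged extended regions.
#' @export
extend_regions <- function(regions, flank_bp = 200000, chrom_bounds = NULL) {
  if (!nrow(regions)) return(regions[, c("chrom", "start_bp", "end_bp")])
  start <- pmax(1, regions$start_bp - flank_bp)
  end <- regions$end_bp + flank_bp
  if (!is.null(chrom_bounds)) {
    cap <- chrom_bounds$end_bp[match(regions$chrom, chrom_bounds$chrom)]
    end <- ifelse(is.na(cap), end, pmin(end, cap))
  }
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(start, end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Intersect regions with annotation features
#'
#' Reports every (region, feature) pair overlapping by at least 1 bp under
#' closed-interval semantics, with the overlap length — the behaviour of
#' `bedtools intersect` on the equivalent BED intervals.
#'
#' @param regions data.frame `chrom, start_bp, end_bp`.
#' @param annotation data.frame from [read_annotation()] (or any frame with
#'   `chrom, start_bp, end_bp, name`).
#' @param strict_chroms error (listing offenders) when the two inputs share
#'   no chromosome naming — a common silent failure mode.
#' @return data.frame `region_idx, chrom, region_start, region_end, name,
#'   feature_start, feature_end, overlap_bp`.
#' @export
intersect_annotations <- function(regions, annotation, strict_chroms = TRUE) {
  if (strict_chroms && nrow(regions) && nrow(annotation) &&
      !length(intersect(unique(regions$chrom), unique(annotation$chrom)))) {
    stop("no shared chromosome names; regions use {",
         paste(utils::head(unique(regions$chrom), 5), collapse = ","),
         "} but annotation uses {",
         paste(utils::head(unique(annotation$chrom), 5), collapse = ","), "}")
  }
  empty <- data.frame(region_idx = integer(), chrom = character(),
                      region_start = integer(), region_end = integer(),
                      name = character(), feature_start = integer(),
                      feature_end = integer(), overlap_bp = integer())
  if (!nrow(regions) || !nrow(annotation)) return(empty)
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start_bp,
                                                  regions$end_bp))
  gr_a <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start_bp,
                                                  annotation$end_bp))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_a))
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(gr_r[qi], gr_a[si]))
  data.frame(region_idx = qi, chrom = regions$chrom[qi],
             region_start = regions$start_bp[qi],
             region_end = regions$end_bp[qi],
             name = annotation$name[si],
             feature_start = annotation$start_bp[si],
             feature_end = annotation$end_bp[si],
             overlap_bp = w, stringsAsFactors = FALSE)
}

# case-fold and strip trailing .version suffixes from gene identifiers
.normalize_gene_ids <- function(x) {
  unique(toupper(sub("\\.[0-9]+$", "", trimws(x))))
}

#' Compare labelled gene sets
#'
#' Computes the counts (and members) of every exclusive intersection region
#' of up to four labelled gene sets — the numbers behind a Venn diagram.
#' Identifiers are normalized (case-folded, version suffixes stripped)
#' before comparison. For two sets A and B the output satisfies
#' `|A| = unique_A + shared`.
#'
#' @param sets named list of character vectors of gene identifiers
#'   (2 to 4 sets).
#' @return list with `regions` (data.frame `labels, n` for each of the
#'   2^k - 1 exclusive regions), `members` (named list of the genes in each
#'   region) and `set_sizes`.
#' @export
compare_gene_sets <- function(sets) {
  k <- length(sets)
  stopifnot(k >= 2L, k <= 4L, !is.null(names(sets)))
  sets <- lapply(sets, .normalize_gene_ids)
  labs <- names(sets)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labs, m, simplify = FALSE)), recursive = FALSE)
  members <- lapply(combos, function(in_labs) {
    out_labs <- setdiff(labs, in_labs)
    inter <- Reduce(intersect, sets[in_labs])
    setdiff(inter, unlist(sets[out_labs]))
  })
  names(members) <- vapply(combos, paste, "", collapse = "&")
  list(regions = data.frame(labels = names(members),
                            n = lengths(members), row.names = NULL),
       members = members,
       set_sizes = lengths(sets))
}

#' Write gene lists and Venn counts
#' @param comparison result of [compare_gene_sets()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_gene_sets <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(comparison$members)) {
    writeLines(comparison$members[[nm]],
               file.path(dir, paste0("genes_", gsub("&", "_AND_", nm), ".txt")))
  }
  jsonlite::write_json(
    stats::setNames(as.list(comparison$regions$n), comparison$regions$labels),
    file.path(dir, "venn_counts.json"), auto_unbox = TRUE)
  invisible(dir)
}
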