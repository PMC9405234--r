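#' @useDynLib ldsweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Variant metadata table
#'
#' Builds the per-variant metadata data frame used by [genotype_matrix()] and
#' [haplotype_matrix()]. Coordinates are 1-based base pairs. Variants with an
#' unknown position (`NA` or `pos < 1`) are dropped at construction time, and
#' duplicated positions within a chromosome are deduplicated (first record
#' kept), so that positions are strictly increasing within each chromosome.
#'
#' @param chrom chromosome labels (character or integer; autosome labels such
#'   as `"1"`..`"29"` for cattle, but any string is accepted).
#' @param pos 1-based physical positions.
#' @param vid variant identifiers; defaults to `chrom:pos`.
#' @param ref,alt single-character alleles; must differ per variant.
#' @param ancestral which allele is ancestral: `"ref"`, `"alt"` or `NA`
#'   (unknown).
#' @return data.frame with columns `chrom, pos, vid, ref, alt, ancestral`,
#'   sorted by `(chrom, pos)`.
#' @export
variant_table <- function(chrom, pos, vid = NULL,
                          ref = "A", alt = "G", ancestral = NA_character_) {
  n <- length(pos)
  v <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    pos = as.integer(pos),
    vid = if (is.null(vid)) paste0(rep_len(chrom, n), ":", pos)
          else as.character(vid),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    ancestral = rep_len(as.character(ancestral), n),
    stringsAsFactors = FALSE
  )
  bad <- !v$ancestral %in% c("ref", "alt") & !is.na(v$ancestral)
  if (any(bad)) stop("ancestral must be 'ref', 'alt' or NA")
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  keep <- !is.na(v$pos) & v$pos >= 1L
  if (any(!keep)) {
    message(sum(!keep), " variant(s) with unknown position dropped")
    v <- v[keep, , drop = FALSE]
  }
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  dup <- duplicated(paste(v$chrom, v$pos))
  if (any(dup)) {
    message(sum(dup), " duplicate-position variant(s) dropped")
    v <- v[!dup, , drop = FALSE]
  }
  if (anyDuplicated(v$vid)) stop("duplicated variant ids")
  rownames(v) <- NULL
  v
}

#' Sample metadata table
#'
#' @param sid unique sample identifiers.
#' @param population population label per sample.
#' @return data.frame with columns `sid, population`.
#' @export
sample_table <- function(sid, population = "pop1") {
  sid <- as.character(sid)
  if (anyDuplicated(sid)) stop("sample ids must be unique")
  data.frame(sid = sid,
             population = rep_len(as.character(population), length(sid)),
             stringsAsFactors = FALSE)
}

#' Diploid genotype matrix
#'
#' Container for a samples x variants matrix of alt-allele dosages
#' (0, 1, 2 or `NA` for missing), with sample and variant metadata.
#' Variant columns follow the (chrom, pos) order of `variants`.
#'
#' @param dosages integer matrix, samples in rows, variants in columns.
#'   `NA` encodes a missing call; values outside \{0,1,2,NA\} are rejected.
#' @param variants data.frame as from [variant_table()]. Reordering/filtering
#'   applied by the variant constructor is propagated to `dosages` by
#'   matching `vid` column names when present, otherwise by position (in which
#'   case the input must already be sorted).
#' @param samples data.frame as from [sample_table()].
#' @return object of class `geno_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!all(dosages %in% c(0L, 1L, 2L, NA))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(dosages) != nrow(samples)) stop("sample dimension mismatch")
  if (!is.null(colnames(dosages))) {
    if (!all(variants$vid %in% colnames(dosages))) {
      stop("variant ids absent from dosage column names")
    }
    dosages <- dosages[, variants$vid, drop = FALSE]
  } else if (ncol(dosages) != nrow(variants)) {
    stop("variant dimension mismatch")
  }
  colnames(dosages) <- variants$vid
  rownames(dosages) <- samples$sid
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' Phased haplotype matrix
#'
#' Container for phased binary haplotypes: a (2 x samples) x variants matrix
#' over \{0,1\} where 1 marks the alt allele. Haplotype rows `2k-1` and `2k`
#' belong to sample `k`.
#'
#' @param haps integer 0/1 matrix with `2 * nrow(samples)` rows.
#' @param variants,samples metadata as for [genotype_matrix()].
#' @return object of class `haplo_matrix`.
#' @export
haplotype_matrix <- function(haps, variants, samples) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (!all(haps %in% c(0L, 1L))) stop("haplotype entries must be 0 or 1")
  if (nrow(haps) != 2L * nrow(samples)) {
    stop("haps must have two rows per sample")
  }
  if (!is.null(colnames(haps))) {
    if (!all(variants$vid %in% colnames(haps))) {
      stop("variant ids absent from haplotype column names")
    }
    haps <- haps[, variants$vid, drop = FALSE]
  } else if (ncol(haps) != nrow(variants)) {
    stop("variant dimension mismatch")
  }
  colnames(haps) <- variants$vid
  rownames(haps) <- paste0(rep(samples$sid, each = 2L), c("_1", "_2"))
  structure(list(haps = haps, variants = variants, samples = samples),
            class = "haplo_matrix")
}

#' @method print geno_matrix
#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$samples), "samples x", nrow(x$variants),
      "variants on", length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @method print haplo_matrix
#' @export
print.haplo_matrix <- function(x, ...) {
  cat("haplo_matrix:", nrow(x$samples), "samples (",
      nrow(x$haps), "haplotypes ) x", nrow(x$variants), "variants\n")
  invisible(x)
}

#' Collapse phased haplotypes to diploid dosages
#'
#' @param h a `haplo_matrix`.
#' @return the corresponding `geno_matrix` (dosage = sum of the two
#'   haplotype alleles per sample).
#' @export
as_genotypes <- function(h) {
  stopifnot(inherits(h, "haplo_matrix"))
  n <- nrow(h$samples)
  d <- h$haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       h$haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(d, h$variants, h$samples)
}

n_variants <- function(x) nrow(x$variants)
n_samples <- function(x) nrow(x$samples)

# ---- PLINK bed/bim/fam ------------------------------------------------------

# 2-bit SNP-major v1 codes: 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2.
# We store dosages as counts of the bim A1 allele (taken as alt).
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK bed/bim/fam fileset
#'
#' Reads a SNP-major PLINK v1 binary fileset into a [genotype_matrix()].
#' Dosages count copies of the bim allele-1 (A1), which is mapped to `alt`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return a `geno_matrix`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing PLINK file(s): ",
                            paste(missing, collapse = ", "))
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character", "NULL",
                                          "integer", "character", "character"),
                           col.names = c("chrom", "vid", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = c("character", "character", rep("NULL", 4)),
                           col.names = c("fid", "sid", "x1", "x2", "x3", "x4"))
  n <- nrow(fam); l <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic)) {
    stop("not a SNP-major PLINK v1 bed file (bad magic bytes)")
  }
  bpv <- ceiling(n / 4)            # bytes per variant
  if (length(raw) - 3L != bpv * l) {
    stop("bed payload size inconsistent with bim/fam dimensions")
  }
  body <- raw[-(1:3)]
  # decode all 2-bit fields at once
  codes <- matrix(0L, nrow = 4L * bpv, ncol = l)
  ints <- as.integer(body)
  dim(ints) <- c(bpv, l)
  for (k in 0:3) {
    codes[seq_len(bpv) * 4L - 3L + k, ] <- bitwAnd(ints %/% (4L^k), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00->2 copies of A1, 10->1, 11->0, 01->missing
  dos <- matrix(NA_integer_, n, l)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  variants <- variant_table(bim$chrom, bim$pos, bim$vid,
                            ref = bim$a2, alt = bim$a1)
  colnames(dos) <- bim$vid
  genotype_matrix(dos, variants, sample_table(fam$sid))
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink()]: the alt allele is written as bim A1.
#'
#' @param g a `geno_matrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$vid, 0L, v$pos, v$alt, v$ref),
    paste0(prefix, ".bim"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$samples$sid, g$samples$sid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosages); l <- ncol(g$dosages); bpv <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4L * bpv, ncol = l)   # pad/missing code 01
  d <- g$dosages
  cd <- matrix(1L, n, l)
  cd[!is.na(d) & d == 2L] <- 0L
  cd[!is.na(d) & d == 1L] <- 2L
  cd[!is.na(d) & d == 0L] <- 3L
  codes[seq_len(n), ] <- cd
  ints <- integer(bpv * l)
  dim(ints) <- c(bpv, l)
  for (k in 0:3) {
    ints <- ints + codes[seq_len(bpv) * 4L - 3L + k, , drop = FALSE] * 4L^k
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(ints), con)
  invisible(prefix)
}

# ---- VCF --------------------------------------------------------------------

#' Read genotypes or phased haplotypes from a VCF
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_matrix()] or, when
#' `phased = TRUE`, a [haplotype_matrix()]. Only biallelic SNP records are
#' used; multiallelic records are skipped with a logged count. The ancestral
#' allele is taken from the `AA` INFO tag when present.
#'
#' @param path VCF file (plain or bgzipped).
#' @param phased if `TRUE`, every genotype must use the phased separator
#'   `|`; an unphased genotype is an error.
#' @return `geno_matrix` or `haplo_matrix`.
#' @export
read_vcf <- function(path, phased = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt[, -1, drop = FALSE]
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(!biallelic)) {
    message(sum(!biallelic), " non-biallelic-SNP record(s) skipped")
    fix <- fix[biallelic, , drop = FALSE]
    gt <- gt[biallelic, , drop = FALSE]
  }
  info <- fix$INFO %||% rep("", nrow(fix))
  info[is.na(info)] <- ""
  aa <- vapply(strsplit(info, ";", fixed = TRUE), function(fields) {
    hit <- grep("^AA=", fields, value = TRUE)
    if (length(hit)) sub("^AA=", "", hit[1L]) else NA_character_
  }, character(1))
  ancestral <- ifelse(is.na(aa), NA_character_,
                      ifelse(aa == fix$REF, "ref",
                             ifelse(aa == fix$ALT, "alt", NA_character_)))
  variants <- variant_table(fix$CHROM, as.integer(fix$POS), fix$ID,
                            ref = fix$REF, alt = fix$ALT,
                            ancestral = ancestral)
  # variant_table may reorder/drop; align gt by vid
  rownames(gt) <- fix$ID
  gt <- gt[variants$vid, , drop = FALSE]
  gtf <- sub(":.*", "", gt)             # GT is the first field by VCF spec
  samples <- sample_table(colnames(gt))
  as_allele_matrix <- function(x) {     # regex/coercion drop dim; restore it
    matrix(suppressWarnings(as.integer(x)), nrow(gt), ncol(gt))
  }
  if (phased) {
    if (any(grepl("/", gtf))) stop("unphased genotype found but phased input required")
    a1 <- as_allele_matrix(sub("\\|.*", "", gtf))
    a2 <- as_allele_matrix(sub(".*\\|", "", gtf))
    if (anyNA(a1) || anyNA(a2)) stop("missing or malformed GT in phased VCF")
    n <- ncol(gt)
    haps <- matrix(0L, 2L * n, nrow(gt))
    haps[seq(1L, 2L * n, 2L), ] <- t(a1)
    haps[seq(2L, 2L * n, 2L), ] <- t(a2)
    haplotype_matrix(haps, variants, samples)
  } else {
    a1 <- as_allele_matrix(substr(gtf, 1L, 1L))
    a2 <- as_allele_matrix(substr(gtf, 3L, 3L))
    dos <- t(a1 + a2)                   # NA propagates for ./.
    genotype_matrix(dos, variants, samples)
  }
}

#' Write phased haplotypes (or genotypes) to a VCF
#'
#' Writes a minimal VCF 4.2 with GT and, when the ancestral allele is known,
#' an `AA` INFO tag. Haplotype input is written phased (`|`), genotype input
#' unphased (`/`, heterozygotes as `0/1`).
#'
#' @param x `haplo_matrix` or `geno_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  info <- ifelse(is.na(v$ancestral), ".",
                 paste0("AA=", ifelse(v$ancestral == "ref", v$ref, v$alt)))
  if (inherits(x, "haplo_matrix")) {
    n <- nrow(x$samples)
    a1 <- t(x$haps[seq(1L, 2L * n, 2L), , drop = FALSE])
    a2 <- t(x$haps[seq(2L, 2L * n, 2L), , drop = FALSE])
    gt <- matrix(paste0(a1, "|", a2), nrow = nrow(v))
  } else {
    d <- t(x$dosages)
    gt <- matrix("./.", nrow(v), nrow(x$samples))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples$sid), collapse = "\t"))
  body <- cbind(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS", info, "GT", gt)
  writeLines(c(hdr, apply(body, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

# ---- grouping and frequencies ----------------------------------------------

#' Read a sample-to-population map
#'
#' @param path TSV with columns `sample_id` and `population` (header required).
#' @return named character vector, `sid -> population`.
#' @export
read_population_map <- function(path) {
  m <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "population") %in% names(m))) {
    stop("population map needs columns sample_id and population")
  }
  stats::setNames(m$population, m$sample_id)
}

#' Split a genotype or haplotype matrix by population
#'
#' Partitions samples by population label; the variant set is identical
#' across outputs. An empty label group yields an empty matrix that keeps the
#' full variant metadata.
#'
#' @param x `geno_matrix` or `haplo_matrix`.
#' @param map named character vector (`sid -> population`) or `NULL` to use
#'   the `population` column of the sample table.
#' @return named list of matrices, one per population level in `map`.
#' @export
split_by_population <- function(x, map = NULL) {
  if (is.null(map)) map <- stats::setNames(x$samples$population, x$samples$sid)
  unmapped <- setdiff(x$samples$sid, names(map))
  if (length(unmapped)) stop("unmapped sample(s): ",
                             paste(unmapped, collapse = ", "))
  pops <- map[x$samples$sid]
  out <- lapply(unique(unname(map)), function(p) {
    idx <- which(pops == p)
    s <- x$samples[idx, , drop = FALSE]
    s$population <- p
    rownames(s) <- NULL
    if (inherits(x, "haplo_matrix")) {
      hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
      haplotype_matrix(x$haps[hrows, , drop = FALSE], x$variants, s)
    } else {
      genotype_matrix(x$dosages[idx, , drop = FALSE], x$variants, s)
    }
  })
  names(out) <- unique(unname(map))
  out
}

#' Per-variant allele frequencies
#'
#' Computes the alt-allele frequency and minor allele frequency per variant,
#' using non-missing calls only. A variant with no non-missing call is
#' flagged (`NA` frequency), never silently set to zero.
#'
#' @param g `geno_matrix` (a `haplo_matrix` is collapsed first).
#' @return data.frame `vid, n_called, freq_alt, maf`.
#' @export
allele_frequencies <- function(g) {
  if (inherits(g, "haplo_matrix")) g <- as_genotypes(g)
  d <- g$dosages
  n_called <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0L] <- NA_real_
  data.frame(vid = g$variants$vid,
             n_called = as.integer(n_called),
             freq_alt = freq,
             maf = pmin(freq, 1 - freq),
             row.names = NULL)
}

#' Subset helper: keep a set of variants
#' @param x `geno_matrix` or `haplo_matrix`.
#' @param keep logical or index vector over variants.
#' @return same class as `x`.
#' @export
keep_variants <- function(x, keep) {
  v <- x$variants[keep, , drop = FALSE]
  rownames(v) <- NULL
  if (inherits(x, "haplo_matrix")) {
    haplotype_matrix(x$haps[, keep, drop = FALSE], v, x$samples)
  } else {
    genotype_matrix(x$dosages[, keep, drop = FALSE], v, x$samples)
  }
}

#' Subset helper: keep a set of samples
#' @param x `geno_matrix` or `haplo_matrix`.
#' @param keep logical or index vector over samples.
#' @return same class as `x`.
#' @export
keep_samples <- function(x, keep) {
  idx <- seq_len(nrow(x$samples))[keep]
  s <- x$samples[idx, , drop = FALSE]
  rownames(s) <- NULL
  if (inherits(x, "haplo_matrix")) {
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haplotype_matrix(x$haps[hrows, , drop = FALSE], x$variants, s)
  } else {
    genotype_matrix(x$dosages[idx, , drop = FALSE], x$variants, s)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
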