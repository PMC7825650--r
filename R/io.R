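# Readers and writers for the on-disk formats: minimal VCFv4.2 genotypes,
# probe-track TSV, BED gene regions, and the tabular reports.

#' Write a genotype matrix as minimal VCFv4.2
#'
#' Emits one unphased GT field per subject ("0/0", "0/1", "1/1", "./.").
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_map <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$subjects), collapse = "\t"))
  rows <- vapply(seq_len(nrow(gm$variants)), function(j) {
    v <- gm$variants[j, ]
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1])
    paste(c(v$chrom, v$pos, v$rsid, v$ref, v$alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read biallelic SNV genotypes from a VCF
#'
#' GT-only reader for biallelic SNVs; "./." (or any call with a missing
#' allele) is treated as missing. Phased separators are accepted and the
#' phase discarded.
#'
#' @param path VCF file path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT)
  if (!all(keep)) {
    warning(sum(!keep), " non-biallelic-SNV record(s) dropped")
    v <- v[keep, ]
    fix <- fix[keep, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  count_alt <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_integer_)
      sum(as.integer(p))
    }, integer(1))
  }
  calls <- matrix(count_alt(as.vector(alleles)),
                  nrow = nrow(gt), ncol = ncol(gt))
  variants <- data.frame(rsid = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(calls), variants, subjects = colnames(gt))
}

#' Write / read a probe-level log2-ratio track
#'
#' Three-column tab-separated format: `chrom`, `pos`, `log2ratio`.
#'
#' @param series A [probe_series()].
#' @param path File path.
#' @return `path` (writer) or a [probe_series()] (reader), invisibly for
#'   the writer.
#' @export
write_probe_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "probe_series"))
  df <- data.frame(chrom = series$chrom, pos = series$positions,
                   log2ratio = series$log2r)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param subject Subject id to attach to the track.
#' @rdname write_probe_series_tsv
#' @export
read_probe_series_tsv <- function(path, subject) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (length(unique(df$chrom)) != 1)
    stop("a probe track holds one chromosome; found ",
         length(unique(df$chrom)))
  probe_series(subject, df$chrom[1], df$pos, df$log2ratio)
}

#' Write / read gene regions as BED
#'
#' On disk BED is 0-based half-open; coordinates are converted to and from
#' the package's 1-based inclusive convention at this boundary.
#'
#' @param regions A [gene_region()] data frame.
#' @param path File path.
#' @return `path` (writer) or a [gene_region()] (reader).
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                   end = regions$end, name = regions$gene)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_region(gene = df[[4]], chrom = as.character(df[[1]]),
              start = df[[2]] + 1L, end = df[[3]])
}

#' Write tabular reports as TSV
#'
#' Generic TSV writer used for QC reports, segment tables, diplotype tables
#' and combined frequency tables.
#'
#' @param df A data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
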