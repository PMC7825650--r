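# Joining diplotypes with gene-level CNV status and tabulating combined
# frequency categories.

#' Combined diplotype-by-CNV category label
#'
#' Appends a CNV suffix to the diplotype label: none when the summary
#' status is neutral, " gain" for gain or amplification, " loss" for loss
#' or deletion (the two extreme levels fold into gain/loss for labelling).
#'
#' @param label Diplotype label (e.g. "*1*3").
#' @param status Gene-level summary CNV status.
#' @return Character category label, e.g. "*1*1 loss".
#' @examples
#' combine_category("*1*1", "loss")
#' @export
combine_category <- function(label, status) {
  if (!all(status %in% cnv_status_levels()))
    stop("unknown CNV status: ", paste(setdiff(status, cnv_status_levels()),
                                       collapse = ", "))
  suffix <- c(deletion = " loss", loss = " loss", neutral = "",
              gain = " gain", amplification = " gain")[status]
  paste0(label, suffix)
}

#' Tabulate combined categories across a cohort
#'
#' Counts subjects per (gene, category); every subject must contribute
#' exactly one category per gene, so per gene the counts sum to `n`.
#' Percentages are count / n x 100, rounded half-up to 2 decimals. Rows are
#' ordered by gene, then descending count, then label.
#'
#' @param categories Data frame with columns `subject`, `gene`, `category`.
#' @param n Cohort size.
#' @return Data frame of class `frequency_table` with `gene`, `category`,
#'   `count`, `percent`.
#' @export
tabulate_categories <- function(categories, n) {
  if (n <= 0) stop("cohort size must be positive")
  per_gene <- table(categories$gene)
  if (any(per_gene != n))
    stop("each subject must yield exactly one category per gene")
  agg <- stats::aggregate(list(count = categories$subject),
                          by = list(gene = categories$gene,
                                    category = categories$category),
                          FUN = length)
  agg$percent <- round_half_up(agg$count / n * 100, 2)
  agg <- agg[order(agg$gene, -agg$count, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n") <- n
  class(agg) <- c("frequency_table", "data.frame")
  agg
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("combined SNV x CNV frequency table (N =", attr(x, "n"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Run the combined SNV x CNV analysis end to end
#'
#' For each gene: (1) assigns star-allele diplotypes from the genotype
#' matrix; (2) segments every subject's probe series by sparse Bayesian
#' learning plus backward elimination, classifies segment means against the
#' log2-ratio cutoffs, and keeps non-neutral regions longer than the bp
#' cutoff; (3) summarizes each subject's CNV status over the padded gene
#' region; (4) combines diplotype and summary status into a single category
#' per subject per gene and tabulates counts and percentages.
#'
#' @param genotypes A [genotype_matrix()] covering the defining SNVs.
#' @param probes List of [probe_series()] objects (any number per subject;
#'   subjects with no series are copy-neutral everywhere).
#' @param regions A [gene_region()] data frame (unpadded gene bounds).
#' @param defs A [star_allele_defs()] table.
#' @param seg_params A [segmentation_params()].
#' @param cuts A [classifier_thresholds()].
#' @param pad Flanking bases added to each gene region (default 10000).
#' @return List with `diplotypes`, `segments` (all classified segments),
#'   `cnv_regions` (after filtering), `gene_status` (subject x gene summary
#'   plus status sets), `gene_freq` (gain/loss table), and `table` (the
#'   combined `frequency_table`).
#' @export
run_combined_analysis <- function(genotypes, probes, regions,
                                  defs = star_allele_defs(),
                                  seg_params = segmentation_params(),
                                  cuts = classifier_thresholds(),
                                  pad = 10000L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  padded <- pad_gene_region(regions, pad)

  diplo <- assign_diplotypes(genotypes, defs, genes = regions$gene)

  seg_list <- lapply(probes, function(ps)
    classify_segments(segment_series(ps, seg_params), cuts))
  segments <- do.call(rbind, seg_list)
  if (is.null(segments))
    segments <- data.frame(subject = character(0), chrom = character(0),
                           start_pos = numeric(0), end_pos = numeric(0),
                           n_probes = integer(0), mean_log2 = numeric(0),
                           status = character(0))
  cnv_regions <- filter_regions(segments, cuts)

  subjects <- genotypes$subjects
  status_rows <- list()
  summary_rows <- list()
  for (gi in seq_len(nrow(padded))) {
    region <- padded[gi, , drop = FALSE]
    for (s in subjects) {
      segs <- cnv_regions[cnv_regions$subject == s, , drop = FALSE]
      st <- gene_cnv_status(segs, region)
      status_rows[[length(status_rows) + 1]] <-
        data.frame(subject = s, gene = region$gene, status = st$statuses,
                   stringsAsFactors = FALSE)
      summary_rows[[length(summary_rows) + 1]] <-
        data.frame(subject = s, gene = region$gene, summary = st$summary,
                   stringsAsFactors = FALSE)
    }
  }
  status_sets <- do.call(rbind, status_rows)
  summaries <- do.call(rbind, summary_rows)

  merged <- merge(diplo, summaries, by = c("subject", "gene"))
  merged$category <- combine_category(merged$label, merged$summary)
  tab <- tabulate_categories(merged[, c("subject", "gene", "category")],
                             n = length(subjects))

  non_neutral <- status_sets[status_sets$status != "neutral", , drop = FALSE]
  gene_freq <- if (nrow(non_neutral) > 0 || nrow(status_sets) > 0) {
    cnv_frequency_table(status_sets, length(subjects))
  } else NULL

  list(diplotypes = diplo, segments = segments, cnv_regions = cnv_regions,
       gene_status = merged[, c("subject", "gene", "label", "summary",
                                "category")],
       status_sets = status_sets, gene_freq = gene_freq, table = tab)
}
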