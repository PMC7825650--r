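# Variant-level QC and population-genetic statistics.

#' Alternative-allele frequency of one variant
#'
#' Counts alternative alleles over all non-missing diploid calls. Missing
#' calls are excluded from both numerator and denominator.
#'
#' @param calls Integer vector of genotype calls in \{0, 1, 2, NA\}.
#' @return Frequency in \[0, 1\].
#' @examples
#' alt_allele_frequency(c(0L, 1L, 2L, NA))  # 3 alt alleles / 6 -> 0.5
#' @export
alt_allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stop("all calls are missing; frequency undefined")
  if (!all(calls[ok] %in% 0:2)) stop("calls must be 0, 1, 2 or NA")
  sum(calls[ok]) / (2 * sum(ok))
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions p^2, 2pq, q^2 expected under random mating, with
#' the allele frequency estimated from the same counts. No continuity
#' correction is applied. A monomorphic variant is returned as a perfect fit
#' (statistic 0, p-value 1).
#'
#' @param n_AA,n_Aa,n_aa Observed counts of hom-ref, het and hom-alt subjects.
#' @return List with `statistic` (chi-squared) and `p_value`.
#' @examples
#' hwe_chisq(25, 50, 25)  # exact HWE proportions: statistic 0, p 1
#' @export
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no observed genotypes")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1)
    return(list(statistic = 0, p_value = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' QC thresholds for variant filtering
#'
#' @param max_missing_rate Variants with missing rate strictly greater than
#'   this are removed (default 0.05).
#' @param min_maf Variants with minor allele frequency strictly less than
#'   this are removed (default 0.01).
#' @param min_hwe_p Variants with HWE p-value strictly less than this are
#'   removed (default 1e-6).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05, min_maf = 0.01,
                          min_hwe_p = 1e-6) {
  vals <- c(max_missing_rate, min_maf, min_hwe_p)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Filter variants by missingness, MAF and HWE
#'
#' A variant is removed iff its missing rate exceeds `max_missing_rate`, its
#' minor allele frequency (min of alt frequency and its complement) falls
#' below `min_maf`, or its HWE p-value falls below `min_hwe_p`. All three
#' statistics are computed on the full input matrix; rules are not
#' re-evaluated after removals, so the filter is idempotent. Boundary values
#' pass: exactly 0.05 missing, exactly 0.01 MAF and exactly 1e-6 p survive.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (the filtered matrix) and `report`, a data
#'   frame with one row per input variant: `rsid`, `miss_rate`, `maf`,
#'   `hwe_p`, `status` ("kept"/"removed") and `reason` (first failing rule:
#'   "missingness", "maf" or "hwe", else NA).
#' @export
qc_filter <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$calls) == 0) stop("empty genotype matrix")
  nv <- ncol(gm$calls)
  miss <- colMeans(is.na(gm$calls))
  maf <- hwe_p <- rep(NA_real_, nv)
  for (j in seq_len(nv)) {
    g <- gm$calls[, j]
    if (all(is.na(g))) next
    f <- alt_allele_frequency(g)
    maf[j] <- min(f, 1 - f)
    hw <- hwe_chisq(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                    sum(g == 2, na.rm = TRUE))
    hwe_p[j] <- hw$p_value
  }
  reason <- rep(NA_character_, nv)
  reason[is.na(reason) & (is.na(hwe_p) | hwe_p < thresholds$min_hwe_p)] <- "hwe"
  reason[is.na(maf) | maf < thresholds$min_maf] <- "maf"
  reason[miss > thresholds$max_missing_rate] <- "missingness"
  # precedence above is applied in reverse so that missingness wins, then maf
  keep <- is.na(reason)
  report <- data.frame(rsid = gm$variants$rsid, miss_rate = miss, maf = maf,
                       hwe_p = hwe_p,
                       status = ifelse(keep, "kept", "removed"),
                       reason = reason, stringsAsFactors = FALSE)
  filtered <- genotype_matrix(gm$calls[, keep, drop = FALSE],
                              gm$variants[keep, , drop = FALSE], gm$subjects)
  list(genotypes = filtered, report = report)
}

#' Gene regions with flanking padding
#'
#' @param gene Gene symbol(s).
#' @param chrom Chromosome name(s), e.g. "19".
#' @param start,end 1-based inclusive hg19 coordinates.
#' @return Data frame of class `gene_region`.
#' @export
gene_region <- function(gene, chrom, start, end) {
  if (any(start > end)) stop("start must not exceed end")
  if (any(start < 1)) stop("start must be >= 1")
  structure(data.frame(gene = as.character(gene), chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("gene_region", "data.frame"))
}

#' Pad gene regions up- and downstream
#'
#' Extends each region by `pad` bp on both sides, clamping the start at 1.
#' Padding is strand-independent.
#'
#' @param regions A [gene_region()] data frame.
#' @param pad Bases added on each side (default 10000, i.e. 10 kb).
#' @return The padded `gene_region` data frame.
#' @examples
#' pad_gene_region(gene_region("TPMT", "6", 18128545L, 18155374L))
#' @export
pad_gene_region <- function(regions, pad = 10000L) {
  stopifnot(inherits(regions, "data.frame"))
  regions$start <- as.integer(pmax(1, regions$start - pad))
  regions$end <- as.integer(regions$end + pad)
  regions
}
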