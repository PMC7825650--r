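#' Genotype matrix container
#'
#' Holds unphased biallelic genotypes for a cohort as allele counts of the
#' alternative allele: 0 (hom ref), 1 (het), 2 (hom alt), `NA` (missing).
#' Positions are 1-based hg19 coordinates.
#'
#' @param calls Integer matrix, subjects in rows, variants in columns, values
#'   in \{0, 1, 2, NA\}.
#' @param variants Data frame with columns `rsid`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per column of `calls`.
#' @param subjects Character vector of subject ids; defaults to the row names
#'   of `calls` or `S1..Sn`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `subjects`.
#' @examples
#' gm <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 2L, 0L), nrow = 2),
#'   variants = data.frame(rsid = c("rs1", "rs2"), chrom = "1",
#'                         pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' dim(gm$calls)
#' @export
genotype_matrix <- function(calls, variants, subjects = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("genotype calls must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("rsid", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(variants)))
    stop("variants must have columns: ", paste(needed, collapse = ", "))
  if (nrow(variants) != ncol(calls))
    stop("number of variants (", nrow(variants),
         ") does not match genotype columns (", ncol(calls), ")")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (is.null(subjects)) {
    subjects <- rownames(calls) %||% paste0("S", seq_len(nrow(calls)))
  }
  if (length(subjects) != nrow(calls))
    stop("number of subjects does not match genotype rows")
  dimnames(calls) <- list(subjects, variants$rsid)
  structure(list(calls = calls, variants = variants,
                 subjects = as.character(subjects)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subjects), "subjects x",
      nrow(x$variants), "variants\n")
  cat("  missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' Subset a genotype matrix by variant
#'
#' @param gm A [genotype_matrix()].
#' @param rsids Character vector of variant ids to keep, in the given order.
#' @return A `genotype_matrix` restricted to those variants.
#' @export
subset_variants <- function(gm, rsids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- match(rsids, gm$variants$rsid)
  if (anyNA(idx)) stop("unknown variant ids: ",
                       paste(rsids[is.na(idx)], collapse = ", "))
  genotype_matrix(gm$calls[, idx, drop = FALSE],
                  gm$variants[idx, , drop = FALSE], gm$subjects)
}
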