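# Table-driven star-allele diplotype assignment from unphased genotypes.

#' Star-allele definition table
#'
#' Each named allele is defined by one or more variant alleles; *1 is the
#' implicit all-reference haplotype and never appears in the table. The
#' packaged defaults cover CYP4F2 *2 (rs3093105) and *3 (rs2108622), TPMT
#' *3C (rs1142345), CYP2C19 *2 (rs4244285) and *3 (rs4986893), and CYP3A5
#' *3 (rs776746).
#'
#' @param df Data frame with columns `gene`, `allele`, `rsid`, `alt`; if
#'   `NULL` the packaged defaults are returned.
#' @return Data frame of class `star_allele_defs`.
#' @export
star_allele_defs <- function(df = NULL) {
  if (is.null(df)) {
    df <- utils::read.table(
      system.file("extdata", "star_alleles.tsv", package = "pgxcombine"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  needed <- c("gene", "allele", "rsid", "alt")
  if (!all(needed %in% names(df)))
    stop("definitions need columns: ", paste(needed, collapse = ", "))
  if (any(df$allele == "*1")) stop("*1 is implicit and must not be defined")
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("star_allele_defs", "data.frame"))
}

# defining loci of a gene, in table order of first appearance
gene_loci <- function(defs, gene) {
  sub <- defs[defs$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown gene: ", gene)
  unique(sub$rsid)
}

# named haplotypes of a gene as 0/1 vectors over its defining loci
gene_haplotypes <- function(defs, gene) {
  loci <- gene_loci(defs, gene)
  sub <- defs[defs$gene == gene, , drop = FALSE]
  alleles <- unique(sub$allele)
  haps <- list("*1" = rep(0L, length(loci)))
  for (a in alleles) {
    h <- rep(0L, length(loci))
    h[match(sub$rsid[sub$allele == a], loci)] <- 1L
    haps[[a]] <- h
  }
  haps
}

# canonical label: two allele names in ascending star-number order
diplotype_label <- function(a1, a2) {
  ord <- order(c(star_number(a1), star_number(a2)), c(a1, a2))
  paste(c(a1, a2)[ord], collapse = "")
}

#' Assign a star-allele diplotype from unphased genotypes
#'
#' Enumerates all unordered pairs of named haplotypes (the gene's defined
#' alleles plus the all-reference *1) and keeps those whose allele-count
#' sums reproduce the observed genotypes at the gene's defining SNVs. If
#' exactly one named pair is consistent the canonical diplotype is emitted
#' (so a double heterozygote across two single-SNV alleles resolves to the
#' trans pair). A genotype explained only by an unnamed haplotype carrying
#' several alleles' defining variants cannot be phased into named alleles;
#' it is emitted as a composite per-locus label - each variant-carrying
#' locus rendered as *1*X (het) or *X*X (hom alt) and joined by "-" in
#' definition-table order - with `resolved = FALSE`.
#'
#' @param genotypes Named integer vector (by rsid) of calls in \{0, 1, 2\}
#'   at the gene's defining SNVs; missing values are an error.
#' @param gene Gene symbol.
#' @param defs A [star_allele_defs()] table.
#' @return List of class `diplotype` with `gene`, `label`, `resolved`.
#' @examples
#' defs <- star_allele_defs(data.frame(
#'   gene = "CYP4F2", allele = c("*2", "*3"),
#'   rsid = c("rs3093105", "rs2108622"), alt = c("G", "T")))
#' assign_diplotype(c(rs3093105 = 1L, rs2108622 = 1L), "CYP4F2", defs)$label
#' @export
assign_diplotype <- function(genotypes, gene, defs = star_allele_defs()) {
  loci <- gene_loci(defs, gene)
  g <- genotypes[loci]
  if (anyNA(g))
    stop("missing genotype at defining SNV(s): ",
         paste(loci[is.na(g)], collapse = ", "), " (", gene, ")")
  if (!all(g %in% 0:2)) stop("genotypes must be 0, 1 or 2")

  haps <- gene_haplotypes(defs, gene)
  nm <- names(haps)
  consistent <- list()
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      if (all(haps[[i]] + haps[[j]] == g))
        consistent[[length(consistent) + 1]] <- c(nm[i], nm[j])
    }
  }
  if (length(consistent) == 1) {
    lab <- diplotype_label(consistent[[1]][1], consistent[[1]][2])
    return(structure(list(gene = gene, label = lab, resolved = TRUE),
                     class = "diplotype"))
  }
  # no (or no unique) named pair: composite per-locus genotype label
  allele_of <- vapply(loci, function(rs) {
    defs$allele[defs$gene == gene & defs$rsid == rs][1]
  }, character(1))
  parts <- character(0)
  for (i in seq_along(loci)) {
    if (g[i] == 1) parts <- c(parts, paste0("*1", allele_of[i]))
    if (g[i] == 2) parts <- c(parts, paste0(allele_of[i], allele_of[i]))
  }
  structure(list(gene = gene, label = paste(parts, collapse = "-"),
                 resolved = FALSE),
            class = "diplotype")
}

#' @export
print.diplotype <- function(x, ...) {
  cat(x$gene, x$label, if (!x$resolved) "(unresolved)", "\n")
  invisible(x)
}

#' Assign diplotypes for a cohort
#'
#' @param gm A [genotype_matrix()] containing every defining SNV of every
#'   gene in `defs` that is listed in `genes`.
#' @param defs A [star_allele_defs()] table.
#' @param genes Genes to call; defaults to all genes in `defs` whose
#'   defining SNVs are all present in `gm`.
#' @return Data frame with `subject`, `gene`, `label`, `resolved`.
#' @export
assign_diplotypes <- function(gm, defs = star_allele_defs(), genes = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(genes)) {
    genes <- unique(defs$gene)
    genes <- genes[vapply(genes, function(g)
      all(gene_loci(defs, g) %in% gm$variants$rsid), logical(1))]
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    loci <- gene_loci(defs, g)
    calls <- gm$calls[, loci, drop = FALSE]
    res <- lapply(seq_len(nrow(calls)), function(s) {
      gv <- calls[s, ]
      names(gv) <- loci
      assign_diplotype(gv, g, defs)
    })
    data.frame(subject = gm$subjects, gene = g,
               label = vapply(res, `[[`, character(1), "label"),
               resolved = vapply(res, `[[`, logical(1), "resolved"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
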