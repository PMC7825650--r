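# Shared helpers for building small in-memory fixtures.

toy_variants <- function(k, chrom = "1") {
  data.frame(rsid = paste0("rs", seq_len(k)), chrom = chrom,
             pos = seq_len(k) * 1000L, ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

toy_genotype_matrix <- function(calls, chrom = "1") {
  genotype_matrix(calls, toy_variants(ncol(calls), chrom))
}

# two-haplotype pool config over k loci: hap of all-1 with freq f1,
# all-0 with freq 1 - f1
two_hap_config <- function(n, seed, k = 2, f1 = 0.3) {
  simulation_config(
    n_subjects = n, seed = seed,
    variant_specs = within(toy_variants(k), alt_freq <- f1),
    haplotype_pool = list(haps = rbind(rep(1L, k), rep(0L, k)),
                          freq = c(f1, 1 - f1)))
}

# exhaustive minimum-RSS segmentation with exactly k breakpoints and a
# minimum segment length; independent oracle for the SBL + BE pipeline
min_rss_breakpoints <- function(y, k, min_seg_len) {
  n <- length(y)
  if (k == 0) return(integer(0))
  cand <- utils::combn(n - 1, k)
  best <- NULL
  best_rss <- Inf
  for (c_i in seq_len(ncol(cand))) {
    B <- cand[, c_i]
    lens <- diff(c(0, B, n))
    if (any(lens < min_seg_len)) next
    bounds <- c(0, B, n)
    rss <- 0
    for (s in seq_len(length(bounds) - 1)) {
      idx <- (bounds[s] + 1):bounds[s + 1]
      rss <- rss + sum((y[idx] - mean(y[idx]))^2)
    }
    if (rss < best_rss) {
      best_rss <- rss
      best <- B
    }
  }
  best
}

# breakpoint indices implied by a segments data frame
segment_breakpoints <- function(segs) {
  bp <- cumsum(segs$n_probes)
  bp[-length(bp)]
}
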