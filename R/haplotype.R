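# Haplotype frequency estimation by EM from unphased genotypes,
# pairwise LD statistics, and confidence-interval haplotype blocks.

# enumerate the ordered haplotype pairs consistent with one complete
# multilocus genotype; returns a 2-column matrix of haplotype indices
# (1-based into the 2^k lexicographic table, locus 1 most significant)
consistent_pairs <- function(g) {
  k <- length(g)
  het <- which(g == 1)
  h1 <- ifelse(g == 2, 1L, 0L)
  h2 <- h1
  if (length(het) == 0) {
    idx <- hap_index(h1, k)
    return(matrix(c(idx, idx), ncol = 2))
  }
  n_conf <- 2^length(het)
  out <- matrix(0L, n_conf, 2)
  for (c_i in seq_len(n_conf)) {
    bits <- as.integer(intToBits(c_i - 1L))[seq_along(het)]
    a <- h1; b <- h2
    a[het] <- bits
    b[het] <- 1L - bits
    out[c_i, ] <- c(hap_index(a, k), hap_index(b, k))
  }
  out
}

hap_index <- function(h, k) {
  sum(h * 2^((k - 1):0)) + 1L
}

hap_label <- function(idx, k) {
  vapply(idx, function(i) {
    bits <- as.integer(intToBits(i - 1L))[k:1]
    paste(bits, collapse = "")
  }, character(1))
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies at `k` biallelic loci via the
#' standard EM algorithm: the E-step distributes each ambiguous multilocus
#' genotype over its consistent haplotype pairs in proportion to the current
#' frequency products; the M-step re-estimates frequencies from the expected
#' haplotype counts. Initialization is the linkage-equilibrium product of
#' single-locus allele frequencies (deterministic, no random restarts).
#' Subjects with a missing call at any locus are dropped.
#'
#' @param geno Matrix of genotypes (subjects x loci) in \{0, 1, 2, NA\}.
#' @param tol Convergence tolerance on the max absolute frequency change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List with `freq` (named vector over haplotypes written as 0/1
#'   strings in locus order, alt allele = 1), `loglik`, `iterations`,
#'   `converged` and `n_used`.
#' @examples
#' g <- rbind(c(0, 0), c(1, 1), c(2, 2))
#' em_haplotype_freqs(g)$freq
#' @export
em_haplotype_freqs <- function(geno, tol = 1e-8, max_iter = 1000) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  if (k < 2) stop("at least two loci are required")
  if (k > 12) stop("too many loci for explicit 2^k enumeration")
  complete <- stats::complete.cases(geno)
  if (!any(complete)) stop("no fully observed subject")
  geno <- geno[complete, , drop = FALSE]
  n <- nrow(geno)
  nh <- 2^k

  # collapse to unique genotype rows with multiplicities
  key <- apply(geno, 1, paste, collapse = ",")
  tab <- table(key)
  ug <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  wt <- as.numeric(tab)
  pairs <- lapply(seq_len(nrow(ug)), function(i) consistent_pairs(ug[i, ]))

  # linkage-equilibrium initialization
  pa <- colMeans(geno) / 2
  f <- rep(1, nh)
  for (j in seq_len(k)) {
    bit <- bitwAnd((seq_len(nh) - 1L) %/% 2^(k - j), 1L)
    f <- f * ifelse(bit == 1L, pa[j], 1 - pa[j])
  }
  f <- f / sum(f)

  loglik <- -Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    counts <- rep(0, nh)
    ll <- 0
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      p_conf <- f[pr[, 1]] * f[pr[, 2]]
      tot <- sum(p_conf)
      if (tot <= 0) {
        # degenerate: distribute uniformly to keep EM defined
        p_conf <- rep(1 / nrow(pr), nrow(pr))
        tot <- 1e-300
      } else {
        p_conf <- p_conf / tot
      }
      ll <- ll + wt[i] * log(tot)
      for (r in seq_len(nrow(pr))) {
        counts[pr[r, 1]] <- counts[pr[r, 1]] + wt[i] * p_conf[r]
        counts[pr[r, 2]] <- counts[pr[r, 2]] + wt[i] * p_conf[r]
      }
    }
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    loglik <- ll
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not converge in ", it, " iterations (max change > tol)")
  names(f) <- hap_label(seq_len(nh), k)
  list(freq = f, loglik = loglik, iterations = it, converged = converged,
       n_used = n)
}

# multinomial log-likelihood of the 3x3 two-locus genotype table given
# haplotype frequencies (p11, p10, p01, p00); alt allele coded 1
two_locus_loglik <- function(tab9, p11, p10, p01, p00) {
  h <- c(p11, p10, p01, p00)
  h[h < 0] <- 0
  # genotype class probabilities; rows locus A genotype 2,1,0 x cols B 2,1,0
  P <- c(
    p11^2, 2 * p11 * p10, p10^2,
    2 * p11 * p01, 2 * (p11 * p00 + p10 * p01), 2 * p10 * p00,
    p01^2, 2 * p01 * p00, p00^2
  )
  P[P < 0] <- 0
  if (any(tab9 > 0 & P <= 0)) return(-Inf)
  sum(tab9[tab9 > 0] * log(P[tab9 > 0]))
}

#' Pairwise linkage disequilibrium between two loci
#'
#' Estimates two-locus haplotype frequencies by [em_haplotype_freqs()], then
#' derives D (covariance between alt-allele indicators), D' (D scaled by its
#' admissible maximum), and r-squared. A 90% confidence interval for D' is
#' obtained from the normalized likelihood over a 201-point grid on
#' \[0, 1\] (cumulative bounds at 5% and 95%), holding the allele
#' frequencies at their sample estimates; this is the deterministic analogue
#' of the interval used by confidence-interval block finders.
#'
#' @param ga,gb Genotype vectors in \{0, 1, 2, NA\} at loci A and B.
#' @param n_grid Grid points for the D' likelihood (default 201).
#' @return An object of class `ld_result`: list with `D`, `Dprime`, `r2`,
#'   `dprime_ci` (lower, upper), and `p_a`, `p_b` (alt-allele frequencies).
#' @export
pairwise_ld <- function(ga, gb, n_grid = 201) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  p_a <- mean(ga) / 2
  p_b <- mean(gb) / 2
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1)
    stop("both loci must be polymorphic")
  em <- em_haplotype_freqs(cbind(ga, gb))
  p11 <- em$freq[["11"]]
  D <- p11 - p_a * p_b
  if (D >= 0) {
    dmax <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    dmax <- min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  dprime <- min(dprime, 1)
  r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  r2 <- min(r2, 1)

  # D' likelihood grid at the MLE sign of D
  tab9 <- table(factor(ga, levels = 2:0), factor(gb, levels = 2:0))
  tab9 <- as.numeric(t(tab9))  # row-major: A=2 row first, B=2 col first
  s <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(grid, function(d) {
    q11 <- p_a * p_b + s * d * dmax
    q10 <- p_a - q11
    q01 <- p_b - q11
    q00 <- 1 - q11 - q10 - q01
    two_locus_loglik(tab9, q11, q10, q01, q00)
  }, numeric(1))
  lik <- exp(ll - max(ll[is.finite(ll)]))
  lik[!is.finite(lik)] <- 0
  cum <- cumsum(lik) / sum(lik)
  lower <- grid[which(cum >= 0.05)[1]]
  upper <- grid[which(cum >= 0.95)[1]]
  structure(list(D = as.numeric(D), Dprime = dprime, r2 = as.numeric(r2),
                 dprime_ci = c(lower = lower, upper = upper),
                 p_a = p_a, p_b = p_b, n_used = length(ga)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD: D = %.4f, D' = %.3f (90%% CI %.2f-%.2f), r2 = %.3f\n",
              x$D, x$Dprime, x$dprime_ci[1], x$dprime_ci[2], x$r2))
  invisible(x)
}

#' Block-finding thresholds (confidence-interval rule)
#'
#' Defaults follow the confidence-interval block definition as popularized
#' by Haploview: a pair is in strong LD when its D' CI upper bound is at
#' least 0.98 and its lower bound at least 0.70; it shows strong evidence of
#' recombination when the upper bound falls below 0.90; a span qualifies as
#' a block when at least 95% of its informative pairs are in strong LD.
#'
#' @param ci_upper_strong,ci_lower_strong,ci_upper_recomb,informative_frac
#'   Rule thresholds as above.
#' @return A list of class `block_thresholds`.
#' @export
block_thresholds <- function(ci_upper_strong = 0.98, ci_lower_strong = 0.70,
                             ci_upper_recomb = 0.90, informative_frac = 0.95) {
  structure(list(ci_upper_strong = ci_upper_strong,
                 ci_lower_strong = ci_lower_strong,
                 ci_upper_recomb = ci_upper_recomb,
                 informative_frac = informative_frac),
            class = "block_thresholds")
}

# classify every variant pair: +1 strong LD, -1 strong recombination,
# 0 uninformative; returns a k x k matrix (upper triangle used)
pair_ld_classes <- function(calls, thresholds) {
  k <- ncol(calls)
  cls <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(calls[, i]) & !is.na(calls[, j])
      if (sum(ok) < 2) next
      pa <- mean(calls[ok, i]) / 2
      pb <- mean(calls[ok, j]) / 2
      if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) next
      ld <- pairwise_ld(calls[, i], calls[, j])
      ci <- ld$dprime_ci
      if (ci["upper"] >= thresholds$ci_upper_strong &&
          ci["lower"] >= thresholds$ci_lower_strong) {
        cls[i, j] <- 1L
      } else if (ci["upper"] < thresholds$ci_upper_recomb) {
        cls[i, j] <- -1L
      }
    }
  }
  cls
}

# does the span [i, j] satisfy the informative-pair rule?
span_is_block <- function(cls, i, j, informative_frac) {
  sub <- cls[i:j, i:j]
  inf_pairs <- sum(sub != 0)
  strong <- sum(sub == 1)
  inf_pairs > 0 && strong / inf_pairs >= informative_frac
}

#' Haplotype blocks by the confidence-interval rule
#'
#' Classifies every variant pair as strong LD, strong recombination or
#' uninformative from the 90% D' confidence interval, then enumerates all
#' contiguous spans of two or more variants and keeps those in which the
#' strong-LD fraction of informative pairs meets the threshold. Maximal
#' non-overlapping spans are selected greedily, longest first with ties
#' broken leftmost. Haplotype frequencies inside each block are estimated by
#' [em_haplotype_freqs()] over the block's loci.
#'
#' @param gm A [genotype_matrix()] with variants sorted by position.
#' @param thresholds A [block_thresholds()].
#' @return List of `haplotype_block` objects; each has `variants` (rsids),
#'   `first`, `last` (column indices), and `haplotypes` (data frame with
#'   `hap` as a ref/alt nucleotide string in position order and `freq`).
#' @export
gabriel_blocks <- function(gm, thresholds = block_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  k <- nrow(gm$variants)
  if (k < 2) stop("at least two variants are required")
  if (is.unsorted(gm$variants$pos)) stop("variants must be position-sorted")
  cls <- pair_ld_classes(gm$calls, thresholds)

  spans <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (span_is_block(cls, i, j, thresholds$informative_frac))
        spans[[length(spans) + 1]] <- c(i, j)
    }
  }
  if (length(spans) == 0) return(list())
  spans <- do.call(rbind, spans)
  ord <- order(-(spans[, 2] - spans[, 1]), spans[, 1])
  spans <- spans[ord, , drop = FALSE]

  taken <- rep(FALSE, k)
  blocks <- list()
  for (r in seq_len(nrow(spans))) {
    i <- spans[r, 1]; j <- spans[r, 2]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    em <- em_haplotype_freqs(gm$calls[, i:j, drop = FALSE])
    keep <- em$freq > 1e-6
    hstr <- vapply(names(em$freq)[keep], function(h) {
      bits <- as.integer(strsplit(h, "")[[1]])
      paste(ifelse(bits == 1, gm$variants$alt[i:j], gm$variants$ref[i:j]),
            collapse = "-")
    }, character(1))
    haps <- data.frame(hap = unname(hstr), freq = unname(em$freq[keep]),
                       stringsAsFactors = FALSE)
    haps <- haps[order(-haps$freq), , drop = FALSE]
    rownames(haps) <- NULL
    blocks[[length(blocks) + 1]] <- structure(
      list(variants = gm$variants$rsid[i:j], first = i, last = j,
           haplotypes = haps),
      class = "haplotype_block")
  }
  # report blocks left to right
  blocks[order(vapply(blocks, `[[`, 1L, "first"))]
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("haplotype block:", paste(x$variants, collapse = ", "), "\n")
  print(x$haplotypes)
  invisible(x)
}
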