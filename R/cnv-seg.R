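# Piecewise-constant segmentation of aCGH log2-ratio probe series:
# sparse Bayesian learning over a step-function basis, backward
# elimination of breakpoints, copy-number classification and gene-level
# summaries.

#' Probe-level log2-ratio series
#'
#' @param subject Subject id.
#' @param chrom Chromosome name.
#' @param positions Strictly increasing 1-based bp positions.
#' @param log2r Log2 intensity ratio per probe (0 at copy-neutral state).
#' @return An object of class `probe_series`.
#' @export
probe_series <- function(subject, chrom, positions, log2r) {
  positions <- as.numeric(positions)
  log2r <- as.numeric(log2r)
  if (length(positions) != length(log2r))
    stop("positions and log2r must have equal length")
  if (length(positions) < 2) stop("a probe series needs at least 2 probes")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  structure(list(subject = as.character(subject), chrom = as.character(chrom),
                 positions = positions, log2r = log2r),
            class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat("probe_series:", x$subject, "chr", x$chrom, "-", length(x$log2r),
      "probes,", x$positions[1], "-", x$positions[length(x$positions)], "bp\n")
  invisible(x)
}

#' Segmentation parameters
#'
#' @param T Breakpoint t-statistic threshold for backward elimination
#'   (default 4.5).
#' @param a Sparseness hyperparameter of the hierarchical prior on
#'   breakpoint weights (default 0.2); larger values prune more aggressively.
#' @param min_seg_len Minimum probes per reported segment (default 6).
#' @param tol Convergence tolerance on breakpoint weights (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(T = 4.5, a = 0.2, min_seg_len = 6,
                                tol = 1e-6, max_iter = 500) {
  if (T <= 0) stop("T must be positive")
  if (min_seg_len < 1) stop("min_seg_len must be >= 1")
  structure(list(T = T, a = a, min_seg_len = as.integer(min_seg_len),
                 tol = tol, max_iter = max_iter),
            class = "segmentation_params")
}

# normalized step-function basis: column m is the unit-norm, zero-mean step
# with its jump between probes m and m+1
step_basis <- function(n) {
  m <- seq_len(n - 1)
  F <- matrix(0, n, n - 1)
  for (b in m) {
    F[seq_len(b), b] <- -sqrt((n - b) / (n * b))
    F[(b + 1):n, b] <- sqrt(b / (n * (n - b)))
  }
  F
}

#' Robust per-track noise-variance estimate
#'
#' Estimates the per-probe noise variance from lag-1 differences of the
#' log2 ratios. True copy-number jumps contaminate only a sparse minority
#' of the differences, so the largest 10 percent of absolute differences
#' (at least four) are discarded and the mean of the remaining squared
#' differences is rescaled by the Gaussian truncation factor
#' 1 - 2 c phi(c) / q (with c the standard-normal quantile at the kept
#' fraction q), giving a nearly unbiased estimate of Var(diff) under pure
#' Gaussian noise. The probe noise variance is half the difference
#' variance. Compared with the MAD this estimator has much lower sampling
#' variance on short tracks, where an underestimated sigma would inflate
#' every breakpoint t-statistic. It assumes breakpoints occupy fewer than
#' 10 percent of probe transitions.
#'
#' @param y Numeric vector of ordered log2 ratios (length >= 2).
#' @return The estimated per-probe noise variance (may be 0 for a
#'   noiseless piecewise-constant input).
#' @export
robust_noise_variance <- function(y) {
  d <- diff(y)
  k <- length(d)
  n_drop <- max(4L, ceiling(0.1 * k))
  n_keep <- max(k - n_drop, min(k, 5L))
  d_kept <- sort(abs(d))[seq_len(n_keep)]
  q <- n_keep / k
  shrink <- if (q >= 1) 1 else {
    cq <- stats::qnorm((1 + q) / 2)
    1 - 2 * cq * stats::dnorm(cq) / q
  }
  mean(d_kept^2) / shrink / 2
}

#' Sparse Bayesian learning of breakpoint weights
#'
#' Fits y = F w + e where F is the normalized step-function basis with one
#' column per candidate breakpoint between adjacent probes, under a
#' hierarchical sparse prior on w: w_m ~ N(0, 1/alpha_m) with a Gamma
#' hyperprior on alpha_m governed by the sparseness parameter `a`. EM
#' alternates the posterior moments of w with hyperparameter updates;
#' candidate breakpoints whose precision diverges are pruned from the
#' active set. The noise variance is estimated robustly from lag-1 probe
#' differences by [robust_noise_variance()], which is insensitive to the
#' sparse true jumps.
#'
#' @param series A [probe_series()].
#' @param params A [segmentation_params()].
#' @return An object of class `sbl_fit`: list with `series`, `breakpoints`
#'   (indices m of surviving candidates; breakpoint m lies between probes m
#'   and m+1), `weights` (posterior mean per candidate, zero if pruned),
#'   `post_var` (posterior variance, NA if pruned), `sigma2` (noise-variance
#'   estimate), `iterations`, `converged`.
#' @export
sbl_segment <- function(series, params = segmentation_params()) {
  stopifnot(inherits(series, "probe_series"))
  y <- series$log2r
  n <- length(y)
  if (!all(is.finite(y))) stop("log2 ratios must be finite")
  if (n < 2 * params$min_seg_len)
    stop("series too short: need at least 2 * min_seg_len probes")
  yc <- y - mean(y)
  F <- step_basis(n)
  FtF <- crossprod(F)
  Fty <- drop(crossprod(F, yc))
  M <- n - 1

  active <- seq_len(M)
  alpha <- rep(1, M)
  # noise variance held fixed during EM so that the saturated step basis
  # (n - 1 candidates for n probes) cannot absorb the noise and collapse
  # the variance estimate
  sigma2 <- max(robust_noise_variance(y), 1e-12)
  w <- rep(0, M)
  post_var <- rep(NA_real_, M)
  converged <- FALSE
  it <- 0
  while (it < params$max_iter && length(active) > 0) {
    it <- it + 1
    A <- FtF[active, active, drop = FALSE] / sigma2
    diag(A) <- diag(A) + alpha[active]
    Sigma <- chol2inv(chol(A))
    mu <- drop(Sigma %*% Fty[active]) / sigma2
    dvar <- diag(Sigma)
    w_new <- rep(0, M)
    w_new[active] <- mu
    alpha[active] <- (1 + 2 * params$a) / (mu^2 + dvar)
    delta <- max(abs(w_new - w))
    w <- w_new
    post_var[active] <- dvar
    drop_idx <- alpha[active] > 1e8
    if (any(drop_idx)) {
      w[active[drop_idx]] <- 0
      post_var[active[drop_idx]] <- NA_real_
      active <- active[!drop_idx]
    }
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(series = series, breakpoints = active, weights = w,
                 post_var = post_var, sigma2 = sigma2, iterations = it,
                 converged = converged),
            class = "sbl_fit")
}

# t statistics of each breakpoint in sorted set B against its current
# neighbor segments; sigma2 is the pooled noise-variance estimate
breakpoint_tstats <- function(y, B, sigma2) {
  if (length(B) == 0) return(numeric(0))
  bounds <- c(0, B, length(y))
  vapply(seq_along(B), function(i) {
    left <- (bounds[i] + 1):bounds[i + 1]
    right <- (bounds[i + 1] + 1):bounds[i + 2]
    se <- sqrt(sigma2 * (1 / length(left) + 1 / length(right)))
    abs(mean(y[right]) - mean(y[left])) / se
  }, numeric(1))
}

segments_from_breakpoints <- function(series, B) {
  y <- series$log2r
  bounds <- c(0, sort(B), length(y))
  out <- lapply(seq_len(length(bounds) - 1), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    data.frame(subject = series$subject, chrom = series$chrom,
               start_pos = series$positions[idx[1]],
               end_pos = series$positions[idx[length(idx)]],
               n_probes = length(idx), mean_log2 = mean(y[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Backward elimination of breakpoints
#'
#' Starting from the breakpoints surviving sparse Bayesian learning, scores
#' each breakpoint by t = |difference of adjacent segment means| / its
#' standard error (using the pooled noise variance from the SBL stage) and
#' repeatedly removes the minimum-t breakpoint, recomputing neighbor means
#' and scores, until every breakpoint has t >= T. Minimum segment length is
#' then enforced: while any segment is shorter than `min_seg_len` probes,
#' the shortest (leftmost on ties) segment is merged into a neighbor by
#' dropping whichever of its boundary breakpoints has the lower t. Segment
#' means are recomputed exactly from member probes.
#'
#' @param fit An `sbl_fit` from [sbl_segment()].
#' @param params A [segmentation_params()].
#' @return Data frame of class `cnv_segments` with columns `subject`,
#'   `chrom`, `start_pos`, `end_pos`, `n_probes`, `mean_log2`; segments are
#'   contiguous and jointly cover all probes.
#' @export
backward_eliminate <- function(fit, params = segmentation_params()) {
  stopifnot(inherits(fit, "sbl_fit"))
  y <- fit$series$log2r
  B <- sort(fit$breakpoints)
  sigma2 <- fit$sigma2

  # t-statistic criterion
  while (length(B) > 0) {
    t <- breakpoint_tstats(y, B, sigma2)
    if (min(t) >= params$T) break
    B <- B[-which.min(t)]
  }

  # minimum segment length, shortest segment first
  repeat {
    if (length(B) == 0) break
    bounds <- c(0, B, length(y))
    lens <- diff(bounds)
    if (all(lens >= params$min_seg_len)) break
    s <- which.min(lens)  # leftmost shortest
    if (s == 1) {
      drop_i <- 1
    } else if (s == length(lens)) {
      drop_i <- length(B)
    } else {
      t <- breakpoint_tstats(y, B, sigma2)
      drop_i <- if (t[s - 1] <= t[s]) s - 1 else s
    }
    B <- B[-drop_i]
  }

  segs <- segments_from_breakpoints(fit$series, B)
  class(segs) <- c("cnv_segments", "data.frame")
  segs
}

#' Segment a probe series
#'
#' Convenience wrapper running [sbl_segment()] then [backward_eliminate()].
#'
#' @param series A [probe_series()].
#' @param params A [segmentation_params()].
#' @return A `cnv_segments` data frame.
#' @export
segment_series <- function(series, params = segmentation_params()) {
  backward_eliminate(sbl_segment(series, params), params)
}

#' Copy-number classification thresholds
#'
#' @param gain_loss_cut Absolute log2-ratio cutoff for gain/loss
#'   (default 0.25).
#' @param amp_del_cut Absolute cutoff for amplification/deletion
#'   (default 0.8).
#' @param min_region_bp CNV regions must span strictly more than this many
#'   bp to be retained (default 50).
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(gain_loss_cut = 0.25, amp_del_cut = 0.8,
                                  min_region_bp = 50) {
  if (!(gain_loss_cut > 0 && gain_loss_cut < amp_del_cut))
    stop("need 0 < gain_loss_cut < amp_del_cut")
  structure(list(gain_loss_cut = gain_loss_cut, amp_del_cut = amp_del_cut,
                 min_region_bp = min_region_bp),
            class = "classifier_thresholds")
}

#' Copy-number status levels
#'
#' @return Character vector of the five status levels in increasing
#'   copy-number order.
#' @export
cnv_status_levels <- function() {
  c("deletion", "loss", "neutral", "gain", "amplification")
}

#' Classify a segment mean as a copy-number status
#'
#' Mutually exclusive, total partition of the real line: amplification if
#' mean >= +`amp_del_cut`; gain if +`gain_loss_cut` <= mean <
#' +`amp_del_cut`; deletion if mean <= -`amp_del_cut`; loss if
#' -`amp_del_cut` < mean <= -`gain_loss_cut`; neutral otherwise.
#'
#' @param mean_log2 Numeric vector of segment mean log2 ratios.
#' @param cuts A [classifier_thresholds()].
#' @return Character vector of statuses.
#' @examples
#' classify_segment(c(-1, -0.4, 0, 0.4, 1))
#' @export
classify_segment <- function(mean_log2, cuts = classifier_thresholds()) {
  if (any(!is.finite(mean_log2))) stop("segment means must be finite")
  ifelse(mean_log2 >= cuts$amp_del_cut, "amplification",
  ifelse(mean_log2 >= cuts$gain_loss_cut, "gain",
  ifelse(mean_log2 <= -cuts$amp_del_cut, "deletion",
  ifelse(mean_log2 <= -cuts$gain_loss_cut, "loss", "neutral"))))
}

#' Add a status column to segments
#'
#' @param segments A `cnv_segments` data frame.
#' @param cuts A [classifier_thresholds()].
#' @return The same data frame with a `status` column.
#' @export
classify_segments <- function(segments, cuts = classifier_thresholds()) {
  segments$status <- classify_segment(segments$mean_log2, cuts)
  segments
}

#' Retain non-neutral CNV regions longer than the bp cutoff
#'
#' Keeps classified segments whose status is not neutral and whose span
#' (`end_pos - start_pos + 1`, 1-based inclusive) strictly exceeds
#' `min_region_bp`; a region of exactly that length is dropped.
#'
#' @param segments Classified `cnv_segments` (with `status`).
#' @param cuts A [classifier_thresholds()].
#' @return The filtered data frame.
#' @export
filter_regions <- function(segments, cuts = classifier_thresholds()) {
  if (is.null(segments$status)) stop("segments must be classified first")
  keep <- segments$status != "neutral" &
    (segments$end_pos - segments$start_pos + 1) > cuts$min_region_bp
  segments[keep, , drop = FALSE]
}

#' Gene-level CNV status for one subject
#'
#' A filtered segment contributes to a gene iff it overlaps the padded gene
#' region by at least 1 bp. The status set may contain both gain-side and
#' loss-side entries; the summary status is the contributing segment with
#' the largest |mean log2| (ties broken by longer bp span, then leftmost).
#' With no overlapping segment both the set and the summary are "neutral".
#'
#' @param segments One subject's filtered, classified segments.
#' @param region A single padded [gene_region()] row.
#' @return List with `statuses` (character set) and `summary` (single
#'   status).
#' @export
gene_cnv_status <- function(segments, region) {
  if (nrow(region) != 1) stop("one region at a time")
  ov <- segments$chrom == region$chrom &
    segments$start_pos <= region$end & segments$end_pos >= region$start
  hits <- segments[ov, , drop = FALSE]
  if (nrow(hits) == 0)
    return(list(statuses = "neutral", summary = "neutral"))
  ord <- order(-abs(hits$mean_log2),
               -(hits$end_pos - hits$start_pos + 1), hits$start_pos)
  list(statuses = unique(hits$status), summary = hits$status[ord[1]])
}

#' Gene-level CNV gain/loss frequency table
#'
#' A subject counts toward a gene's gain frequency if any of their statuses
#' at that gene is gain or amplification, and toward its loss frequency if
#' any is loss or deletion; the two columns are not mutually exclusive.
#' Percentages are count / cohort x 100, rounded half-up to 2 decimals.
#'
#' @param gene_status Data frame with columns `subject`, `gene`, `status`
#'   (one row per status in a subject's status set for that gene).
#' @param n_subjects Cohort size.
#' @param min_freq If not `NULL`, keep only genes where
#'   max(gain%, loss%) strictly exceeds this value (e.g. 1).
#' @return Data frame with `gene`, `gain_n`, `loss_n`, `gain_pct`,
#'   `loss_pct`.
#' @export
cnv_frequency_table <- function(gene_status, n_subjects, min_freq = NULL) {
  if (n_subjects <= 0) stop("cohort size must be positive")
  genes <- sort(unique(gene_status$gene))
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- gene_status[gene_status$gene == g, , drop = FALSE]
    gain_n <- length(unique(sub$subject[sub$status %in%
                                          c("gain", "amplification")]))
    loss_n <- length(unique(sub$subject[sub$status %in%
                                          c("loss", "deletion")]))
    data.frame(gene = g, gain_n = gain_n, loss_n = loss_n,
               gain_pct = round_half_up(gain_n / n_subjects * 100, 2),
               loss_pct = round_half_up(loss_n / n_subjects * 100, 2),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(min_freq))
    out <- out[pmax(out$gain_pct, out$loss_pct) > min_freq, , drop = FALSE]
  rownames(out) <- NULL
  out
}
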