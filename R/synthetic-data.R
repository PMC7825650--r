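# Synthetic cohorts: genotypes with controlled allele/haplotype
# frequencies, probe-level log2-ratio tracks with planted copy-number
# events, and the deterministic 614-subject worked-example cohort.

#' Simulation configuration
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; all randomness derives from it.
#' @param variant_specs Data frame with `rsid`, `chrom`, `pos`, `ref`,
#'   `alt`, `alt_freq` (alt-allele frequency in \[0, 1\]).
#' @param haplotype_pool Optional list with `haps` (matrix of 0/1 allele
#'   vectors, one row per haplotype, columns matching `variant_specs`) and
#'   `freq` (frequencies summing to 1). When given, each subject is two
#'   independent draws from the pool; otherwise loci are independent
#'   Bernoulli draws at their `alt_freq` (linkage equilibrium).
#' @param probe_spacing Bp between adjacent probes (default 1000).
#' @param noise_sd Standard deviation of per-probe Gaussian noise
#'   (default 0.15).
#' @param probe_spans Data frame with `chrom`, `start`, `end`: the bp range
#'   covered by probes on each chromosome.
#' @param planted_events Data frame with `subject`, `chrom`, `start`,
#'   `end`, `shift`: piecewise-constant log2 shifts added inside
#'   \[start, end\] for that subject. Shifts around +/-0.4 emulate the
#'   single-copy band and +/-1.0 two-fold amplification / single-copy
#'   deletion, straddling the 0.25 and 0.8 classification cutoffs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects, seed, variant_specs = NULL,
                              haplotype_pool = NULL, probe_spacing = 1000,
                              noise_sd = 0.15, probe_spans = NULL,
                              planted_events = NULL) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (probe_spacing < 1) stop("probe_spacing must be >= 1")
  if (!is.null(variant_specs)) {
    if (any(variant_specs$alt_freq < 0 | variant_specs$alt_freq > 1))
      stop("alt-allele frequencies must lie in [0, 1]")
  }
  if (!is.null(haplotype_pool)) {
    if (abs(sum(haplotype_pool$freq) - 1) > 1e-9)
      stop("haplotype pool frequencies must sum to 1")
    if (any(haplotype_pool$freq < 0 | haplotype_pool$freq > 1))
      stop("haplotype frequencies must lie in [0, 1]")
    if (!is.null(variant_specs) &&
        ncol(haplotype_pool$haps) != nrow(variant_specs))
      stop("each pool haplotype must cover all variants")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), variant_specs = variant_specs,
                 haplotype_pool = haplotype_pool,
                 probe_spacing = probe_spacing, noise_sd = noise_sd,
                 probe_spans = probe_spans, planted_events = planted_events),
            class = "simulation_config")
}

#' Simulate unphased genotypes with phased truth
#'
#' Each subject receives two independently drawn haplotypes - from the
#' configured pool when one is given, otherwise per-locus Bernoulli draws
#' at the specified alt-allele frequencies (linkage equilibrium). The
#' unphased genotype is the allele-count sum; the phased draw is retained
#' for oracle comparisons.
#'
#' @param config A [simulation_config()] with `variant_specs`.
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (list of the two haplotype matrices `h1`, `h2`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  vs <- config$variant_specs
  if (is.null(vs)) stop("variant_specs are required")
  n <- config$n_subjects
  k <- nrow(vs)
  set.seed(derive_seed(config$seed, 1L))
  if (!is.null(config$haplotype_pool)) {
    pool <- config$haplotype_pool
    i1 <- sample.int(nrow(pool$haps), n, replace = TRUE, prob = pool$freq)
    i2 <- sample.int(nrow(pool$haps), n, replace = TRUE, prob = pool$freq)
    h1 <- pool$haps[i1, , drop = FALSE]
    h2 <- pool$haps[i2, , drop = FALSE]
  } else {
    h1 <- matrix(stats::rbinom(n * k, 1, rep(vs$alt_freq, each = n)), n, k)
    h2 <- matrix(stats::rbinom(n * k, 1, rep(vs$alt_freq, each = n)), n, k)
  }
  calls <- h1 + h2
  gm <- genotype_matrix(calls,
                        data.frame(rsid = vs$rsid, chrom = vs$chrom,
                                   pos = vs$pos, ref = vs$ref, alt = vs$alt,
                                   stringsAsFactors = FALSE))
  list(genotypes = gm, truth = list(h1 = h1, h2 = h2))
}

#' Simulate one subject's probe series on one chromosome
#'
#' Probes are placed at regular spacing across the configured span; the
#' log2 ratio is a 0 baseline, plus the planted shift inside any of the
#' subject's events on that chromosome, plus Gaussian noise. The noiseless
#' truth is retained as attribute `"truth"`.
#'
#' @param config A [simulation_config()] with `probe_spans`.
#' @param subject Subject id (matched against `planted_events$subject`).
#' @param chrom Chromosome name (matched against `probe_spans$chrom`).
#' @return A [probe_series()]; attribute `"truth"` holds the planted
#'   per-probe mean.
#' @export
simulate_probe_series <- function(config, subject, chrom) {
  stopifnot(inherits(config, "simulation_config"))
  span <- config$probe_spans[config$probe_spans$chrom == chrom, , drop = FALSE]
  if (nrow(span) != 1) stop("no probe span configured for chromosome ", chrom)
  positions <- seq(span$start, span$end, by = config$probe_spacing)
  truth <- rep(0, length(positions))
  ev <- config$planted_events
  if (!is.null(ev)) {
    ev <- ev[ev$subject == subject & ev$chrom == chrom, , drop = FALSE]
    if (nrow(ev) > 1) {
      o <- order(ev$start)
      if (any(ev$start[o][-1] <= ev$end[o][-nrow(ev)]))
        stop("planted events overlap")
    }
    for (r in seq_len(nrow(ev))) {
      if (ev$start[r] < span$start || ev$end[r] > span$end)
        stop("planted event outside the probe span")
      inside <- positions >= ev$start[r] & positions <= ev$end[r]
      truth[inside] <- truth[inside] + ev$shift[r]
    }
  }
  set.seed(derive_seed(config$seed,
                       i = string_hash(as.character(subject)),
                       j = string_hash(as.character(chrom))))
  log2r <- truth + stats::rnorm(length(positions), 0, config$noise_sd)
  ps <- probe_series(subject, chrom, positions, log2r)
  attr(ps, "truth") <- truth
  ps
}

# ---- deterministic worked-example cohort -------------------------------

table3_gene_regions <- function() {
  gene_region(gene = c("CYP4F2", "TPMT"), chrom = c("19", "6"),
              start = c(15988834L, 18128545L), end = c(16008884L, 18155374L))
}

table3_star_alleles <- function() {
  star_allele_defs(data.frame(
    gene = c("CYP4F2", "CYP4F2", "TPMT"),
    allele = c("*2", "*3", "*3C"),
    rsid = c("rs3093105", "rs2108622", "rs1142345"),
    alt = c("G", "T", "G"),
    stringsAsFactors = FALSE))
}

# per-subject category plan: CYP4F2 genotype (rs3093105, rs2108622), TPMT
# genotype (rs1142345), and planted CNV events, laid out in fixed blocks
table3_plan <- function() {
  cyp <- rbind(
    data.frame(label = "*1*1",       g1 = 0, g2 = 0, cnv = "neutral", n = 258),
    data.frame(label = "*1*2",       g1 = 1, g2 = 0, cnv = "neutral", n = 1),
    data.frame(label = "*1*3",       g1 = 0, g2 = 1, cnv = "neutral", n = 150),
    data.frame(label = "*3*3",       g1 = 0, g2 = 2, cnv = "neutral", n = 22),
    data.frame(label = "*2*3",       g1 = 1, g2 = 1, cnv = "neutral", n = 114),
    data.frame(label = "*1*2-*3*3",  g1 = 1, g2 = 2, cnv = "neutral", n = 31),
    data.frame(label = "*2*2-*3*3",  g1 = 2, g2 = 2, cnv = "neutral", n = 13),
    data.frame(label = "*1*1",       g1 = 0, g2 = 0, cnv = "gain",    n = 9),
    data.frame(label = "*1*3",       g1 = 0, g2 = 1, cnv = "gain",    n = 6),
    data.frame(label = "*2*3",       g1 = 1, g2 = 1, cnv = "gain",    n = 6),
    data.frame(label = "*3*3",       g1 = 0, g2 = 2, cnv = "gain",    n = 1),
    data.frame(label = "*1*1",       g1 = 0, g2 = 0, cnv = "loss",    n = 2),
    data.frame(label = "*2*3",       g1 = 1, g2 = 1, cnv = "loss",    n = 1))
  tpmt <- rbind(
    data.frame(label = "*1*1",  g = 0, cnv = "neutral", n = 287),
    data.frame(label = "*1*3C", g = 1, cnv = "neutral", n = 8),
    data.frame(label = "*1*1",  g = 0, cnv = "loss",    n = 308),
    data.frame(label = "*1*3C", g = 1, cnv = "loss",    n = 11))
  list(cyp = cyp, tpmt = tpmt)
}

#' Deterministic 614-subject combined SNV x CNV fixture
#'
#' Builds a complete synthetic cohort of 614 subjects in which the CYP4F2
#' genotypes at rs3093105/rs2108622, the TPMT genotype at rs1142345, and
#' planted copy-number events over the CYP4F2 (chr19) and TPMT (chr6) gene
#' regions are laid out so that running [run_combined_analysis()] on the
#' fixture reproduces a fixed set of combined diplotype-by-CNV category
#' counts (e.g. 258 copy-neutral CYP4F2 *1*1 subjects, 22 subjects with a
#' CYP4F2 gain, 308 subjects with a TPMT *1*1 loss). Genotypes and the
#' event layout are deterministic; the seed only drives the per-probe
#' Gaussian noise (sd `noise_sd`) on the log2-ratio tracks. Planted gains
#' shift the track by +1.0 (a two-fold amplification, log2 4/2) and
#' losses by -1.0 (the idealized single-copy loss, log2 1/2) across the
#' unpadded gene region; the combined report folds the resulting
#' amplification/deletion calls into the gain/loss category suffixes.
#' These amplitudes keep every planted event more than ten estimated
#' noise standard deviations from the detection threshold, so category
#' counts do not depend on the noise seed.
#'
#' @param seed Integer seed for the probe noise.
#' @param noise_sd Per-probe noise standard deviation (default 0.15).
#' @return List with `genotypes` (614 x 3 [genotype_matrix()]), `probes`
#'   (list of 1228 [probe_series()], one per subject per chromosome),
#'   `regions` (unpadded [gene_region()]s), `defs` (star-allele
#'   definitions), `truth` (per-subject planted labels and CNV states) and
#'   `config` (the underlying [simulation_config()]).
#' @export
make_table3_fixture <- function(seed = 1L, noise_sd = 0.15) {
  plan <- table3_plan()
  n <- 614L
  subjects <- sprintf("S%03d", seq_len(n))

  cyp_g1 <- rep(plan$cyp$g1, plan$cyp$n)
  cyp_g2 <- rep(plan$cyp$g2, plan$cyp$n)
  cyp_cnv <- rep(plan$cyp$cnv, plan$cyp$n)
  cyp_lab <- rep(plan$cyp$label, plan$cyp$n)
  tpmt_g <- rep(plan$tpmt$g, plan$tpmt$n)
  tpmt_cnv <- rep(plan$tpmt$cnv, plan$tpmt$n)
  tpmt_lab <- rep(plan$tpmt$label, plan$tpmt$n)
  stopifnot(length(cyp_g1) == n, length(tpmt_g) == n)

  variants <- data.frame(
    rsid = c("rs3093105", "rs2108622", "rs1142345"),
    chrom = c("19", "19", "6"),
    pos = c(15989101L, 15990431L, 18130918L),
    ref = c("T", "C", "A"), alt = c("G", "T", "G"),
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(cbind(cyp_g1, cyp_g2, tpmt_g), variants, subjects)

  regions <- table3_gene_regions()
  # probe tracks cover the +/-10 kb padded regions plus a buffer flank of
  # at least eight probes strictly outside each padded boundary, anchored
  # so that a probe falls exactly on each gene-region start: 11 probes
  # inside the CYP4F2 region and 14 inside TPMT. The buffer means a short
  # segment pinned to a track end (which faces only one elimination
  # t-test) cannot overlap the padded region unless it is long enough for
  # the 0.25 classification cutoff to be a >5 sigma event for its mean
  spans <- data.frame(chrom = c("19", "6"),
                      start = c(15962834, 18100545),
                      end = c(16034884, 18180545))
  shift <- c(neutral = 0, gain = 1, loss = -1)
  ev <- rbind(
    data.frame(subject = subjects[cyp_cnv != "neutral"], chrom = "19",
               start = regions$start[1], end = regions$end[1],
               shift = shift[cyp_cnv[cyp_cnv != "neutral"]],
               stringsAsFactors = FALSE),
    data.frame(subject = subjects[tpmt_cnv != "neutral"], chrom = "6",
               start = regions$start[2], end = regions$end[2],
               shift = shift[tpmt_cnv[tpmt_cnv != "neutral"]],
               stringsAsFactors = FALSE))

  config <- simulation_config(n_subjects = n, seed = seed,
                              variant_specs = variants,
                              probe_spacing = 2000, noise_sd = noise_sd,
                              probe_spans = spans, planted_events = ev)

  probes <- vector("list", 2L * n)
  idx <- 0L
  for (s in subjects) {
    for (ch in c("19", "6")) {
      idx <- idx + 1L
      probes[[idx]] <- simulate_probe_series(config, s, ch)
    }
  }
  names(probes) <- paste(rep(subjects, each = 2), rep(c("19", "6"), n),
                         sep = ":")

  truth <- data.frame(subject = subjects,
                      cyp4f2_label = cyp_lab, cyp4f2_cnv = cyp_cnv,
                      tpmt_label = tpmt_lab, tpmt_cnv = tpmt_cnv,
                      stringsAsFactors = FALSE)
  list(genotypes = gm, probes = probes, regions = regions,
       defs = table3_star_alleles(), truth = truth, config = config)
}
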