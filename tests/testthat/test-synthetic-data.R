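test_that("genotype simulation honors degenerate pools and allele frequencies", {
  # degenerate pool: everyone hom-ref
  cfg <- simulation_config(
    n_subjects = 10, seed = 1,
    variant_specs = within(toy_variants(2), alt_freq <- 0),
    haplotype_pool = list(haps = rbind(c(0L, 0L)), freq = 1))
  sim <- simulate_genotypes(cfg)
  expect_true(all(sim$genotypes$calls == 0))
  expect_equal(alt_allele_frequency(sim$genotypes$calls[, 1]), 0)

  # empirical frequency within 3 binomial SDs of the target
  cfg2 <- simulation_config(
    n_subjects = 10000, seed = 2,
    variant_specs = within(toy_variants(1)[, ], alt_freq <- 0.5))
  sim2 <- simulate_genotypes(cfg2)
  f <- alt_allele_frequency(sim2$genotypes$calls[, 1])
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 20000))

  # phased truth is consistent with the unphased calls
  expect_equal(sim2$truth$h1 + sim2$truth$h2,
               unname(sim2$genotypes$calls))
})

test_that("two-haplotype pool produces near-perfect two-locus LD", {
  sim <- simulate_genotypes(two_hap_config(5000, seed = 4, f1 = 0.3))
  ld <- pairwise_ld(sim$genotypes$calls[, 1], sim$genotypes$calls[, 2])
  expect_gt(ld$r2, 0.99)
})

test_that("config validation rejects bad frequencies and pool mismatches", {
  vs <- within(toy_variants(2), alt_freq <- c(0.5, 1.2))
  expect_error(simulation_config(10, 1, variant_specs = vs), "\\[0, 1\\]")
  expect_error(simulation_config(
    10, 1, variant_specs = within(toy_variants(2), alt_freq <- 0.5),
    haplotype_pool = list(haps = rbind(c(1L, 1L)), freq = 0.9)),
    "sum to 1")
  expect_error(simulation_config(
    10, 1, variant_specs = within(toy_variants(3), alt_freq <- 0.5),
    haplotype_pool = list(haps = rbind(c(1L, 1L), c(0L, 0L)),
                          freq = c(0.5, 0.5))),
    "cover all variants")
})

test_that("probe series are exact without noise and carry planted truth", {
  spans <- data.frame(chrom = "1", start = 1000, end = 40000)
  cfg <- simulation_config(
    n_subjects = 2, seed = 3,
    variant_specs = within(toy_variants(1), alt_freq <- 0.5),
    probe_spacing = 1000, noise_sd = 0, probe_spans = spans,
    planted_events = data.frame(subject = "S1", chrom = "1",
                                start = 10000, end = 29000, shift = 0.4))
  ps <- simulate_probe_series(cfg, "S1", "1")
  expect_equal(length(ps$log2r), 40)
  inside <- ps$positions >= 10000 & ps$positions <= 29000
  expect_true(all(ps$log2r[inside] == 0.4))
  expect_true(all(ps$log2r[!inside] == 0))
  # subject without events is flat
  ps2 <- simulate_probe_series(cfg, "S2", "1")
  expect_true(all(ps2$log2r == 0))

  # overlapping events and out-of-span events are rejected
  cfg$planted_events <- data.frame(subject = "S1", chrom = "1",
                                   start = c(5000, 9000),
                                   end = c(10000, 12000), shift = 0.4)
  expect_error(simulate_probe_series(cfg, "S1", "1"), "overlap")
  cfg$planted_events <- data.frame(subject = "S1", chrom = "1",
                                   start = 100, end = 5000, shift = 0.4)
  expect_error(simulate_probe_series(cfg, "S1", "1"), "span")
})

test_that("noiseless planted events are recovered exactly by segmentation", {
  spans <- data.frame(chrom = "1", start = 1000, end = 50000)
  cfg <- simulation_config(
    n_subjects = 1, seed = 5,
    variant_specs = within(toy_variants(1), alt_freq <- 0.5),
    probe_spacing = 1000, noise_sd = 0, probe_spans = spans,
    planted_events = data.frame(subject = "S1", chrom = "1",
                                start = 20000, end = 35000, shift = -1))
  ps <- simulate_probe_series(cfg, "S1", "1")
  segs <- classify_segments(segment_series(ps))
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start_pos[2], 20000)
  expect_equal(segs$end_pos[2], 35000)
  expect_equal(segs$status, c("neutral", "deletion", "neutral"))
})

test_that("noisy planted events are recovered within one probe", {
  spans <- data.frame(chrom = "1", start = 1000, end = 40000)
  cfg <- simulation_config(
    n_subjects = 1, seed = 6,
    variant_specs = within(toy_variants(1), alt_freq <- 0.5),
    probe_spacing = 1000, noise_sd = 0.15, probe_spans = spans,
    planted_events = data.frame(subject = "S1", chrom = "1",
                                start = 15000, end = 26000, shift = -1))
  ps <- simulate_probe_series(cfg, "S1", "1")
  segs <- segment_series(ps)
  bp <- segment_breakpoints(segs)
  expect_true(any(abs(bp - 14) <= 1))  # true breakpoints after probes 14, 26
  expect_true(any(abs(bp - 26) <= 1))
})

test_that("simulations are reproducible for a fixed seed", {
  cfg <- two_hap_config(200, seed = 7)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))

  fx1 <- make_table3_fixture(seed = 123)
  fx2 <- make_table3_fixture(seed = 123)
  expect_identical(fx1, fx2)
  fx3 <- make_table3_fixture(seed = 124)
  expect_false(identical(fx1$probes[[1]]$log2r, fx3$probes[[1]]$log2r))
})

test_that("the worked-example fixture has the planned genotype and event layout", {
  fx <- make_table3_fixture(seed = 1)
  expect_equal(length(fx$genotypes$subjects), 614)
  expect_equal(nrow(fx$truth), 614)
  # CYP4F2 diplotype truth sums
  expect_equal(sum(fx$truth$cyp4f2_cnv == "gain"), 22)
  expect_equal(sum(fx$truth$cyp4f2_cnv == "loss"), 3)
  expect_equal(sum(fx$truth$tpmt_cnv == "loss"), 319)
  # genotypes at defining SNVs: spot-check one category per gene
  g <- fx$genotypes$calls
  first_23 <- which(fx$truth$cyp4f2_label == "*2*3")[1]
  expect_equal(unname(g[first_23, c("rs3093105", "rs2108622")]), c(1L, 1L))
  first_3c <- which(fx$truth$tpmt_label == "*1*3C")[1]
  expect_equal(unname(g[first_3c, "rs1142345"]), 1L)
  # planted events lie inside the probe spans and over the gene regions
  ev <- fx$config$planted_events
  expect_true(all(ev$shift[ev$chrom == "6"] == -1))
  expect_true(all(ev$shift %in% c(1, -1)))
  spans <- fx$config$probe_spans
  for (ch in c("19", "6")) {
    sp <- spans[spans$chrom == ch, ]
    expect_true(all(ev$start[ev$chrom == ch] >= sp$start))
    expect_true(all(ev$end[ev$chrom == ch] <= sp$end))
  }
  expect_equal(unique(ev$start[ev$chrom == "19"]), fx$regions$start[1])
  expect_equal(unique(ev$end[ev$chrom == "6"]), fx$regions$end[2])
})
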