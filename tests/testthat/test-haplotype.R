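test_that("EM haplotype frequencies handle degenerate and phase-determined input", {
  # all hom-ref at 2 loci
  g <- matrix(0L, 5, 2)
  em <- em_haplotype_freqs(g)
  expect_equal(unname(em$freq["00"]), 1)
  expect_equal(sum(em$freq), 1)

  # no double heterozygote: EM equals direct haplotype counting
  g <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2), c(0, 1))
  em <- em_haplotype_freqs(g)
  # haplotypes countable by hand: each genotype resolves uniquely
  counts <- c("00" = 0, "01" = 0, "10" = 0, "11" = 0)
  hand <- list(c("00", "00"), c("10", "00"), c("10", "10"),
               c("11", "10"), c("11", "11"), c("01", "00"))
  for (p in hand) {
    counts[p[1]] <- counts[p[1]] + 1
    counts[p[2]] <- counts[p[2]] + 1
  }
  expect_equal(em$freq[names(counts)], counts / sum(counts),
               tolerance = 1e-6)
})

test_that("EM recovers pool haplotype frequencies and has monotone likelihood", {
  cfg <- two_hap_config(2000, seed = 5, k = 2, f1 = 0.3)
  sim <- simulate_genotypes(cfg)
  em <- em_haplotype_freqs(sim$genotypes$calls)
  expect_lt(abs(em$freq[["11"]] - 0.3), 0.03)
  expect_lt(abs(em$freq[["00"]] - 0.7), 0.03)
  expect_equal(sum(em$freq), 1, tolerance = 1e-9)

  # non-decreasing log-likelihood across iteration counts
  lls <- sapply(1:6, function(i)
    suppressWarnings(em_haplotype_freqs(sim$genotypes$calls,
                                        max_iter = i))$loglik)
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("pairwise LD: independence, complete LD, and a hand-counted D", {
  # independent loci
  set.seed(21)
  n <- 5000
  ga <- rbinom(n, 1, 0.4) + rbinom(n, 1, 0.4)
  gb <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  ld <- pairwise_ld(ga, gb)
  expect_lt(ld$r2, 0.01)

  # complete LD from a two-haplotype pool
  cfg <- two_hap_config(2000, seed = 6, k = 2, f1 = 0.3)
  sim <- simulate_genotypes(cfg)
  ld2 <- pairwise_ld(sim$genotypes$calls[, 1], sim$genotypes$calls[, 2])
  expect_equal(ld2$Dprime, 1, tolerance = 1e-3)
  expect_equal(ld2$r2, 1, tolerance = 1e-3)

  # 3 subjects, no double hets: D from hand-counted haplotypes
  ga3 <- c(2L, 1L, 0L)
  gb3 <- c(2L, 0L, 0L)
  # haplotypes: (11,11), (10,00), (00,00) -> p11=2/6, pA=3/6, pB=2/6
  ld3 <- pairwise_ld(ga3, gb3)
  expect_equal(ld3$D, 2 / 6 - (3 / 6) * (2 / 6), tolerance = 1e-6)

  expect_error(pairwise_ld(c(0L, 0L, 0L), c(0L, 1L, 2L)), "polymorphic")
})

test_that("LD invariants: r2 identity, bounds, and allele-label symmetry", {
  set.seed(31)
  for (i in 1:10) {
    f <- runif(2, 0.2, 0.8)
    n <- 300
    ga <- rbinom(n, 1, f[1]) + rbinom(n, 1, f[1])
    gb <- ifelse(runif(n) < 0.7, ga, rbinom(n, 1, f[2]) + rbinom(n, 1, f[2]))
    if (var(ga) == 0 || var(gb) == 0) next
    ld <- pairwise_ld(ga, gb)
    expect_gte(ld$Dprime, 0); expect_lte(ld$Dprime, 1)
    expect_gte(ld$r2, 0); expect_lte(ld$r2, 1)
    expect_equal(ld$r2,
                 ld$D^2 / (ld$p_a * (1 - ld$p_a) * ld$p_b * (1 - ld$p_b)),
                 tolerance = 1e-6)
    ld_flip <- pairwise_ld(2L - ga, gb)
    expect_equal(ld_flip$r2, ld$r2, tolerance = 1e-6)
  }
})

test_that("block finding: complete-LD pair, one 6-variant block, two separated blocks", {
  # 2 variants in complete LD
  cfg <- two_hap_config(500, seed = 8, k = 2, f1 = 0.4)
  gm <- simulate_genotypes(cfg)$genotypes
  blocks <- gabriel_blocks(gm)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$variants, c("rs1", "rs2"))

  # 6 variants from one ancestral two-haplotype pool form a single block
  cfg6 <- two_hap_config(500, seed = 9, k = 6, f1 = 0.4)
  gm6 <- simulate_genotypes(cfg6)$genotypes
  blocks6 <- gabriel_blocks(gm6)
  expect_length(blocks6, 1)
  expect_length(blocks6[[1]]$variants, 6)
  # two haplotypes at ~0.4/0.6
  top <- blocks6[[1]]$haplotypes
  expect_gte(nrow(top), 2)
  expect_lt(abs(sort(top$freq, decreasing = TRUE)[1] - 0.6), 0.05)

  # two independent 3-variant blocks separated by an unlinked variant
  set.seed(10)
  n <- 500
  blockA <- simulate_genotypes(two_hap_config(n, seed = 11, k = 3,
                                              f1 = 0.35))$genotypes$calls
  blockB <- simulate_genotypes(two_hap_config(n, seed = 12, k = 3,
                                              f1 = 0.45))$genotypes$calls
  unlinked <- rbinom(n, 1, 0.5) + rbinom(n, 1, 0.5)
  calls <- cbind(blockA, unlinked, blockB)
  storage.mode(calls) <- "integer"
  gm7 <- toy_genotype_matrix(calls)
  blocks7 <- gabriel_blocks(gm7)
  expect_length(blocks7, 2)
  expect_equal(blocks7[[1]]$variants, paste0("rs", 1:3))
  expect_equal(blocks7[[2]]$variants, paste0("rs", 5:7))
})

test_that("block selection equals a brute-force span enumeration on <= 7 variants", {
  # independent oracle over all contiguous spans under the same pair rules
  oracle_blocks <- function(gm, thr = block_thresholds()) {
    k <- ncol(gm$calls)
    cls <- matrix(0L, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pa <- mean(gm$calls[, i]) / 2
      pb <- mean(gm$calls[, j]) / 2
      if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) next
      ci <- pairwise_ld(gm$calls[, i], gm$calls[, j])$dprime_ci
      if (ci[2] >= thr$ci_upper_strong && ci[1] >= thr$ci_lower_strong) {
        cls[i, j] <- 1L
      } else if (ci[2] < thr$ci_upper_recomb) cls[i, j] <- -1L
    }
    spans <- list()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sub <- cls[i:j, i:j]
      ninf <- sum(sub != 0)
      if (ninf > 0 && sum(sub == 1) / ninf >= thr$informative_frac)
        spans[[length(spans) + 1]] <- c(i, j, j - i)
    }
    if (!length(spans)) return(list())
    spans <- do.call(rbind, spans)
    spans <- spans[order(-spans[, 3], spans[, 1]), , drop = FALSE]
    chosen <- list(); used <- rep(FALSE, k)
    for (r in seq_len(nrow(spans))) {
      i <- spans[r, 1]; j <- spans[r, 2]
      if (!any(used[i:j])) { used[i:j] <- TRUE
        chosen[[length(chosen) + 1]] <- c(i, j) }
    }
    chosen[order(sapply(chosen, `[`, 1))]
  }

  set.seed(13)
  n <- 400
  blockA <- simulate_genotypes(two_hap_config(n, seed = 14, k = 3,
                                              f1 = 0.3))$genotypes$calls
  rest <- sapply(1:4, function(i) {
    f <- runif(1, 0.2, 0.6); rbinom(n, 1, f) + rbinom(n, 1, f)
  })
  calls <- cbind(blockA, rest)
  storage.mode(calls) <- "integer"
  gm <- toy_genotype_matrix(calls)

  got <- gabriel_blocks(gm)
  want <- oracle_blocks(gm)
  expect_equal(length(got), length(want))
  for (i in seq_along(got))
    expect_equal(c(got[[i]]$first, got[[i]]$last), unname(want[[i]]))
})
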