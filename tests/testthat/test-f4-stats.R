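test_that("f4 on hand-computed frequency quadruples", {
  # SNP 1: (1,0,1,0) -> contribution 1; SNP 2: (0,0,1,0) -> 0; mean 0.5
  freqs <- rbind(c(1, 0), c(0, 0), c(1, 1), c(0, 0))
  panel <- panel_from_freqs(freqs)
  res <- f4(panel, "pop1", "pop2", "pop3", "pop4", block_size = 1)
  expect_equal(res$value, 0.5)
  expect_equal(res$n_snps_used, 2L)

  # p_C = p_D everywhere: exactly zero
  z <- f4(panel, "pop1", "pop2", "pop3", "pop3")
  expect_identical(z$value, 0)
})

test_that("f4 is antisymmetric under within-pair swaps", {
  panel <- simulate_panel(sim_config(n_regions = 4, n_per_region = 8,
                                     n_snps = 2000, fst_per_region = 0.03,
                                     n_chromosomes = 2, total_map_cm = 200,
                                     missing_rate = 0.05, seed = 6))$panel
  pops <- paste0("region", 1:4)
  base <- f4(panel, pops[1], pops[2], pops[3], pops[4])
  swap_ab <- f4(panel, pops[2], pops[1], pops[3], pops[4])
  swap_cd <- f4(panel, pops[1], pops[2], pops[4], pops[3])
  both <- f4(panel, pops[2], pops[1], pops[4], pops[3])
  expect_equal(swap_ab$value, -base$value, tolerance = 1e-12)
  expect_equal(swap_cd$value, -base$value, tolerance = 1e-12)
  expect_equal(both$value, base$value, tolerance = 1e-12)
  expect_equal(swap_ab$se, base$se, tolerance = 1e-12)
})

test_that("f4 equals a full-enumeration oracle on small panels", {
  for (seed in 1:10) {
    panel <- simulate_panel(sim_config(n_regions = 4, n_per_region = 5,
                                       n_snps = 10, fst_per_region = 0.1,
                                       n_chromosomes = 1, total_map_cm = 50,
                                       missing_rate = 0.15, seed = seed))$panel
    got <- f4(panel, "region1", "region2", "region3", "region4")
    want <- f4_oracle(panel, "region1", "region2", "region3", "region4")
    expect_equal(got$value, want, tolerance = 1e-12)
  }
})

test_that("sites with an entirely missing population are dropped", {
  freqs <- rbind(c(1, 0.5), c(0, 0), c(1, 1), c(0, 0))
  panel <- panel_from_freqs(freqs)
  g <- panel$genotypes
  g[1, 2] <- NA_integer_    # pop1 (single sample) missing at SNP 2
  p2 <- genotype_panel(g, panel$snps, panel$samples)
  res <- f4(p2, "pop1", "pop2", "pop3", "pop4")
  expect_equal(res$n_snps_used, 1L)
  expect_equal(res$value, 1)
  expect_error(f4(p2, "pop1", "pop2", "pop3", "nope"), "nope")
})

test_that("jackknife SE calibrates against the replicate SD", {
  reps <- 200
  stats <- t(vapply(seq_len(reps), function(seed) {
    panel <- simulate_panel(sim_config(n_regions = 4, n_per_region = 10,
                                       n_snps = 10000,
                                       fst_per_region = 0.01,
                                       n_chromosomes = 4,
                                       total_map_cm = 400,
                                       seed = seed))$panel
    res <- f4(panel, "region1", "region2", "region3", "region4",
              block_size = 500)
    c(res$value, res$se)
  }, numeric(2)))
  empirical_sd <- stats::sd(stats[, 1])
  mean_se <- mean(stats[, 2])
  expect_lt(abs(mean_se - empirical_sd) / empirical_sd, 0.20)
})

test_that("the scan ranks the target's own region highest under drift", {
  hits <- vapply(1:10, function(seed) {
    panel <- simulate_panel(sim_config(n_regions = 5, n_per_region = 15,
                                       n_snps = 8000,
                                       fst_per_region = c(0.1, 0.02, 0.02,
                                                          0.02, 0.02),
                                       n_chromosomes = 4, total_map_cm = 400,
                                       target_region = 4, seed = seed))$panel
    scan <- f4_panel_scan(panel, "ancient", outgroup = "region1",
                          anchor = "region2",
                          test_regions = paste0("region", 3:5))
    scan$region[which.max(scan$value)] == "region4"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("identical regions give f4 values within noise of zero", {
  inside <- vapply(1:40, function(seed) {
    set.seed(seed)
    n_snp <- 2000
    p <- stats::runif(n_snp, 0.1, 0.9)
    g <- matrix(stats::rbinom(40 * n_snp, 2L, rep(p, each = 40)), nrow = 40)
    panel <- genotype_panel(
      g, roh_test_snps(n_snp, 0.05),
      data.frame(sample_id = sprintf("s%02d", 1:40),
                 label = rep(paste0("pop", 1:4), each = 10))
    )
    res <- f4(panel, "pop1", "pop2", "pop3", "pop4", block_size = 200)
    abs(res$value) <= 2 * res$se
  }, logical(1))
  expect_gte(mean(inside), 0.85)   # ~95% nominal coverage, binomial noise
})

test_that("a single-region scan equals the direct call", {
  panel <- simulate_panel(sim_config(n_regions = 4, n_per_region = 6,
                                     n_snps = 1000, fst_per_region = 0.05,
                                     n_chromosomes = 2, total_map_cm = 100,
                                     seed = 8))$panel
  scan <- f4_panel_scan(panel, "ancient", "region1", "region2", "region3")
  direct <- f4(panel, "region1", "ancient", "region2", "region3")
  expect_equal(scan$value, direct$value)
  expect_equal(scan$se, direct$se)
})
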