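# shorthand codes: H = homozygous (2), E = heterozygous (1), M = missing
calls_from <- function(s) {
  map <- c(H = 2L, E = 1L, M = NA_integer_, R = 0L)
  unname(map[strsplit(s, "")[[1]]])
}

scaled_params <- function(...) {
  roh_params(max_het_count = 1, max_het_prop = 0.25, min_length_cm = 1,
             min_hom_snps = 4, total_map_cm = 100, ...)
}

test_that("MAF filter keeps only SNPs strictly above the threshold", {
  # 10 SNPs; supplied reference frequencies, 4 at or below MAF 0.03
  freq <- c(0.5, 0.03, 0.2, 0.01, 0.99, 0.9, 0.03, 0.4, 0.3, 0.96)
  g <- matrix(rep(c(0L, 1L, 2L), length.out = 30), nrow = 3)
  snps <- roh_test_snps(10)
  samples <- data.frame(sample_id = paste0("s", 1:3), label = "x")
  panel <- genotype_panel(g, snps, samples)
  kept <- filter_snps(panel, 0.03, freq = freq)
  expect_equal(nrow(kept$snps), 6L)
  # p = 0.03 exactly is removed (strict inequality); p = 0.5 retained
  expect_false("m2" %in% kept$snps$snp_id)
  expect_true("m1" %in% kept$snps$snp_id)
  # order preserved
  expect_equal(kept$snps$snp_id, snps$snp_id[pmin(freq, 1 - freq) > 0.03])
  expect_error(filter_snps(panel, 0.49, freq = rep(0.01, 10)), "no SNPs")
})

test_that("the worked scan example trims, accepts and rescans as specified", {
  calls <- calls_from("HHHHHEEHH")
  snps <- roh_test_snps(9, spacing_cm = 0.5)
  segs <- call_roh(calls, snps, scaled_params())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_index, 1L)
  expect_equal(segs$end_index, 5L)     # trimmed to the last homozygote
  expect_equal(segs$length_cm, 2.0)
  expect_equal(segs$n_hom, 5L)
  expect_equal(segs$n_het, 0L)         # tallies recounted after trimming
})

test_that("degenerate scans behave: all-het, all-hom, missing spanning", {
  p <- scaled_params()
  snps <- roh_test_snps(20, spacing_cm = 0.5)
  expect_equal(nrow(call_roh(rep(1L, 20), snps, p)), 0L)

  # fully homozygous chromosome: one tiling segment, F from the map length
  segs <- call_roh(rep(2L, 20), snps, p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$length_cm, 9.5)
  expect_equal(segs$n_hom, 20L)

  # missing calls are spanned but not counted in either tally
  m <- call_roh(calls_from("HHMMHHHH"), roh_test_snps(8, 0.5), p)
  expect_equal(m$n_hom, 6L)
  expect_equal(m$n_het, 0L)
  expect_equal(m$length_cm, 3.5)

  # ref-homozygous and alt-homozygous calls count alike
  mixed <- call_roh(calls_from("HRHRHRHR"), roh_test_snps(8, 0.5), p)
  expect_equal(mixed$n_hom, 8L)
})

test_that("scan matches an independent literal-rules oracle on random inputs", {
  p <- scaled_params()
  for (seed in 1:25) {
    set.seed(seed)
    calls <- sample(c(0L, 1L, 2L, NA_integer_), 60, replace = TRUE,
                    prob = c(0.3, 0.25, 0.4, 0.05))
    snps <- roh_test_snps(60, spacing_cm = 0.4)
    got <- call_roh(calls, snps, p)
    want <- roh_oracle(calls, snps$position_cm, p)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start_index, want$start_index)
      expect_equal(got$end_index, want$end_index)
      expect_equal(got$n_hom, want$n_hom)
      expect_equal(got$n_het, want$n_het)
      expect_equal(got$length_cm, want$length_cm, tolerance = 1e-12)
    }
  }
})

test_that("every emitted segment satisfies the acceptance thresholds", {
  p <- roh_params(max_het_count = 3, max_het_prop = 0.1, min_length_cm = 2,
                  min_hom_snps = 8, total_map_cm = 200)
  for (seed in 1:10) {
    set.seed(seed)
    calls <- sample(c(0L, 1L, 2L, NA_integer_), 400, replace = TRUE,
                    prob = c(0.35, 0.1, 0.5, 0.05))
    snps <- roh_test_snps(400, spacing_cm = 0.5,
                          chromosome = rep(1:2, each = 200))
    snps$position_cm <- rep((0:199) * 0.5, 2)
    snps$position_bp <- rep(as.integer((1:200) * 1e5), 2)
    segs <- call_roh(calls, snps, p)
    if (nrow(segs) == 0) next
    expect_true(all(segs$length_cm > p$min_length_cm))
    expect_true(all(segs$n_hom >= p$min_hom_snps))
    expect_true(all(segs$n_het <= p$max_het_count))
    expect_true(all(segs$n_het / (segs$n_het + segs$n_hom) <=
                      p$max_het_prop))
    # segments within a chromosome are disjoint and ordered
    for (ch in unique(segs$chromosome)) {
      s <- segs[segs$chromosome == ch, ]
      if (nrow(s) > 1) {
        expect_true(all(s$start_index[-1] > s$end_index[-nrow(s)]))
      }
    }
  }
})

test_that("F is the map fraction of accepted fragments", {
  p <- roh_params(total_map_cm = 3523.4)
  empty <- call_roh(rep(1L, 10), roh_test_snps(10), p)
  expect_equal(inbreeding_coefficient(empty, p)$f, 0)

  seg <- tibble::tibble(chromosome = 1L, start_index = 1L, end_index = 2L,
                        start_cm = 0, end_cm = 35.234, length_cm = 35.234,
                        n_hom = 1000L, n_het = 0L)
  expect_equal(inbreeding_coefficient(seg, p)$f, 0.01)

  sat <- dplyr::mutate(seg, length_cm = 3523.4)
  expect_equal(inbreeding_coefficient(sat, p)$f, 1)

  # F invariant under chromosome relabelling
  two <- dplyr::bind_rows(seg, dplyr::mutate(seg, chromosome = 7L))
  relabelled <- dplyr::mutate(two, chromosome = c(12L, 3L))
  expect_equal(inbreeding_coefficient(two, p)$f,
               inbreeding_coefficient(relabelled, p)$f)
})

test_that("planted ROH are recovered within tolerance across seeds", {
  plan <- data.frame(chromosome = c(2, 7, 18), start_cm = c(30, 60, 100),
                     length_cm = c(40, 25, 19))
  true_f <- sum(plan$length_cm) / 3523.4
  params <- roh_params(min_hom_snps = 50, total_map_cm = 3523.4)
  f_hat <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_regions = 2, n_per_region = 6, n_snps = 22000,
                      fst_per_region = 0.01, roh_plan = plan,
                      target_region = 1, missing_rate = 0.02, seed = seed)
    sim <- simulate_panel(cfg)
    res <- estimate_inbreeding(sim$panel, "ancient", params)
    # every planted tract must overlap a reported fragment
    for (i in seq_len(nrow(plan))) {
      hits <- res$segments$chromosome == plan$chromosome[i] &
        res$segments$start_cm < plan$start_cm[i] + plan$length_cm[i] &
        res$segments$end_cm > plan$start_cm[i]
      expect_true(any(hits))
    }
    res$f
  }, numeric(1))
  expect_true(all(abs(f_hat - true_f) / true_f < 0.10))
})

test_that("heterozygote errors below half the tolerated proportion barely move F", {
  # denser map than the recovery test: the error-tolerance property needs
  # min_hom_snps to correspond to a small cM span relative to the tracts
  plan <- data.frame(chromosome = c(3, 11), start_cm = c(10, 20),
                     length_cm = c(45, 30))
  params <- roh_params(min_hom_snps = 50, total_map_cm = 1000)
  base_cfg <- function(err, seed) {
    sim_config(n_regions = 2, n_per_region = 6, n_snps = 20000,
               n_chromosomes = 12, total_map_cm = 1000,
               fst_per_region = 0.01, roh_plan = plan, target_region = 1,
               het_error_rate = err, seed = seed)
  }
  rel_change <- vapply(1:5, function(seed) {
    clean <- estimate_inbreeding(simulate_panel(base_cfg(0, seed))$panel,
                                 "ancient", params)$f
    noisy <- estimate_inbreeding(
      simulate_panel(base_cfg(params$max_het_prop / 2 * 0.9, seed))$panel,
      "ancient", params)$f
    abs(noisy - clean) / clean
  }, numeric(1))
  expect_true(all(rel_change < 0.10))
})
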