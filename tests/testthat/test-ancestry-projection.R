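two_pop_panel <- function(seed = 1, fst = 0.05, n_per = 100, n_snps = 5000) {
  simulate_panel(sim_config(n_regions = 2, n_per_region = n_per,
                            n_snps = n_snps, fst_per_region = fst,
                            n_chromosomes = 5, total_map_cm = 500,
                            seed = seed))$panel
}

test_that("PC1 separates two drifted populations completely", {
  for (seed in 1:3) {
    panel <- two_pop_panel(seed)
    model <- suppressWarnings(fit_reference_pca(panel, n_components = 2))
    pc1 <- split(model$scores[, 1], model$labels)
    ranges <- vapply(pc1, range, numeric(2))
    # disjoint PC1 ranges: complete linear separability
    expect_true(max(ranges[1, ]) > min(ranges[2, ]) ||
                  max(ranges[2, ]) < min(ranges[1, ]))
  }
})

test_that("reference samples reproduce their own scores when projected", {
  panel <- two_pop_panel(2, n_per = 30, n_snps = 1500)
  model <- suppressWarnings(fit_reference_pca(panel, n_components = 8))
  for (id in panel$samples$sample_id[c(1, 17, 60)]) {
    coords <- project_sample(model, panel_sample(panel, id)[model$snp_ids])
    expect_equal(unname(coords), unname(model$scores[id, ]),
                 tolerance = 1e-8)
  }
  # duplicated individuals land on identical coordinates
  g <- panel$genotypes
  dup <- rbind(g, g[1, , drop = FALSE])
  samples <- rbind(panel$samples,
                   tibble::tibble(sample_id = "dup1", label = "region1"))
  dup_panel <- genotype_panel(dup, panel$snps, samples)
  m2 <- suppressWarnings(fit_reference_pca(dup_panel, n_components = 4))
  expect_equal(unname(m2$scores["dup1", ]),
               unname(m2$scores[panel$samples$sample_id[1], ]),
               tolerance = 1e-10)
})

test_that("least-squares projection resists missingness", {
  panel <- two_pop_panel(3, n_per = 60, n_snps = 4000)
  model <- suppressWarnings(fit_reference_pca(panel, n_components = 5))
  id <- panel$samples$sample_id[5]
  full <- panel_sample(panel, id)[model$snp_ids]
  truth <- model$scores[id, ]
  spread <- apply(model$scores, 2, stats::sd)
  for (seed in 1:5) {
    set.seed(seed)
    masked <- full
    masked[sample(length(masked), length(masked) * 0.5)] <- NA_integer_
    coords <- project_sample(model, masked)
    # within a modest fraction of the score dispersion on leading PCs
    expect_lt(abs(coords[1] - truth[1]), 0.5 * spread[1])
  }
  all_missing <- rep(NA_integer_, length(full))
  names(all_missing) <- names(full)
  expect_error(project_sample(model, all_missing), "non-missing")
})

test_that("weighted distance does the arithmetic and scales correctly", {
  expect_equal(weighted_distance(c(1, 2), c(1, 2), c(4, 1), k = 2), 0)
  expect_equal(weighted_distance(c(1, 1), c(0, 0), c(4, 1), k = 2), sqrt(5))
  d1 <- weighted_distance(c(1, 3, 2), c(0, 1, 5), c(3, 2, 1), k = 3)
  d2 <- weighted_distance(c(1, 3, 2), c(0, 1, 5), 7 * c(3, 2, 1), k = 3)
  expect_equal(d2, sqrt(7) * d1, tolerance = 1e-12)
  expect_error(weighted_distance(c(1, 2), c(0, 0), c(4, 1), k = 5),
               "components")
})

test_that("a query at a region centroid is assigned there with confidence", {
  panel <- simulate_panel(sim_config(n_regions = 3, n_per_region = 60,
                                     n_snps = 4000, fst_per_region = 0.05,
                                     n_chromosomes = 4, total_map_cm = 400,
                                     seed = 4))$panel
  model <- fit_reference_pca(panel, n_components = 5)
  centroid <- colMeans(model$scores[model$labels == "region2", ])
  a <- assign_region(model, centroid, k = 5)
  expect_equal(a$best_region, "region2")
  expect_true(all(a$regions$p_value[a$regions$label != "region2"] < 0.01))
  # an exact reference individual sits at distance zero
  a2 <- assign_region(model, model$scores[10, ], k = 5)
  expect_equal(min(a2$distances$distance), 0, tolerance = 1e-10)
})

test_that("twin regions produce a roughly uniform p-value against each other", {
  # two regions simulated from identical frequencies: the Welch test of the
  # best region against its twin should reject at ~ the nominal rate
  p_twin <- vapply(1:40, function(seed) {
    set.seed(seed)
    n_snp <- 800
    p <- stats::runif(n_snp, 0.1, 0.9)
    g <- matrix(stats::rbinom(60 * n_snp, 2L, rep(p, each = 60)), nrow = 60)
    panel <- genotype_panel(
      g, roh_test_snps(n_snp, 0.1),
      data.frame(sample_id = sprintf("s%02d", 1:60),
                 label = rep(c("a", "b"), each = 30))
    )
    model <- fit_reference_pca(panel, n_components = 4)
    query <- colMeans(model$scores)
    a <- assign_region(model, query, k = 4)
    a$regions$p_value[!is.na(a$regions$p_value)][1]
  }, numeric(1))
  reject <- mean(p_twin < 0.05)
  expect_lt(reject, 0.20)          # no runaway false-significance
  expect_gt(mean(p_twin), 0.2)     # not degenerately small either
})

test_that("monomorphic SNPs are dropped with a warning, small regions excluded", {
  panel <- two_pop_panel(5, n_per = 10, n_snps = 300)
  g <- panel$genotypes
  g[, 1] <- 0L
  g[, 2] <- 2L
  p2 <- genotype_panel(g, panel$snps, panel$samples)
  expect_warning(model <- fit_reference_pca(p2, n_components = 3),
                 "monomorphic")
  # the two forced-monomorphic SNPs are gone (plus any by chance)
  expect_false(any(panel$snps$snp_id[1:2] %in% model$snp_ids))
  expect_lte(length(model$snp_ids), 298L)

  lone <- genotype_panel(
    rbind(g, g[3, , drop = FALSE]),
    panel$snps,
    dplyr::bind_rows(panel$samples,
                     tibble::tibble(sample_id = "solo", label = "lonely"))
  )
  m3 <- suppressWarnings(fit_reference_pca(lone, n_components = 3))
  expect_warning(assign_region(m3, m3$scores[1, ], k = 3), "lonely")
})
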