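#' f4 statistic with block-jackknife standard error
#'
#' For four populations A, B, C, D the per-SNP contribution is
#' (p_A - p_B)(p_C - p_D) with p the observed alternate-allele frequency in
#' each population; the statistic is the mean over usable SNPs (those where
#' every population has at least one observed genotype). In the orientation
#' used for ancestry scans — A an outgroup, B the ancient individual, C a
#' fixed anchor population, D the test population — a positive value
#' indicates excess shared drift (affinity) between B and D.
#'
#' The standard error comes from a weighted delete-one-block jackknife over
#' consecutive blocks of `block_size` usable SNPs, with blocks weighted by
#' their SNP counts, which is robust to linkage between nearby SNPs.
#'
#' @param panel A [genotype_panel()].
#' @param pop_a,pop_b,pop_c,pop_d Sample labels (or for the ancient
#'   individual, a label attached to a single sample) naming the four
#'   populations.
#' @param block_size Jackknife block size in SNPs (default 500).
#' @return A one-row tibble of class `f4_result`: `pop_a` ... `pop_d`,
#'   `value`, `se`, `z`, `n_snps_used`, `n_blocks`.
#' @export
f4 <- function(panel, pop_a, pop_b, pop_c, pop_d, block_size = 500) {
  stopifnot(block_size >= 1)
  labs <- c(pop_a, pop_b, pop_c, pop_d)
  absent <- setdiff(labs, panel$samples$label)
  if (length(absent) > 0) {
    stop("label(s) not in panel: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  p <- vapply(labs, function(l) allele_frequencies(panel, l),
              numeric(nrow(panel$snps)))
  usable <- rowSums(is.na(p)) == 0
  if (!any(usable)) stop("no SNP has observed genotypes in all four",
                         " populations", call. = FALSE)
  d <- (p[usable, 1] - p[usable, 2]) * (p[usable, 3] - p[usable, 4])
  n <- length(d)
  value <- mean(d)

  block <- ceiling(seq_len(n) / block_size)
  m <- tabulate(block)
  g <- length(m)
  if (g < 2) {
    se <- NA_real_
  } else {
    block_sum <- vapply(seq_len(g), function(b) sum(d[block == b]),
                        numeric(1))
    theta_minus <- (sum(d) - block_sum) / (n - m)   # leave-one-block-out
    # weighted jackknife (Busing et al. 1999), as used for f-statistics
    h <- n / m
    theta_j <- g * value - sum((1 - m / n) * theta_minus)
    tau <- h * value - (h - 1) * theta_minus
    se <- sqrt(sum((tau - theta_j)^2 / (h - 1)) / g)
  }
  out <- tibble::tibble(
    pop_a = pop_a, pop_b = pop_b, pop_c = pop_c, pop_d = pop_d,
    value = value, se = se, z = value / se,
    n_snps_used = n, n_blocks = g
  )
  structure(out, class = c("f4_result", class(out)))
}

#' f4 scan of an ancient individual against a set of test regions
#'
#' Runs [f4()] once per test region in the fixed orientation
#' (outgroup : ancient ; anchor : region), returning one row per region.
#' Regions are reported in the order supplied, so a geographic south-to-north
#' ordering can be imposed by the caller.
#'
#' @param panel A [genotype_panel()].
#' @param ancient Label of the ancient individual.
#' @param outgroup Label of the outgroup population (role of A).
#' @param anchor Label of the fixed comparison population (role of C).
#' @param test_regions Character vector of region labels (role of D).
#' @param block_size Jackknife block size in SNPs.
#' @return A tibble of class `f4_scan`, one `f4_result` row per region plus
#'   a `region` column; positive `value` means affinity between the ancient
#'   individual and that region.
#' @export
f4_panel_scan <- function(panel, ancient, outgroup, anchor, test_regions,
                          block_size = 500) {
  rows <- purrr::map(test_regions, function(region) {
    res <- f4(panel, outgroup, ancient, anchor, region,
              block_size = block_size)
    dplyr::mutate(res, region = region, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("f4_scan", setdiff(class(out), "f4_result")))
}
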