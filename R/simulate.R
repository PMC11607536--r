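#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genotype panel: a set of
#' geographically structured regions under Balding-Nichols drift, a uniform
#' genetic map, and an ancient target individual with planted runs of
#' homozygosity. Defaults follow the structure the downstream estimators
#' assume: 22 autosomes totalling 3523.4 cM of genetic map, region-level
#' differentiation of the magnitude seen between Scandinavian counties
#' (Fst of a few per mille), and a target with realistic missingness.
#'
#' @param n_regions Number of source regions.
#' @param n_per_region Reference samples simulated per region.
#' @param n_snps Total SNPs, spread over chromosomes proportionally to map
#'   length.
#' @param fst_per_region Drift parameter per region, each in (0, 1); recycled
#'   if length 1.
#' @param ancestral_maf_range Interval within (0, 0.5] from which ancestral
#'   minor-allele frequencies are drawn uniformly (mirrored to (0,1) so ref
#'   and alt are exchangeable).
#' @param map_cm_per_mb Genetic-map rate (cM per Mb), uniform; physical
#'   positions are derived from the cM grid at this rate.
#' @param n_chromosomes Number of autosomes to lay the map over.
#' @param total_map_cm Total genetic-map length in cM, split equally across
#'   chromosomes. Default 3523.4, the autosomal map length the inbreeding
#'   coefficient is expressed against.
#' @param roh_plan Data frame (or NULL) with columns `chromosome`,
#'   `start_cm`, `length_cm`: homozygous tracts to plant in the target.
#' @param target_region Region index the ancient target is drawn from.
#' @param missing_rate Fraction of genotype calls set missing uniformly at
#'   random (reference samples and target alike).
#' @param missing_in_roh Should missingness also hit planted tracts?
#'   Default `FALSE`, keeping planted tracts error-free.
#' @param het_error_rate Rate at which homozygous calls inside planted
#'   tracts are flipped to heterozygous (imputation-error knob, default 0).
#' @param seed Integer seed; the whole panel is deterministic given it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_regions = 8,
                       n_per_region = 100,
                       n_snps = 20000,
                       fst_per_region = 0.005,
                       ancestral_maf_range = c(0.05, 0.5),
                       map_cm_per_mb = 1.0,
                       n_chromosomes = 22,
                       total_map_cm = 3523.4,
                       roh_plan = NULL,
                       target_region = 1,
                       missing_rate = 0,
                       missing_in_roh = FALSE,
                       het_error_rate = 0,
                       seed = 1) {
  fst_per_region <- rep_len(fst_per_region, n_regions)
  stopifnot(
    n_regions >= 1, n_per_region >= 1, n_snps >= 1, n_chromosomes >= 1,
    all(fst_per_region > 0), all(fst_per_region < 1),
    length(ancestral_maf_range) == 2,
    ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
    ancestral_maf_range[1] <= ancestral_maf_range[2],
    map_cm_per_mb > 0, total_map_cm > 0,
    missing_rate >= 0, missing_rate < 1,
    het_error_rate >= 0, het_error_rate < 1,
    target_region >= 1, target_region <= n_regions
  )
  chr_len <- total_map_cm / n_chromosomes
  if (!is.null(roh_plan)) {
    roh_plan <- tibble::as_tibble(roh_plan)
    stopifnot(all(c("chromosome", "start_cm", "length_cm") %in%
                    names(roh_plan)))
    out_of_map <- roh_plan$chromosome < 1 |
      roh_plan$chromosome > n_chromosomes |
      roh_plan$start_cm < 0 |
      roh_plan$start_cm + roh_plan$length_cm > chr_len
    if (any(out_of_map)) {
      stop("roh_plan tract ", which(out_of_map)[1],
           " lies outside the simulated map", call. = FALSE)
    }
  }
  structure(
    list(n_regions = n_regions, n_per_region = n_per_region, n_snps = n_snps,
         fst_per_region = fst_per_region,
         ancestral_maf_range = ancestral_maf_range,
         map_cm_per_mb = map_cm_per_mb, n_chromosomes = n_chromosomes,
         total_map_cm = total_map_cm, chr_length_cm = chr_len,
         roh_plan = roh_plan, target_region = target_region,
         missing_rate = missing_rate, missing_in_roh = missing_in_roh,
         het_error_rate = het_error_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a structured genotype panel with an ancient target
#'
#' Balding-Nichols model: each SNP has an ancestral frequency p drawn
#' uniformly from the configured minor-allele range and mirrored to (0,1);
#' each region then draws its own frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the region's drift parameter, so the
#' between-region variance of the regional frequency is p(1-p)F. Reference
#' genotypes are Binomial(2, regional frequency). One extra sample,
#' `"ancient"`, is drawn from the target region; inside each planted tract a
#' single haplotype is sampled per SNP and doubled, making the tract
#' perfectly homozygous (optionally degraded by `het_error_rate`).
#' Missingness is applied uniformly at random, sparing planted tracts unless
#' `missing_in_roh = TRUE`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]; the target has
#'   sample id `"ancient"` and label `"ancient"`) and `truth` (a tibble with
#'   `true_region` — the label `region<k>` —, `true_f` — the planted ROH
#'   fraction of the total map —, and the planted tract table).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ref <- config$n_regions * config$n_per_region
  n_snp <- config$n_snps

  # uniform map: SNPs spread evenly over chromosomes of equal cM length
  chr <- sort(rep_len(seq_len(config$n_chromosomes), n_snp))
  pos_cm <- unlist(lapply(split(seq_len(n_snp), chr), function(idx) {
    k <- length(idx)
    config$chr_length_cm * (seq_len(k) - 0.5) / k
  }), use.names = FALSE)
  pos_bp <- as.integer(round(pos_cm / config$map_cm_per_mb * 1e6)) + 1L

  maf <- stats::runif(n_snp, config$ancestral_maf_range[1],
                      config$ancestral_maf_range[2])
  p_anc <- ifelse(stats::runif(n_snp) < 0.5, maf, 1 - maf)

  region_freq <- matrix(0, nrow = config$n_regions, ncol = n_snp)
  for (r in seq_len(config$n_regions)) {
    f <- config$fst_per_region[r]
    region_freq[r, ] <- stats::rbeta(n_snp,
                                     p_anc * (1 - f) / f,
                                     (1 - p_anc) * (1 - f) / f)
  }
  # guard against numerically degenerate Beta draws
  region_freq <- pmin(pmax(region_freq, 1e-9), 1 - 1e-9)

  g <- matrix(0L, nrow = n_ref + 1L, ncol = n_snp)
  region_of <- rep(seq_len(config$n_regions), each = config$n_per_region)
  for (r in seq_len(config$n_regions)) {
    rows <- which(region_of == r)
    g[rows, ] <- stats::rbinom(length(rows) * n_snp, 2L,
                               rep(region_freq[r, ], each = length(rows)))
  }
  target_row <- n_ref + 1L
  qt <- region_freq[config$target_region, ]
  g[target_row, ] <- stats::rbinom(n_snp, 2L, qt)

  in_tract <- rep(FALSE, n_snp)
  if (!is.null(config$roh_plan) && nrow(config$roh_plan) > 0) {
    for (i in seq_len(nrow(config$roh_plan))) {
      tr <- config$roh_plan[i, ]
      sel <- chr == tr$chromosome &
        pos_cm >= tr$start_cm & pos_cm <= tr$start_cm + tr$length_cm
      in_tract <- in_tract | sel
      hap <- stats::rbinom(sum(sel), 1L, qt[sel])
      g[target_row, sel] <- 2L * hap
    }
    if (config$het_error_rate > 0) {
      idx <- which(in_tract)
      flip <- idx[stats::runif(length(idx)) < config$het_error_rate]
      g[target_row, flip] <- 1L
    }
  }

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(g)) < config$missing_rate, nrow(g))
    if (!config$missing_in_roh && any(in_tract)) {
      miss[target_row, in_tract] <- FALSE
    }
    g[miss] <- NA_integer_
  }

  samples <- tibble::tibble(
    sample_id = c(sprintf("ref%04d", seq_len(n_ref)), "ancient"),
    label = c(paste0("region", region_of), "ancient")
  )
  snps <- tibble::tibble(
    snp_id = paste0("snp", seq_len(n_snp)),
    chromosome = chr, position_bp = pos_bp, position_cm = pos_cm,
    ref = "A", alt = "G"
  )
  true_f <- if (is.null(config$roh_plan)) 0 else
    sum(config$roh_plan$length_cm) / config$total_map_cm
  list(
    panel = genotype_panel(g, snps, samples),
    truth = list(
      true_region = paste0("region", config$target_region),
      true_f = true_f,
      roh_plan = config$roh_plan
    )
  )
}

#' Simulate sex-chromosome read counts
#'
#' The Y-aligned read count is Binomial(total, q) with q near zero for an XX
#' individual (a small `noise_floor` of mismapped reads) and q near 0.089 —
#' the empirical Y share of sex-chromosome alignments in males — for XY; the
#' remainder aligns to X.
#'
#' @param karyotype `"XX"` or `"XY"`.
#' @param total_sex_reads Total reads aligned to X plus Y; must be positive.
#' @param seed Integer seed.
#' @param q_xy Expected Y fraction for an XY individual (default 0.089).
#' @param noise_floor Expected Y fraction for an XX individual (default
#'   0.001, representing mismapping; set 0 for a clean XX).
#' @return A tibble with columns `n_x`, `n_y`.
#' @export
simulate_sex_reads <- function(karyotype = c("XY", "XX"), total_sex_reads,
                               seed = 1, q_xy = 0.089, noise_floor = 0.001) {
  karyotype <- match.arg(karyotype)
  stopifnot(total_sex_reads > 0)
  set.seed(seed)
  q <- if (karyotype == "XY") q_xy else noise_floor
  n_y <- stats::rbinom(1, as.integer(total_sex_reads), q)
  tibble::tibble(n_x = as.integer(total_sex_reads) - n_y, n_y = n_y)
}

#' Simulate a stable-isotope measurement from a marine diet fraction
#'
#' Inverse of the linear two-endpoint mixing model: each isotope value is
#' the convex combination of its terrestrial and marine endpoint at the
#' given marine fraction, plus Gaussian measurement noise.
#'
#' @param marine_fraction Diet fraction in \[0, 1\].
#' @param noise_sd Per-isotope measurement noise (permil), default 0.
#' @param seed Integer seed.
#' @param endpoints A [diet_endpoints()].
#' @return A tibble with columns `d13c`, `d15n` (permil, VPDB/AIR).
#' @export
simulate_isotopes <- function(marine_fraction, noise_sd = 0, seed = 1,
                              endpoints = diet_endpoints()) {
  stopifnot(marine_fraction >= 0, marine_fraction <= 1, noise_sd >= 0)
  set.seed(seed)
  f <- marine_fraction
  tibble::tibble(
    d13c = (1 - f) * endpoints$d13c_terrestrial + f * endpoints$d13c_marine +
      stats::rnorm(1, 0, noise_sd),
    d15n = (1 - f) * endpoints$d15n_terrestrial + f * endpoints$d15n_marine +
      stats::rnorm(1, 0, noise_sd)
  )
}
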