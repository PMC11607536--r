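#' Runs-of-homozygosity scan parameters
#'
#' Acceptance thresholds for homozygous fragments in imputed diploid
#' genotypes. The defaults are deliberately tolerant of isolated genotype
#' errors — common in imputed ancient samples — rather than breaking a
#' fragment at the first heterozygote: a candidate fragment may accumulate
#' up to `max_het_count` heterozygous calls as long as they stay below
#' `max_het_prop` of its genotyped calls, and is accepted only if longer
#' than `min_length_cm` (strict) with at least `min_hom_snps` homozygous
#' genotypes.
#'
#' @param maf_min Minor-allele-frequency filter applied before the scan;
#'   only SNPs with MAF strictly above this enter (default 0.03).
#' @param max_het_count Maximum heterozygous genotypes tolerated inside one
#'   candidate fragment (default 60).
#' @param max_het_prop Maximum heterozygous proportion of a candidate's
#'   genotyped (non-missing) calls (default 0.01).
#' @param min_length_cm Minimum fragment genetic length, strict (default 1).
#' @param min_hom_snps Minimum homozygous genotypes per fragment
#'   (default 1000; scale down with SNP density on sparse panels).
#' @param total_map_cm Autosomal genetic-map length the inbreeding
#'   coefficient is expressed against (default 3523.4 cM).
#' @return A `roh_params` list.
#' @export
roh_params <- function(maf_min = 0.03, max_het_count = 60,
                       max_het_prop = 0.01, min_length_cm = 1.0,
                       min_hom_snps = 1000, total_map_cm = 3523.4) {
  stopifnot(maf_min >= 0, maf_min < 0.5, max_het_count >= 0,
            max_het_prop > 0, max_het_prop < 1,
            min_length_cm > 0, min_hom_snps >= 1, total_map_cm > 0)
  structure(list(maf_min = maf_min, max_het_count = max_het_count,
                 max_het_prop = max_het_prop, min_length_cm = min_length_cm,
                 min_hom_snps = min_hom_snps, total_map_cm = total_map_cm),
            class = "roh_params")
}

#' Filter a panel to common SNPs
#'
#' Retains SNPs whose minor-allele frequency, computed from the panel's own
#' (or a supplied reference) allele frequencies, is strictly above
#' `maf_min`. Rare alleles carry little information about homozygosity by
#' descent — most individuals are homozygous at them by chance — so the ROH
#' scan runs on common SNPs only.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Threshold; SNPs with `min(p, 1-p) > maf_min` are kept.
#' @param freq Optional numeric vector of reference alternate-allele
#'   frequencies (one per SNP) to use instead of the panel's own.
#' @return The filtered `genotype_panel`, SNP order preserved.
#' @export
filter_snps <- function(panel, maf_min = 0.03, freq = NULL) {
  p <- freq %||% allele_frequencies(panel)
  if (length(p) != nrow(panel$snps)) {
    stop("frequency vector length does not match panel SNPs", call. = FALSE)
  }
  keep <- !is.na(p) & pmin(p, 1 - p) > maf_min
  if (!any(keep)) stop("no SNPs pass the MAF filter", call. = FALSE)
  panel_subset_snps(panel, keep)
}

#' Scan one individual for runs of homozygosity
#'
#' Left-to-right scan per chromosome over ordered genotype calls. A
#' candidate fragment opens at the first homozygous call at or after the
#' scan cursor and extends call by call; missing calls are spanned but
#' counted in neither tally. A heterozygote is admitted into the candidate
#' unless adding it would push the heterozygote count over
#' `max_het_count` or the heterozygote proportion (het / (het + hom)) over
#' `max_het_prop` — in that case the candidate is closed. On closure
#' (violation or chromosome end) the candidate is trimmed back to its last
#' homozygous call and accepted iff its genetic length strictly exceeds
#' `min_length_cm` and it holds at least `min_hom_snps` homozygous calls.
#' The scan resumes after the candidate's end when accepted, and after the
#' candidate's first internal heterozygote when rejected (so no acceptable
#' fragment starting inside a rejected candidate can be missed).
#'
#' @param calls Integer vector of genotype codes (0/1/2/NA) for one
#'   individual, aligned with `snps`.
#' @param snps SNP table with `chromosome` and `position_cm` columns,
#'   ordered; typically `panel$snps` after [filter_snps()].
#' @param params A [roh_params()].
#' @return A tibble of class `roh_segments`, one row per accepted fragment:
#'   `chromosome`, `start_index`/`end_index` (positions in the filtered SNP
#'   sequence, inclusive), `start_cm`, `end_cm`, `length_cm`, `n_hom`,
#'   `n_het`.
#' @export
call_roh <- function(calls, snps, params = roh_params()) {
  stopifnot(length(calls) == nrow(snps))
  validate_snp_order(snps)
  segs <- lapply(split(seq_along(calls), snps$chromosome), function(idx) {
    scan_chromosome(calls[idx], snps$position_cm[idx], params, idx[1] - 1L,
                    snps$chromosome[idx[1]])
  })
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chromosome = integer(), start_index = integer(),
                          end_index = integer(), start_cm = numeric(),
                          end_cm = numeric(), length_cm = numeric(),
                          n_hom = integer(), n_het = integer())
  }
  out <- dplyr::arrange(out, .data$chromosome, .data$start_cm)
  structure(out, class = c("roh_segments", class(out)))
}

# scan one chromosome; offset converts local indices to panel-wide ones
scan_chromosome <- function(calls, cm, params, offset, chromosome) {
  n <- length(calls)
  is_hom <- !is.na(calls) & (calls == 0L | calls == 2L)
  is_het <- !is.na(calls) & calls == 1L
  segments <- list()
  cursor <- 1L
  while (cursor <= n) {
    start <- cursor
    while (start <= n && !is_hom[start]) start <- start + 1L
    if (start > n) break
    n_hom <- 0L
    n_het <- 0L
    last_hom <- start
    first_het <- NA_integer_
    j <- start
    violated <- FALSE
    while (j <= n) {
      if (is_hom[j]) {
        n_hom <- n_hom + 1L
        last_hom <- j
      } else if (is_het[j]) {
        if (n_het + 1L > params$max_het_count ||
            (n_het + 1L) / (n_het + 1L + n_hom) > params$max_het_prop) {
          violated <- TRUE
          break
        }
        n_het <- n_het + 1L
        if (is.na(first_het)) first_het <- j
      }
      j <- j + 1L
    }
    # trim to last homozygous call; recount tallies inside the trimmed span
    span <- start:last_hom
    seg_hom <- sum(is_hom[span])
    seg_het <- sum(is_het[span])
    len <- cm[last_hom] - cm[start]
    accepted <- len > params$min_length_cm && seg_hom >= params$min_hom_snps
    if (accepted) {
      segments[[length(segments) + 1L]] <- tibble::tibble(
        chromosome = chromosome,
        start_index = start + offset, end_index = last_hom + offset,
        start_cm = cm[start], end_cm = cm[last_hom], length_cm = len,
        n_hom = seg_hom, n_het = seg_het
      )
      cursor <- last_hom + 1L
    } else if (!is.na(first_het) && first_het <= last_hom) {
      cursor <- first_het + 1L
    } else if (violated) {
      cursor <- j + 1L      # pure-hom candidate ended by an early het
    } else {
      break                  # chromosome end, nothing acceptable remains
    }
  }
  dplyr::bind_rows(segments)
}

#' Inbreeding coefficient from accepted ROH fragments
#'
#' F is the summed genetic length of accepted autosomal homozygous
#' fragments as a proportion of the total autosomal map
#' (`params$total_map_cm`, default 3523.4 cM).
#'
#' @param segments An `roh_segments` tibble from [call_roh()].
#' @param params A [roh_params()] (supplies `total_map_cm`).
#' @return A list of class `inbreeding_result`: `f`, `segments`,
#'   `total_map_cm`.
#' @export
inbreeding_coefficient <- function(segments, params = roh_params()) {
  f <- sum(segments$length_cm) / params$total_map_cm
  if (f > 1 + 1e-9) stop("ROH length exceeds total map length", call. = FALSE)
  structure(list(f = min(f, 1), segments = segments,
                 total_map_cm = params$total_map_cm),
            class = "inbreeding_result")
}

#' Full ROH/inbreeding pipeline for one panel sample
#'
#' Convenience wrapper: MAF-filters the panel, scans the named sample, and
#' returns the inbreeding coefficient with its fragments.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Sample to scan.
#' @param params A [roh_params()].
#' @param freq Optional reference alternate-allele frequencies for the MAF
#'   filter (see [filter_snps()]).
#' @return An `inbreeding_result`.
#' @export
estimate_inbreeding <- function(panel, sample_id, params = roh_params(),
                                freq = NULL) {
  filtered <- filter_snps(panel, params$maf_min, freq = freq)
  segs <- call_roh(panel_sample(filtered, sample_id), filtered$snps, params)
  inbreeding_coefficient(segs, params)
}

#' @export
print.inbreeding_result <- function(x, ...) {
  cat("<inbreeding_result> F = ", format(x$f, digits = 4), " (",
      nrow(x$segments), " fragment(s), ",
      format(sum(x$segments$length_cm), digits = 5), " / ",
      x$total_map_cm, " cM)\n", sep = "")
  invisible(x)
}
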