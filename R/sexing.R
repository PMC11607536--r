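#' Genetic sex determination from sex-chromosome read counts
#'
#' Computes the R_Y statistic — the fraction of sex-chromosome-aligned reads
#' mapping to the Y chromosome, R_Y = n_Y / (n_Y + n_X) — with a binomial
#' normal-approximation 95% confidence interval,
#' R_Y +/- 1.96 * sqrt(R_Y (1 - R_Y) / n), clipped to \[0, 1\]. A karyotype
#' is called against the standard thresholds: confident XX below 0.016,
#' confident XY above 0.075, otherwise indeterminate.
#'
#' @param counts Data frame with columns `n_x` and `n_y` (one row per
#'   library/individual), or a single numeric `n_x` with `n_y` supplied.
#' @param n_y Y-aligned read count when `counts` is given as a scalar `n_x`.
#' @param xx_max,xy_min Decision thresholds on R_Y (defaults 0.016, 0.075).
#' @param decision `"ci"` (default) calls XX only when the whole confidence
#'   interval sits below `xx_max` and XY only when it sits wholly above
#'   `xy_min` (conservative); `"point"` compares the point estimate alone.
#' @return A tibble of class `sex_call` with columns `n_x`, `n_y`, `r_y`,
#'   `ci_low`, `ci_high`, `karyotype` and threshold metadata attributes.
#' @examples
#' compute_ry(5302575, 515795)
#' @export
compute_ry <- function(counts, n_y = NULL,
                       xx_max = 0.016, xy_min = 0.075,
                       decision = c("ci", "point")) {
  decision <- match.arg(decision)
  if (is.numeric(counts) && !is.null(n_y)) {
    counts <- tibble::tibble(n_x = counts, n_y = n_y)
  }
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("n_x", "n_y") %in% names(counts)))
  if (any(counts$n_x < 0 | counts$n_y < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  n <- counts$n_x + counts$n_y
  if (any(n == 0)) {
    stop("n_x + n_y is zero: R_Y undefined", call. = FALSE)
  }
  r <- counts$n_y / n
  half <- 1.96 * sqrt(r * (1 - r) / n)
  lo <- pmax(r - half, 0)
  hi <- pmin(r + half, 1)
  karyotype <- dplyr::case_when(
    decision == "ci" & hi < xx_max ~ "XX",
    decision == "ci" & lo > xy_min ~ "XY",
    decision == "point" & r < xx_max ~ "XX",
    decision == "point" & r > xy_min ~ "XY",
    .default = "indeterminate"
  )
  out <- tibble::tibble(
    n_x = counts$n_x, n_y = counts$n_y,
    r_y = r, ci_low = lo, ci_high = hi, karyotype = karyotype
  )
  structure(out,
            class = c("sex_call", class(out)),
            xx_max = xx_max, xy_min = xy_min, decision = decision)
}

#' Endogenous DNA content
#'
#' Percentage of sequenced read pairs that mapped uniquely to the target
#' organism's reference genome, the standard yield statistic of an ancient
#' DNA library.
#'
#' @param mapped_unique Uniquely mapped read (pair) count.
#' @param total_read_pairs Total sequenced read pairs; must be positive and
#'   at least `mapped_unique`.
#' @param digits Decimal places in the reported percentage (default 1, the
#'   conventional precision).
#' @return Percentage in \[0, 100\], rounded to `digits`.
#' @examples
#' endogenous_rate(204791462, 5860146617)  # 3.5
#' @export
endogenous_rate <- function(mapped_unique, total_read_pairs, digits = 1) {
  if (total_read_pairs <= 0) stop("total_read_pairs must be positive",
                                  call. = FALSE)
  if (any(mapped_unique < 0) || any(mapped_unique > total_read_pairs)) {
    stop("mapped_unique must lie in [0, total_read_pairs]", call. = FALSE)
  }
  round(100 * mapped_unique / total_read_pairs, digits)
}
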