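#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sex call
#'
#' @param x A `sex_call` from [compute_ry()].
#' @param ... Unused.
#' @return A tibble with one row per library: counts, `r_y`, the confidence
#'   bounds and the karyotype call.
#' @export
tidy.sex_call <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.sex_call
#' @export
glance.sex_call <- function(x, ...) {
  tibble::tibble(
    n_libraries = nrow(x),
    xx_max = attr(x, "xx_max"), xy_min = attr(x, "xy_min"),
    decision = attr(x, "decision")
  )
}

#' Tidy a calibration result
#'
#' `tidy()` returns the posterior density grid; `glance()` one row with the
#' posterior median and the HPD summary. Use `x$hpd` for the interval table.
#'
#' @param x A `calibration_result` from [calibrate_c14()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.calibration_result <- function(x, ...) {
  x$grid
}

#' @rdname tidy.calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    age_bp = x$age_bp, sigma = x$sigma, level = x$level,
    median_ce = sort(x$grid$cal_ce)[
      which(cumsum(x$grid$density[order(x$grid$cal_ce)]) >= 0.5)[1]],
    n_hpd_intervals = nrow(x$hpd),
    hpd_total_mass = sum(x$hpd$probability)
  )
}

#' Tidy an inbreeding result
#'
#' `tidy()` returns the accepted fragment table; `glance()` the coefficient.
#'
#' @param x An `inbreeding_result` from [inbreeding_coefficient()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.inbreeding_result <- function(x, ...) {
  tibble::as_tibble(x$segments)
}

#' @rdname tidy.inbreeding_result
#' @export
glance.inbreeding_result <- function(x, ...) {
  tibble::tibble(
    f = x$f, n_segments = nrow(x$segments),
    total_roh_cm = sum(x$segments$length_cm),
    total_map_cm = x$total_map_cm
  )
}

#' Tidy a PCA model
#'
#' `tidy()` returns reference sample scores in long-friendly wide form;
#' `glance()` per-component eigenvalues and variance shares.
#'
#' @param x A `pca_model` from [fit_reference_pca()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pca_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(x$scores), label = x$labels),
    tibble::as_tibble(x$scores)
  )
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_share = x$eigenvalues / sum(x$eigenvalues)
  )
}

#' Tidy an ancestry assignment
#'
#' `tidy()` returns the per-region summary (mean weighted distance and the
#' Welch p-value against the best region); `glance()` one row with the call.
#'
#' @param x An `ancestry_assignment` from [assign_region()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ancestry_assignment <- function(x, ...) {
  x$regions
}

#' @rdname tidy.ancestry_assignment
#' @export
glance.ancestry_assignment <- function(x, ...) {
  runner_up <- x$regions[x$regions$label != x$best_region, ]
  tibble::tibble(
    best_region = x$best_region,
    n_regions = nrow(x$regions),
    min_p_vs_best = min(x$regions$p_value, na.rm = TRUE),
    runner_up = runner_up$label[1],
    runner_up_p = runner_up$p_value[1],
    k = x$k, weight = x$weight
  )
}
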