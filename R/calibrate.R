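#' Diet mixing-model endpoints
#'
#' Terrestrial and marine endpoint values for bone-collagen stable isotopes,
#' used to place a measured individual on the terrestrial-marine dietary
#' continuum. Defaults are the endpoints in use for medieval Scandinavian
#' skeletal material: delta13C -22 permil (fully terrestrial) to -12 permil
#' (fully marine), delta15N 10 permil to 23 permil.
#'
#' @param d13c_terrestrial,d13c_marine delta13C endpoints (permil, VPDB).
#' @param d15n_terrestrial,d15n_marine delta15N endpoints (permil, AIR).
#' @return A `diet_endpoints` list.
#' @export
diet_endpoints <- function(d13c_terrestrial = -22, d13c_marine = -12,
                           d15n_terrestrial = 10, d15n_marine = 23) {
  if (d13c_terrestrial == d13c_marine || d15n_terrestrial == d15n_marine) {
    stop("marine and terrestrial endpoints must differ per isotope",
         call. = FALSE)
  }
  structure(list(d13c_terrestrial = d13c_terrestrial,
                 d13c_marine = d13c_marine,
                 d15n_terrestrial = d15n_terrestrial,
                 d15n_marine = d15n_marine),
            class = "diet_endpoints")
}

#' Estimate the marine dietary fraction from stable isotopes
#'
#' Linear two-endpoint mixing per isotope:
#' f_i = (value_i - terrestrial_i) / (marine_i - terrestrial_i), clipped to
#' \[0, 1\]. The combined estimate averages the delta13C and delta15N
#' fractions; either single-isotope estimate is also reported and can be
#' selected as the combined value via `combine`.
#'
#' @param isotopes Data frame with columns `d13c` and `d15n` (permil), or a
#'   single numeric `d13c` with `d15n` supplied.
#' @param d15n delta15N value when `isotopes` is a scalar delta13C.
#' @param endpoints A [diet_endpoints()].
#' @param combine `"mean"` (default), `"d13c"` or `"d15n"`.
#' @return A tibble with columns `d13c`, `d15n`, `f_d13c`, `f_d15n`,
#'   `marine_fraction`.
#' @examples
#' estimate_marine_fraction(-19.84, 12.38)  # marine_fraction ~ 0.1995
#' @export
estimate_marine_fraction <- function(isotopes, d15n = NULL,
                                     endpoints = diet_endpoints(),
                                     combine = c("mean", "d13c", "d15n")) {
  combine <- match.arg(combine)
  if (is.numeric(isotopes) && !is.null(d15n)) {
    isotopes <- tibble::tibble(d13c = isotopes, d15n = d15n)
  }
  isotopes <- tibble::as_tibble(isotopes)
  stopifnot(all(c("d13c", "d15n") %in% names(isotopes)))
  if (any(!is.finite(isotopes$d13c)) || any(!is.finite(isotopes$d15n))) {
    stop("isotope values must be finite", call. = FALSE)
  }
  if (any(isotopes$d13c > 0)) {
    warning("positive delta13C: collagen values are conventionally negative",
            " - check the sign", call. = FALSE)
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  f13 <- clip01((isotopes$d13c - endpoints$d13c_terrestrial) /
                  (endpoints$d13c_marine - endpoints$d13c_terrestrial))
  f15 <- clip01((isotopes$d15n - endpoints$d15n_terrestrial) /
                  (endpoints$d15n_marine - endpoints$d15n_terrestrial))
  f <- switch(combine,
              mean = (f13 + f15) / 2,
              d13c = f13,
              d15n = f15)
  tibble::tibble(d13c = isotopes$d13c, d15n = isotopes$d15n,
                 f_d13c = f13, f_d15n = f15, marine_fraction = f)
}

#' Mix a terrestrial and a marine calibration curve
#'
#' Builds the diet-corrected calibration curve for an individual with marine
#' dietary fraction `alpha`: on the 1-year intersection grid of the two
#' curves (each linearly interpolated),
#' \deqn{\mu(t) = (1-\alpha)\,\mu_T(t) + \alpha\,(\mu_M(t) + \Delta R)}
#' \deqn{\sigma(t)^2 = ((1-\alpha)\sigma_T(t))^2 + (\alpha\sigma_M(t))^2 +
#'   (\alpha\,\sigma_{\Delta R})^2 +
#'   (\sigma_\alpha\,(\mu_M(t)+\Delta R-\mu_T(t)))^2}
#' the convention of OxCal's Mix_Curves: linear means, errors in quadrature,
#' with optional uncertainty on the local reservoir offset and on the
#' mixing fraction itself.
#'
#' @param terrestrial,marine Two [cal_curve()] objects with overlapping
#'   calendar range.
#' @param alpha Marine fraction in \[0, 1\].
#' @param delta_r Local marine reservoir offset (14C yr), default 0.
#' @param delta_r_sigma One-sigma of `delta_r`, default 0.
#' @param alpha_sigma One-sigma of `alpha`, default 0.
#' @return A [cal_curve()] on the 1-year intersection grid.
#' @export
mix_curves <- function(terrestrial, marine, alpha,
                       delta_r = 0, delta_r_sigma = 0, alpha_sigma = 0) {
  stopifnot(alpha >= 0, alpha <= 1, delta_r_sigma >= 0, alpha_sigma >= 0)
  lo <- max(min(terrestrial$cal_bp), min(marine$cal_bp))
  hi <- min(max(terrestrial$cal_bp), max(marine$cal_bp))
  if (lo >= hi) stop("calibration curves do not overlap", call. = FALSE)
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  tc <- interpolate_curve(terrestrial, grid)
  mc <- interpolate_curve(marine, grid)
  mu <- (1 - alpha) * tc$c14_age + alpha * (mc$c14_age + delta_r)
  var <- ((1 - alpha) * tc$sigma)^2 + (alpha * mc$sigma)^2 +
    (alpha * delta_r_sigma)^2 +
    (alpha_sigma * (mc$c14_age + delta_r - tc$c14_age))^2
  cal_curve(cal_bp = grid, c14_age = mu, sigma = sqrt(var))
}

#' Calibrate a conventional radiocarbon age
#'
#' Probability-density calibration on a 1-year calendar grid: for each
#' calendar year t with curve mean mu(t) and error sigma_c(t), the
#' likelihood of the measurement (age_bp, sigma) is
#' \deqn{L(t) \propto \frac{1}{\sqrt{\sigma^2+\sigma_c(t)^2}}
#'   \exp\!\left(-\frac{(age - \mu(t))^2}{2(\sigma^2+\sigma_c(t)^2)}\right)}
#' normalised over the grid to a posterior (uniform calendar prior). The
#' highest-posterior-density region at the requested level is the smallest
#' set of grid years whose mass reaches the level, merged into contiguous
#' intervals.
#'
#' @param age_bp Conventional radiocarbon age (14C yr BP).
#' @param sigma One-sigma measurement error (14C yr); must be positive.
#' @param curve A [cal_curve()] (already diet-corrected if needed; see
#'   [mix_curves()]).
#' @param level HPD probability level, default 0.954 (the conventional
#'   two-sigma level).
#' @param boundary `"warn"` (default) or `"error"`: behaviour when posterior
#'   mass is concentrated at the grid boundary (> 1e-6 in an edge cell),
#'   which signals that the curve does not cover the measurement.
#' @return A `calibration_result` list: `grid` (tibble with `cal_bp`,
#'   `cal_ce`, `density`), `hpd` (tibble with `start_ce`, `end_ce`,
#'   `start_bp`, `end_bp`, `probability` in percent), `level`, `age_bp`,
#'   `sigma`.
#' @export
calibrate_c14 <- function(age_bp, sigma, curve, level = 0.954,
                          boundary = c("warn", "error")) {
  boundary <- match.arg(boundary)
  stopifnot(sigma > 0, level > 0, level < 1)
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  cc <- interpolate_curve(curve, grid)
  tot_var <- sigma^2 + cc$sigma^2
  log_lik <- -0.5 * (age_bp - cc$c14_age)^2 / tot_var - 0.5 * log(tot_var)
  dens <- exp(log_lik - max(log_lik))
  dens <- dens / sum(dens)

  edge_mass <- max(dens[1], dens[length(dens)])
  if (edge_mass > 1e-6) {
    msg <- paste0("posterior mass at grid boundary (", signif(edge_mass, 3),
                  "): curve may not cover the measurement")
    if (boundary == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  hpd <- hpd_from_density(grid, dens, level)
  structure(
    list(
      grid = tibble::tibble(cal_bp = grid, cal_ce = 1950 - grid,
                            density = dens),
      hpd = hpd, level = level, age_bp = age_bp, sigma = sigma
    ),
    class = "calibration_result"
  )
}

# smallest density-threshold set of grid years with mass >= level, merged
# into intervals; density ties at the threshold are included as a whole so
# the set is well defined on plateaued curves
hpd_from_density <- function(grid, dens, level) {
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  n_in <- which(cum >= level)[1]
  if (is.na(n_in)) n_in <- length(dens)
  threshold <- dens[ord[n_in]]
  in_set <- dens >= threshold

  runs <- rle(in_set)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- which(runs$values)
  hpd <- tibble::tibble(
    start_bp = grid[ends[seg]],          # larger BP = older = interval start
    end_bp = grid[starts[seg]],
    start_ce = 1950 - grid[ends[seg]],
    end_ce = 1950 - grid[starts[seg]],
    probability = vapply(seg, function(s)
      round(100 * sum(dens[starts[s]:ends[s]]), 1), numeric(1))
  )
  dplyr::arrange(hpd, .data$start_ce)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$age_bp, " +/- ", x$sigma, " 14C BP, ",
      sprintf("%.1f%%", 100 * x$level), " HPD:\n", sep = "")
  for (i in seq_len(nrow(x$hpd))) {
    cat(sprintf("  %d-%d cal CE (%.1f%%)\n",
                x$hpd$start_ce[i], x$hpd$end_ce[i], x$hpd$probability[i]))
  }
  invisible(x)
}
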