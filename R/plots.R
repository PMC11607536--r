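#' Plot a calibrated radiocarbon posterior
#'
#' Posterior density over calendar years (CE) with the HPD intervals
#' shaded.
#'
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_result <- function(object, ...) {
  grid <- object$grid
  in_hpd <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(object$hpd))) {
    in_hpd <- in_hpd | (grid$cal_ce >= object$hpd$start_ce[i] &
                          grid$cal_ce <= object$hpd$end_ce[i])
  }
  grid$in_hpd <- in_hpd
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$cal_ce, y = .data$density)) +
    ggplot2::geom_area(data = grid[grid$in_hpd, ], fill = "steelblue",
                       alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "calendar year (cal CE)", y = "posterior density",
      title = sprintf("%d ± %d 14C BP, %.1f%% HPD shaded",
                      round(object$age_bp), round(object$sigma),
                      100 * object$level)
    ) +
    ggplot2::theme_minimal()
}

#' Plot reference PCA scores with an optional projected query
#'
#' @param object A `pca_model`.
#' @param query Optional coordinates from [project_sample()], drawn as a
#'   labelled point.
#' @param components Two components to display (default PC1, PC2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_model <- function(object, query = NULL,
                               components = c(1, 2), ...) {
  d <- tidy.pca_model(object)
  xs <- paste0("PC", components[1])
  ys <- paste0("PC", components[2])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xs]], y = .data[[ys]],
                                       colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(colour = "region") +
    ggplot2::theme_minimal()
  if (!is.null(query)) {
    q <- tibble::tibble(x = query[components[1]], y = query[components[2]])
    p <- p +
      ggplot2::geom_point(data = q, ggplot2::aes(x = .data$x, y = .data$y),
                          inherit.aes = FALSE, shape = 8, size = 3) +
      ggplot2::annotate("text", x = q$x, y = q$y, label = "query",
                        vjust = -1, size = 3)
  }
  p
}

#' Plot an f4 scan with one-standard-error bars
#'
#' Regions on the vertical axis in the supplied order (first region at the
#' bottom, matching a south-to-north geographic ordering when given one);
#' positive values indicate affinity between the ancient individual and the
#' region.
#'
#' @param object An `f4_scan` from [f4_panel_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.f4_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$region)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$value - .data$se,
                   xmax = .data$value + .data$se),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("f4(%s, %s; %s, region)", d$pop_a[1],
                              d$pop_b[1], d$pop_c[1]),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot accepted ROH fragments along the genome
#'
#' One horizontal track per chromosome with accepted fragments drawn as
#' segments on the genetic map.
#'
#' @param object An `inbreeding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inbreeding_result <- function(object, ...) {
  segs <- tibble::as_tibble(object$segments)
  if (nrow(segs) == 0) {
    segs <- tibble::tibble(chromosome = integer(), start_cm = numeric(),
                           end_cm = numeric())
  }
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_cm, xend = .data$end_cm,
                   y = factor(.data$chromosome),
                   yend = factor(.data$chromosome)),
      linewidth = 3, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "genetic position (cM)", y = "chromosome",
      title = sprintf("accepted ROH fragments, F = %.4f", object$f)
    ) +
    ggplot2::theme_minimal()
}
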