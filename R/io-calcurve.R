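#' Read a radiocarbon calibration curve (.14c layout)
#'
#' Parses the standard calibration-curve table layout used for curves such
#' as IntCal20 and Marine20: comment lines starting with `#`, then three (or
#' more) comma- or whitespace-delimited numeric columns — calendar age
#' (cal BP, 1950 datum), curve radiocarbon age (14C yr BP) and the curve's
#' one-sigma error (14C yr). Extra columns (Delta-14C and its error in the
#' published files) are ignored.
#'
#' @param path Curve file.
#' @return A `cal_curve`: a tibble with columns `cal_bp`, `c14_age`, `sigma`,
#'   sorted so `cal_bp` is strictly increasing.
#' @export
read_cal_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0) {
    stop("no data rows in calibration curve file: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines[body_idx]), "[,[:space:]]+")
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    stop("line ", body_idx[which(n_col < 3)[1]],
         ": fewer than 3 columns", call. = FALSE)
  }
  num <- vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[1:3]))
  }, numeric(3))
  bad <- which(colSums(is.na(num)) > 0)
  if (length(bad) > 0) {
    stop("line ", body_idx[bad[1]], ": non-numeric field", call. = FALSE)
  }
  cal_curve(cal_bp = num[1, ], c14_age = num[2, ], sigma = num[3, ])
}

#' Construct and validate a calibration curve
#'
#' @param cal_bp Calendar ages (years BP); any order, re-sorted ascending.
#' @param c14_age Curve mean radiocarbon age per grid point (14C yr BP).
#' @param sigma Curve one-sigma error per grid point; must be positive.
#' @return A `cal_curve` tibble with strictly increasing `cal_bp`.
#' @export
cal_curve <- function(cal_bp, c14_age, sigma) {
  if (length(cal_bp) != length(c14_age) || length(cal_bp) != length(sigma)) {
    stop("cal_bp, c14_age and sigma must have equal length", call. = FALSE)
  }
  if (length(cal_bp) == 0) stop("empty calibration curve", call. = FALSE)
  if (any(sigma <= 0)) {
    stop("curve sigma must be positive everywhere", call. = FALSE)
  }
  ord <- order(cal_bp)
  cal_bp <- cal_bp[ord]
  if (any(diff(cal_bp) <= 0)) {
    stop("duplicate cal BP grid points", call. = FALSE)
  }
  structure(
    tibble::tibble(cal_bp = cal_bp, c14_age = c14_age[ord],
                   sigma = sigma[ord]),
    class = c("cal_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Write a calibration curve in .14c layout
#'
#' @param curve A [cal_curve()].
#' @param path Output path.
#' @param comment Header comment line(s), written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_cal_curve <- function(curve, path, comment = "cal BP, 14C age BP, sigma") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%g,%g,%g", curve$cal_bp, curve$c14_age, curve$sigma),
             con)
  invisible(path)
}

# linear interpolation of mean and sigma onto an arbitrary cal BP grid
interpolate_curve <- function(curve, grid) {
  tibble::tibble(
    cal_bp = grid,
    c14_age = stats::approx(curve$cal_bp, curve$c14_age, xout = grid)$y,
    sigma = stats::approx(curve$cal_bp, curve$sigma, xout = grid)$y
  )
}
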