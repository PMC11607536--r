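#' Run an end-to-end individual profile
#'
#' Orchestrates the package's stages — genetic sexing, marine-diet
#' estimation, diet-corrected radiocarbon calibration, the ROH/inbreeding
#' scan, PCA projection with region assignment, and the f4 scan — from a
#' single declarative configuration, returning one consolidated report.
#' All randomness flows from one top-level seed, so identical config and
#' seed give an identical report.
#'
#' @param config Nested list (or path to a YAML file with the same
#'   structure). Recognised sections, each optional — a stage runs iff its
#'   section is present:
#' \describe{
#'   \item{seed}{Top-level integer seed (default 1).}
#'   \item{simulate}{Arguments for [sim_config()]; the simulated panel then
#'     serves the roh/ancestry/f4 stages unless they name their own input.}
#'   \item{panel}{`list(path=, format="eigenstrat"|"vcf", ...)` to load a
#'     panel from disk instead of simulating.}
#'   \item{sexing}{`list(n_x=, n_y=)` read counts, or
#'     `list(karyotype=, total_sex_reads=)` to simulate them.}
#'   \item{diet}{`list(d13c=, d15n=)` or `list(marine_fraction=, noise_sd=)`
#'     to simulate; optional endpoint overrides.}
#'   \item{calibrate}{`list(age_bp=, sigma=, terrestrial=, marine=, level=,
#'     delta_r=)`: curve file paths (.14c); the marine fraction defaults to
#'     the diet stage's estimate.}
#'   \item{roh}{`list(sample_id=, params=list(...))`; defaults to the
#'     simulated target `"ancient"`.}
#'   \item{ancestry}{`list(sample_id=, n_components=, k=)`.}
#'   \item{f4}{`list(ancient=, outgroup=, anchor=, test_regions=,
#'     block_size=)`.}
#' }
#' @return A `profile_report` list with one element per executed stage
#'   (`sex`, `diet`, `date`, `inbreeding`, `ancestry`, `f4_table`, `truth`
#'   when simulated) plus `provenance` (seed, config digest, package
#'   version).
#' @export
run_profile <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- intersect(names(config),
                      c("simulate", "panel", "sexing", "diet", "calibrate",
                        "roh", "ancestry", "f4"))
  if (length(stages) == 0) {
    stop("no stage enabled in configuration", call. = FALSE)
  }
  validate_profile_config(config)
  seed <- config$seed %||% 1L
  report <- list()
  panel <- NULL
  truth <- NULL

  if ("panel" %in% stages) {
    p <- config$panel
    panel <- switch(
      p$format %||% "eigenstrat",
      eigenstrat = read_eigenstrat(p$path,
                                   genetic_unit = p$genetic_unit %||%
                                     "morgans"),
      vcf = read_vcf_panel(p$path),
      stop("unknown panel format: ", p$format, call. = FALSE)
    )
  } else if ("simulate" %in% stages) {
    sim <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                 config$simulate))
    out <- simulate_panel(sim)
    panel <- out$panel
    truth <- out$truth
    report$truth <- truth
  }

  if ("sexing" %in% stages) {
    s <- config$sexing
    counts <- if (!is.null(s$n_x)) {
      tibble::tibble(n_x = s$n_x, n_y = s$n_y)
    } else {
      simulate_sex_reads(s$karyotype, s$total_sex_reads, seed = seed)
    }
    report$sex <- compute_ry(counts)
  }

  marine_fraction <- NULL
  if ("diet" %in% stages) {
    d <- config$diet
    ep <- do.call(diet_endpoints, d$endpoints %||% list())
    iso <- if (!is.null(d$d13c)) {
      tibble::tibble(d13c = d$d13c, d15n = d$d15n)
    } else {
      simulate_isotopes(d$marine_fraction, d$noise_sd %||% 0, seed = seed,
                        endpoints = ep)
    }
    report$diet <- estimate_marine_fraction(iso, endpoints = ep)
    marine_fraction <- report$diet$marine_fraction[1]
  }

  if ("calibrate" %in% stages) {
    cc <- config$calibrate
    terr <- read_cal_curve(cc$terrestrial)
    alpha <- cc$alpha %||% marine_fraction %||%
      stop("calibrate stage needs 'alpha' or a diet stage", call. = FALSE)
    curve <- if (!is.null(cc$marine)) {
      mix_curves(terr, read_cal_curve(cc$marine), alpha,
                 delta_r = cc$delta_r %||% 0)
    } else {
      terr
    }
    report$date <- calibrate_c14(cc$age_bp, cc$sigma, curve,
                                 level = cc$level %||% 0.954)
  }

  if ("roh" %in% stages) {
    r <- config$roh
    params <- do.call(roh_params, r$params %||% list())
    report$inbreeding <- estimate_inbreeding(
      panel, r$sample_id %||% "ancient", params
    )
  }

  if ("ancestry" %in% stages) {
    a <- config$ancestry
    model <- fit_reference_pca(panel, n_components = a$n_components %||% 10)
    coords <- project_sample(model,
                             panel_sample(panel, a$sample_id %||% "ancient"))
    report$ancestry <- assign_region(model, coords, k = a$k %||% 10)
  }

  if ("f4" %in% stages) {
    fz <- config$f4
    regions <- fz$test_regions %||%
      setdiff(unique(panel$samples$label),
              c(fz$ancient %||% "ancient", fz$outgroup, fz$anchor))
    report$f4_table <- f4_panel_scan(
      panel, fz$ancient %||% "ancient", fz$outgroup, fz$anchor,
      regions, block_size = fz$block_size %||% 500
    )
  }

  report$provenance <- list(
    seed = seed,
    stages = stages,
    config_digest = config_digest(config),
    package_version = as.character(utils::packageVersion("adnaprofile"))
  )
  structure(report, class = "profile_report")
}

# fail before any computation if an enabled stage lacks its input
validate_profile_config <- function(config) {
  needs_panel <- intersect(names(config), c("roh", "ancestry", "f4"))
  if (length(needs_panel) > 0 &&
      !any(c("panel", "simulate") %in% names(config))) {
    stop("stage(s) ", paste(needs_panel, collapse = ", "),
         " need a 'panel' or 'simulate' section", call. = FALSE)
  }
  if (!is.null(config$panel) && !is.null(config$panel$path) &&
      !is.null(config$panel$format) && config$panel$format == "vcf" &&
      !file.exists(config$panel$path)) {
    stop("panel file not found: ", config$panel$path, call. = FALSE)
  }
  if (!is.null(config$sexing) && is.null(config$sexing$n_x) &&
      is.null(config$sexing$karyotype)) {
    stop("sexing stage needs read counts or a karyotype to simulate",
         call. = FALSE)
  }
  if (!is.null(config$calibrate)) {
    cc <- config$calibrate
    if (is.null(cc$age_bp) || is.null(cc$sigma) || is.null(cc$terrestrial)) {
      stop("calibrate stage needs age_bp, sigma and a terrestrial curve",
           call. = FALSE)
    }
    for (f in c(cc$terrestrial, cc$marine)) {
      if (!file.exists(f)) stop("curve file not found: ", f, call. = FALSE)
    }
  }
  invisible(config)
}

# order-independent digest of the configuration (no external deps)
config_digest <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  # small rolling hash; stability matters, cryptographic strength does not
  bytes <- utf8ToInt(as.character(txt))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Write a profile report to JSON
#'
#' Serialises the tabular parts of a `profile_report` (tidied per stage)
#' into one JSON document.
#'
#' @param report A `profile_report` from [run_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_report <- function(report, path) {
  out <- list(provenance = report$provenance)
  if (!is.null(report$sex)) out$sex <- as.list(tibble::as_tibble(report$sex))
  if (!is.null(report$diet)) out$diet <- as.list(report$diet)
  if (!is.null(report$date)) {
    out$date <- list(level = report$date$level,
                     hpd = as.list(report$date$hpd))
  }
  if (!is.null(report$inbreeding)) {
    out$inbreeding <- list(f = report$inbreeding$f,
                           segments = as.list(report$inbreeding$segments))
  }
  if (!is.null(report$ancestry)) {
    out$ancestry <- list(best_region = report$ancestry$best_region,
                         regions = as.list(report$ancestry$regions))
  }
  if (!is.null(report$f4_table)) {
    out$f4 <- as.list(tibble::as_tibble(report$f4_table))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.profile_report <- function(x, ...) {
  cat("<profile_report> stages:",
      paste(x$provenance$stages, collapse = ", "), "\n")
  if (!is.null(x$sex)) {
    cat("  sex: ", x$sex$karyotype[1],
        sprintf(" (R_Y = %.4f)", x$sex$r_y[1]), "\n", sep = "")
  }
  if (!is.null(x$diet)) {
    cat(sprintf("  marine diet: %.1f%%\n",
                100 * x$diet$marine_fraction[1]))
  }
  if (!is.null(x$date)) {
    cat(sprintf("  date: %d HPD interval(s) at %.1f%%\n",
                nrow(x$date$hpd), 100 * x$date$level))
  }
  if (!is.null(x$inbreeding)) {
    cat(sprintf("  inbreeding: F = %.4f (%d fragment(s))\n",
                x$inbreeding$f, nrow(x$inbreeding$segments)))
  }
  if (!is.null(x$ancestry)) {
    cat("  ancestry: ", x$ancestry$best_region, "\n", sep = "")
  }
  if (!is.null(x$f4_table)) {
    top <- x$f4_table$region[which.max(x$f4_table$value)]
    cat("  f4: highest affinity with ", top, "\n", sep = "")
  }
  invisible(x)
}
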