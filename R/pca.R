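#' Fit a reference PCA on a genotype panel
#'
#' smartpca-style principal component analysis of the reference samples:
#' each SNP j is centred by twice its observed alternate-allele frequency
#' (mean_j = 2 p_j) and scaled by the binomial standard deviation unit
#' sqrt(p_j (1 - p_j)); missing genotypes are set to zero after centring
#' (the mean). Components come from the eigendecomposition of the sample
#' covariance of the normalised matrix, computed via the samples-by-samples
#' cross-product so panels with many more SNPs than samples stay cheap.
#' Column signs are fixed deterministically (largest-magnitude loading
#' positive) so results are reproducible.
#'
#' @param panel A [genotype_panel()] of reference samples. Samples labelled
#'   `exclude_labels` (default `"ancient"`) are left out of the fit; project
#'   them afterwards with [project_sample()].
#' @param n_components Number of components to retain (default 10).
#' @param exclude_labels Labels excluded from the reference fit.
#' @param bayesian_freq Use the shrunk frequency estimate
#'   (1 + alt count) / (2 + 2n) instead of the raw observed frequency.
#'   Off by default; at reference-panel sizes the two are indistinguishable.
#' @return A `pca_model` list: `snp_ids`, `center`, `scale`, `loadings`
#'   (SNP x component, orthonormal), `eigenvalues` (non-increasing),
#'   `scores` (reference sample x component), `labels`, `dropped_snps`
#'   (monomorphic SNPs removed, by id).
#' @export
fit_reference_pca <- function(panel, n_components = 10,
                              exclude_labels = "ancient",
                              bayesian_freq = FALSE) {
  keep <- !(panel$samples$label %in% exclude_labels)
  g <- panel$genotypes[keep, , drop = FALSE]
  labels <- panel$samples$label[keep]
  n <- nrow(g)
  if (n_components > min(n - 1, ncol(g))) {
    stop("n_components exceeds min(samples - 1, SNPs)", call. = FALSE)
  }
  n_obs <- colSums(!is.na(g))
  if (any(n_obs == 0)) {
    stop("SNP(s) with no observed genotype among reference samples",
         call. = FALSE)
  }
  alt <- colSums(g, na.rm = TRUE)
  p <- if (bayesian_freq) (1 + alt) / (2 + 2 * n_obs) else alt / (2 * n_obs)

  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) dropped from the PCA",
            call. = FALSE)
  }
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  center <- 2 * p
  scale <- sqrt(p * (1 - p))

  x <- sweep(g, 2, center, "-")
  x[is.na(x)] <- 0
  x <- sweep(x, 2, scale, "/")

  cp <- tcrossprod(x)                      # samples x samples
  eig <- eigen(cp, symmetric = TRUE)
  k <- n_components
  d <- sqrt(pmax(eig$values[seq_len(k)], 0))
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  loadings <- crossprod(x, u) %*% diag(1 / d, k)

  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, k)
  rownames(scores) <- panel$samples$sample_id[keep]
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(loadings) <- paste0("PC", seq_len(k))

  structure(
    list(snp_ids = panel$snps$snp_id[poly], center = center, scale = scale,
         loadings = loadings,
         eigenvalues = eig$values[seq_len(k)] / (n - 1),
         scores = scores, labels = labels,
         dropped_snps = panel$snps$snp_id[!poly]),
    class = "pca_model"
  )
}

#' Project an individual onto a reference PCA by least squares
#'
#' lsqproject-style projection for partially missing samples: the
#' individual's non-missing genotypes are normalised with the model's
#' centring and scaling, and its coordinates are the least-squares solution
#' of x_obs ~ L_obs s over the loadings rows restricted to observed SNPs.
#' With no missingness and orthonormal loadings this is the exact transform
#' (reference samples reproduce their own scores); with missingness it
#' avoids the shrinkage toward zero that naive zero-filling causes.
#'
#' @param model A `pca_model` from [fit_reference_pca()].
#' @param genotypes Named (by SNP id) or model-aligned integer vector of
#'   genotype codes 0/1/2/NA for one individual.
#' @return Numeric vector of coordinates, length `ncol(model$loadings)`.
#' @export
project_sample <- function(model, genotypes) {
  if (!is.null(names(genotypes))) {
    genotypes <- genotypes[model$snp_ids]
  }
  if (length(genotypes) != length(model$snp_ids)) {
    stop("genotype vector not aligned to the model's SNPs", call. = FALSE)
  }
  obs <- which(!is.na(genotypes))
  k <- ncol(model$loadings)
  if (length(obs) < k) {
    stop("fewer non-missing SNPs (", length(obs),
         ") than components (", k, ")", call. = FALSE)
  }
  x <- (genotypes[obs] - model$center[obs]) / model$scale[obs]
  l_obs <- model$loadings[obs, , drop = FALSE]
  fit <- stats::lm.fit(l_obs, x)
  if (fit$rank < k) stop("loadings rank-deficient on observed SNPs",
                         call. = FALSE)
  stats::setNames(fit$coefficients, colnames(model$loadings))
}

#' Eigenvalue-weighted Euclidean distance in PC space
#'
#' d = sqrt( sum_{j=1..k} lambda_j (a_j - b_j)^2 ): components are weighted
#' by the variance they explain, so high-order noise components barely
#' contribute. `b` may be a matrix (one row per individual).
#'
#' @param a Coordinates of the query (length >= k).
#' @param b Coordinates of a second individual, or a matrix of them.
#' @param eigenvalues Per-component variances (length >= k).
#' @param k Number of leading components used (default 10).
#' @param weight `"linear"` (default, lambda_j inside the square sum) or
#'   `"squared"` (lambda_j^2), recorded in the result attributes of
#'   [assign_region()].
#' @return Numeric distance (vector if `b` is a matrix).
#' @export
weighted_distance <- function(a, b, eigenvalues, k = 10,
                              weight = c("linear", "squared")) {
  weight <- match.arg(weight)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (length(a) < k || ncol(b) < k || length(eigenvalues) < k) {
    stop("fewer than k = ", k, " components available", call. = FALSE)
  }
  w <- eigenvalues[seq_len(k)]
  if (weight == "squared") w <- w^2
  d2 <- sweep(b[, seq_len(k), drop = FALSE], 2, a[seq_len(k)], "-")^2
  sqrt(as.vector(d2 %*% w))
}

#' Assign a projected individual to its closest reference region
#'
#' Computes the eigenvalue-weighted distance from the query to every
#' reference individual, averages within each region (label), and declares
#' the region with the smallest mean distance the best match. Each other
#' region is then compared to the best one with a Welch two-sample
#' two-sided t-test on the per-individual distance sets, quantifying
#' whether the query is significantly closer to the best region.
#'
#' @param model A `pca_model`.
#' @param query_coords Coordinates from [project_sample()].
#' @param k Leading components used (default 10).
#' @param weight Passed to [weighted_distance()].
#' @return An `ancestry_assignment` list: `coords`, `best_region`,
#'   `regions` (tibble: `label`, `n`, `mean_distance`, `p_value` vs the best
#'   region, `NA` for the best itself), `distances` (per-individual tibble),
#'   `k`, `weight`.
#' @export
assign_region <- function(model, query_coords, k = 10,
                          weight = c("linear", "squared")) {
  weight <- match.arg(weight)
  d <- weighted_distance(query_coords, model$scores, model$eigenvalues,
                         k = k, weight = weight)
  dist_tbl <- tibble::tibble(sample_id = rownames(model$scores),
                             label = model$labels, distance = d)
  counts <- table(dist_tbl$label)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("region(s) with < 2 reference samples excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    dist_tbl <- dist_tbl[!dist_tbl$label %in% small, ]
  }
  if (nrow(dist_tbl) == 0) stop("no region with >= 2 reference samples",
                                call. = FALSE)
  by_region <- dplyr::summarise(
    dplyr::group_by(dist_tbl, .data$label),
    n = dplyr::n(), mean_distance = mean(.data$distance), .groups = "drop"
  )
  best <- by_region$label[which.min(by_region$mean_distance)]
  best_d <- dist_tbl$distance[dist_tbl$label == best]
  by_region$p_value <- vapply(by_region$label, function(lab) {
    if (lab == best) return(NA_real_)
    stats::t.test(best_d, dist_tbl$distance[dist_tbl$label == lab],
                  alternative = "two.sided", var.equal = FALSE)$p.value
  }, numeric(1))
  structure(
    list(coords = query_coords, best_region = best,
         regions = dplyr::arrange(by_region, .data$mean_distance),
         distances = dist_tbl, k = k, weight = weight),
    class = "ancestry_assignment"
  )
}

#' @export
print.ancestry_assignment <- function(x, ...) {
  cat("<ancestry_assignment> best region: ", x$best_region,
      " (eigenvalue-weighted, k = ", x$k, ")\n", sep = "")
  print(x$regions, n = Inf)
  invisible(x)
}
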