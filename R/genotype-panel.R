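#' Construct a genotype panel
#'
#' A genotype panel couples a samples-by-SNPs matrix of diploid genotype
#' codes (0/1/2 alternate-allele counts, `NA` for missing) with a SNP table
#' carrying physical and genetic-map coordinates and a sample table carrying
#' population/region labels. It is the common currency of the package: the
#' ROH scanner, the PCA projection and the f4 statistics all consume it.
#'
#' @param genotypes Integer matrix, samples in rows and SNPs in columns.
#'   Allowed values are 0, 1, 2 and `NA` (missing). Row names, when present,
#'   must agree with `samples$sample_id`.
#' @param snps Data frame with one row per SNP (in column order of
#'   `genotypes`) and columns `chromosome` (integer autosome 1-22),
#'   `position_bp` (1-based physical coordinate), `position_cm` (genetic-map
#'   coordinate in centimorgans), `ref` and `alt` (allele symbols). An
#'   optional `snp_id` column is kept; one is generated otherwise.
#' @param samples Data frame with columns `sample_id` and `label`
#'   (population or region of origin), one row per genotype row.
#'
#' @details
#' Validation enforces the panel invariants: SNPs strictly ordered by
#' (chromosome, position_bp); `position_cm` non-decreasing within each
#' chromosome; genotype codes drawn from \{0, 1, 2, NA\}; exactly one label
#' per sample. Violations are errors, not warnings, because every
#' downstream scan assumes them.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `snps` (tibble), `samples` (tibble).
#' @seealso [read_eigenstrat()], [read_vcf_panel()], [simulate_panel()]
#' @export
genotype_panel <- function(genotypes, snps, samples) {
  if (!is.matrix(genotypes)) {
    genotypes <- as.matrix(genotypes)
  }
  storage.mode(genotypes) <- "integer"
  snps <- tibble::as_tibble(snps)
  samples <- tibble::as_tibble(samples)

  required <- c("chromosome", "position_bp", "position_cm", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("snp table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("sample_id", "label") %in% names(samples))) {
    stop("sample table needs columns 'sample_id' and 'label'", call. = FALSE)
  }
  if (nrow(samples) != nrow(genotypes)) {
    stop("sample table has ", nrow(samples), " rows but genotype matrix has ",
         nrow(genotypes), call. = FALSE)
  }
  if (nrow(snps) != ncol(genotypes)) {
    stop("snp table has ", nrow(snps), " rows but genotype matrix has ",
         ncol(genotypes), " columns", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (!"snp_id" %in% names(snps)) {
    snps$snp_id <- paste0("snp", seq_len(nrow(snps)))
  }

  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad)) {
    stop("genotype codes outside {0, 1, 2, NA} at ", sum(bad), " cell(s)",
         call. = FALSE)
  }
  validate_snp_order(snps)

  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- snps$snp_id
  structure(
    list(genotypes = genotypes, snps = snps, samples = samples),
    class = "genotype_panel"
  )
}

validate_snp_order <- function(snps) {
  if (nrow(snps) < 2) return(invisible(snps))
  key <- order(snps$chromosome, snps$position_bp)
  if (!identical(key, seq_len(nrow(snps)))) {
    stop("SNPs not ordered by (chromosome, position_bp)", call. = FALSE)
  }
  same_chr <- diff(snps$chromosome) == 0
  if (any(same_chr & diff(snps$position_bp) <= 0)) {
    stop("SNP physical positions not strictly increasing within a chromosome",
         call. = FALSE)
  }
  if (any(same_chr & diff(snps$position_cm) < 0)) {
    stop("genetic-map positions decrease within a chromosome", call. = FALSE)
  }
  invisible(snps)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$snps$chromosome), collapse = " "),
      "\n", sep = "")
  n_mis <- sum(is.na(x$genotypes))
  cat("  missing calls: ", n_mis, " (",
      sprintf("%.2f%%", 100 * n_mis / length(x$genotypes)), ")\n", sep = "")
  labs <- table(x$samples$label)
  cat("  labels: ",
      paste(names(labs), labs, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Alternate-allele frequencies of a panel
#'
#' Observed alternate-allele frequency per SNP, computed from non-missing
#' genotypes. Samples can be restricted to a subset of labels (for
#' population-specific frequencies, as in the f4 statistics).
#'
#' @param panel A [genotype_panel()].
#' @param labels Optional character vector of sample labels to restrict to.
#' @return Numeric vector, one frequency per SNP; `NaN` where every retained
#'   genotype is missing.
#' @export
allele_frequencies <- function(panel, labels = NULL) {
  g <- panel$genotypes
  if (!is.null(labels)) {
    keep <- panel$samples$label %in% labels
    if (!any(keep)) {
      stop("no samples carry label(s): ", paste(labels, collapse = ", "),
           call. = FALSE)
    }
    g <- g[keep, , drop = FALSE]
  }
  colMeans(g, na.rm = TRUE) / 2
}

#' Extract one sample's genotype calls
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Sample identifier present in the panel.
#' @return Integer vector of genotype codes aligned to `panel$snps`.
#' @export
panel_sample <- function(panel, sample_id) {
  i <- match(sample_id, panel$samples$sample_id)
  if (is.na(i)) {
    stop("sample '", sample_id, "' not in panel", call. = FALSE)
  }
  panel$genotypes[i, ]
}

#' Subset a panel by SNP index
#'
#' @param panel A [genotype_panel()].
#' @param keep Logical or integer index over SNPs.
#' @return A new `genotype_panel` with the retained SNPs, order preserved.
#' @export
panel_subset_snps <- function(panel, keep) {
  genotype_panel(
    panel$genotypes[, keep, drop = FALSE],
    panel$snps[keep, , drop = FALSE],
    panel$samples
  )
}
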