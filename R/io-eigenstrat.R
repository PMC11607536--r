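#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' Reads the plain-text EIGENSTRAT representation of a genotype panel: a
#' `.geno` file with one row of 0/1/2/9 characters per SNP (columns are
#' samples), a six-column `.snp` file (snp id, chromosome, genetic position,
#' physical position, ref, alt) and a three-column `.ind` file
#' (sample id, sex, label).
#'
#' @param prefix Path prefix; `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#'   must exist. Alternatively pass the three paths explicitly.
#' @param geno,snp,ind Explicit file paths, overriding `prefix`.
#' @param genetic_unit Unit of the `.snp` genetic-position column:
#'   `"morgans"` (the format's convention, default) or `"cM"`. Positions are
#'   converted to centimorgans internally.
#' @return A [genotype_panel()]. Genotype code 9 maps to `NA`. Contigs other
#'   than autosomes 1-22 are dropped with a warning.
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL,
                            genetic_unit = c("morgans", "cM")) {
  genetic_unit <- match.arg(genetic_unit)
  if (!is.null(prefix)) {
    geno <- geno %||% paste0(prefix, ".geno")
    snp <- snp %||% paste0(prefix, ".snp")
    ind <- ind %||% paste0(prefix, ".ind")
  }
  for (f in c(geno, snp, ind)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }

  ind_tab <- utils::read.table(ind, header = FALSE,
                               col.names = c("sample_id", "sex", "label"),
                               colClasses = "character")
  snp_tab <- utils::read.table(
    snp, header = FALSE,
    col.names = c("snp_id", "chromosome", "gpos", "position_bp", "ref", "alt"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character")
  )
  cm <- if (genetic_unit == "morgans") snp_tab$gpos * 100 else snp_tab$gpos

  lines <- readLines(geno)
  if (length(lines) != nrow(snp_tab)) {
    stop("geno file has ", length(lines), " rows but snp file lists ",
         nrow(snp_tab), " SNPs", call. = FALSE)
  }
  widths <- nchar(lines)
  bad <- which(widths != nrow(ind_tab))
  if (length(bad) > 0) {
    stop("geno row ", bad[1], " has ", widths[bad[1]], " characters, expected ",
         nrow(ind_tab), " (one per sample)", call. = FALSE)
  }
  # one row per SNP, one character per sample
  codes <- matrix(
    match(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
          c("0", "1", "2", "9")),
    nrow = nrow(ind_tab), ncol = length(lines)
  )
  if (anyNA(codes)) {
    stop("geno file contains characters outside 0/1/2/9", call. = FALSE)
  }
  g <- codes - 1L
  g[g == 3L] <- NA_integer_

  chrom <- suppressWarnings(as.integer(snp_tab$chromosome))
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  if (!all(keep)) {
    warning(sum(!keep), " SNP(s) on non-autosomal contigs dropped",
            call. = FALSE)
  }
  snps <- tibble::tibble(
    snp_id = snp_tab$snp_id[keep],
    chromosome = chrom[keep],
    position_bp = snp_tab$position_bp[keep],
    position_cm = cm[keep],
    ref = snp_tab$ref[keep],
    alt = snp_tab$alt[keep]
  )
  genotype_panel(
    g[, keep, drop = FALSE],
    snps,
    tibble::tibble(sample_id = ind_tab$sample_id, label = ind_tab$label)
  )
}

#' Write a genotype panel as an EIGENSTRAT triplet
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path prefix for `.geno`, `.snp`, `.ind`.
#' @param genetic_unit Unit to write genetic positions in (default morgans,
#'   the format's convention).
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(panel, prefix,
                             genetic_unit = c("morgans", "cM")) {
  genetic_unit <- match.arg(genetic_unit)
  g <- t(panel$genotypes)          # SNP rows, sample columns
  g[is.na(g)] <- 9L
  writeLines(apply(g, 1, paste0, collapse = ""), paste0(prefix, ".geno"))

  gpos <- if (genetic_unit == "morgans") {
    panel$snps$position_cm / 100
  } else {
    panel$snps$position_cm
  }
  utils::write.table(
    data.frame(panel$snps$snp_id, panel$snps$chromosome,
               format(gpos, scientific = FALSE, trim = TRUE, digits = 12),
               panel$snps$position_bp, panel$snps$ref, panel$snps$alt),
    paste0(prefix, ".snp"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  utils::write.table(
    data.frame(panel$samples$sample_id, "U", panel$samples$label),
    paste0(prefix, ".ind"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
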