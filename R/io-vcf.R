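#' Read a bi-allelic SNP VCF into a genotype panel
#'
#' Wraps [vcfR::read.vcfR()] and converts GT fields to 0/1/2 alternate-allele
#' counts. Only bi-allelic SNP records on autosomes 1-22 enter the panel.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param labels Optional named character vector mapping sample id to a
#'   population/region label; unmapped samples get label `"unknown"`.
#' @param multiallelic `"error"` (default) aborts on the first record with
#'   more than one ALT allele, naming it; `"skip"` drops such records with a
#'   warning.
#' @param cm_per_mb Genetic-map rate used to fill `position_cm` when the VCF
#'   carries no map (VCFs rarely do); default 1 cM/Mb.
#' @return A [genotype_panel()]; `./.` genotypes map to `NA`.
#' @export
read_vcf_panel <- function(path, labels = NULL,
                           multiallelic = c("error", "skip"),
                           cm_per_mb = 1) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    first <- which(multi)[1]
    msg <- paste0("multi-allelic record at ", fix$CHROM[first], ":",
                  fix$POS[first],
                  if (!is.na(fix$ID[first]) && fix$ID[first] != ".")
                    paste0(" (", fix$ID[first], ")") else "")
    if (multiallelic == "error") stop(msg, call. = FALSE)
    warning(sum(multi), " multi-allelic record(s) skipped; first: ", msg,
            call. = FALSE)
  }
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  chrom <- suppressWarnings(as.integer(sub("^chr", "", fix$CHROM)))
  autosomal <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  keep <- !multi & is_snp & autosomal
  if (any(!autosomal & !multi & is_snp)) {
    warning(sum(!autosomal & !multi & is_snp),
            " SNP(s) on non-autosomal contigs dropped", call. = FALSE)
  }
  if (!any(keep)) stop("no bi-allelic autosomal SNPs in ", path, call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  count_alt <- function(x) {
    x <- sub(":.*", "", x)
    out <- rep(NA_integer_, length(x))
    alleles <- strsplit(x, "[/|]")
    known <- vapply(alleles, function(a)
      length(a) == 2 && all(a %in% c("0", "1")), logical(1))
    out[known] <- vapply(alleles[known],
                         function(a) sum(a == "1"), integer(1))
    out
  }
  g <- apply(gt, 2, count_alt)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)  # single-SNP edge case

  pos <- as.integer(fix$POS[keep])
  snps <- tibble::tibble(
    snp_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                    paste0(fix$CHROM[keep], "_", pos), fix$ID[keep]),
    chromosome = chrom[keep],
    position_bp = pos,
    position_cm = pos / 1e6 * cm_per_mb,
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  ids <- colnames(gt)
  lab <- if (is.null(labels)) rep("unknown", length(ids)) else {
    out <- unname(labels[ids])
    out[is.na(out)] <- "unknown"
    out
  }
  ord <- order(snps$chromosome, snps$position_bp)
  genotype_panel(t(g)[, ord, drop = FALSE], snps[ord, ],
                 tibble::tibble(sample_id = ids, label = lab))
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT-only genotype fields, suitable
#' for round-tripping through [read_vcf_panel()]. Unphased diploid codes:
#' 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=adnaprofile",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  ), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(panel$snps))) {
    g <- panel$genotypes[, j]
    gt <- ifelse(is.na(g), "./.", code[as.character(g)])
    writeLines(paste(c(panel$snps$chromosome[j], panel$snps$position_bp[j],
                       panel$snps$snp_id[j], panel$snps$ref[j],
                       panel$snps$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
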