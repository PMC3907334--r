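#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 file with phased `GT` fields (`0|1` style), one
#' column per sample, suitable for any standard VCF reader.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_haplotype_vcf()]
#' @export
write_haplotype_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  n_samples <- length(panel$samples)
  H <- panel$haplotypes
  gt <- matrix("", nrow(v), n_samples)
  for (s in seq_len(n_samples)) {
    gt[, s] <- paste0(H[2L * s - 1L, ], "|", H[2L * s, ])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF with phased `GT` fields via \pkg{vcfR}.  Unphased genotypes
#' (`/` separator) are rejected: r-squared here is computed by direct
#' haplotype counting, which requires phase.  Monomorphic or multi-allelic
#' sites are skipped with a warning.
#'
#' @param path VCF file path.
#' @param population Population label to attach.
#' @return A [haplotype_panel()].
#' @export
read_haplotype_vcf <- function(path, population = "POP") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt[, -1L, drop = FALSE]  # drop FORMAT column
  samples <- colnames(gt)
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!keep)) {
    warning(sum(!keep), " multi-allelic site(s) skipped")
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
  }
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop_bad_arg("unphased genotypes found; phased GT ('|') required")
  }
  # strip any trailing FORMAT subfields, keep the GT token
  gt_tok <- sub(":.*$", "", gt)
  n_var <- nrow(fix)
  H <- matrix(0L, 2L * length(samples), n_var)
  for (s in seq_along(samples)) {
    parts <- strsplit(gt_tok[, s], "|", fixed = TRUE)
    H[2L * s - 1L, ] <- as.integer(vapply(parts, `[`, character(1), 1L))
    H[2L * s, ] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  mono <- colSums(H) == 0L | colSums(H) == nrow(H)
  if (any(mono)) {
    warning(sum(mono), " monomorphic site(s) skipped")
    H <- H[, !mono, drop = FALSE]
    fix <- fix[!mono, , drop = FALSE]
  }
  variants <- data.frame(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  haplotype_panel(H, variants, samples, population)
}
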