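#' Describe a synthetic genome
#'
#' A minimal genome description used by all synthetic-data generators:
#' chromosome names, their lengths in base pairs, and a default random seed.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer vector of chromosome lengths (bp), parallel
#'   to `chrom_names`; all must be positive.
#' @param seed Default integer seed for generators run against this genome.
#'
#' @return An object of class `genome_spec`: a list with elements
#'   `chrom_names`, `chrom_lengths` (named) and `seed`.
#' @examples
#' gs <- genome_spec(c("chr1", "chr2"), c(5e6, 3e6), seed = 1)
#' @export
genome_spec <- function(chrom_names, chrom_lengths, seed = 1L) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names)) {
    stop_bad_arg("chromosome names must be unique")
  }
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_lengths) != length(chrom_names)) {
    stop_bad_arg("chrom_names and chrom_lengths must have equal length")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop_bad_arg("all chromosome lengths must be positive")
  }
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = setNames(chrom_lengths, chrom_names),
      seed = as.integer(seed)
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", length(x$chrom_names), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}
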