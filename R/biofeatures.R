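#' Generate synthetic chromatin biofeature tracks
#'
#' Emulates interval tracks from chromatin assays (DNase I hypersensitivity,
#' histone-mark and transcription-factor ChIP-seq peaks).  Per track and
#' chromosome the number of features is Poisson with mean
#' `density * length / 1e6`; starts are uniform, widths uniform in
#' `width_range`, and intervals are clipped to chromosome bounds.
#'
#' @param spec A [genome_spec()].
#' @param track_names Character vector of track names (e.g. `"H3K27Ac"`).
#' @param density Features per megabase (> 0 unless exactly 0, which yields
#'   empty tracks).
#' @param width_range Length-2 interval of feature widths in bp.
#' @param seed Integer seed.
#'
#' @return A named list of [GenomicRanges::GRanges] (0-based half-open on
#'   disk as BED; 1-based closed in memory, the Bioconductor convention).
#' @export
generate_biofeature_tracks <- function(spec, track_names, density,
                                       width_range = c(200, 2000), seed) {
  stopifnot(inherits(spec, "genome_spec"))
  if (density < 0) stop_bad_arg("density must be >= 0")
  with_seed(seed, {
    tracks <- lapply(track_names, function(nm) {
      gr_list <- lapply(seq_along(spec$chrom_names), function(ci) {
        chrom <- spec$chrom_names[ci]
        L <- spec$chrom_lengths[[ci]]
        n <- rpois(1L, density * L / 1e6)
        if (n == 0L) {
          return(GenomicRanges::GRanges(seqnames = character(0),
                                        ranges = IRanges::IRanges()))
        }
        start0 <- sort(floor(runif(n, 0, L - 1)))
        width <- round(runif(n, width_range[1], width_range[2]))
        end0 <- pmin(start0 + width, L)
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1,
                                                       end = end0))
      })
      gr <- suppressWarnings(do.call(c, gr_list))
      GenomicRanges::reduce(gr)
    })
    names(tracks) <- track_names
    tracks
  })
}

#' Write a track as BED
#'
#' Writes BED6 (name/score/strand filled with placeholders when absent).
#' Coordinates are converted to BED's 0-based half-open convention.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name Feature name stem (recycled with an index).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name = "feature") {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = sprintf("%s_%d", name, seq_along(gr)),
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", ".", s)
    },
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' Reads via \pkg{rtracklayer}, returning 1-based closed `GRanges`; the
#' score column (column 5), when present, is preserved.
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
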