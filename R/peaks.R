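#' Read a peak list from BED
#'
#' Expects BED with the tag-density (peak height) in column 5.
#'
#' @param path BED file path.
#' @return `GRanges` with a numeric `height` metadata column.
#' @export
read_peaks <- function(path) {
  gr <- read_bed(path)
  if (is.null(gr$score)) stop_bad_arg("peak BED needs a score column (height)")
  gr$height <- as.numeric(gr$score)
  gr
}

#' Rank peaks by height and cut the list
#'
#' `mode = "top_n"` keeps the `n` highest peaks (height ties broken by
#' genomic order).  `mode = "knee"` finds the inflection point of the
#' log-height versus rank curve — the rank with maximal perpendicular
#' distance to the chord joining the curve's endpoints — and keeps all
#' peaks above it; this captures the point where tag counts rise
#' geometrically over background without fixing an absolute cutoff.
#'
#' @param peaks `GRanges` with a `height` column (or a data frame with
#'   `chrom`, `start`, `end`, `height`).
#' @param mode `"top_n"` or `"knee"`.
#' @param n Number of peaks to keep in `top_n` mode.
#' @return The retained subset, in genomic order.
#' @export
rank_and_cut <- function(peaks, mode = c("top_n", "knee"), n = NULL) {
  mode <- match.arg(mode)
  gr <- .as_peak_granges(peaks)
  h <- gr$height
  if (mode == "top_n") {
    if (is.null(n)) stop_bad_arg("top_n mode needs n")
    if (n > length(gr)) {
      stop_bad_arg("n (", n, ") exceeds peak count (", length(gr), ")")
    }
    # genomic position as the tie-breaker: stable sort on (-height)
    ord <- order(-h)
    keep <- sort(ord[seq_len(n)])
    return(gr[keep])
  }
  if (length(unique(h)) < 2L) {
    stop_bad_arg("knee undefined: all peak heights equal; ",
                 "use mode = 'top_n' with an explicit n")
  }
  ord <- order(-h)
  y <- log(h[ord])
  x <- seq_along(y)
  # perpendicular distance from each point to the chord between endpoints
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  dist <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  # the elbow point itself is the first background-like rank: cut above it
  knee <- max(which.max(dist) - 1L, 1L)
  gr[sort(ord[seq_len(knee)])]
}

.as_peak_granges <- function(peaks) {
  if (methods::is(peaks, "GRanges")) {
    if (is.null(peaks$height)) stop_bad_arg("peaks need a height column")
    return(peaks)
  }
  if (any(peaks$end <= peaks$start)) stop_bad_arg("peak end must exceed start")
  GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end),
    height = peaks$height
  )
}

#' Overlap between two peak sets
#'
#' The overlap fraction of `a` in `b` is the share of `a` peaks that
#' intersect at least one `b` peak by at least 1 bp; both directions are
#' reported.  A reciprocal mode additionally requires the intersection to
#' cover at least `reciprocal` of each peak's width.
#'
#' @param a,b Peak `GRanges` (or data frames, as in [rank_and_cut()]).
#' @param reciprocal Optional fraction in (0, 1\]; if set, a pair only
#'   counts when the intersection covers at least this fraction of both
#'   peaks.
#' @return List with `fraction_a_in_b`, `fraction_b_in_a`, and `pairs`, a
#'   data frame of matched peak indices.
#' @export
peak_set_overlap <- function(a, b, reciprocal = NULL) {
  a <- .as_peak_granges(a)
  b <- .as_peak_granges(b)
  if (!length(a)) stop_bad_arg("peak set `a` is empty")
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L)
  if (!is.null(reciprocal)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(a[qi], b[si]))
    keep <- ov >= reciprocal * GenomicRanges::width(a[qi]) &
      ov >= reciprocal * GenomicRanges::width(b[si])
    hits <- hits[keep]
  }
  pairs <- data.frame(a = S4Vectors::queryHits(hits),
                      b = S4Vectors::subjectHits(hits))
  list(
    fraction_a_in_b = length(unique(pairs$a)) / length(a),
    fraction_b_in_a = if (length(b)) length(unique(pairs$b)) / length(b) else NA_real_,
    pairs = pairs
  )
}

#' Motif density as a function of distance from peak center
#'
#' For each peak, scans the `+/- flank` bp around the peak center in
#' `bin`-bp bins and counts motif placements (either strand) whose match
#' score reaches `score_min`; a placement is assigned to the bin holding
#' its center.  The profile is the per-bin mean count over peaks.  Flat
#' profiles on random sequence and center-peaked profiles for motifs
#' enriched at binding summits are the expected signatures.
#'
#' @param peaks Peak `GRanges`.
#' @param x A [pwm()].
#' @param genome Named `DNAStringSet` (or plain named character vector of
#'   chromosome sequences).
#' @param flank Half-width of the profiled region (bp); must be a
#'   multiple of `bin`.
#' @param bin Bin width (bp).
#' @param score_min Match-score threshold for counting a hit.
#' @return Data frame with `bin_center` (bp from peak center, negative =
#'   upstream) and `mean_count`.
#' @export
motif_center_profile <- function(peaks, x, genome, flank = 500L, bin = 50L,
                                 score_min = 0.8) {
  peaks <- .as_peak_granges(peaks)
  if (!length(peaks)) stop_bad_arg("no peaks to profile")
  if (flank %% bin != 0L) stop_bad_arg("flank must be a multiple of bin")
  seqs <- .chrom_sequences(genome)
  L <- pwm_length(x)
  S <- .pwm_score_matrix(x)
  comp <- c(4L, 3L, 2L, 1L)
  n_bins <- 2L * flank / bin
  bin_edges <- seq(-flank, flank, by = bin)
  counts <- matrix(0, length(peaks), n_bins)
  centers <- floor((GenomicRanges::start(peaks) +
                      GenomicRanges::end(peaks)) / 2)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  for (i in seq_along(peaks)) {
    chrom_seq <- seqs[[chroms[i]]]
    lo <- centers[i] - flank - floor(L / 2)
    hi <- centers[i] + flank + floor(L / 2)
    if (lo < 1 || hi > nchar(chrom_seq)) next
    code <- .encode_seq(substr(chrom_seq, lo, hi), n_policy = "zero")
    n_off <- length(code) - L + 1L
    for (o in seq_len(n_off)) {
      sub <- code[o:(o + L - 1L)]
      if (anyNA(sub)) next
      s <- max(.motif_score_fast(S, sub), .motif_score_fast(S, rev(comp[sub])))
      if (s >= score_min) {
        hit_center <- lo + o - 1L + floor((L - 1L) / 2) - centers[i]
        b <- findInterval(hit_center, bin_edges,
                          rightmost.closed = TRUE, left.open = TRUE)
        if (b >= 1L && b <= n_bins) counts[i, b] <- counts[i, b] + 1
      }
    }
  }
  data.frame(
    bin_center = bin_edges[-length(bin_edges)] + bin / 2,
    mean_count = colMeans(counts)
  )
}

.chrom_sequences <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop_bad_arg("genome must be a named DNAStringSet or named character vector")
}

#' Random genome sequence for a genome spec
#'
#' Uniform i.i.d. bases per chromosome; a convenience substrate for motif
#' profiling on synthetic data.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return A named `DNAStringSet`.
#' @export
random_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    seqs <- vapply(spec$chrom_lengths, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, spec$chrom_names))
  })
}
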