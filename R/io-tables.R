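#' Write / read a luciferase plate table
#'
#' Plain CSV with columns `enhancer`, `allele`, `dht`, `prep`,
#' `transfection`, `batch`, `replicate`, `luminescence`.
#'
#' @param observations Plate data frame.
#' @param path File path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_plate_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a ground-truth table as TSV
#'
#' @param truth Data frame (e.g. planted proxy pairs or disruptions).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write posterior draws in long format
#'
#' CSV with columns `chain`, `iteration`, `parameter`, `value`.
#'
#' @param posterior A `luciferase_posterior`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path) {
  long <- do.call(rbind, lapply(seq_along(posterior$draws), function(ch) {
    m <- posterior$draws[[ch]]
    data.frame(
      chain = ch,
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
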