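#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes r-squared between two variants by direct haplotype counting:
#' with haplotype frequencies `p_AB` etc., `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`.  Requires phased data; both
#' variants must be polymorphic in the panel.
#'
#' @param panel A [haplotype_panel()].
#' @param a,b Variant ids (or column indices) in the panel.
#' @return r-squared in \[0, 1\].
#' @examples
#' gs <- genome_spec("chr1", 1e6)
#' p <- simulate_haplotype_panel(gs, 50, 10, 1e5, 0.9, seed = 1)
#' pairwise_r2(p, "snp0001", "snp0002")
#' @export
pairwise_r2 <- function(panel, a, b) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$haplotypes
  x <- H[, a]
  y <- H[, b]
  .r2_from_haplotypes(x, y)
}

.r2_from_haplotypes <- function(x, y) {
  n <- length(x)
  pA <- sum(x) / n
  pB <- sum(y) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop_bad_arg("LD undefined for a monomorphic variant")
  }
  pAB <- sum(x == 1L & y == 1L) / n
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Find SNPs correlated with a GWAS index SNP
#'
#' For each population in which the index SNP was reported, scans all
#' panel variants within a window centered on the index (default 1 Mb
#' total, i.e. index +/- 500 kb) and retains those with r-squared at or
#' above `r2_min` in at least one reporting population.  The index SNP
#' itself is always included.  Monomorphic sites are skipped with a
#' warning rather than aborting the scan.
#'
#' @param panels Named list of [haplotype_panel()], keyed by population.
#' @param index_id Variant id of the index SNP.
#' @param populations Populations in which the index was reported
#'   (default: all panels).
#' @param window Total window size in bp centered on the index (default
#'   1e6, read as +/- window/2).
#' @param r2_min r-squared cutoff (default 0.5).
#'
#' @return Data frame of correlated SNPs: `index_id`, `id`, `chrom`,
#'   `pos`, `ref`, `alt`, one `r2_<population>` column per population, and
#'   `is_index`.
#' @export
find_correlated_snps <- function(panels, index_id,
                                 populations = names(panels),
                                 window = 1e6, r2_min = 0.5) {
  if (is.null(names(panels)) || !all(populations %in% names(panels))) {
    stop_bad_arg("panels must be named by population and cover `populations`")
  }
  for (pop in populations) {
    if (!index_id %in% panels[[pop]]$variants$id) {
      stop_bad_arg("index SNP ", index_id, " absent from panel ", pop)
    }
  }
  ref_pop <- populations[1]
  v <- panels[[ref_pop]]$variants
  idx_row <- v[v$id == index_id, ]
  half <- window / 2
  in_window <- v$chrom == idx_row$chrom &
    abs(v$pos - idx_row$pos) <= half
  cand <- v[in_window, , drop = FALSE]

  r2 <- matrix(NA_real_, nrow(cand), length(populations),
               dimnames = list(cand$id, populations))
  for (pop in populations) {
    panel <- panels[[pop]]
    for (id in cand$id) {
      if (!id %in% panel$variants$id) next
      r2[id, pop] <- tryCatch(
        pairwise_r2(panel, index_id, id),
        error = function(e) {
          warning("skipping ", id, " in ", pop, ": ", conditionMessage(e))
          NA_real_
        }
      )
    }
  }
  keep <- apply(r2, 1L, function(z) any(!is.na(z) & z >= r2_min)) |
    cand$id == index_id
  out <- cand[keep, , drop = FALSE]
  out <- cbind(index_id = index_id, out,
               setNames(as.data.frame(r2[keep, , drop = FALSE]),
                        paste0("r2_", populations)))
  out$is_index <- out$id == index_id
  rownames(out) <- NULL
  # output invariant to variant-file ordering: sort by position then id
  out[order(out$pos, out$id), , drop = FALSE]
}

#' Tier correlated SNPs by cross-population support
#'
#' Flags each correlated SNP by whether its LD with the index holds in
#' every listed population: tier `"shared"` requires r-squared >= `r2_min`
#' in all of them, `"shared_high"` requires r-squared >= `r2_high` in all
#' of them, and everything else is `"single"`.  An empty shared tier is a
#' valid outcome.
#'
#' @param corr Output of [find_correlated_snps()].
#' @param populations Populations that must all support the proxy.
#' @param r2_min Threshold for the `shared` tier (default 0.5).
#' @param r2_high Threshold for the `shared_high` tier (default 0.8).
#' @return `corr` with an added `tier` factor
#'   (`single < shared < shared_high`).
#' @export
intersect_populations <- function(corr, populations, r2_min = 0.5,
                                  r2_high = 0.8) {
  cols <- paste0("r2_", populations)
  missing_cols <- setdiff(cols, names(corr))
  if (length(missing_cols)) {
    stop_bad_arg("no r2 columns for population(s): ",
                 paste(sub("^r2_", "", missing_cols), collapse = ", "))
  }
  r2 <- as.matrix(corr[, cols, drop = FALSE])
  all_min <- apply(r2, 1L, function(z) all(!is.na(z) & z >= r2_min))
  all_high <- apply(r2, 1L, function(z) all(!is.na(z) & z >= r2_high))
  corr$tier <- factor(
    ifelse(all_high, "shared_high", ifelse(all_min, "shared", "single")),
    levels = c("single", "shared", "shared_high"), ordered = TRUE
  )
  corr
}
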