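#' Phased haplotype panels
#'
#' A `haplotype_panel` holds phased alleles for one population: an integer
#' matrix of 0/1 allele codes with one row per haplotype (two per sample)
#' and one column per variant, plus a variant table.  Allele 0 is the
#' reference allele.  All linkage-disequilibrium computation in the package
#' runs on these panels by direct haplotype counting.
#'
#' @param haplotypes Integer matrix (2 * n_samples rows, n_variants columns)
#'   of 0/1 codes; column names are variant ids.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per column of `haplotypes`.
#' @param samples Character vector of sample names (half the row count).
#' @param population Population label (e.g. `"EUR"`).
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, variants, samples, population = "POP") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop_bad_arg("haplotype codes must be 0/1 (biallelic, phased)")
  }
  if (nrow(haplotypes) != 2L * length(samples)) {
    stop_bad_arg("need exactly two haplotypes per sample")
  }
  if (ncol(haplotypes) != nrow(variants)) {
    stop_bad_arg("one variant row per haplotype column required")
  }
  if (anyDuplicated(variants$id)) stop_bad_arg("variant ids must be unique")
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1)) stop_bad_arg("positions are 1-based, must be >= 1")
  if (any(variants$ref == variants$alt)) stop_bad_arg("ref and alt must differ")
  colnames(haplotypes) <- variants$id
  structure(
    list(
      haplotypes = haplotypes,
      variants = as.data.frame(variants, stringsAsFactors = FALSE),
      samples = as.character(samples),
      population = population
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> population ", x$population, ": ",
      length(x$samples), " samples (", nrow(x$haplotypes), " haplotypes) x ",
      ncol(x$haplotypes), " variants\n", sep = "")
  invisible(x)
}

# Draw one 0/1 template of length n with allele frequency p, redrawing until
# polymorphic (both alleles present).
.polymorphic_bernoulli <- function(n, p, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- rbinom(n, 1L, p)
    if (any(x == 1L) && any(x == 0L)) return(x)
  }
  stop_bad_arg("could not draw a polymorphic variant; maf too extreme for n")
}

.random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' Variants are laid out along the first chromosome of `spec` and grouped
#' into blocks of `block_len` bp.  Each block has a template haplotype with
#' allele frequency drawn uniformly from `maf_range`; every variant in the
#' block copies the template per haplotype, resampling a fresh allele with
#' probability `eps` chosen so that the expected pairwise r-squared between
#' two block-mates equals `within_block_r2` (each variant correlates with
#' the template at r = 1 - eps, so a pair achieves r^2 = (1 - eps)^4, giving
#' eps = 1 - within_block_r2^(1/4)).  Variants in different blocks are
#' independent.
#'
#' @param spec A [genome_spec()].
#' @param n_samples Number of diploid samples (>= 2); the panel carries
#'   twice as many haplotypes.
#' @param n_variants Number of variants.
#' @param block_len Block length in bp.
#' @param within_block_r2 Target expected pairwise r-squared within a block,
#'   in \[0, 1\].
#' @param maf_range Length-2 numeric interval inside (0, 0.5] from which the
#'   per-block allele frequency is drawn.
#' @param seed Integer seed; the generator touches no global random state.
#' @param population Population label stored on the panel.
#'
#' @return A [haplotype_panel()]; the block assignment is attached as the
#'   `block` attribute (integer per variant).
#' @examples
#' gs <- genome_spec("chr1", 1e6)
#' p <- simulate_haplotype_panel(gs, n_samples = 50, n_variants = 20,
#'                               block_len = 1e5, within_block_r2 = 0.8,
#'                               seed = 1)
#' @export
simulate_haplotype_panel <- function(spec, n_samples, n_variants, block_len,
                                     within_block_r2,
                                     maf_range = c(0.05, 0.5), seed,
                                     population = "POP") {
  stopifnot(inherits(spec, "genome_spec"))
  if (n_samples < 2) stop_bad_arg("n_samples must be >= 2")
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    stop_bad_arg("within_block_r2 must be in [0, 1]")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_bad_arg("maf_range must lie inside (0, 0.5]; a monomorphic request (maf 0) is degenerate")
  }
  chrom <- spec$chrom_names[1]
  L <- spec$chrom_lengths[[1]]
  pos <- round(seq_len(n_variants) * L / (n_variants + 1))
  pos <- pmax(1, pos)
  block <- as.integer(pos %/% block_len)
  eps <- 1 - within_block_r2^(1 / 4)
  n_hap <- 2L * n_samples

  with_seed(seed, {
    H <- matrix(0L, n_hap, n_variants)
    for (b in unique(block)) {
      idx <- which(block == b)
      p <- runif(1, maf_range[1], maf_range[2])
      template <- .polymorphic_bernoulli(n_hap, p)
      for (j in idx) {
        repeat {
          resample <- runif(n_hap) < eps
          col <- template
          col[resample] <- rbinom(sum(resample), 1L, p)
          if (any(col == 1L) && any(col == 0L)) break
        }
        H[, j] <- col
      }
    }
    al <- .random_alleles(n_variants)
    variants <- data.frame(
      id = sprintf("snp%04d", seq_len(n_variants)),
      chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
      stringsAsFactors = FALSE
    )
    panel <- haplotype_panel(H, variants,
                             samples = sprintf("S%03d", seq_len(n_samples)),
                             population = population)
    attr(panel, "block") <- block
    panel
  })
}

#' Simulate matched haplotype panels for two populations with planted proxies
#'
#' Emits two panels sharing one variant list, with `n_pairs` planted
#' index/proxy pairs.  Every pair is in high LD (target r-squared `pair_r2`)
#' in population A; a fraction `1 - ld_divergence` of the pairs is also in
#' high LD in population B, while the remaining pairs are simulated
#' independently there (r-squared ~ 0).  The remaining
#' `shared_variants - 2 * n_pairs` variants are unlinked filler.  The
#' returned truth table records, per pair, the target r-squared in each
#' population and whether the pair is a dual-population proxy.
#'
#' @param spec A [genome_spec()].
#' @param shared_variants Total variant count shared by the two panels.
#' @param ld_divergence Fraction in \[0, 1\] of planted pairs that are in
#'   high LD in population A only.
#' @param seed Integer seed.
#' @param n_samples Diploid samples per population.
#' @param n_pairs Number of planted index/proxy pairs (default one per ten
#'   shared variants).
#' @param pair_r2 Target r-squared for a planted high-LD pair.
#' @param maf_range Allele-frequency interval, as in
#'   [simulate_haplotype_panel()].
#'
#' @return A list with `panels` (named list `popA`, `popB` of
#'   [haplotype_panel()]s) and `truth`, a data frame with columns
#'   `index_id`, `proxy_id`, `r2_popA`, `r2_popB`, `dual`.
#' @export
simulate_two_population_panels <- function(spec, shared_variants,
                                           ld_divergence, seed,
                                           n_samples = 100,
                                           n_pairs = max(1L, shared_variants %/% 10L),
                                           pair_r2 = 0.9,
                                           maf_range = c(0.1, 0.5)) {
  stopifnot(inherits(spec, "genome_spec"))
  if (ld_divergence < 0 || ld_divergence > 1) {
    stop_bad_arg("ld_divergence must be in [0, 1]")
  }
  if (2L * n_pairs > shared_variants) {
    stop_bad_arg("need at least two shared variants per planted pair")
  }
  chrom <- spec$chrom_names[1]
  L <- spec$chrom_lengths[[1]]
  m <- shared_variants
  pos <- round(seq_len(m) * L / (m + 1))
  n_hap <- 2L * n_samples
  n_dual <- as.integer(round(n_pairs * (1 - ld_divergence)))
  eps_pair <- 1 - pair_r2^(1 / 4)

  # variant j belongs to pair k for j = 2k-1 (index) and j = 2k (proxy)
  pair_of <- rep(NA_integer_, m)
  pair_of[seq_len(2L * n_pairs)] <- rep(seq_len(n_pairs), each = 2L)

  sim_pop <- function(linked_pairs, population) {
    H <- matrix(0L, n_hap, m)
    for (k in seq_len(n_pairs)) {
      cols <- c(2L * k - 1L, 2L * k)
      p <- runif(1, maf_range[1], maf_range[2])
      if (k %in% linked_pairs) {
        template <- .polymorphic_bernoulli(n_hap, p)
        for (j in cols) {
          repeat {
            resample <- runif(n_hap) < eps_pair
            col <- template
            col[resample] <- rbinom(sum(resample), 1L, p)
            if (any(col == 1L) && any(col == 0L)) break
          }
          H[, j] <- col
        }
      } else {
        for (j in cols) H[, j] <- .polymorphic_bernoulli(n_hap, p)
      }
    }
    filler <- setdiff(seq_len(m), seq_len(2L * n_pairs))
    for (j in filler) {
      H[, j] <- .polymorphic_bernoulli(n_hap, runif(1, maf_range[1], maf_range[2]))
    }
    H
  }

  with_seed(seed, {
    al <- .random_alleles(m)
    variants <- data.frame(
      id = sprintf("snp%04d", seq_len(m)),
      chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
      stringsAsFactors = FALSE
    )
    samples <- sprintf("S%03d", seq_len(n_samples))
    HA <- sim_pop(seq_len(n_pairs), "popA")
    HB <- sim_pop(seq_len(n_dual), "popB")
    truth <- data.frame(
      index_id = variants$id[2L * seq_len(n_pairs) - 1L],
      proxy_id = variants$id[2L * seq_len(n_pairs)],
      r2_popA = pair_r2,
      r2_popB = ifelse(seq_len(n_pairs) <= n_dual, pair_r2, 0),
      dual = seq_len(n_pairs) <= n_dual,
      stringsAsFactors = FALSE
    )
    list(
      panels = list(
        popA = haplotype_panel(HA, variants, samples, "popA"),
        popB = haplotype_panel(HB, variants, samples, "popB")
      ),
      truth = truth
    )
  })
}
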