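# Shared fixtures and independent oracles used across test files.

# Build a panel directly from a haplotype matrix (columns = variants).
panel_from_matrix <- function(H, chrom = "chr1", population = "POP") {
  n_var <- ncol(H)
  variants <- data.frame(
    id = sprintf("v%03d", seq_len(n_var)),
    chrom = chrom,
    pos = seq_len(n_var) * 1000L,
    ref = rep("A", n_var),
    alt = rep("G", n_var),
    stringsAsFactors = FALSE
  )
  haplotype_panel(H, variants, samples = sprintf("S%d", seq_len(nrow(H) / 2)),
                  population = population)
}

# Independent r2 oracle: tabulate the four haplotype classes explicitly.
brute_force_r2 <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Expand haplotype-class counts (AB, Ab, aB, ab) into two allele columns.
haplotypes_from_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  x <- c(rep(1L, n_AB + n_Ab), rep(0L, n_aB + n_ab))
  y <- c(rep(1L, n_AB), rep(0L, n_Ab), rep(1L, n_aB), rep(0L, n_ab))
  cbind(x, y)
}

# A fixed-base column for hand-built PWMs.
fixed_col <- function(base) {
  col <- rep(0, 4)
  col[match(base, c("A", "C", "G", "T"))] <- 1
  col
}

# Reverse complement of a PWM: reverse columns, swap A<->T and C<->G rows.
revcomp_pwm <- function(p) {
  m <- p$mat[c(4, 3, 2, 1), rev(seq_len(ncol(p$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(paste0(p$name, "_rc"), m, pseudocount = p$pseudocount,
      weights = p$weights)
}

revcomp_seq <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# A deterministic high-information PWM with an exact-zero base at its top
# position (pseudocount off), for annihilation tests.
zero_base_pwm <- function(name = "zero", weights = "ic") {
  m <- cbind(fixed_col("A"), fixed_col("C"),
             c(0.6, 0.4, 0, 0), c(0.25, 0.25, 0.25, 0.25),
             fixed_col("G"), fixed_col("T"))
  pwm(name, m, pseudocount = 0, weights = weights)
}
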