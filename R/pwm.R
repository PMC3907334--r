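DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrices
#'
#' A `pwm` wraps a 4 x L base-frequency matrix (rows A, C, G, T; columns
#' sum to 1) together with a pseudocount setting and a positional-weight
#' scheme.  Motif-match scores are consensus-normalized so that the
#' consensus sequence scores exactly 1 and any zero-frequency base (with
#' pseudocounts disabled) annihilates the score to 0.
#'
#' @param name Motif name.
#' @param mat Numeric 4 x L matrix of base frequencies (or counts, which
#'   are normalized per column); rows in A, C, G, T order.
#' @param pseudocount Pseudocount added to each frequency before
#'   renormalization; `0` disables.  Default 0.001.
#' @param weights Positional-weight scheme: `"ic"` (information content,
#'   normalized so the most informative position has weight 1) or
#'   `"uniform"` (all weights 1).
#'
#' @return An object of class `pwm`.
#' @examples
#' m <- matrix(c(1, 0, 0, 0,  0, 0, 1, 0,  .25, .25, .25, .25,
#'               0, .5, 0, .5), 4, 4, dimnames = list(c("A","C","G","T")))
#' p <- pwm("toy", m)
#' consensus_sequence(p)
#' @export
pwm <- function(name, mat, pseudocount = 0.001, weights = c("ic", "uniform")) {
  weights <- match.arg(weights)
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop_bad_arg("pwm matrix must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 4L) stop_bad_arg("motif length must be >= 4")
  if (any(mat < 0)) stop_bad_arg("frequencies must be non-negative")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop_bad_arg("every column needs positive mass")
  mat <- sweep(mat, 2L, cs, "/")
  rownames(mat) <- DNA_BASES
  structure(
    list(name = name, mat = mat, pseudocount = pseudocount,
         weights = weights),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": length ", ncol(x$mat),
      ", pseudocount ", x$pseudocount,
      ", weights '", x$weights, "', consensus ",
      consensus_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Motif length
#' @param x A [pwm()].
#' @return Integer motif length.
#' @export
pwm_length <- function(x) ncol(x$mat)

# Frequencies after pseudocount and renormalization.
pwm_frequencies <- function(x) {
  f <- x$mat + x$pseudocount
  sweep(f, 2L, colSums(f), "/")
}

#' Per-position information content (bits)
#'
#' `IC_i = 2 + sum_b f_ib log2 f_ib`, computed on pseudocounted
#' frequencies; 0 bits for a uniform column, 2 bits for a fixed base.
#'
#' @param x A [pwm()].
#' @return Numeric vector of length `pwm_length(x)`.
#' @export
information_content <- function(x) {
  f <- pwm_frequencies(x)
  lf <- ifelse(f > 0, log2(f), 0)
  2 + colSums(f * lf)
}

#' Positional weights
#'
#' Weights encode the importance of each motif position.  Under the
#' `"ic"` scheme, `w_i = IC_i / max_j IC_j`, so the most informative
#' position gets weight 1 and uninformative positions contribute little to
#' the match score.  Under `"uniform"`, all weights are 1 and the score
#' reduces to the plain consensus-normalized product.
#'
#' @param x A [pwm()].
#' @return Non-negative numeric vector with maximum 1.
#' @export
positional_weights <- function(x) {
  if (x$weights == "uniform") return(rep(1, pwm_length(x)))
  ic <- information_content(x)
  if (max(ic) <= 0) {
    stop_bad_arg("all positions have zero information content; ",
                 "use weights = 'uniform' for flat matrices")
  }
  ic / max(ic)
}

#' Consensus sequence (argmax base per position, ties to the first base)
#' @param x A [pwm()].
#' @return Character scalar of length `pwm_length(x)`.
#' @export
consensus_sequence <- function(x) {
  paste(DNA_BASES[apply(x$mat, 2L, which.max)], collapse = "")
}

.encode_seq <- function(seq, n_policy = c("error", "zero")) {
  n_policy <- match.arg(n_policy)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(chars, DNA_BASES)
  if (anyNA(code) && n_policy == "error") {
    stop_bad_arg("sequence contains non-ACGT characters: ",
                 paste(unique(chars[is.na(code)]), collapse = ","))
  }
  code
}

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

#' Positionally weighted motif match score
#'
#' The match score of a length-L sequence against a PWM is the weighted
#' consensus-normalized product
#' \deqn{s = \prod_i \left( f_{i,b_i} / \max_b f_{i,b} \right)^{w_i}}
#' where `f` is the (pseudocounted) frequency matrix, `b_i` the observed
#' base at position i and `w_i` the positional weight.  The score lies in
#' \[0, 1\]: it is 1 iff the sequence takes a maximal-frequency base at
#' every position with positive weight, and 0 iff some base has exactly
#' zero frequency (possible only with pseudocounts disabled).
#'
#' @param x A [pwm()].
#' @param seq Character scalar over A/C/G/T, exactly `pwm_length(x)` long.
#' @param n_policy How to treat ambiguity codes: `"error"` (default) or
#'   `"zero"` (score 0).
#' @return Score in \[0, 1\].
#' @export
motif_score <- function(x, seq, n_policy = c("error", "zero")) {
  n_policy <- match.arg(n_policy)
  L <- pwm_length(x)
  code <- .encode_seq(seq, n_policy)
  if (length(code) != L) {
    stop_bad_arg("sequence length ", length(code), " != motif length ", L)
  }
  if (anyNA(code)) return(0)
  .motif_score_fast(.pwm_score_matrix(x), code)
}

# Precompute the per-base per-position score factors (f/colmax)^w once;
# scanning then reduces to indexed products.
.pwm_score_matrix <- function(x) {
  f <- pwm_frequencies(x)
  ratio <- sweep(f, 2L, apply(f, 2L, max), "/")
  w <- positional_weights(x)
  S <- t(t(ratio)^w)  # column i raised to w[i]
  # 0^0 = 1 in R: a zero-weight position never annihilates the score
  S
}

.motif_score_fast <- function(S, code) {
  prod(S[cbind(code, seq_along(code))])
}

#' Best motif hit in a window
#'
#' Scans every placement of the motif in `window_seq` on the requested
#' strands and returns the maximal match score.  Minus-strand placements
#' score the reverse complement of the covered bases; the reported offset
#' is always the 0-based start of the placement on the forward window.
#' Ties are broken by smallest offset, then by the + strand.
#'
#' @param x A [pwm()].
#' @param window_seq Character scalar, length >= `pwm_length(x)`.
#' @param strands Strands to scan (default both).
#' @param n_policy Ambiguity policy, see [motif_score()].
#' @return A `motif_hit`: list with `pwm`, `score`, `offset` (0-based),
#'   `strand`.
#' @export
scan_best_hit <- function(x, window_seq, strands = c("+", "-"),
                          n_policy = c("error", "zero")) {
  n_policy <- match.arg(n_policy)
  L <- pwm_length(x)
  code <- .encode_seq(window_seq, n_policy)
  nw <- length(code)
  if (nw < L) stop_bad_arg("window shorter than motif")
  S <- .pwm_score_matrix(x)
  offsets <- 0:(nw - L)
  best <- list(score = -1, offset = NA_integer_, strand = NA_character_)
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G in code space
  for (o in offsets) {
    sub <- code[(o + 1L):(o + L)]
    if (anyNA(sub)) {
      scores <- c("+" = 0, "-" = 0)
    } else {
      scores <- c("+" = .motif_score_fast(S, sub),
                  "-" = .motif_score_fast(S, rev(comp[sub])))
    }
    for (st in intersect(c("+", "-"), strands)) {
      if (scores[[st]] > best$score + 1e-15) {
        best <- list(score = scores[[st]], offset = o, strand = st)
      }
    }
  }
  structure(list(pwm = x$name, score = best$score, offset = best$offset,
                 strand = best$strand),
            class = "motif_hit")
}

#' Allele-aware response-element disruption call
#'
#' Scores both alleles of a variant against a PWM over every motif
#' placement covering the variant position, on both strands.  A variant
#' *matches* the motif if its stronger allele reaches `tau_match`; it
#' *disrupts* the response element if it matches and the allelic score
#' difference reaches `tau_delta`.  This separates functional candidates
#' (allele-dependent binding) from variants that merely fall inside a
#' likely binding site.
#'
#' @param x A [pwm()].
#' @param context_seq Sequence context around the variant; must cover at
#'   least `pwm_length(x) - 1` bases on each side of the variant for all
#'   covering placements to be scannable.
#' @param var_pos 1-based position of the variant within `context_seq`.
#' @param ref,alt Reference / alternate alleles (single bases);
#'   `context_seq` must carry `ref` at `var_pos`.
#' @param tau_match Match threshold on the stronger allele (default 0.8).
#' @param tau_delta Disruption threshold on |s_ref - s_alt| (default 0.2).
#' @param n_policy Ambiguity policy, see [motif_score()].
#' @return A `disruption_call`: list with `pwm`, `ref_hit`, `alt_hit`,
#'   `delta`, `is_match`, `is_disruption`, `stronger_allele`.
#' @export
score_allele_disruption <- function(x, context_seq, var_pos, ref, alt,
                                    tau_match = 0.8, tau_delta = 0.2,
                                    n_policy = c("error", "zero")) {
  n_policy <- match.arg(n_policy)
  L <- pwm_length(x)
  chars <- strsplit(toupper(context_seq), "", fixed = TRUE)[[1]]
  if (var_pos < 1 || var_pos > length(chars)) {
    stop_bad_arg("var_pos outside context")
  }
  if (chars[var_pos] != toupper(ref)) {
    stop_bad_arg("context carries '", chars[var_pos], "' at var_pos, not ref '",
                 ref, "'")
  }
  lo <- max(1L, var_pos - (L - 1L))
  hi <- min(length(chars), var_pos + (L - 1L))
  if (hi - lo + 1L < L) stop_bad_arg("context too short to cover the variant")
  sub_ref <- chars[lo:hi]
  sub_alt <- sub_ref
  sub_alt[var_pos - lo + 1L] <- toupper(alt)
  ref_hit <- scan_best_hit(x, paste(sub_ref, collapse = ""),
                           n_policy = n_policy)
  alt_hit <- scan_best_hit(x, paste(sub_alt, collapse = ""),
                           n_policy = n_policy)
  delta <- abs(ref_hit$score - alt_hit$score)
  is_match <- max(ref_hit$score, alt_hit$score) >= tau_match
  structure(
    list(pwm = x$name, ref_hit = ref_hit, alt_hit = alt_hit, delta = delta,
         is_match = is_match,
         is_disruption = is_match && delta >= tau_delta,
         stronger_allele = if (ref_hit$score >= alt_hit$score) "ref" else "alt"),
    class = "disruption_call"
  )
}
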