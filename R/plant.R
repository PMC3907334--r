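#' Plant allele-disrupting variants in motif contexts
#'
#' Builds a sequence context for every variant in a panel.  For
#' `n_planted` variants the context embeds a motif from the library so the
#' variant sits at the motif's maximal-weight (maximal information)
#' position: the *match* allele completes the consensus (score 1 by
#' construction) and the *disrupting* allele has frequency at most
#' `max_disrupt_freq` at that position, so its score collapses.  Remaining
#' variants receive random contexts.  The returned truth table records the
#' planted (variant, motif) pairs and alleles.
#'
#' @param panel A [haplotype_panel()].
#' @param pwms Named list of [pwm()] objects.
#' @param n_planted Number of variants to plant (cannot exceed the panel's
#'   variant count).
#' @param seed Integer seed.
#' @param max_disrupt_freq Maximal frequency of the disrupting allele at
#'   the planted position (default 0.05).
#'
#' @return A list with `contexts` (data frame: `id`, `context`, `var_pos`,
#'   `ref`, `alt`) and `truth` (data frame: `variant_id`, `pwm`,
#'   `match_allele`, `disrupt_allele`, `motif_pos`).
#' @export
plant_disruptions <- function(panel, pwms, n_planted, seed,
                              max_disrupt_freq = 0.05) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_var <- nrow(panel$variants)
  if (n_planted > n_var) {
    stop_bad_arg("n_planted (", n_planted, ") exceeds available variants (",
                 n_var, ")")
  }
  # motifs usable for planting: the max-weight position must have a base
  # rare enough to act as the disrupting allele
  usable <- Filter(function(p) {
    m <- which.max(positional_weights(p))
    min(p$mat[, m]) <= max_disrupt_freq
  }, pwms)
  if (n_planted > 0L && !length(usable)) {
    stop_bad_arg("no motif in the library has a plantable ",
                 "(near-zero frequency) base at its top position")
  }
  Lmax <- max(vapply(pwms, pwm_length, integer(1)))
  ctx_len <- 2L * Lmax - 1L
  center <- Lmax

  with_seed(seed, {
    planted_idx <- sample.int(n_var, n_planted)
    contexts <- data.frame(
      id = panel$variants$id,
      context = vapply(seq_len(n_var), function(i) {
        paste(sample(DNA_BASES, ctx_len, replace = TRUE), collapse = "")
      }, character(1)),
      var_pos = center,
      ref = NA_character_, alt = NA_character_,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(variant_id = character(0), pwm = character(0),
                        match_allele = character(0),
                        disrupt_allele = character(0),
                        motif_pos = integer(0), stringsAsFactors = FALSE)
    for (i in seq_len(n_var)) {
      if (i %in% planted_idx) {
        p <- usable[[sample.int(length(usable), 1L)]]
        L <- pwm_length(p)
        m <- which.max(positional_weights(p))
        cons <- strsplit(consensus_sequence(p), "", fixed = TRUE)[[1]]
        match_allele <- cons[m]
        disrupt_allele <- DNA_BASES[which.min(p$mat[, m])]
        chars <- strsplit(contexts$context[i], "", fixed = TRUE)[[1]]
        motif_start <- center - m + 1L
        chars[motif_start:(motif_start + L - 1L)] <- cons
        contexts$context[i] <- paste(chars, collapse = "")
        contexts$ref[i] <- match_allele
        contexts$alt[i] <- disrupt_allele
        truth <- rbind(truth, data.frame(
          variant_id = contexts$id[i], pwm = p$name,
          match_allele = match_allele, disrupt_allele = disrupt_allele,
          motif_pos = m, stringsAsFactors = FALSE
        ))
      } else {
        chars <- strsplit(contexts$context[i], "", fixed = TRUE)[[1]]
        contexts$ref[i] <- chars[center]
        contexts$alt[i] <- sample(setdiff(DNA_BASES, chars[center]), 1L)
      }
    }
    list(contexts = contexts, truth = truth)
  })
}
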