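#' Scan SNP contexts against a PWM library
#'
#' Applies [score_allele_disruption()] to every (SNP, motif) pair and
#' returns the long table of calls.
#'
#' @param contexts Data frame with `id`, `context`, `var_pos`, `ref`,
#'   `alt` (as emitted by [plant_disruptions()]).
#' @param pwms Named list of [pwm()] objects.
#' @param tau_match,tau_delta Disruption thresholds, see
#'   [score_allele_disruption()].
#' @param n_policy Ambiguity policy, see [motif_score()].
#' @return Data frame: `variant_id`, `pwm`, `s_ref`, `s_alt`, `delta`,
#'   `strand`, `offset`, `is_match`, `is_disruption`.
#' @export
evaluate_disruptions <- function(contexts, pwms, tau_match = 0.8,
                                 tau_delta = 0.2,
                                 n_policy = c("error", "zero")) {
  n_policy <- match.arg(n_policy)
  rows <- vector("list", nrow(contexts) * length(pwms))
  k <- 0L
  for (i in seq_len(nrow(contexts))) {
    for (p in pwms) {
      call <- score_allele_disruption(
        p, contexts$context[i], contexts$var_pos[i],
        contexts$ref[i], contexts$alt[i],
        tau_match = tau_match, tau_delta = tau_delta, n_policy = n_policy
      )
      k <- k + 1L
      rows[[k]] <- data.frame(
        variant_id = contexts$id[i], pwm = p$name,
        s_ref = call$ref_hit$score, s_alt = call$alt_hit$score,
        delta = call$delta,
        strand = if (call$ref_hit$score >= call$alt_hit$score) {
          call$ref_hit$strand
        } else {
          call$alt_hit$strand
        },
        offset = call$ref_hit$offset,
        is_match = call$is_match, is_disruption = call$is_disruption,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Per-PWM disruption counts
#'
#' Counts SNPs whose disruption call is positive for each motif; a SNP
#' may count toward several motifs.  Accepts either the long call table
#' from [evaluate_disruptions()] or a logical SNP-by-PWM label matrix.
#'
#' @param calls Long call table (`pwm`, `is_disruption`) or logical
#'   matrix with PWM columns.
#' @param pwm_names Optional PWM names fixing the output order.
#' @return Named integer vector of counts.
#' @export
count_disruptions <- function(calls, pwm_names = NULL) {
  if (is.matrix(calls)) {
    counts <- colSums(calls != 0)
  } else {
    pwms <- pwm_names %||% sort(unique(calls$pwm))
    counts <- vapply(pwms, function(p) {
      sum(calls$is_disruption[calls$pwm == p])
    }, numeric(1))
  }
  if (!is.null(pwm_names)) {
    counts <- counts[pwm_names]
    counts[is.na(counts)] <- 0
    names(counts) <- pwm_names
  }
  setNames(as.integer(counts), names(counts))
}

#' Draw a background SNP sample
#'
#' Uniform sampling without replacement from a SNP universe, optionally
#' restricted to SNPs falling inside at least one biofeature track (the
#' same genomic-region filter used to select the foreground set).
#'
#' @param universe Data frame with an `id` column and, when `tracks` is
#'   given, `chrom` and `pos`.
#' @param draw_size Sample size (default 663).
#' @param seed Integer seed.
#' @param tracks Optional named list of `GRanges`; restricts the universe
#'   to SNPs within at least one track.
#' @return Character vector of sampled SNP ids.
#' @export
draw_background <- function(universe, draw_size = 663L, seed, tracks = NULL) {
  if (!is.null(tracks)) {
    inside <- rep(FALSE, nrow(universe))
    gr <- .snp_granges(universe)
    for (nm in names(tracks)) {
      inside <- inside | IRanges::overlapsAny(gr, tracks[[nm]])
    }
    universe <- universe[inside, , drop = FALSE]
  }
  if (nrow(universe) < draw_size) {
    stop_bad_arg("universe (", nrow(universe),
                 " SNPs after restriction) smaller than draw_size (",
                 draw_size, ")")
  }
  with_seed(seed, universe$id[sample.int(nrow(universe), draw_size)])
}

#' Resampled background distribution of disruption counts
#'
#' Draws `n_draws` independent samples of `draw_size` SNPs (without
#' replacement within a draw) from a labelled universe and records the
#' per-PWM disruption count of each draw, together with per-PWM mean and
#' sample standard deviation (n-1 denominator).
#'
#' @param labels Logical/0-1 matrix, SNPs (rows, rownames = ids) by PWMs
#'   (columns): which SNP disrupts which motif.
#' @param n_draws Number of draws (default 200, minimum 2).
#' @param draw_size SNPs per draw (default 663).
#' @param seed Integer seed.
#' @return Object of class `background_distribution`: list with `counts`
#'   (n_draws x n_pwms), `mean`, `sd`, `n_draws`, `draw_size`, `seed`.
#' @export
background_distribution <- function(labels, n_draws = 200L, draw_size = 663L,
                                    seed) {
  if (n_draws < 2L) stop_bad_arg("n_draws must be >= 2")
  if (nrow(labels) < draw_size) {
    stop_bad_arg("universe smaller than draw_size")
  }
  labels <- labels != 0
  counts <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      colSums(labels[sample.int(nrow(labels), draw_size), , drop = FALSE])
    }, numeric(ncol(labels)))
  })
  counts <- matrix(counts, nrow = n_draws, ncol = ncol(labels),
                   byrow = TRUE, dimnames = list(NULL, colnames(labels)))
  structure(
    list(counts = counts, mean = colMeans(counts),
         sd = apply(counts, 2L, sd),
         n_draws = n_draws, draw_size = draw_size, seed = seed),
    class = "background_distribution"
  )
}

#' @export
print.background_distribution <- function(x, ...) {
  cat("<background_distribution> ", x$n_draws, " draws of ", x$draw_size,
      " SNPs over ", ncol(x$counts), " PWMs\n", sep = "")
  invisible(x)
}

#' Per-PWM enrichment z scores
#'
#' `z = (n - mu) / sigma` per motif: the observed disruption count as a
#' standardized deviation from the resampled background.  Motifs with
#' zero background standard deviation get `NA` (flagged undefined) rather
#' than an infinite score.
#'
#' @param observed Named integer vector of observed counts (names = PWM).
#' @param background A [background_distribution()].
#' @return Named numeric vector of z scores (`NA` where sd is 0).
#' @export
z_scores <- function(observed, background) {
  pwms <- colnames(background$counts)
  missing_p <- setdiff(names(observed), pwms)
  if (length(missing_p)) {
    stop_bad_arg("PWM(s) absent from background: ",
                 paste(missing_p, collapse = ", "))
  }
  z <- setNames(rep(NA_real_, length(observed)), names(observed))
  mu <- background$mean[names(observed)]
  sg <- background$sd[names(observed)]
  ok <- sg > 0
  z[ok] <- (observed[ok] - mu[ok]) / sg[ok]
  z
}

#' Bootstrap confidence intervals on background counts
#'
#' Empirical per-PWM quantiles of the background draw counts (type-7
#' linear interpolation) at the two-sided `alpha` level.  With
#' `bonferroni = TRUE` the quantile probabilities are divided across the
#' `m` motifs tested — `alpha/(2m)` and `1 - alpha/(2m)` — correcting the
#' family of intervals for multiple testing; uncorrected intervals use
#' `alpha/2` and `1 - alpha/2`.
#'
#' @param background A [background_distribution()].
#' @param alpha Two-sided level in (0, 1) (default 0.05).
#' @param bonferroni Apply the correction (default TRUE).
#' @param m Number of tests for the correction (default: number of PWMs).
#' @return Data frame: `pwm`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(background, alpha = 0.05, bonferroni = TRUE,
                         m = ncol(background$counts)) {
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("alpha must be in (0, 1)")
  p_lo <- if (bonferroni) alpha / (2 * m) else alpha / 2
  q <- apply(background$counts, 2L, quantile,
             probs = c(p_lo, 1 - p_lo), type = 7, names = FALSE)
  data.frame(pwm = colnames(background$counts),
             lower = q[1L, ], upper = q[2L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full enrichment table for one background
#'
#' Combines observed counts, background moments, z scores and bootstrap
#' intervals; a motif is flagged significant when its observed count
#' falls outside its interval.
#'
#' @inheritParams z_scores
#' @inheritParams bootstrap_ci
#' @return Data frame: `pwm`, `n`, `mu`, `sd`, `z`, `ci_lo`, `ci_hi`,
#'   `significant`.
#' @export
enrichment_table <- function(observed, background, alpha = 0.05,
                             bonferroni = TRUE,
                             m = ncol(background$counts)) {
  z <- z_scores(observed, background)
  ci <- bootstrap_ci(background, alpha = alpha, bonferroni = bonferroni,
                     m = m)
  ci <- ci[match(names(observed), ci$pwm), ]
  data.frame(
    pwm = names(observed), n = as.integer(observed),
    mu = unname(background$mean[names(observed)]),
    sd = unname(background$sd[names(observed)]),
    z = unname(z), ci_lo = ci$lower, ci_hi = ci$upper,
    significant = observed < ci$lower | observed > ci$upper,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Shapiro-Wilk normality check of enrichment z scores
#'
#' Reported as a diagnostic of whether the standardized enrichment scores
#' behave like a normal sample; never used to gate the pipeline.
#'
#' @param z Numeric vector of z scores (non-finite values dropped).
#' @return `htest` object from [stats::shapiro.test()].
#' @export
test_z_normality <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 3L) stop_bad_arg("need >= 3 finite z scores")
  if (sd(z) == 0) stop_bad_arg("z scores are constant; normality test undefined")
  shapiro.test(z)
}
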