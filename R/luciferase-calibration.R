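.rtrunc <- function(draw_fn, lo, hi) {
  for (i in 1:100) {
    x <- draw_fn()
    if (x >= lo && x <= hi) return(x)
  }
  min(max(draw_fn(), lo), hi)
}

#' Simulation-based calibration of the basal allelic contrast
#'
#' Checks that the nominal 95% credible interval of the basal
#' allelic-activity contrast achieves its stated coverage: per replicate,
#' hyperparameters and effects are drawn from the model's priors (extreme
#' hyperparameter draws truncated so the simulated data stay finite),
#' plate data are simulated at a reduced design (two enhancers by two
#' alleles, `n_preps` preps, `n_transfections` transfections,
#' `n_batches` batches, duplicates), the model is refit, and coverage of
#' `exp(E1 - E2)` is recorded along with the log-scale error of the
#' posterior-mean contrast.  Nuisance prep/transfection/batch effects are
#' drawn as zero-centered normals at their prior scales; measurement
#' noise is held at `noise_sd`.
#'
#' @param n_replicates Number of calibration replicates (default 50).
#' @param seed Integer seed governing the whole run.
#' @param chains,iterations,warmup Sampler settings per replicate fit
#'   (reduced by default: 2 chains of 1200 iterations, half warmup).
#' @param n_preps,n_transfections,n_batches Reduced design parameters.
#' @param noise_sd Measurement noise sd on the log scale (default 0.1).
#'
#' @return Data frame with one row per replicate: `true_log_contrast`,
#'   `post_mean_log`, `lower`, `upper` (fold scale), `covered`,
#'   `log_error`.
#' @export
prior_calibration_basal <- function(n_replicates = 50L, seed,
                                    chains = 2L, iterations = 1200L,
                                    warmup = iterations %/% 2L,
                                    n_preps = 3L, n_transfections = 2L,
                                    n_batches = 2L, noise_sd = 0.1) {
  enh <- c("enh1_A", "enh1_G", "enh2_A", "enh2_G")
  rows <- lapply(seq_len(n_replicates), function(rep) {
    rep_seed <- seed + 1000L * rep
    truth <- with_seed(rep_seed, {
      nu_E <- .rtrunc(function() rexp(1, 1 / 20), 2, 100)
      s_E <- .rtrunc(function() rexp(1, 1 / 8), 0.1, 2)
      s_A <- .rtrunc(function() rexp(1, 2), 0.05, 1)
      s_P <- .rtrunc(function() rexp(1, 1), 0.02, 0.5)
      s_T <- .rtrunc(function() rexp(1, 2), 0.02, 0.5)
      s_B <- .rtrunc(function() rexp(1, 1), 0.02, 0.5)
      E <- vapply(enh, function(e) {
        .rtrunc(function() rt(1, nu_E) * s_E, -3, 3)
      }, numeric(1))
      A <- vapply(enh, function(e) {
        .rtrunc(function() rcauchy(1, 0, s_A), -3, 3)
      }, numeric(1))
      list(E = E, A = A, s_P = s_P, s_T = s_T, s_B = s_B)
    })
    sim <- simulate_luciferase_dataset(
      enh,
      true_params = list(L0 = 2, E = truth$E, A = truth$A,
                         P_sd = truth$s_P, T_sd = truth$s_T,
                         B_sd = truth$s_B),
      n_preps = n_preps, n_transfections = n_transfections,
      n_batches = n_batches, n_replicates = 2L,
      noise_sd = noise_sd, seed = rep_seed + 1L
    )
    fit <- suppressWarnings(fit_model(
      build_design(sim$observations), chains = chains,
      iterations = iterations, warmup = warmup, seed = rep_seed + 2L
    ))
    ct <- contrast_basal(fit, "enh1_A", "enh1_G")
    true_log <- truth$E[["enh1_A"]] - truth$E[["enh1_G"]]
    data.frame(
      true_log_contrast = true_log,
      post_mean_log = mean(log(ct$draws)),
      lower = ct$lower, upper = ct$upper,
      covered = ct$lower <= exp(true_log) && exp(true_log) <= ct$upper,
      log_error = mean(log(ct$draws)) - true_log
    )
  })
  do.call(rbind, rows)
}
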