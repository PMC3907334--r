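# t density with location 0, scale s, df nu, on the log scale
.dt_ls <- function(x, nu, s) dt(x / s, df = nu, log = TRUE) - log(s)

#' Build the design registry for the luciferase model
#'
#' Converts a plate table into contiguous integer indices per factor
#' level (enhancer, androgen response, prep, transfection, batch, noise
#' group), fixes the reference level `L0` to the empirical mean of the
#' log measurements of the two negative-control enhancers (whose basal
#' effects are pinned at 0), and checks that both negative controls and
#' the positive control appear in every batch (a warning, not an error,
#' when absent).
#'
#' @param observations Data frame with columns `enhancer`, `dht`,
#'   `prep`, `transfection`, `batch`, `luminescence` (> 0).
#' @param neg_controls,pos_control Control enhancer ids.
#' @param noise Noise pooling: `"per_group"` (one sd per enhancer x
#'   condition group) or `"global"`.
#' @return Object of class `luciferase_design`.
#' @export
build_design <- function(observations,
                         neg_controls = c("neg_ctrl_1", "neg_ctrl_2"),
                         pos_control = "pos_ctrl",
                         noise = c("per_group", "global")) {
  noise <- match.arg(noise)
  if (!nrow(observations)) stop_bad_arg("empty data")
  if (any(observations$luminescence <= 0)) {
    stop_bad_arg("luminescence must be positive")
  }
  obs <- observations
  obs$logy <- log(obs$luminescence)
  for (b in unique(obs$batch)) {
    present <- unique(obs$enhancer[obs$batch == b])
    missing_ctrl <- setdiff(c(neg_controls, pos_control), present)
    if (length(missing_ctrl)) {
      warning("batch ", b, " lacks control(s): ",
              paste(missing_ctrl, collapse = ", "))
    }
  }
  is_neg <- obs$enhancer %in% neg_controls
  if (!any(is_neg)) {
    stop_bad_arg("no negative-control observations; L0 cannot be anchored")
  }
  enh_levels <- sort(unique(obs$enhancer))
  free_enh <- setdiff(enh_levels, neg_controls)  # E pinned at 0 for negs
  prep_levels <- sort(unique(obs$prep))
  trans_levels <- sort(unique(obs$transfection))
  batch_levels <- sort(unique(obs$batch))
  group <- if (noise == "per_group") {
    paste(obs$enhancer, obs$dht, sep = ":")
  } else {
    rep("all", nrow(obs))
  }
  group_levels <- sort(unique(group))
  structure(
    list(
      obs = obs,
      L0 = mean(obs$logy[is_neg]),
      neg_controls = neg_controls, pos_control = pos_control,
      noise = noise,
      enh_levels = enh_levels, free_enh = free_enh,
      prep_levels = prep_levels, trans_levels = trans_levels,
      batch_levels = batch_levels, group_levels = group_levels,
      # nesting maps for likelihood-invariant recentering moves; NA when a
      # level is not nested cleanly
      enh_of_prep = vapply(prep_levels, function(p) {
        e <- unique(obs$enhancer[obs$prep == p])
        if (length(e) == 1L) match(e, free_enh) else NA_integer_
      }, integer(1)),
      prep_of_trans = vapply(trans_levels, function(tt) {
        p <- unique(obs$prep[obs$transfection == tt])
        if (length(p) == 1L) match(p, prep_levels) else NA_integer_
      }, integer(1)),
      batch_of_trans = vapply(trans_levels, function(tt) {
        b <- unique(obs$batch[obs$transfection == tt])
        if (length(b) == 1L) match(b, batch_levels) else NA_integer_
      }, integer(1)),
      enh_of_trans = vapply(trans_levels, function(tt) {
        e <- unique(obs$enhancer[obs$transfection == tt])
        if (length(e) == 1L) match(e, free_enh) else NA_integer_
      }, integer(1)),
      eF_idx = match(obs$enhancer, free_enh),      # NA for neg controls
      a_idx = match(obs$enhancer, enh_levels),
      p_idx = match(obs$prep, prep_levels),
      t_idx = match(obs$transfection, trans_levels),
      b_idx = match(obs$batch, batch_levels),
      g_idx = match(group, group_levels),
      D = as.integer(obs$dht)
    ),
    class = "luciferase_design"
  )
}

#' @export
print.luciferase_design <- function(x, ...) {
  cat("<luciferase_design> ", nrow(x$obs), " observations, ",
      length(x$enh_levels), " enhancers (", length(x$free_enh),
      " free), ", length(x$prep_levels), " preps, ",
      length(x$trans_levels), " transfections, ",
      length(x$batch_levels), " batches; noise '", x$noise, "'\n", sep = "")
  invisible(x)
}

.init_params <- function(design) {
  list(
    E = setNames(rep(0, length(design$free_enh)), design$free_enh),
    A = setNames(rep(0, length(design$enh_levels)), design$enh_levels),
    P = setNames(rep(0, length(design$prep_levels)), design$prep_levels),
    T = setNames(rep(0, length(design$trans_levels)), design$trans_levels),
    B = setNames(rep(0, length(design$batch_levels)), design$batch_levels),
    sigma = setNames(rep(0.2, length(design$group_levels)),
                     design$group_levels),
    nu_E = 20, s_E = 1, s_A = 0.5, s_P = 0.5, nu_T = 3, s_T = 0.5,
    s_B = 0.5, tau = 0.5
  )
}

.linear_predictor <- function(params, design) {
  E_term <- ifelse(is.na(design$eF_idx), 0, params$E[design$eF_idx])
  design$L0 + E_term + params$A[design$a_idx] * design$D +
    params$P[design$p_idx] + params$T[design$t_idx] +
    params$B[design$b_idx]
}

#' Log posterior density of the luciferase model
#'
#' Likelihood: `log y_i ~ Normal(mu_i, sigma_g(i))` with
#' `mu_i = L0 + E_e(i) + A_e(i) D_i + P_p(i) + T_t(i) + B_b(i)`; `L0` is
#' fixed by the negative-control constraint (see [build_design()]).
#' Priors: `E ~ t(nu_E, s_E)` with `nu_E ~ Exp(mean 20)` and
#' `s_E ~ Exp(mean 8)`; `A ~ Cauchy(0, s_A)`, `s_A ~ Exp(mean 1/2)`;
#' `P ~ Normal(0, s_P)`, `s_P ~ Exp(mean 1)`; `T ~ t(nu_T, s_T)`,
#' `nu_T ~ Exp(mean 3)`, `s_T ~ Exp(mean 1/2)`; `B ~ Normal(0, s_B)`,
#' `s_B ~ Exp(mean 1)`; noise sds `sigma_g ~ half-Normal(tau)` with
#' `tau ~ Exp(mean 1)`.  All exponential hyperpriors are parameterized by
#' their mean.  Out-of-support parameter values return `-Inf` rather
#' than raising an error.
#'
#' @param params Named list as produced by the sampler: effect vectors
#'   `E`, `A`, `P`, `T`, `B`, noise `sigma` (per group), and
#'   hyperparameters `nu_E`, `s_E`, `s_A`, `s_P`, `nu_T`, `s_T`, `s_B`,
#'   `tau`.
#' @param design A [build_design()] registry.
#' @return Log posterior density (up to an additive constant).
#' @export
log_posterior <- function(params, design) {
  scales <- c(params$s_E, params$s_A, params$s_P, params$s_T, params$s_B,
              params$tau, params$nu_E, params$nu_T, params$sigma)
  if (any(!is.finite(unlist(params))) || any(scales <= 0)) return(-Inf)
  mu <- .linear_predictor(params, design)
  sig <- params$sigma[design$g_idx]
  ll <- sum(dnorm(design$obs$logy, mu, sig, log = TRUE))
  lp <- sum(.dt_ls(params$E, params$nu_E, params$s_E)) +
    dexp(params$nu_E, rate = 1 / 20, log = TRUE) +
    dexp(params$s_E, rate = 1 / 8, log = TRUE) +
    sum(dcauchy(params$A, 0, params$s_A, log = TRUE)) +
    dexp(params$s_A, rate = 2, log = TRUE) +
    sum(dnorm(params$P, 0, params$s_P, log = TRUE)) +
    dexp(params$s_P, rate = 1, log = TRUE) +
    sum(.dt_ls(params$T, params$nu_T, params$s_T)) +
    dexp(params$nu_T, rate = 1 / 3, log = TRUE) +
    dexp(params$s_T, rate = 2, log = TRUE) +
    sum(dnorm(params$B, 0, params$s_B, log = TRUE)) +
    dexp(params$s_B, rate = 1, log = TRUE) +
    sum(dnorm(params$sigma, 0, params$tau, log = TRUE) + log(2)) +
    dexp(params$tau, rate = 1, log = TRUE)
  ll + lp
}

# Vectorized Metropolis update for one effect factor.  Levels touch
# disjoint observation sets, so per-level proposals are conditionally
# independent and can be accepted independently in one pass.
.update_factor <- function(v, idx, resid, sig, prior_fn, prop_sd, active) {
  K <- length(v)
  dv <- rnorm(K, 0, prop_sd)
  vn <- v + dv
  dvi <- dv[idx]
  dll_obs <- -0.5 * ((resid[active] - dvi[active])^2 -
                       resid[active]^2) / sig[active]^2
  dll <- rep(0, K)
  agg <- rowsum(dll_obs, idx[active])
  dll[as.integer(rownames(agg))] <- agg[, 1L]
  log_alpha <- dll + prior_fn(vn) - prior_fn(v)
  acc <- log(runif(K)) < log_alpha
  acc[!is.finite(log_alpha)] <- FALSE
  if (any(acc)) {
    v[acc] <- vn[acc]
    touched <- active & acc[idx]
    resid[touched] <- resid[touched] - dv[idx[touched]]
  }
  list(v = v, resid = resid, acc = acc)
}

# Likelihood-invariant recentering move along an additive ridge: shift an
# upper-level effect by delta and subtract delta from all nested
# lower-level effects, leaving every linear predictor unchanged.  Valid
# only for upper levels whose observations are all covered by cleanly
# nested lower levels; acceptance is the prior ratio.
.ridge_move <- function(upper, lower, map, valid, prior_up, prior_low,
                        prop_sd) {
  K <- length(upper)
  delta <- rnorm(K, 0, prop_sd)
  delta[!valid] <- 0
  ok <- !is.na(map)
  low_new <- lower
  low_new[ok] <- lower[ok] - delta[map[ok]]
  dpl <- prior_low(low_new) - prior_low(lower)
  agg <- rowsum(dpl[ok], map[ok])
  dlow <- rep(0, K)
  dlow[as.integer(rownames(agg))] <- agg[, 1L]
  log_alpha <- prior_up(upper + delta) - prior_up(upper) + dlow
  acc <- log(runif(K)) < log_alpha & valid
  acc[!is.finite(log_alpha)] <- FALSE
  if (any(acc)) {
    upper[acc] <- upper[acc] + delta[acc]
    adj <- ok & acc[map]
    lower[adj] <- lower[adj] - delta[map[adj]]
  }
  list(upper = upper, lower = lower, acc = acc)
}

# Upper levels eligible for a recentering move: all their observations
# must route through lower levels nested under that same upper level.
.ridge_valid <- function(n_upper, obs_upper, obs_lower_map, active = TRUE) {
  ou <- obs_upper[active]
  om <- obs_lower_map[active]
  bad <- unique(ou[is.na(om) | om != ou])
  !(seq_len(n_upper) %in% bad)
}

# Scalar Metropolis update on the log scale for a positive hyperparameter.
.update_positive_scalar <- function(x, target_fn, prop_sd) {
  xn <- x * exp(rnorm(1L, 0, prop_sd))
  # Jacobian of the log transform: + log(x)
  log_alpha <- target_fn(xn) + log(xn) - target_fn(x) - log(x)
  if (is.finite(log_alpha) && log(runif(1L)) < log_alpha) {
    list(x = xn, acc = TRUE)
  } else {
    list(x = x, acc = FALSE)
  }
}

.run_chain <- function(design, iterations, warmup, seed, thin = 1L) {
  d <- design
  n_obs <- nrow(d$obs)
  logy <- d$obs$logy
  active_all <- rep(TRUE, n_obs)
  active_E <- !is.na(d$eF_idx)
  active_A <- d$D == 1L
  idx_E <- d$eF_idx
  idx_E[!active_E] <- 1L  # placeholder, masked by `active`

  with_seed(seed, {
    p <- .init_params(design)
    # jitter the start so chains are overdispersed
    p$E <- p$E + rnorm(length(p$E), 0, 0.5)
    p$A <- p$A + rnorm(length(p$A), 0, 0.5)
    resid <- logy - .linear_predictor(p, d)
    sd_of <- list(E = rep(0.3, length(p$E)), A = rep(0.3, length(p$A)),
                  P = rep(0.2, length(p$P)), T = rep(0.2, length(p$T)),
                  B = rep(0.2, length(p$B)),
                  sigma = rep(0.3, length(p$sigma)),
                  hyper = rep(0.4, 8L),
                  rEP = rep(0.3, length(p$E)),
                  rPT = rep(0.2, length(p$P)),
                  rBT = rep(0.2, length(p$B)),
                  rET = rep(0.2, length(p$E)))
    valid_EP <- .ridge_valid(length(p$E), idx_E,
                             d$enh_of_prep[d$p_idx], active_E)
    valid_PT <- .ridge_valid(length(p$P), d$p_idx,
                             d$prep_of_trans[d$t_idx])
    valid_BT <- .ridge_valid(length(p$B), d$b_idx,
                             d$batch_of_trans[d$t_idx])
    valid_ET <- .ridge_valid(length(p$E), idx_E,
                             d$enh_of_trans[d$t_idx], active_E)
    n_ridge <- 5L
    hyper_names <- c("nu_E", "s_E", "s_A", "s_P", "nu_T", "s_T", "s_B",
                     "tau")
    n_keep <- (iterations - warmup) %/% thin
    par_names <- c(paste0("E[", d$free_enh, "]"),
                   paste0("A[", d$enh_levels, "]"),
                   paste0("P[", d$prep_levels, "]"),
                   paste0("T[", d$trans_levels, "]"),
                   paste0("B[", d$batch_levels, "]"),
                   paste0("sigma[", d$group_levels, "]"),
                   hyper_names)
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    acc_count <- 0
    acc_total <- 0
    kept <- 0L

    for (it in seq_len(iterations)) {
      adapt <- it <= warmup
      gamma <- if (adapt) min(0.25, 3 / sqrt(it)) else 0
      target <- 0.35
      sig_obs <- p$sigma[d$g_idx]

      upd <- .update_factor(p$E, idx_E, resid, sig_obs,
                            function(v) .dt_ls(v, p$nu_E, p$s_E),
                            sd_of$E, active_E)
      p$E <- upd$v; resid <- upd$resid
      if (adapt) sd_of$E <- sd_of$E * exp(gamma * (upd$acc - target))
      acc_count <- acc_count + sum(upd$acc); acc_total <- acc_total + length(upd$acc)

      upd <- .update_factor(p$A, d$a_idx, resid, sig_obs,
                            function(v) dcauchy(v, 0, p$s_A, log = TRUE),
                            sd_of$A, active_A)
      p$A <- upd$v; resid <- upd$resid
      if (adapt) sd_of$A <- sd_of$A * exp(gamma * (upd$acc - target))
      acc_count <- acc_count + sum(upd$acc); acc_total <- acc_total + length(upd$acc)

      upd <- .update_factor(p$P, d$p_idx, resid, sig_obs,
                            function(v) dnorm(v, 0, p$s_P, log = TRUE),
                            sd_of$P, active_all)
      p$P <- upd$v; resid <- upd$resid
      if (adapt) sd_of$P <- sd_of$P * exp(gamma * (upd$acc - target))

      upd <- .update_factor(p$T, d$t_idx, resid, sig_obs,
                            function(v) .dt_ls(v, p$nu_T, p$s_T),
                            sd_of$T, active_all)
      p$T <- upd$v; resid <- upd$resid
      if (adapt) sd_of$T <- sd_of$T * exp(gamma * (upd$acc - target))

      upd <- .update_factor(p$B, d$b_idx, resid, sig_obs,
                            function(v) dnorm(v, 0, p$s_B, log = TRUE),
                            sd_of$B, active_all)
      p$B <- upd$v; resid <- upd$resid
      if (adapt) sd_of$B <- sd_of$B * exp(gamma * (upd$acc - target))

      # recentering moves along the additive ridges (likelihood-invariant,
      # prior-only acceptance; cheap, so repeated several times per sweep)
      for (r in seq_len(n_ridge)) {
        upd <- .ridge_move(p$E, p$P, d$enh_of_prep, valid_EP,
                           function(v) .dt_ls(v, p$nu_E, p$s_E),
                           function(v) dnorm(v, 0, p$s_P, log = TRUE),
                           sd_of$rEP)
        p$E <- upd$upper; p$P <- upd$lower
        if (adapt) sd_of$rEP <- sd_of$rEP * exp(gamma * (upd$acc - target))

        upd <- .ridge_move(p$P, p$T, d$prep_of_trans, valid_PT,
                           function(v) dnorm(v, 0, p$s_P, log = TRUE),
                           function(v) .dt_ls(v, p$nu_T, p$s_T),
                           sd_of$rPT)
        p$P <- upd$upper; p$T <- upd$lower
        if (adapt) sd_of$rPT <- sd_of$rPT * exp(gamma * (upd$acc - target))

        upd <- .ridge_move(p$B, p$T, d$batch_of_trans, valid_BT,
                           function(v) dnorm(v, 0, p$s_B, log = TRUE),
                           function(v) .dt_ls(v, p$nu_T, p$s_T),
                           sd_of$rBT)
        p$B <- upd$upper; p$T <- upd$lower
        if (adapt) sd_of$rBT <- sd_of$rBT * exp(gamma * (upd$acc - target))

        upd <- .ridge_move(p$E, p$T, d$enh_of_trans, valid_ET,
                           function(v) .dt_ls(v, p$nu_E, p$s_E),
                           function(v) .dt_ls(v, p$nu_T, p$s_T),
                           sd_of$rET)
        p$E <- upd$upper; p$T <- upd$lower
        if (adapt) sd_of$rET <- sd_of$rET * exp(gamma * (upd$acc - target))
      }

      # noise sds: disjoint groups, vectorized log-scale RW
      dv <- rnorm(length(p$sigma), 0, sd_of$sigma)
      sig_new <- p$sigma * exp(dv)
      ll_old <- rowsum(-0.5 * (resid / sig_obs)^2 - log(sig_obs), d$g_idx)
      sig_new_obs <- sig_new[d$g_idx]
      ll_new <- rowsum(-0.5 * (resid / sig_new_obs)^2 - log(sig_new_obs),
                       d$g_idx)
      log_alpha <- (ll_new - ll_old)[, 1L] +
        dnorm(sig_new, 0, p$tau, log = TRUE) -
        dnorm(p$sigma, 0, p$tau, log = TRUE) +
        log(sig_new) - log(p$sigma)
      acc <- log(runif(length(p$sigma))) < log_alpha
      acc[!is.finite(log_alpha)] <- FALSE
      p$sigma[acc] <- sig_new[acc]
      if (adapt) sd_of$sigma <- sd_of$sigma * exp(gamma * (acc - target))

      # hyperparameters: scalar log-scale RW, prior-only targets
      targets <- list(
        nu_E = function(x) sum(.dt_ls(p$E, x, p$s_E)) +
          dexp(x, 1 / 20, log = TRUE),
        s_E = function(x) sum(.dt_ls(p$E, p$nu_E, x)) +
          dexp(x, 1 / 8, log = TRUE),
        s_A = function(x) sum(dcauchy(p$A, 0, x, log = TRUE)) +
          dexp(x, 2, log = TRUE),
        s_P = function(x) sum(dnorm(p$P, 0, x, log = TRUE)) +
          dexp(x, 1, log = TRUE),
        nu_T = function(x) sum(.dt_ls(p$T, x, p$s_T)) +
          dexp(x, 1 / 3, log = TRUE),
        s_T = function(x) sum(.dt_ls(p$T, p$nu_T, x)) +
          dexp(x, 2, log = TRUE),
        s_B = function(x) sum(dnorm(p$B, 0, x, log = TRUE)) +
          dexp(x, 1, log = TRUE),
        tau = function(x) sum(dnorm(p$sigma, 0, x, log = TRUE)) +
          dexp(x, 1, log = TRUE)
      )
      for (h in seq_along(hyper_names)) {
        nm <- hyper_names[h]
        upd <- .update_positive_scalar(p[[nm]], targets[[nm]],
                                       sd_of$hyper[h])
        p[[nm]] <- upd$x
        if (adapt) {
          sd_of$hyper[h] <- sd_of$hyper[h] * exp(gamma * (upd$acc - target))
        }
      }

      if (it > warmup && (it - warmup) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(p$E, p$A, p$P, p$T, p$B, p$sigma,
                           p$nu_E, p$s_E, p$s_A, p$s_P, p$nu_T, p$s_T,
                           p$s_B, p$tau)
      }
    }
    list(draws = draws, acceptance = acc_count / max(1, acc_total))
  })
}

#' Fit the hierarchical luciferase model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs: per-factor vectorized random-walk
#' updates (effect levels touch disjoint observations, so their proposals
#' are conditionally independent), log-scale random walks for the
#' positive hyperparameters and noise scales, with proposal scales
#' adapted during warmup toward a moderate acceptance rate.  Chains are
#' jittered at initialization; convergence is checked with split-chain
#' R-hat and the result carries a `converged` flag (a warning, never a
#' silent pass, when any reported quantity has R-hat above 1.05).
#'
#' @param data A [build_design()] registry, or a plate data frame (then
#'   `...` is forwarded to [build_design()]).
#' @param chains Number of chains (>= 2 for diagnostics; default 4).
#' @param iterations Total iterations per chain (default 4000).
#' @param warmup Warmup iterations discarded (default half).
#' @param seed Integer seed; chain c runs at `seed + c - 1`.
#' @param thin Keep every `thin`-th draw (default 1).
#' @param ... Passed to [build_design()] when `data` is a data frame.
#' @return Object of class `luciferase_posterior`: per-chain draw
#'   matrices, the design, sampler metadata, diagnostics and the
#'   `converged` flag.
#' @export
fit_model <- function(data, chains = 4L, iterations = 4000L,
                      warmup = iterations %/% 2L, seed, thin = 1L, ...) {
  design <- if (inherits(data, "luciferase_design")) {
    data
  } else {
    build_design(data, ...)
  }
  if (iterations <= 0L || warmup >= iterations) {
    stop_bad_arg("need iterations > warmup >= 0")
  }
  runs <- lapply(seq_len(chains), function(ch) {
    .run_chain(design, iterations, warmup, seed = seed + ch - 1L,
               thin = thin)
  })
  post <- structure(
    list(
      draws = lapply(runs, `[[`, "draws"),
      acceptance = vapply(runs, `[[`, numeric(1), "acceptance"),
      design = design, chains = chains, iterations = iterations,
      warmup = warmup, seed = seed, converged = NA
    ),
    class = "luciferase_posterior"
  )
  diag <- diagnostics(post)
  core <- grepl("^(E|A)\\[", diag$parameter)
  post$diagnostics <- diag
  post$converged <- all(is.na(diag$rhat[core]) | diag$rhat[core] <= 1.05)
  if (isFALSE(post$converged)) {
    warning("R-hat > 1.05 on reported quantities; posterior flagged ",
            "non-converged")
  }
  post
}

#' @export
print.luciferase_posterior <- function(x, ...) {
  cat("<luciferase_posterior> ", x$chains, " chains x ",
      nrow(x$draws[[1]]), " kept draws, ",
      ncol(x$draws[[1]]), " parameters; converged: ", x$converged,
      "\n", sep = "")
  invisible(x)
}

#' Pooled posterior draws
#' @param x A `luciferase_posterior`.
#' @param ... Unused.
#' @return Matrix of draws, all chains stacked.
#' @export
as.matrix.luciferase_posterior <- function(x, ...) {
  do.call(rbind, x$draws)
}

.split_rhat <- function(chains_mat) {
  # chains_mat: list of numeric vectors (one per chain), equal length
  halves <- unlist(lapply(chains_mat, function(v) {
    n <- length(v) %/% 2L
    list(v[seq_len(n)], v[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L || m < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(chains_mat) {
  pooled <- unlist(chains_mat)
  N <- length(chains_mat[[1]])
  M <- length(chains_mat)
  if (var(pooled) == 0) return(NA_real_)
  # mean autocorrelation across chains, truncated at the first negative
  # adjacent-pair sum (Geyer initial positive sequence)
  max_lag <- min(N - 1L, 200L)
  rho <- rowMeans(vapply(chains_mat, function(v) {
    acf(v, lag.max = max_lag, plot = FALSE)$acf[-1L, 1L, 1L]
  }, numeric(max_lag)))
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  min(M * N, M * N / (1 + 2 * s))
}

#' Convergence diagnostics
#'
#' Split-chain R-hat and autocorrelation-based effective sample size for
#' every stored parameter.
#'
#' @param posterior A `luciferase_posterior`.
#' @return Data frame: `parameter`, `rhat`, `ess`, `mean`, `sd`.
#' @export
diagnostics <- function(posterior) {
  stopifnot(inherits(posterior, "luciferase_posterior"))
  draws <- posterior$draws
  if (length(draws) < 2L) {
    warning("single chain: R-hat unavailable")
  }
  pars <- colnames(draws[[1]])
  out <- lapply(pars, function(pn) {
    per_chain <- lapply(draws, function(m) m[, pn])
    pooled <- unlist(per_chain)
    data.frame(
      parameter = pn,
      rhat = if (length(draws) >= 2L) .split_rhat(per_chain) else NA_real_,
      ess = .ess(per_chain),
      mean = mean(pooled), sd = sd(pooled),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

.contrast_summary <- function(draws, name, scale = "fold") {
  q <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(contrast = name, mean = mean(draws), lower = q[1], upper = q[2],
         scale = scale, draws = draws),
    class = "contrast_summary"
  )
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CI %.3f-%.3f, %s scale)\n",
              x$contrast, x$mean, x$lower, x$upper, x$scale))
  invisible(x)
}

.effect_draws <- function(posterior, prefix, enh) {
  pn <- paste0(prefix, "[", enh, "]")
  m <- as.matrix(posterior)
  if (pn %in% colnames(m)) return(m[, pn])
  # negative controls are pinned at 0 and carry no E column
  if (prefix == "E" && enh %in% posterior$design$neg_controls) {
    return(rep(0, nrow(m)))
  }
  stop_bad_arg("unknown enhancer '", enh, "'")
}

#' Posterior basal-activity contrast between two enhancer alleles
#'
#' Per-draw `exp(E_1 - E_2)`: the fold difference in basal (vehicle)
#' activity between two enhancer-allele constructs, summarized as the
#' posterior mean with the 2.5th-97.5th percentile credible interval.
#'
#' @param posterior A `luciferase_posterior`.
#' @param enhancer1,enhancer2 Enhancer ids.
#' @return A `contrast_summary` on the fold scale.
#' @export
contrast_basal <- function(posterior, enhancer1, enhancer2) {
  d <- exp(.effect_draws(posterior, "E", enhancer1) -
             .effect_draws(posterior, "E", enhancer2))
  .contrast_summary(d, paste0("basal ", enhancer1, " / ", enhancer2))
}

#' Posterior androgen induction of one enhancer
#'
#' Per-draw `exp(A_e)`: the fold induction under DHT relative to
#' vehicle.
#'
#' @param posterior A `luciferase_posterior`.
#' @param enhancer Enhancer id.
#' @return A `contrast_summary` on the fold scale.
#' @export
contrast_induction <- function(posterior, enhancer) {
  d <- exp(.effect_draws(posterior, "A", enhancer))
  .contrast_summary(d, paste0("induction ", enhancer))
}

#' Posterior allelic ratio of androgen induction
#'
#' Per-draw `exp(A_1 - A_2)`: the fold difference in DHT induction
#' between two alleles of an enhancer.
#'
#' @param posterior A `luciferase_posterior`.
#' @param enhancer1,enhancer2 Enhancer ids.
#' @return A `contrast_summary` on the fold scale.
#' @export
contrast_induction_ratio <- function(posterior, enhancer1, enhancer2) {
  d <- exp(.effect_draws(posterior, "A", enhancer1) -
             .effect_draws(posterior, "A", enhancer2))
  .contrast_summary(d, paste0("induction ratio ", enhancer1, " / ",
                              enhancer2))
}
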