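#' Simulate a plate-structured luciferase reporter dataset
#'
#' Generates log-normal luminescence measurements from the additive model
#' on the natural-log scale
#' `log y = L0 + E_e + A_e * D + P_p + T_t + B_b + noise`,
#' where `E` is the per-enhancer basal effect, `A` the androgen response
#' (active only under DHT, `D = 1`), `P` a plasmid-prep effect, `T` a
#' transfection effect and `B` a plate-batch effect.  The default layout
#' mirrors a typical experiment: 6 plasmid preps per enhancer, 4
#' transfections of each prep in each batch, every sample in duplicate,
#' both conditions (vehicle and DHT), and the two negative-control
#' enhancers plus the positive control run on every batch.
#'
#' @param enhancers Character vector of test enhancer ids; encode allele
#'   identity in the id (e.g. `"JAZF1_A"`, `"JAZF1_G"`).
#' @param true_params List of ground-truth parameters: `L0` (reference
#'   log level), `E` (named basal effects; missing names default to 0),
#'   `A` (named androgen responses; missing names default to 0), and the
#'   nuisance scales `P_sd`, `T_sd`, `B_sd` from which prep, transfection
#'   and batch effects are drawn, or explicit named vectors `P`, `T`,
#'   `B`.
#' @param n_preps Plasmid preps per test enhancer (default 6).
#' @param n_transfections Transfections per prep per batch (default 4).
#' @param n_batches Plate batches (default 1).
#' @param n_replicates On-plate replicates per sample (default 2).
#' @param noise_sd Measurement noise sd on the log scale.
#' @param seed Integer seed.
#' @param n_control_preps Preps for each control enhancer (default 1;
#'   must be >= 1 — the negative controls anchor the reference level).
#' @param neg_controls,pos_control Control enhancer ids.
#' @param pos_ctrl_effect Basal effect of the positive control when not
#'   given in `true_params$E`.
#'
#' @return List with `observations` (data frame: `enhancer`, `allele`,
#'   `dht`, `prep`, `transfection`, `batch`, `replicate`, `luminescence`)
#'   and `truth` (all realized effect values, including the drawn `P`,
#'   `T`, `B`).
#' @export
simulate_luciferase_dataset <- function(enhancers, true_params,
                                        n_preps = 6L, n_transfections = 4L,
                                        n_batches = 1L, n_replicates = 2L,
                                        noise_sd = 0.1, seed,
                                        n_control_preps = 1L,
                                        neg_controls = c("neg_ctrl_1",
                                                         "neg_ctrl_2"),
                                        pos_control = "pos_ctrl",
                                        pos_ctrl_effect = 2) {
  if (n_control_preps < 1L || length(neg_controls) != 2L) {
    stop_bad_arg("the two negative-control enhancers (and the positive ",
                 "control) must be run on each batch")
  }
  all_enh <- c(enhancers, neg_controls, pos_control)
  E <- setNames(rep(0, length(all_enh)), all_enh)
  E[names(true_params[["E"]])] <- true_params[["E"]]
  if (!pos_control %in% names(true_params[["E"]] %||% character(0))) {
    E[pos_control] <- pos_ctrl_effect
  }
  E[neg_controls] <- 0
  A <- setNames(rep(0, length(all_enh)), all_enh)
  A[names(true_params[["A"]])] <- true_params[["A"]]
  A[neg_controls] <- 0
  L0 <- true_params[["L0"]] %||% 0

  with_seed(seed, {
    rows <- list()
    preps_of <- function(e) {
      k <- if (e %in% c(neg_controls, pos_control)) n_control_preps else n_preps
      paste0(e, ".p", seq_len(k))
    }
    prep_ids <- unlist(lapply(all_enh, preps_of))
    P <- true_params[["P"]] %||%
      setNames(rnorm(length(prep_ids), 0, true_params[["P_sd"]] %||% 0.1),
               prep_ids)
    B <- true_params[["B"]] %||%
      setNames(rnorm(n_batches, 0, true_params[["B_sd"]] %||% 0.1),
               paste0("b", seq_len(n_batches)))
    trans_ids <- unlist(lapply(all_enh, function(e) {
      unlist(lapply(preps_of(e), function(p) {
        unlist(lapply(seq_len(n_batches), function(b) {
          paste0(p, ".b", b, ".t", seq_len(n_transfections))
        }))
      }))
    }))
    Tv <- true_params[["T"]] %||%
      setNames(rnorm(length(trans_ids), 0, true_params[["T_sd"]] %||% 0.1),
               trans_ids)
    for (e in all_enh) {
      for (p in preps_of(e)) {
        for (b in seq_len(n_batches)) {
          for (t in seq_len(n_transfections)) {
            tid <- paste0(p, ".b", b, ".t", t)
            for (D in c(0L, 1L)) {
              for (r in seq_len(n_replicates)) {
                mu <- L0 + E[[e]] + A[[e]] * D + P[[p]] + Tv[[tid]] +
                  B[[paste0("b", b)]]
                rows[[length(rows) + 1L]] <- data.frame(
                  enhancer = e,
                  allele = if (grepl("_", e)) sub(".*_", "", e) else NA_character_,
                  dht = D, prep = p, transfection = tid,
                  batch = paste0("b", b), replicate = r,
                  luminescence = exp(mu + rnorm(1L, 0, noise_sd)),
                  stringsAsFactors = FALSE
                )
              }
            }
          }
        }
      }
    }
    obs <- do.call(rbind, rows)
    list(
      observations = obs,
      truth = list(L0 = L0, E = E, A = A, P = P, T = Tv, B = B,
                   noise_sd = noise_sd,
                   neg_controls = neg_controls, pos_control = pos_control)
    )
  })
}
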