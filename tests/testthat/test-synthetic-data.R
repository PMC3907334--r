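test_that("genome_spec validates its inputs", {
  expect_error(genome_spec(c("chr1", "chr1"), c(1e6, 2e6)), "unique")
  expect_error(genome_spec("chr1", 0), "positive")
  gs <- genome_spec(c("chr1", "chr2"), c(5e6, 3e6))
  expect_equal(unname(gs$chrom_lengths), c(5e6, 3e6))
})

test_that("perfect within-block LD yields identical variant columns", {
  gs <- genome_spec("chr1", 1e6)
  p <- simulate_haplotype_panel(gs, 50, 2, block_len = 1e6,
                                within_block_r2 = 1.0, seed = 1)
  expect_identical(unname(p$haplotypes[, 1]), unname(p$haplotypes[, 2]))
  expect_equal(pairwise_r2(p, "snp0001", "snp0002"), 1.0)
})

test_that("zero within-block LD gives near-independent variants", {
  gs <- genome_spec("chr1", 1e6)
  p <- simulate_haplotype_panel(gs, 5000, 10, block_len = 1e6,
                                within_block_r2 = 0, seed = 2)
  pairs <- combn(10, 2)
  r2 <- apply(pairs, 2, function(ij) {
    brute_force_r2(p$haplotypes[, ij[1]], p$haplotypes[, ij[2]])
  })
  expect_lt(mean(r2), 0.01)
})

test_that("planted block r2 targets are recovered by the brute-force oracle", {
  gs <- genome_spec("chr1", 1e6)
  for (target in c(0.5, 0.8)) {
    p <- simulate_haplotype_panel(gs, 600, 10, block_len = 1e6,
                                  within_block_r2 = target, seed = 3)
    pairs <- combn(10, 2)
    r2 <- apply(pairs, 2, function(ij) {
      brute_force_r2(p$haplotypes[, ij[1]], p$haplotypes[, ij[2]])
    })
    expect_lt(abs(mean(r2) - target), 0.1)
  }
})

test_that("across-block variants are uncorrelated in expectation", {
  gs <- genome_spec("chr1", 1e6)
  p <- simulate_haplotype_panel(gs, 1000, 10, block_len = 1e5,
                                within_block_r2 = 0.9, seed = 4)
  blocks <- attr(p, "block")
  pairs <- combn(10, 2)
  cross <- pairs[, blocks[pairs[1, ]] != blocks[pairs[2, ]], drop = FALSE]
  r2 <- apply(cross, 2, function(ij) {
    brute_force_r2(p$haplotypes[, ij[1]], p$haplotypes[, ij[2]])
  })
  expect_lt(mean(r2), 0.01)
})

test_that("haplotype simulation is deterministic given the seed", {
  gs <- genome_spec("chr1", 1e6)
  a <- simulate_haplotype_panel(gs, 40, 12, 2e5, 0.7, seed = 9)
  b <- simulate_haplotype_panel(gs, 40, 12, 2e5, 0.7, seed = 9)
  c <- simulate_haplotype_panel(gs, 40, 12, 2e5, 0.7, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$haplotypes, c$haplotypes))
})

test_that("degenerate maf requests are rejected", {
  gs <- genome_spec("chr1", 1e6)
  expect_error(
    simulate_haplotype_panel(gs, 10, 5, 1e5, 0.5, maf_range = c(0, 0.5),
                             seed = 1),
    "monomorphic"
  )
  expect_error(
    simulate_haplotype_panel(gs, 1, 5, 1e5, 0.5, seed = 1),
    "n_samples"
  )
})

test_that("two-population divergence controls the dual-proxy fraction", {
  gs <- genome_spec("chr1", 5e6)
  for (div in c(0, 1, 0.5)) {
    tp <- simulate_two_population_panels(gs, 60, div, seed = 5,
                                         n_samples = 150, n_pairs = 20)
    expect_equal(sum(tp$truth$dual), round(20 * (1 - div)))
    r2A <- mapply(function(i, x) {
      brute_force_r2(tp$panels$popA$haplotypes[, i],
                     tp$panels$popA$haplotypes[, x])
    }, tp$truth$index_id, tp$truth$proxy_id)
    r2B <- mapply(function(i, x) {
      brute_force_r2(tp$panels$popB$haplotypes[, i],
                     tp$panels$popB$haplotypes[, x])
    }, tp$truth$index_id, tp$truth$proxy_id)
    expect_true(all(r2A > 0.5))
    expect_equal(unname(r2B > 0.5), tp$truth$dual)
  }
  expect_error(simulate_two_population_panels(gs, 60, 1.5, seed = 1),
               "ld_divergence")
})

test_that("biofeature track generation matches its Poisson density", {
  gs <- genome_spec("chr1", 10e6)
  empty <- generate_biofeature_tracks(gs, "t", density = 0, seed = 1)
  expect_length(empty$t, 0)
  tr <- generate_biofeature_tracks(gs, c("a", "b"), density = 10,
                                   width_range = c(100, 200), seed = 2)
  # ~Poisson(100): 5 sd tolerance (reduce() can merge a few)
  expect_gt(length(tr$a), 100 - 50)
  expect_lt(length(tr$a), 100 + 50)
  expect_true(all(GenomicRanges::start(tr$a) >= 1))
  expect_true(all(GenomicRanges::end(tr$a) <= 10e6))
  tr2 <- generate_biofeature_tracks(gs, c("a", "b"), density = 10,
                                    width_range = c(100, 200), seed = 2)
  expect_identical(as.data.frame(tr$a), as.data.frame(tr2$a))
  expect_error(generate_biofeature_tracks(gs, "t", density = -1, seed = 1),
               ">= 0")
})

test_that("PWM library generation respects count, lengths and column sums", {
  lib <- generate_pwm_library(87, c(8, 16), "mixed", seed = 6)
  expect_length(lib, 87)
  for (p in lib[1:10]) {
    expect_true(all(abs(colSums(p$mat) - 1) < 1e-9))
    expect_gte(pwm_length(p), 8)
    expect_lte(pwm_length(p), 16)
  }
  lib2 <- generate_pwm_library(87, c(8, 16), "mixed", seed = 6)
  expect_identical(lib, lib2)
  expect_error(generate_pwm_library(5, c(3, 6), "low", seed = 1), ">= 4")
})

test_that("uniform PWM columns carry zero information content", {
  m <- matrix(0.25, 4, 6)
  p <- pwm("flat", m, pseudocount = 0)
  expect_equal(information_content(p), rep(0, 6))
})

test_that("planted disruptions score 1 for the match allele and low for the other", {
  gs <- genome_spec("chr1", 2e6)
  panel <- simulate_haplotype_panel(gs, 30, 25, 2e5, 0.9, seed = 7)
  lib <- generate_pwm_library(12, c(8, 12), "high", seed = 8, pseudocount = 0)
  pl <- plant_disruptions(panel, lib, 8, seed = 9)
  expect_equal(nrow(pl$truth), 8)
  expect_true(all(pl$truth$variant_id %in% panel$variants$id))
  expect_true(all(pl$truth$pwm %in% names(lib)))
  for (k in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[k, ]
    ctx <- pl$contexts[pl$contexts$id == tr$variant_id, ]
    call <- score_allele_disruption(lib[[tr$pwm]], ctx$context, ctx$var_pos,
                                    ctx$ref, ctx$alt)
    expect_equal(call$ref_hit$score, 1.0)
    expect_lt(call$alt_hit$score, 0.8)
    expect_true(call$is_disruption)
  }
  expect_error(plant_disruptions(panel, lib, 1000, seed = 1), "exceeds")
})

test_that("luciferase simulator reproduces its design arithmetic", {
  sim <- simulate_luciferase_dataset(
    c("E1_A", "E1_G"),
    true_params = list(L0 = 1, E = c(E1_A = 0.5, E1_G = 0.2),
                       A = c(E1_A = 1, E1_G = 1)),
    n_preps = 6, n_transfections = 4, n_batches = 1, n_replicates = 2,
    noise_sd = 0.1, seed = 10
  )
  test_rows <- sim$observations$enhancer %in% c("E1_A", "E1_G")
  expect_equal(sum(test_rows), 2 * 6 * 4 * 2 * 2)  # 192
  # controls run on the (single) batch
  expect_true(all(c("neg_ctrl_1", "neg_ctrl_2", "pos_ctrl") %in%
                    sim$observations$enhancer))
  expect_error(
    simulate_luciferase_dataset("E1_A", list(), n_control_preps = 0,
                                seed = 1),
    "negative-control"
  )
})

test_that("noise-free simulation reproduces the linear predictor exactly", {
  sim <- simulate_luciferase_dataset(
    "E1_A",
    true_params = list(L0 = 2, E = c(E1_A = 0.7), A = c(E1_A = 1.2),
                       P_sd = 0, T_sd = 0, B_sd = 0),
    noise_sd = 0, seed = 11
  )
  obs <- sim$observations
  tr <- sim$truth
  mu <- tr$L0 + tr$E[obs$enhancer] + tr$A[obs$enhancer] * obs$dht
  expect_equal(log(obs$luminescence), unname(mu), tolerance = 1e-12)
})

test_that("true effects are recovered by direct averaging at large n", {
  sim <- simulate_luciferase_dataset(
    c("E1_A", "E1_G"),
    true_params = list(L0 = 1, E = c(E1_A = log(1.4), E1_G = 0),
                       A = c(E1_A = 0, E1_G = 0),
                       P_sd = 0, T_sd = 0, B_sd = 0),
    n_preps = 20, n_transfections = 10, noise_sd = 0.1, seed = 12
  )
  obs <- sim$observations
  gm <- function(e) exp(mean(log(obs$luminescence[obs$enhancer == e])))
  expect_equal(gm("E1_A") / gm("E1_G"), 1.4, tolerance = 0.02)
  # zero androgen effect: DHT vs vehicle log difference ~ 0
  dht_diff <- mean(log(obs$luminescence[obs$dht == 1 & obs$enhancer == "E1_A"])) -
    mean(log(obs$luminescence[obs$dht == 0 & obs$enhancer == "E1_A"]))
  expect_lt(abs(dht_diff), 0.02)
})
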