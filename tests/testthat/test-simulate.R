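test_that("all three generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 31)
  a <- simulate_protein(cfg)
  b <- simulate_protein(cfg)
  expect_identical(a, b)

  frags <- digest_sequence(a$protein$sequence,
                           cleavage_rule_preset("trypsin"), 0)
  expect_identical(simulate_observed_masses(a$truth, frags, cfg),
                   simulate_observed_masses(a$truth, frags, cfg))
  t1 <- simulate_trace(a$truth, frags, cfg)
  t2 <- simulate_trace(a$truth, frags, cfg)
  expect_identical(t1$cpm, t2$cpm)
})

test_that("cleavage residue frequency controls the digest granularity", {
  cfg0 <- sim_config(seed = 3, cleavage_residue_freq = 0)
  sim0 <- simulate_protein(cfg0)
  d0 <- digest_sequence(sim0$protein$sequence,
                        cleavage_rule_preset("trypsin"), 0)
  expect_equal(nrow(d0), 1)

  # empirical K/R fraction within 3 binomial SDs of the target rate
  cfg <- sim_config(seed = 17, protein_length = 320)
  res <- strsplit(simulate_protein(cfg)$protein$sequence, "")[[1]]
  p_hat <- mean(res %in% c("K", "R"))
  se <- sqrt(0.10 * 0.90 / 320)
  expect_lte(abs(p_hat - 0.10), 3 * se)
})

test_that("an infeasible phosphosite count is rejected", {
  cfg <- sim_config(seed = 2, protein_length = 12, n_phospho_sites = 10)
  expect_error(simulate_protein(cfg), "S/T/Y positions")
})

test_that("observed masses are exact without noise and biased with bias", {
  cfg0 <- sim_config(seed = 9, mass_noise_sd = 0)
  sim <- simulate_protein(cfg0)
  frags <- digest_sequence(sim$protein$sequence,
                           cleavage_rule_preset("trypsin"), 0)
  ions <- simulate_observed_masses(sim$truth, frags, cfg0)
  for (i in seq_len(nrow(ions))) {
    seq_i <- frags$sequence[frags$name == ions$name[i]]
    expect_equal(ions$mass[i], modified_mh(seq_i, ions$k_true[i]))
  }

  # a +1.2 Da calibration bias still yields the true count at tol 1.5
  cfgb <- sim_config(seed = 9, mass_noise_sd = 0, mass_bias = 1.2)
  ionsb <- simulate_observed_masses(sim$truth, frags, cfgb)
  for (i in seq_len(nrow(ionsb))) {
    seq_i <- frags$sequence[frags$name == ionsb$name[i]]
    diff <- ionsb$mass[i] - peptide_mh(seq_i)
    expect_equal(infer_phospho_count(diff, tol = 1.5), ionsb$k_true[i])
  }
})

test_that("mass noise has the configured spread", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_protein(cfg)
  frags <- digest_sequence(sim$protein$sequence,
                           cleavage_rule_preset("trypsin"), 0)
  resid <- unlist(lapply(1:200, function(r) {
    ions <- simulate_observed_masses(sim$truth, frags, cfg,
                                     seed = cfg$seed + r)
    vapply(seq_len(nrow(ions)), function(i) {
      seq_i <- frags$sequence[frags$name == ions$name[i]]
      ions$mass[i] - modified_mh(seq_i, ions$k_true[i])
    }, numeric(1))
  }))
  expect_gte(length(resid), 1000)
  expect_gte(sd(resid), 0.04)
  expect_lte(sd(resid), 0.06)
})

test_that("fully mutated fragments contribute no signal; background has no peaks", {
  cfg <- sim_config(seed = 4)
  sim <- simulate_protein(cfg)
  frags <- digest_sequence(sim$protein$sequence,
                           cleavage_rule_preset("trypsin"), 0)
  tr <- simulate_trace(sim$truth, frags, cfg,
                       mutated_positions = sim$truth$sites$position)
  expect_equal(nrow(attr(tr, "truth")), 0)

  for (s in 1:5) {
    cfg0 <- sim_config(seed = 100 + s, n_phospho_sites = 0)
    sim0 <- simulate_protein(cfg0)
    frags0 <- digest_sequence(sim0$protein$sequence,
                              cleavage_rule_preset("trypsin"), 0)
    tr0 <- simulate_trace(sim0$truth, frags0, cfg0)
    expect_equal(nrow(detect_peaks(tr0)), 0, info = s)
  }
})

test_that("retention shifts earlier with phosphate count and stays in range", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_protein(cfg)
  frags <- digest_sequence(sim$protein$sequence,
                           cleavage_rule_preset("trypsin"), 0)
  r0 <- fragment_retention(frags, cfg, k = 0)
  r2 <- fragment_retention(frags, cfg, k = 2)
  expect_true(all(r2 <= r0))
  expect_true(all(r0 >= 1 & r0 <= cfg$fractions))
})

test_that("knockout experiments mark the targeted peak absent end to end", {
  ev <- evaluate_absent_calls(40, sim_config(seed = 900))
  expect_gte(ev$sensitivity, 0.9)
  expect_gte(ev$specificity, 0.9)
  expect_gt(ev$tp, 0)
})

test_that("the scaffold scenario reproduces the major-peptide peak loss", {
  sc <- ttp_scenario(seed = 8)
  wt <- sc$traces[["WT"]]
  mut <- sc$traces[["S(88,90,93,197,214,218,228,296)A"]]
  calls <- diff_traces(wt, mut)
  t5_center <- fragment_retention(
    sc$fragments, sim_config(seed = 8), 0)[sc$fragments$name == "T5"] -
    3 * sim_config()$phospho_shift_per_site
  near <- which.min(abs(calls$apex - t5_center))
  expect_equal(calls$status[near], "absent")

  self <- diff_traces(wt, sc$traces[["S197A"]])
  expect_true(any(self$status != "absent"))
})
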