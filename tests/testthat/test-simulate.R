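# Synthetic-data generator: scale, statistical structure, round-trips.

test_that("the energy generator produces the full 1400-model scan", {
  rec <- generate_energy_tables(synthetic_config(seed = 2))
  expect_identical(nrow(rec), 1400L)
  expect_identical(length(unique(rec$template)), 5L)
  expect_identical(sum(rec$state == "inactive"), 2L * 280L)
  # identity substitutions scatter around zero
  self <- rec$ddg_total[rec$wt_aa == rec$mut_aa]
  expect_identical(length(self), 5L * 14L)
  expect_lt(abs(mean(self)), 0.2)
})

test_that("within-state template correlations match the configured level", {
  cfg <- synthetic_config(seed = 3, within_state_correlation = 0.8)
  m <- pairwise_state_correlation(generate_energy_tables(cfg))
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_equal(m, t(m))
  s <- state_correlation_summary(m)
  # 280 shared mutations: sampling error on r = 0.8 is ~0.02-0.03
  expect_equal(s$mean_within, 0.8, tolerance = 0.1)
  expect_gt(s$mean_within, s$mean_cross)
})

test_that("synthetic ensembles respect the presence shape and round-trip", {
  cfg <- synthetic_config(seed = 4)
  # presence 1 everywhere: every residue in every file
  cfg_full <- cfg
  cfg_full$presence_shape[] <- 1
  files <- generate_structure_ensemble(cfg_full, n_structures = 5)
  obs <- read_ensemble_residues(files, 590:620)
  expect_true(all(obs$resolved))
  # binomial presence at residue 600 (configured 0.70)
  files <- generate_structure_ensemble(cfg, n_structures = 300)
  prof <- presence_profile(read_ensemble_residues(files, 597:615))
  p600 <- prof$presence_fraction[prof$residue_number == 600]
  se <- sqrt(0.7 * 0.3 / 300)
  expect_lt(abs(p600 - 0.70), 3 * se)
  # flexibility coupling: rarely-solved residues run hotter
  expect_gt(stats::cor(1 - prof$presence_fraction, prof$mean_norm_bfactor),
            0.5)
})

test_that("energy tables round-trip through write/read exactly", {
  cfg <- synthetic_config(seed = 6)
  rec <- generate_energy_tables(cfg)
  attr(rec, "truth") <- NULL
  path <- tempfile(fileext = ".tsv")
  write_ddg_table(rec, path)
  back <- read_ddg_table(path, c(`4MNE` = "active", `3OG7` = "active",
                                 `4MNF` = "active", `4EHE` = "inactive",
                                 `3TV6` = "inactive"))
  expect_identical(back[, names(rec)], rec)
})

test_that("zero weights give i.i.d. Poisson counts at the base rate", {
  cfg <- synthetic_config(seed = 7)
  cfg$true_feature_weights[] <- 0
  cfg$accessibility_gate <- 1
  sim_feat <- simulate_pocket_study(synthetic_config(seed = 7))$features
  freq <- generate_frequencies(sim_feat, cfg)
  expect_equal(unique(freq$lambda), exp(cfg$count_intercept))
  # mean of 280 Poisson(e) draws
  expect_lt(abs(mean(freq$count) - exp(1)), 3 * sqrt(exp(1) / 280))
})

test_that("the dominant loop-energy weight shows up as the top count association", {
  sim <- simulate_pocket_study(synthetic_config(seed = 8))
  fcols <- grep("^f[1-7]_", names(sim$features), value = TRUE)
  rho <- vapply(fcols, function(f)
    abs(stats::cor(sim$features[[f]], sim$features$count,
                   method = "spearman")), numeric(1))
  expect_identical(names(which.max(rho)), "f3_loop_destab")
})

test_that("the highest expected rate goes to hotspot-like mutations", {
  # property over seeds: the rate maximum always combines a top-5% corrected
  # loop energy with few base substitutions
  for (s in 1:10) {
    sim <- simulate_pocket_study(synthetic_config(seed = s))
    i <- match(sim$features$mutation,
               with(sim$frequencies, paste0(wt_aa, position, mut_aa)))
    top <- which.max(sim$frequencies$lambda[i])
    f3 <- sim$features$f3_loop_destab
    expect_gte(mean(f3 <= f3[top]), 0.95)
    expect_lte(sim$features$f4_nt_substitutions[top], 2L)
  }
  # worked example at the study seed: the winner is a single-base charged
  # substitution at a well-resolved segment position with the maximal
  # corrected loop energy — the V600E pattern
  sim <- simulate_pocket_study(synthetic_config(seed = 42))
  i <- match(sim$features$mutation,
             with(sim$frequencies, paste0(wt_aa, position, mut_aa)))
  top <- which.max(sim$frequencies$lambda[i])
  expect_identical(sim$features$f4_nt_substitutions[top], 1L)
  expect_identical(which.max(sim$features$f3_loop_destab), top)
  expect_identical(which.max(sim$features$count), top)
})

test_that("the full simulation is deterministic given its seed", {
  s1 <- simulate_pocket_study(synthetic_config(seed = 9))
  s2 <- simulate_pocket_study(synthetic_config(seed = 9))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$features, s2$features)
  s3 <- simulate_pocket_study(synthetic_config(seed = 10))
  expect_false(identical(s1$features$count, s3$features$count))
})
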