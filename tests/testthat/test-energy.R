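# ddG table parsing, corrections and the composite activation score.

test_that("ddG tables parse with states assigned from the template map", {
  tab <- data.frame(
    template = c("4EHE", "4MNE", "4EHE"),
    position = c(600L, 600L, 600L), wt_aa = "V",
    mut_aa = c("E", "E", "V"),
    ddg_total = c(2.5, 0.4, 0.0), ddg_solvh = c(1.1, 0.2, 0.0))
  path <- tempfile(fileext = ".tsv")
  write_ddg_table(tab, path)
  rec <- read_ddg_table(path, c(`4EHE` = "inactive", `4MNE` = "active"))
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$state, c("inactive", "active", "inactive"))
  # self-substitution control row parses like any other
  expect_equal(rec$ddg_total[rec$mut_aa == "V"], 0.0)
  # near-zero energies survive the round trip exactly (e.g. a 0.04 E600A-like row)
  tab$ddg_total[2] <- 0.04
  write_ddg_table(tab, path)
  rec <- read_ddg_table(path, c(`4EHE` = "inactive", `4MNE` = "active"))
  expect_identical(rec$ddg_total[2], 0.04)
  expect_error(read_ddg_table(path, c(`4EHE` = "inactive")), "state map")
  tab$ddg_total <- NULL
  write_ddg_table(tab, path)
  expect_error(read_ddg_table(path, c(`4EHE` = "inactive", `4MNE` = "active")),
               "required column")
})

test_that("mutation-space enumeration covers positions x 20 x templates", {
  full <- enumerate_mutation_space(templates = c("4MNE", "3OG7", "4MNF",
                                                 "4EHE", "3TV6"))
  expect_identical(nrow(full), 1400L)
  one <- enumerate_mutation_space(braf_pocket_reference()[1, ], "T1")
  expect_identical(nrow(one), 20L)
  expect_identical(sum(one$wt_aa == one$mut_aa), 1L)
  none <- enumerate_mutation_space(templates = character(0))
  expect_identical(nrow(none), 0L)
})

test_that("destabilization threshold is strict", {
  expect_false(classify_destabilizing(0.80))
  expect_true(classify_destabilizing(0.80 + 1e-9))
  expect_true(classify_destabilizing(0.81))
  expect_false(classify_destabilizing(-1.0))
  cfg <- energy_config(destabilization_threshold = 2)
  expect_false(classify_destabilizing(1.5, cfg))
})

test_that("state averages are plain means over a state's templates", {
  rec <- make_energy_records(positions = 600L, wt = "V", mut_aas = "E",
                             templates = c(I1 = "inactive", I2 = "inactive",
                                           A1 = "active"))
  rec$ddg_total <- c(1.0, 3.0, 5.0)[match(rec$template, c("I1", "I2", "A1"))]
  expect_equal(state_average(rec, 600L, "V", "E", "inactive"), 2.0)
  expect_equal(state_average(rec, 600L, "V", "E", "active"), 5.0)
  expect_error(state_average(rec, 601L, "K", "E", "active"), "no active")
})

test_that("loop presence correction scales only inactive loop energies", {
  prof <- flat_profile(1)
  expect_equal(loop_presence_correction(2.0, 600L, prof), 2.0)
  prof$presence_fraction[prof$residue_number == 600] <- 0.70
  expect_equal(loop_presence_correction(2.0, 600L, prof), 1.4)
  # active-state energies are never corrected
  expect_equal(loop_presence_correction(2.0, 600L, prof, state = "active"), 2.0)
  # non-loop positions pass through
  expect_equal(loop_presence_correction(2.0, 487L, prof), 2.0)
  # magnitude can only shrink
  for (p in seq(0, 1, by = 0.25)) {
    prof$presence_fraction[] <- p
    expect_lte(abs(loop_presence_correction(-3, 599L, prof)), 3)
  }
  expect_error(loop_presence_correction(1, 610L, prof[1:3, ]), "no entry")
})

test_that("salt-bridge correction targets phosphomimetics, never 600", {
  cfg <- energy_config(saltbridge_value = -2)
  expect_equal(saltbridge_correction(599L, "E", cfg), -2)
  expect_equal(saltbridge_correction(599L, "D", cfg), -2)
  expect_equal(saltbridge_correction(601L, "E", cfg), -2)
  expect_equal(saltbridge_correction(602L, "D", cfg), -2)
  expect_equal(saltbridge_correction(600L, "E", cfg), 0)
  expect_equal(saltbridge_correction(599L, "K", cfg), 0)
  expect_equal(saltbridge_correction(487L, "E", cfg), 0)
  # even if 600 is configured as a salt-bridge position it stays excluded
  cfg2 <- energy_config(saltbridge_positions = c(599L, 600L))
  expect_equal(saltbridge_correction(600L, "E", cfg2), 0)
})

test_that("activation score combines loop, active and solvation terms", {
  expect_equal(activation_score(0, 0, 0), 0)
  expect_equal(activation_score(2.0, 0.5, -0.3), 1.2)
  # a favorable salt bridge on the active term raises the score
  expect_equal(activation_score(2.0, 0.5, -0.3, saltbridge = -2), 3.2)
  expect_error(activation_score(NA, 0, 0), "is.finite")
})

test_that("energy summaries: self controls never destabilizing, score ranks", {
  cfg <- energy_config()
  rec <- make_energy_records(positions = c(600L, 487L), wt = c("V", "V"),
                             mut_aas = c("E", "V"),
                             templates = c(A1 = "active", I1 = "inactive"))
  # V600E: strong inactive destabilization, mild active; V->V self: zero
  rec$ddg_total <- ifelse(rec$mut_aa == "V", 0,
                          ifelse(rec$state == "inactive", 3.0, 0.4))
  rec$ddg_solvh <- ifelse(rec$mut_aa == "V", 0, 1.0)
  prof <- flat_profile(0.70)
  s <- summarize_energies(rec, prof, cfg)
  self <- s[s$mut_aa == "V", ]
  expect_true(all(!self$destabilizing_inactive))
  expect_true(all(!self$destabilizing_active))
  expect_equal(self$activation_score, c(0, 0))
  v600e <- s[s$position == 600 & s$mut_aa == "E", ]
  expect_true(v600e$destabilizing_inactive)
  expect_false(v600e$destabilizing_active)
  # loop energy corrected by presence at 600; non-loop 487 untouched
  expect_equal(v600e$loop_energy_corrected, 3.0 * 0.70)
  expect_equal(v600e$activation_score, 3.0 * 0.70 - 0.4 + 1.0)
  v487e <- s[s$position == 487 & s$mut_aa == "E", ]
  expect_equal(v487e$loop_energy, 0)  # no loop decomposition, not a loop position
  # the activating loop mutation outranks the folding-destabilizing one
  expect_gt(v600e$activation_score, v487e$activation_score)
})

test_that("phenotype correlation handles linear, anti-linear and degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_with_phenotype(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_with_phenotype(x, -x)$r, -1)
  out <- correlate_with_phenotype(x, c(2, 1, 4, 3))
  expect_equal(out$r_squared, out$r^2)
  expect_error(correlate_with_phenotype(x, rep(1, 4)), "zero variance")
  expect_error(correlate_with_phenotype(1:2, 1:2), "at least 3")
})
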