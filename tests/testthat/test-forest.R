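# Balanced splits, forest fitting, run evaluation and the full protocol.

toy_features <- function(n = 60, seed = 2) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * 7), n,
                            dimnames = list(NULL, c(
                              "f1_inactive_destab", "f2_active_destab",
                              "f3_loop_destab", "f4_nt_substitutions",
                              "f5_usage_delta", "f6_saltbridge",
                              "f7_solvh_delta"))))
  x$count <- rep(c(0L, 7L), length.out = n)
  x$response <- x$f3_loop_destab + 0.5 * x$f1_inactive_destab +
    rnorm(n, sd = 0.2)
  x$mutation <- paste0("M", seq_len(n))
  x
}

test_that("balanced split samples 70% of each frequency stratum", {
  count <- rep(c(0L, 9L), each = 10)
  set.seed(1)
  sp <- balanced_split(count, forest_config())
  expect_identical(length(sp$train), 14L)
  expect_identical(length(sp$test), 6L)
  expect_identical(sum(count[sp$train] == 0), 7L)
  expect_identical(sum(count[sp$train] > 0), 7L)
  expect_identical(sort(c(sp$train, sp$test)), 1:20)
  # deterministic under a seed
  set.seed(99); a <- balanced_split(count, forest_config())
  set.seed(99); b <- balanced_split(count, forest_config())
  expect_identical(a, b)
  expect_error(balanced_split(rep(0L, 10), forest_config()), "stratum")
})

test_that("the hotspot can be forced into or out of the training set", {
  count <- c(rep(0L, 10), rep(3L, 9), 1000L)
  for (i in 1:25) {
    sp_in <- balanced_split(count, forest_config(), hotspot_index = 20L,
                            include_hotspot = TRUE)
    expect_true(20L %in% sp_in$train)
    sp_out <- balanced_split(count, forest_config(), hotspot_index = 20L,
                             include_hotspot = FALSE)
    expect_false(20L %in% sp_out$train)
    expect_true(20L %in% sp_out$test)
  }
})

test_that("a constant training response yields a degenerate zero-importance fit", {
  x <- toy_features(20)[, 1:7]
  expect_warning(fit <- fit_forest(x, rep(1, 20)), "constant training response")
  expect_true(all(fit$importance == 0))
  expect_equal(predict(fit, x), rep(1, 20))
})

test_that("a single informative feature gets the top importance", {
  ft <- toy_features(n = 200, seed = 4)
  y <- ft$f3_loop_destab  # response IS feature 3
  set.seed(8)
  fit <- fit_forest(ft[, 1:7], y)
  expect_true(all(fit$importance >= 0))
  expect_identical(names(which.max(fit$importance)), "f3_loop_destab")
})

test_that("run evaluation reports correlation, RMSD and their ratio", {
  ft <- toy_features(n = 80, seed = 6)
  set.seed(10)
  fit <- fit_forest(ft[1:60, 1:7], ft$response[1:60])
  ev <- evaluate_run(fit, ft[61:80, 1:7], ft$response[61:80])
  expect_gt(ev$correlation, 0.5)
  expect_gt(ev$rmsd, 0)
  expect_equal(ev$performance, ev$correlation / ev$rmsd)
  expect_error(evaluate_run(fit, ft[61:62, 1:7], ft$response[61:62]),
               ">= 3 test rows")
  # constant predictions (degenerate fit) leave the correlation undefined
  suppressWarnings(degen <- fit_forest(ft[1:20, 1:7], rep(2, 20)))
  expect_error(evaluate_run(degen, ft[61:80, 1:7], ft$response[61:80]),
               "undefined correlation")
})

test_that("the protocol runs both sets, normalizes importances to 100", {
  ft <- toy_features(n = 40)
  cfg <- forest_config(n_runs = 2, hotspot = "M2")
  pr <- run_protocol(ft, cfg, seed = 3)
  expect_s3_class(pr, "forest_protocol")
  expect_identical(nrow(pr$runs), 4L)
  expect_identical(sort(unique(pr$runs$set)),
                   c("with_hotspot", "without_hotspot"))
  expect_equal(unname(rowSums(pr$mean_importance_pct)), c(100, 100),
               tolerance = 1e-9)
  expect_true(all(pr$mean_importance_pct >= 0))
  s <- summary(pr)
  expect_identical(nrow(s$performance), 2L)
})

test_that("the protocol is bit-reproducible from its master seed", {
  ft <- toy_features(n = 40)
  cfg <- forest_config(n_runs = 3, hotspot = "M2")
  pr1 <- run_protocol(ft, cfg, seed = 11)
  pr2 <- run_protocol(ft, cfg, seed = 11)
  expect_identical(pr1, pr2)
  pr3 <- run_protocol(ft, cfg, seed = 12)
  expect_false(identical(pr1$runs, pr3$runs))
})
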