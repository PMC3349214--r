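small_exp_spec <- function(reps = 2, seed = 5) {
  experiment_spec(
    repetitions = reps, dims = c(48, 48, 14), seed = seed,
    ranges = param_ranges(lower = c(-8, -8, -4, -5, -5, -5),
                          upper = c(8, 8, 4, 5, 5, 5)),
    ga_cfg = ga_config(pop = 15, max_generations = 12, stall_generations = 6,
                       ranges = param_ranges(lower = c(-8, -8, -4, -5, -5, -5),
                                             upper = c(8, 8, 4, 5, 5, 5))),
    sx_cfg = simplex_config(max_iter = 40)
  )
}

test_that("random misalignments are uniform within their ranges", {
  rng <- param_ranges()
  set.seed(123)
  draws <- t(replicate(1e4, as.numeric(random_misalignment(rng))))
  expect_true(all(t(draws) >= rng$lower & t(draws) <= rng$upper))
  # mean of U(-40, 40) is 0 with sd 80/sqrt(12); 3-sigma band on the mean
  se <- (80 / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(mean(draws[, 1])), 3 * se)
  # degenerate ranges give exactly zero
  zero <- random_misalignment(param_ranges(lower = rep(0, 6), upper = rep(0, 6)))
  expect_equal(as.numeric(zero), rep(0, 6))
  # identical RNG state, identical draw
  set.seed(9); a <- random_misalignment(rng)
  set.seed(9); b <- random_misalignment(rng)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("signed registration error is the residual of composed transforms", {
  ctr <- c(20, 20, 10)
  applied <- rigid_params(5, -3, 2, 4, -6, 10)
  # the exact inverse transform has zero residual everywhere
  inv <- decompose_matrix(solve(compose_matrix(applied, ctr)), ctr)
  err <- cardalign:::registration_error(inv, applied, ctr)
  expect_equal(err, rep(0, 6), tolerance = 1e-8)
  # a pure extra translation shows up as exactly that signed error
  offb <- as.numeric(inv) + c(1.5, 0, 0, 0, 0, 0)
  err2 <- cardalign:::registration_error(offb, applied, ctr)
  expect_equal(err2[1], 1.5, tolerance = 1e-8)
})

test_that("accuracy experiment records runs and summarizes them consistently", {
  res <- accuracy_experiment(small_exp_spec())
  expect_s3_class(res, "error_summary")
  expect_equal(nrow(res$runs), 2)
  expect_equal(res$summary$parameter, c("tx", "ty", "tz", "rx", "ry", "rz"))
  # summaries are pure functions of the per-run records
  err <- as.matrix(res$runs[, paste0("error_", res$summary$parameter)])
  expect_equal(res$summary$mean_abs_error, unname(colMeans(abs(err))))
  expect_equal(res$summary$sd_error, unname(apply(err, 2, sd)))
  # per-run seeds recorded and distinct
  expect_equal(length(unique(res$runs$seed)), 2)
})

test_that("a recorded run can be replayed in isolation from its seed", {
  spec <- small_exp_spec(reps = 2, seed = 8)
  res <- accuracy_experiment(spec)
  ct <- make_ct_phantom(spec$ct_spec)
  replay <- cardalign:::run_one_registration(ct, spec, "combined",
                                             res$runs$seed[2], 2L)
  expect_equal(as.numeric(replay[1, colnames(res$runs)]),
               as.numeric(res$runs[2, ]))
})

test_that("experiment uses identical misalignment draws across methods", {
  spec <- small_exp_spec(reps = 2, seed = 21)
  cmp <- optimizer_comparison(spec)
  expect_named(cmp, c("simplex", "ga", "combined"))
  app <- paste0("applied_", c("tx", "ty", "tz", "rx", "ry", "rz"))
  expect_equal(cmp$simplex$runs[, app], cmp$combined$runs[, app])
  expect_equal(cmp$ga$runs[, app], cmp$combined$runs[, app])
})

test_that("df_selection_study returns one SI per (df, parameter) with argmax", {
  spec <- experiment_spec(dims = c(40, 40, 12), df_grid = c(1.37, 8), seed = 2)
  st <- df_selection_study(spec, range = 4, step = 1)
  expect_equal(nrow(st$table), 12)
  expect_equal(nrow(st$argmax), 6)
  expect_true(all(st$argmax$best_df %in% c(1.37, 8)))
  # single-DF grid returns that DF for every parameter
  st1 <- df_selection_study(experiment_spec(dims = c(40, 40, 12),
                                            df_grid = 3.375, seed = 2),
                            range = 3, step = 1.5)
  expect_true(all(st1$argmax$best_df == 3.375))
})

test_that("experiment_spec validates and exposes the paper-scale profile", {
  expect_error(experiment_spec(repetitions = 0), "repetitions")
  expect_error(experiment_spec(df_grid = c(-1, 2)), "positive")
  ps <- experiment_spec(profile = "paper")
  expect_equal(ps$dims, c(256L, 256L, 55L))
  expect_equal(ps$repetitions, 150L)
  expect_equal(ps$ct_spec$dims, c(256L, 256L, 55L))
})
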