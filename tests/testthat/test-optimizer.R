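test_that("roulette selection follows fitness proportions", {
  set.seed(101)
  # exactly one nonzero score -> always that index
  expect_true(all(replicate(50, roulette_select(c(0, 0, 3, 0))) == 3))

  # equal scores: uniform within a 3-sigma binomial band at 1e4 draws
  draws <- replicate(1e4, roulette_select(rep(2, 4)))
  freq <- tabulate(draws, 4) / 1e4
  band <- 3 * sqrt(0.25 * 0.75 / 1e4)
  expect_true(all(abs(freq - 0.25) < band))

  # 3:1 scores -> 0.75 / 0.25 within 3 sigma
  draws2 <- replicate(1e4, roulette_select(c(3, 1)))
  f1 <- mean(draws2 == 1)
  expect_lt(abs(f1 - 0.75), 3 * sqrt(0.75 * 0.25 / 1e4))

  expect_error(roulette_select(numeric(0)), "empty")
  expect_error(roulette_select(c(1, NaN)), "finite")
})

test_that("crossover takes a prefix from one parent and the rest from the other", {
  a <- rigid_params(1, 2, 3, 4, 5, 6)
  b <- rigid_params(10, 20, 30, 40, 50, 60)
  set.seed(5)
  for (i in 1:50) {
    child <- as.numeric(ga_crossover(a, b))
    k <- sum(child == as.numeric(a)[1:6] & child < 10)
    expect_true(k >= 1 && k <= 5)
    expect_equal(child, c(as.numeric(a)[seq_len(k)], as.numeric(b)[(k + 1):6]))
  }
  # identical parents reproduce themselves for any cut
  same <- ga_crossover(a, a)
  expect_equal(as.numeric(same), as.numeric(a))
})

test_that("mutation changes at most one gene and respects its range", {
  rng <- param_ranges()
  chrom <- rigid_params(1, 2, 3, 4, 5, 6)
  set.seed(6)
  for (i in 1:200) {
    m <- as.numeric(ga_mutate(chrom, rng))
    expect_lte(sum(m != as.numeric(chrom)), 1)
    expect_true(all(m >= rng$lower - 1e-12 & m <= rng$upper + 1e-12))
  }
  # degenerate range pins the mutated gene to its fixed value
  rng0 <- param_ranges(lower = rep(0, 6), upper = rep(0, 6))
  m0 <- as.numeric(ga_mutate(rigid_params(), rng0))
  expect_equal(m0, rep(0, 6))
})

test_that("GA bookkeeping: elitism trace and population accounting", {
  cfg <- ga_config(pop = 20, ranges = param_ranges(lower = rep(-10, 6),
                                                   upper = rep(10, 6)),
                   max_generations = 8, stall_generations = 50)
  # fraction accounting for admissible (pe, pc)
  for (pe in c(0.1, 0.25, 0.5)) {
    for (pc in c(0.2, 0.6)) {
      if (pe + pc > 1) next
      c2 <- ga_config(pop = 21, pe = pe, pc = pc)
      n_elite <- ceiling(pe * 21)
      n_cross <- round(pc * 21)
      expect_lte(n_elite + n_cross, 21)
      expect_equal(c2$pe + c2$pc + c2$pm, 1)
    }
  }
  set.seed(9)
  res <- ga_optimize(tiny_ct(), tiny_pet(), cfg)
  expect_s3_class(res, "registration_result")
  expect_true(all(diff(res$ga_trace$best) >= 0))
  expect_gte(res$mi, 0)
})

test_that("simplex refinement recovers a small known offset", {
  ref <- mid_ct()
  flt <- mid_pet()
  # misalign the PET by -2 mm in x: the optimum of the refine is near tx = 2
  mis <- apply_rigid(flt, rigid_params(tx = -2))
  res <- simplex_refine(ref, mis, start = rigid_params(),
                        cfg = simplex_config(max_iter = 120))
  expect_lt(abs(as.numeric(res$estimated)[1] - 2), 0.5)
  # greedy: final MI never below the start's
  eng_mi <- mi_similarity(ref, resample_by_df(mis, 3.375), rigid_params(),
                          scheme = "pv", center = volume_center(ref))
  expect_gte(res$mi, eng_mi - 1e-12)
})

test_that("simplex started at the optimum stays there", {
  ref <- mid_ct()
  flt <- mid_pet()
  res <- simplex_refine(ref, flt, start = rigid_params(),
                        cfg = simplex_config(max_iter = 80))
  expect_lt(max(abs(as.numeric(res$estimated))), 1)
})

test_that("our simplex agrees with optim's Nelder-Mead on a smooth objective", {
  # independent cross-check of the local optimizer machinery on a quadratic
  # surrogate: both should find the same maximum
  f <- function(p) -sum((as.numeric(p) - c(1, -2, 0.5, 3, -1, 2))^2)
  ours <- cardalign:::nm_maximize(f, rep(0, 6), init_step = 2,
                                  param_tol = 1e-6, f_tol = 1e-12,
                                  max_iter = 500)
  ref <- stats::optim(rep(0, 6), function(x) -f(x), method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(ours$par, c(1, -2, 0.5, 3, -1, 2), tolerance = 1e-3)
  expect_equal(ours$par, ref$par, tolerance = 1e-2)
})

test_that("registration is deterministic under a fixed seed", {
  ref <- tiny_ct()
  flt <- tiny_pet()
  cfg <- ga_config(pop = 12, max_generations = 5, stall_generations = 10,
                   ranges = param_ranges(lower = rep(-5, 6), upper = rep(5, 6)))
  scfg <- simplex_config(max_iter = 15)
  r1 <- register_volumes(ref, flt, cfg, scfg, seed = 77)
  r2 <- register_volumes(ref, flt, cfg, scfg, seed = 77)
  expect_identical(as.numeric(r1$estimated), as.numeric(r2$estimated))
  expect_identical(r1$mi, r2$mi)
  expect_identical(r1$ga_trace, r2$ga_trace)
  # combined never loses MI against its own GA stage (PV vs NN differ, so
  # compare within the result: simplex trace is non-decreasing)
  expect_true(all(diff(r1$simplex_trace$best) >= 0))
})

test_that("tidy and glance summarize registration results", {
  ref <- tiny_ct()
  flt <- tiny_pet()
  res <- register_volumes(ref, flt,
                          ga_config(pop = 8, max_generations = 3,
                                    ranges = param_ranges(lower = rep(-5, 6),
                                                          upper = rep(5, 6))),
                          simplex_config(max_iter = 10), seed = 3)
  td <- tidy(res)
  expect_equal(td$parameter, c("tx", "ty", "tz", "rx", "ry", "rz"))
  expect_equal(td$unit, rep(c("mm", "degrees"), each = 3))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$seed, 3L)
  expect_gte(gl$mi, gl$ga_mi * 0) # both present and numeric
})

test_that("sn_score normalizes by the per-vector maxima", {
  expect_equal(sn_score(2, 10), 2)                   # single setting
  expect_equal(sn_score(c(2, 4), c(10, 5)), c(1.5, 1.5))
  s <- sn_score(c(1, 5, 3), c(2, 4, 8))
  expect_equal(which.min(s), 1L)                     # best on both axes wins
  expect_equal(sn_score(c(0, 0), c(0, 0)), c(0, 0))  # all-zero: divide by 1
  expect_error(sn_score(c(1, 2), 1), "equal-length")
  expect_error(sn_score(-1, 1), "nonnegative")
})
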