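test_that("hand-computable histograms give exact MI values", {
  expect_equal(mutual_information(matrix(c(2, 0, 0, 2), 2)), 1)
  # outer-product histogram (independent marginals) carries zero information
  h <- outer(c(1, 2, 3), c(4, 1, 2))
  expect_equal(mutual_information(h), 0, tolerance = 1e-12)
  expect_error(mutual_information(matrix(0, 2, 2)), "zero")
  expect_error(mutual_information(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("MI of a volume with itself equals its binned marginal entropy", {
  vol <- tiny_ct()
  labs <- cardalign:::bin_labels(vol$intensities, 64)$labels
  p <- tabulate(labs + 1L, 64)
  p <- p[p > 0] / sum(p)
  expect_equal(mi_similarity(vol, vol, scheme = "nn"), -sum(p * log2(p)),
               tolerance = 1e-12)
})

test_that("PV equals NN at on-grid alignment and GPVE order 1 equals PV", {
  ref <- tiny_ct()
  flt <- tiny_pet()
  h_nn <- joint_histogram(ref, flt, scheme = "nn")
  h_pv <- joint_histogram(ref, flt, scheme = "pv")
  expect_identical(h_pv$weights, h_nn$weights)

  p <- rigid_params(tx = 2.31, ty = -1.2, rz = 4)
  h_pv2 <- joint_histogram(ref, flt, p, scheme = "pv")
  h_g1 <- joint_histogram(ref, flt, p, scheme = "gpve",
                          spline_orders = c(1, 1, 1))
  expect_equal(h_g1$weights, h_pv2$weights, tolerance = 1e-12)
})

test_that("single off-grid voxel splits its PV weight with trilinear fractions", {
  ref <- volume_grid(array(rep(c(0, 1), 4), c(2, 2, 2))) # alternates along x
  flt <- volume_grid(array(5, c(1, 1, 1)), origin = c(0.5, 0, 0))
  h <- joint_histogram(ref, flt, scheme = "pv", bins = 2)
  expect_equal(h$total, 1)
  expect_equal(sort(h$weights[h$weights > 0]), c(0.5, 0.5))
})

test_that("histogram weight is conserved under random transforms", {
  ref <- tiny_ct()
  flt <- tiny_pet()
  set.seed(7)
  for (i in 1:5) {
    p <- rigid_params(runif(1, -8, 8), runif(1, -8, 8), runif(1, -3, 3),
                      runif(1, -10, 10), runif(1, -10, 10), runif(1, -10, 10))
    for (scheme in c("nn", "pv", "gpve")) {
      h <- joint_histogram(ref, flt, p, scheme = scheme)
      expect_true(all(h$weights >= 0))
      # total = whole-weight count of contributing voxels
      expect_equal(h$total, round(h$total), tolerance = 1e-6)
      expect_lte(h$total, prod(flt$dims))
    }
  }
})

test_that("empty overlap raises an explicit error", {
  ref <- tiny_ct()
  flt <- tiny_pet()
  expect_error(joint_histogram(ref, flt, rigid_params(tx = 1000)),
               "overlap")
})

test_that("MI is nearly symmetric in the image pair", {
  ref <- mid_ct()
  flt <- mid_pet()
  p <- rigid_params(tx = 3, ty = -2, rz = 5)
  ctr <- volume_center(ref)
  mi_fwd <- mi_similarity(ref, flt, p, scheme = "pv")
  pinv <- decompose_matrix(solve(compose_matrix(p, ctr)), ctr)
  mi_bwd <- mi_similarity(flt, ref, pinv, scheme = "pv")
  expect_lt(abs(mi_fwd - mi_bwd) / mi_fwd, 0.02)
})

test_that("registered phantom profiles peak at (or adjacent to) zero", {
  ref <- mid_ct()
  flt <- mid_pet()
  for (par in c("tx", "rz")) {
    prof <- mi_profile(ref, flt, par, range = 10, step = 0.5, scheme = "pv",
                       df = 1.37)
    expect_lte(abs(prof$position[which.max(prof$mi)]), 0.5)
  }
})

test_that("smoothness index matches the exact quadratic result", {
  # samples of c*alpha^2 on unit-spaced positions: every interior second
  # difference equals 2c, so SI = 1 / (K * |2c|)
  pos <- -5:5
  for (c in c(0.3, -1.7)) {
    prof <- data.frame(position = pos, mi = c * pos^2)
    K <- length(pos) - 2
    expect_equal(smoothness_index(prof), 1 / (K * abs(2 * c)))
  }
  # linear profile: zero curvature -> documented Inf sentinel
  lin <- data.frame(position = pos, mi = 2 * pos + 1)
  expect_identical(smoothness_index(lin), Inf)
  # a single spike strictly decreases SI
  base <- data.frame(position = pos, mi = 0.1 * pos^2)
  spiked <- base
  spiked$mi[6] <- spiked$mi[6] + 0.5
  expect_lt(smoothness_index(spiked), smoothness_index(base))
  expect_error(smoothness_index(data.frame(position = 1:2, mi = 1:2)), "3")
})

test_that("smoothness index accounts for the sampling step", {
  pos2 <- seq(-5, 5, by = 0.5)
  prof <- data.frame(position = pos2, mi = 0.3 * pos2^2)
  K <- length(pos2) - 2
  expect_equal(smoothness_index(prof), 1 / (K * 0.6))
})

test_that("profile export/import round-trips", {
  prof <- mi_profile(tiny_ct(), tiny_pet(), "tx", range = 2, step = 1,
                     scheme = "nn")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  got <- read_profile_csv(path)
  expect_equal(got$position, prof$position)
  expect_equal(got$mi, prof$mi, tolerance = 1e-12)
})
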