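test_that("phantom volumes honor requested geometry and are deterministic", {
  spec <- phantom_spec("ct", dims = c(256, 256, 55), seed = 5)
  expect_equal(spec$dims, c(256L, 256L, 55L))
  expect_equal(spec$spacing, c(1, 1, 1))

  a <- make_ct_phantom(tiny_ct_spec(seed = 9))
  b <- make_ct_phantom(tiny_ct_spec(seed = 9))
  expect_identical(a$intensities, b$intensities)
  expect_equal(a$dims, c(48L, 48L, 14L))

  c2 <- make_ct_phantom(tiny_ct_spec(seed = 10))
  expect_false(identical(a$intensities, c2$intensities))
})

test_that("zero blur and zero noise give exactly the piecewise-constant map", {
  spec <- phantom_spec("ct", dims = c(40, 40, 12), blur_sd = 0, noise_sd = 0)
  vol <- make_ct_phantom(spec)
  support <- sort(unique(as.numeric(vol$intensities)))
  expect_true(all(support %in% spec$tissues))
  # air, soft tissue, blood pool and both walls are all present
  expect_true(all(c(-1000, 40, 300, 110) %in% support))
})

test_that("noise variance matches the requested sd on a uniform region", {
  spec <- phantom_spec("ct", dims = c(64, 64, 20), blur_sd = 0, noise_sd = 7,
                       seed = 31)
  vol <- make_ct_phantom(spec)
  # with zero blur the air label region is exactly uniform before noise
  air <- vol$intensities[cardalign:::phantom_labels(spec) == 1L]
  expect_gt(length(air), 1e4)
  expect_equal(stats::var(air), 49, tolerance = 0.05)
  expect_equal(mean(air), -1000, tolerance = 1)
})

test_that("default blur SDs are 0.8 (CT) and 2.4 (PET), overridable", {
  expect_equal(phantom_spec("ct")$blur_sd, 0.8)
  expect_equal(phantom_spec("pet")$blur_sd, 2.4)
  expect_equal(phantom_spec("pet", blur_sd = 1.1)$blur_sd, 1.1)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec("ct", dims = c(0, 4, 4)), "dims")
  expect_error(phantom_spec("ct", spacing = c(1, -1, 1)), "spacing")
  expect_error(phantom_spec("ct", epi_axes = c(40, 40, 20),
                            endo_axes = c(45, 30, 10)), "inside")
  expect_error(phantom_spec("ct", noise_sd = -1), ">= 0")
  expect_error(make_pet_phantom(tiny_ct_spec()), "pet")
  expect_error(make_ct_phantom(tiny_pet_spec()), "ct")
})

test_that("fading field matches its closed form and bounds", {
  vol <- tiny_pet()
  # defect centre placed exactly on a voxel centre so g there is a_max
  ctr_idx <- c(24L, 24L, 7L)
  ctr <- vol$origin + (ctr_idx - 1) * vol$spacing
  fs <- fading_spec(center = ctr, a_max = 0.4, sigma = 10)
  g <- fading_field(vol, fs)
  expect_equal(g[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 0.4, tolerance = 1e-12)
  expect_true(all(g >= 0.4 - 1e-12 & g <= 1 + 1e-12))
  # 10 sigma away (outside grid corner direction) ~ 1
  far <- fading_field(volume_grid(array(0, c(2, 2, 2)),
                                  origin = fs$center + c(100, 100, 100)), fs)
  expect_equal(max(abs(far - 1)), 0, tolerance = 1e-15)

  # monotone in a_max at every voxel
  g2 <- fading_field(vol, fading_spec(ctr, 0.2, 10))
  expect_true(all(g2 <= g + 1e-12))

  expect_error(fading_spec(c(0, 0, 0), 0.5, sigma = 0), "sigma")
  expect_error(fading_spec(c(0, 0, 0), 1.2, sigma = 5), "a_max")
})

test_that("a_max = 1 reproduces the unfaded PET phantom exactly", {
  spec <- tiny_pet_spec(seed = 40)
  plain <- make_pet_phantom(spec)
  faded1 <- make_pet_phantom(spec, default_fading(spec, a_max = 1))
  expect_equal(faded1$intensities, plain$intensities, tolerance = 1e-14)
})

test_that("fading halves the blurred signal at the defect centre", {
  spec <- phantom_spec("pet", dims = c(48, 48, 14), noise_sd = 0, seed = 1)
  plain <- make_pet_phantom(spec)
  # defect centre snapped to a voxel centre inside the wall
  idx <- c(36L, 14L, 7L)
  ctr <- plain$origin + (idx - 1) * plain$spacing
  fs <- fading_spec(ctr, a_max = 0.5, sigma = 15)
  faded <- make_pet_phantom(spec, fs)
  expect_equal(faded$intensities[idx[1], idx[2], idx[3]],
               0.5 * plain$intensities[idx[1], idx[2], idx[3]],
               tolerance = 1e-12)
})

test_that("fading centre far outside the grid warns instead of failing", {
  spec <- tiny_pet_spec()
  fs <- fading_spec(center = c(500, 500, 500), a_max = 0.5, sigma = 20)
  expect_warning(make_pet_phantom(spec, fs), "outside")
})

test_that("zero-blur zero-noise CT histogram support equals the tissue table", {
  spec <- phantom_spec("ct", dims = c(36, 36, 12), blur_sd = 0, noise_sd = 0,
                       tissues = c(air = -1000, lung = -700, soft = 30,
                                   blood = 280, myocardium = 120,
                                   rv_myocardium = 105))
  vol <- make_ct_phantom(spec)
  expect_true(all(unique(as.numeric(vol$intensities)) %in% spec$tissues))
})

test_that("posed acquisitions place the heart where the transform says", {
  spec <- phantom_spec("pet", dims = c(96, 96, 40), noise_sd = 0, seed = 3)
  centroid <- function(v) {
    w <- pmax(v$intensities - 30, 0)
    idx <- which(w > 0, arr.ind = TRUE)
    unname(v$origin + (colSums(idx * w[w > 0]) / sum(w[w > 0]) - 1) * v$spacing)
  }
  base <- posed_pet_acquisition(spec, rigid_params())
  c0 <- centroid(base)
  # translation moves the centroid by exactly the translation
  sh <- posed_pet_acquisition(spec, rigid_params(tx = 7, ty = -4, tz = 3))
  expect_equal(centroid(sh) - c0, c(7, -4, 3), tolerance = 0.05)
  # rotation about the grid centre maps the centroid accordingly
  p <- rigid_params(rz = 20)
  M <- compose_matrix(p, (spec$dims - 1) * spec$spacing / 2)
  rot <- posed_pet_acquisition(spec, p)
  expect_equal(centroid(rot), as.numeric(M[1:3, 1:3] %*% c0 + M[1:3, 4]),
               tolerance = 0.05)
})

test_that("identity-pose acquisition matches the full phantom in the interior", {
  spec <- phantom_spec("pet", dims = c(96, 96, 40), noise_sd = 0, seed = 3)
  full <- make_pet_phantom(spec)
  posed <- posed_pet_acquisition(spec, rigid_params())
  i0 <- round((posed$origin - full$origin) / full$spacing) + 1
  sub <- full$intensities[i0[1]:(i0[1] + posed$dims[1] - 1),
                          i0[2]:(i0[2] + posed$dims[2] - 1),
                          i0[3]:(i0[3] + posed$dims[3] - 1)]
  # identical away from the full grid's boundary: the full phantom blurs
  # with reflective edges while the posed generator blurs a padded grid,
  # so only an interior margin wider than the blur support is comparable
  m <- 12
  d <- posed$dims
  a <- posed$intensities[m:(d[1] - m), m:(d[2] - m), m:(d[3] - m)]
  b <- sub[m:(d[1] - m), m:(d[2] - m), m:(d[3] - m)]
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("content cropping shrinks to the heart despite background noise", {
  vol <- make_pet_phantom(phantom_spec("pet", dims = c(160, 160, 55), seed = 5))
  crop <- crop_to_content(vol)
  expect_true(all(crop$dims <= vol$dims))
  expect_lt(prod(crop$dims), 0.75 * prod(vol$dims))
  # the cropped region still contains all strong signal
  expect_equal(max(crop$intensities), max(vol$intensities), tolerance = 1e-9)
})

test_that("phantom specs round-trip through their JSON sidecar", {
  spec <- phantom_spec("pet", dims = c(40, 40, 12), blur_sd = 1.7,
                       noise_sd = 4, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(spec, path)
  got <- read_phantom_spec(path)
  expect_equal(got[names(got) != "tissues"], spec[names(spec) != "tissues"])
  expect_equal(unlist(got$tissues), unlist(spec$tissues))
  expect_identical(make_pet_phantom(got)$intensities,
                   make_pet_phantom(spec)$intensities)
})
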