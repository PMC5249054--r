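h <- 9  # um, the acquisition voxel size used throughout

test_that("volume is exact voxel accounting", {
  expect_equal(object_volume(1000, 10), 1e6)
  expect_equal(object_volume(1, 9), 729)
  # scales with spacing cubed
  expect_equal(object_volume(37, 2 * h), object_volume(37, h) * 8)
})

test_that("equivalent diameters invert the ideal solids", {
  expect_equal(equivalent_diameters(1e6)$d_cube, 100)
  expect_equal(equivalent_diameters(pi / 6 * 100^3)$d_sphere, 100)
  expect_equal(equivalent_diameters(22e5)$d_cube, 130.0591,
               tolerance = 1e-6)
})

test_that("isosurface area converges to analytic on digitized solids", {
  # spheres: within 3% at radius 20 voxels, improving with radius
  err <- vapply(c(10, 20), function(rv) {
    S <- surface_area(digitize_ball(rv), h)
    abs(S / (4 * pi * (rv * h)^2) - 1)
  }, 0)
  expect_lt(err[2], 0.03)
  expect_lt(err[2], err[1])

  # large axis-aligned cuboid: within 5% (edge rounding is the residual)
  cub <- array(FALSE, c(40, 50, 60)); cub[6:35, 6:45, 6:55] <- TRUE
  S <- surface_area(cub, h)
  expect_equal(S / (2 * (30 * 40 + 40 * 50 + 30 * 50) * h^2), 1,
               tolerance = 0.05)
})

test_that("a single-voxel object meshes to a stable sub-cube area", {
  sv <- array(FALSE, c(9, 9, 9)); sv[5, 5, 5] <- TRUE
  S <- surface_area(sv, h)
  # the isosurface of an isolated voxel cuts its corners: the area sits
  # well below the 6 h^2 voxel-face count (measured bias ~ -40%)
  expect_gt(S, sqrt(3) * h^2)   # at least the corner-midpoint octahedron
  expect_lt(S, 6 * h^2)
  expect_equal(S / (6 * h^2), 0.601, tolerance = 0.02)
})

test_that("objects touching the border are refused with advice to pad", {
  m <- array(TRUE, c(3, 3, 3))
  expect_error(surface_area(m, h), "pad")
  expect_error(surface_derivative(m, h, method = "dilation"), "pad")
})

test_that("surface derivative recovers analytic thickening rates", {
  # sphere: d(4 pi r^2)/dr = 8 pi r, within 10%
  sp <- surface_derivative(digitize_ball(20), h)
  expect_equal(sp / (8 * pi * 20 * h), 1, tolerance = 0.1)

  # long cylinder (L/r = 60): d(2 pi r L)/dr = 2 pi L, caps negligible
  cyl <- array(FALSE, c(21, 21, 311))
  g <- seq_len(21) - 11
  disk <- outer(g^2, g^2, `+`) <= 25
  for (k in 6:305) cyl[, , k] <- disk
  sp <- surface_derivative(cyl, h)
  expect_equal(sp / (2 * pi * 300 * h), 1, tolerance = 0.1)

  # wide thin plate: faces dominate and do not grow; S' is small
  # relative to the scale S / delta_r
  pl <- array(FALSE, c(11, 71, 71)); pl[6, 6:65, 6:65] <- TRUE
  sp <- surface_derivative(pl, h)
  S <- surface_area(pl, h)
  expect_lt(abs(sp) / (S / h), 0.15)
})

test_that("the SMI formula hits the ideal shape limits", {
  r <- 50; L <- 5000; A <- 1e4; t <- 2
  expect_equal(smi(4 / 3 * pi * r^3, 4 * pi * r^2, 8 * pi * r), 4)
  expect_equal(smi(pi * r^2 * L, 2 * pi * r * L, 2 * pi * L), 3)
  expect_equal(smi(A * t, 2 * A, 0), 0)
  expect_error(smi(1, 0, 1), "positive")
  expect_message(smi(4 / 3 * pi, 4 * pi, 8 * pi * 1.4), "outside")
})

test_that("measured SMI converges to the shape limits with phantom size", {
  # spheres at increasing radius: |SMI - 4| decreases, < 0.4 at rv = 20
  smi_sphere <- vapply(c(5, 10, 20), function(rv) {
    ph <- make_phantom(phantom_spec("sphere", radius = rv * h),
                       rep(2L * (rv + 5L) + 1L, 3), h)
    lab <- label_components(threshold_volume(ph$volume, "fixed",
                                             fixed_value = 500,
                                             verbose = FALSE))
    measure_objects(lab)$SMI
  }, 0)
  err <- abs(smi_sphere - 4)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.4)

  # long rods: |SMI - 3| decreases with radius, < 0.3 at rv = 6
  smi_rod <- vapply(c(3, 6), function(rv) {
    L <- 40L * rv
    ph <- make_phantom(phantom_spec("cylinder", radius = rv * h,
                                    length = L * h),
                       c(2L * rv + 11L, 2L * rv + 11L, L + 11L), h)
    lab <- label_components(threshold_volume(ph$volume, "fixed",
                                             fixed_value = 500,
                                             verbose = FALSE))
    measure_objects(lab)$SMI
  }, 0)
  expect_lt(abs(smi_rod[2] - 3), 0.3)
  expect_lt(abs(smi_rod[2] - 3), abs(smi_rod[1] - 3))

  # thin wide plates: |SMI| decreases with side, < 0.4 at 60 voxels
  smi_plate <- vapply(c(30L, 60L), function(av) {
    ph <- make_phantom(phantom_spec("plate", side = av * h, thickness = h),
                       c(11L, av + 11L, av + 11L), h)
    lab <- label_components(threshold_volume(ph$volume, "fixed",
                                             fixed_value = 500,
                                             verbose = FALSE))
    measure_objects(lab)$SMI
  }, 0)
  expect_lt(abs(smi_plate[2]), 0.4)
  expect_lt(abs(smi_plate[2]), abs(smi_plate[1]))
})

test_that("SMI is robust to halving the voxel size", {
  # same 180 um sphere sampled at 18 um and 9 um
  smi_at <- vapply(c(18, 9), function(sp) {
    ph <- make_phantom(phantom_spec("sphere", radius = 180),
                       rep(2L * (180 %/% sp + 5L) + 1L, 3), sp)
    lab <- label_components(threshold_volume(ph$volume, "fixed",
                                             fixed_value = 500,
                                             verbose = FALSE))
    measure_objects(lab)$SMI
  }, 0)
  expect_lt(abs(diff(smi_at)), 0.2)
})

test_that("measure_objects returns one calibrated record per object", {
  # a sphere and a rod planted in one volume
  members <- list(
    phantom_spec("sphere", radius = 10 * h, center = c(0, 0, -60 * h)),
    phantom_spec("cylinder", radius = 4 * h, length = 140 * h,
                 center = c(0, 0, 30 * h)))
  ph <- make_phantom(phantom_spec("cluster", members = members),
                     c(31, 31, 231), h)
  lab <- label_components(threshold_volume(ph$volume, "fixed",
                                           fixed_value = 500,
                                           verbose = FALSE))
  m <- measure_objects(lab)
  expect_equal(nrow(m), 2L)
  expect_equal(m$V_um3, m$voxel_count * h^3)
  m <- m[order(m$SMI, decreasing = TRUE), ]
  expect_equal(m$SMI[1], 4, tolerance = 0.4 / 4)
  expect_lt(abs(m$SMI[2] - 3), 0.45)

  # empty labelled volume -> empty table
  empty <- label_components(array(FALSE, c(4, 4, 4)), spacing = h)
  expect_equal(nrow(measure_objects(empty)), 0L)
})

test_that("sample aggregation follows the reporting conventions", {
  one <- data.frame(V_um3 = 2e5, SMI = 3.02, d_sphere_um = 10,
                    d_cube_um = 8)
  agg <- aggregate_sample(one, sample_id = "s1")
  expect_equal(agg$mean_SMI, 3.02)
  expect_equal(agg$sd_SMI, 0)       # single object: SD defined as 0
  expect_true(agg$excluded)         # and the sample is excluded

  three <- data.frame(V_um3 = c(1e5, 3e5, 2e5), SMI = c(2, 3, 4),
                      d_sphere_um = c(10, 30, 20),
                      d_cube_um = c(8, 24, 16))
  agg <- aggregate_sample(three, sample_id = "s2")
  expect_equal(agg$mean_SMI, 3)
  expect_equal(agg$sd_SMI, 1)
  expect_equal(agg$mean_V_1e5_um3, 2)
  expect_equal(agg$max_d_sphere_um, 30)
  expect_false(agg$excluded)

  # permutation invariance
  perm <- three[c(3, 1, 2), ]
  expect_equal(aggregate_sample(perm, "s2"), agg)

  # empty object list: flagged, aggregates undefined
  empty <- aggregate_sample(three[0, ], "s3")
  expect_equal(empty$n_objects, 0L)
  expect_true(empty$excluded)
  expect_true(is.na(empty$mean_SMI))
})
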