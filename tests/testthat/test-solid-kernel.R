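# Solid-geometry kernel: primitives, booleans, measurement, distances,
# sections and edge rounding, checked against closed forms and an
# independent Monte-Carlo containment oracle.

test_that("box primitives have exact closed-form measures", {
  b <- solid_box(1, 1, 1)
  m <- measure_solid(b)
  expect_equal(m$volume, 1)
  expect_equal(m$area, 6)
  expect_equal(c(m$extent_x, m$extent_y, m$extent_z), c(1, 1, 1))
  expect_true(m$watertight)
  expect_equal(m$components, 1)
  expect_equal(m$n_faces, 12)
  expect_equal(measure_solid(solid_box(2, 3, 4))$volume, 24)
  expect_error(solid_box(0, 1, 1), class = "pedspine_validation_error")
})

test_that("revolved solids match closed-form volumes", {
  # rectangle 1 x 2 at radial offset 1..2 -> annular cylinder pi(4-1)*2
  prof <- planar_profile(profile_rectangle(1, 2, center = c(1.5, 0)),
                         plane = "frontal")
  ann <- revolve(prof, sweep_angle = 360, segments = 64)
  expect_equal(measure_solid(ann)$volume, pi * 3 * 2, tolerance = 0.005)
  expect_true(measure_solid(ann)$watertight)
  # partial sweeps are capped and scale linearly with the sweep angle
  q <- revolve(prof, sweep_angle = 90, segments = 64)
  expect_true(measure_solid(q)$watertight)
  expect_equal(measure_solid(q)$volume, pi * 3 * 2 / 4, tolerance = 0.005)
  # semicircle on the axis edge -> sphere
  sp <- solid_sphere(1, segments = 64)
  expect_equal(measure_solid(sp)$volume, 4 * pi / 3, tolerance = 0.005)
  # degenerate / invalid sweeps
  expect_error(revolve(prof, sweep_angle = 0), class = "pedspine_geometry_error")
  crossing <- planar_profile(profile_rectangle(2, 1, center = c(0.25, 0)),
                             plane = "frontal")
  expect_error(revolve(crossing), class = "pedspine_geometry_error")
})

test_that("extrusion handles non-convex profiles", {
  fx <- fixture_profiles()
  expect_equal(profile_area(fx$unit_square$points), 1)
  expect_equal(profile_area(fx$circle_r2$points), 4 * pi, tolerance = 0.005)
  expect_equal(profile_area(fx$l_shape$points), 4)
  ex <- extrude(fx$l_shape, 2)
  expect_equal(measure_solid(ex)$volume, 8)
  expect_true(measure_solid(ex)$watertight)
})

test_that("self-intersecting sketches are rejected", {
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(planar_profile(bow), class = "pedspine_geometry_error")
})

test_that("boolean difference and union conserve volume", {
  fx <- fixture_profiles()$nested_boxes
  d <- solid_difference(fx$outer, fx$inner, voxel = 0.02)
  expect_equal(measure_solid(d)$volume, 0.875, tolerance = 0.005)
  expect_true(measure_solid(d)$watertight)

  u <- solid_union(solid_box(1, 1, 1), solid_box(1, 1, 1, center = c(3, 0, 0)),
                   voxel = 0.05)
  mu <- measure_solid(u)
  expect_equal(mu$volume, 2, tolerance = 0.02)
  expect_equal(mu$components, 2)

  # union is idempotent
  u2 <- solid_union(solid_box(1, 1, 1), solid_box(1, 1, 1), voxel = 0.02)
  expect_equal(measure_solid(u2)$volume, 1, tolerance = 0.005)

  expect_error(solid_csg(add = list()), "positive solid")
})

test_that("boolean algebra reconstitutes the minuend volume", {
  a <- solid_sphere(1, segments = 48)
  b <- solid_box(1.2, 1.2, 1.2, center = c(0.7, 0.5, 0.2))
  a_minus_b <- solid_difference(a, b, voxel = 0.025)
  a_inter_b <- solid_difference(a, a_minus_b, voxel = 0.025)
  va <- measure_solid(a)$volume
  expect_equal(measure_solid(a_minus_b)$volume + measure_solid(a_inter_b)$volume,
               va, tolerance = 0.001 * va)
})

test_that("divergence-theorem volume agrees with the Monte-Carlo oracle", {
  set.seed(420001)
  # note: the box is rotated so its bounding box is strictly larger than
  # the solid (otherwise every sample lands inside and the band is empty)
  for (s in list(solid_sphere(1, segments = 32),
                 rotate_solid(solid_box(1.3, 0.7, 2.1), c(0, 0, 1), 30),
                 solid_difference(solid_box(1, 1, 1), solid_box(0.5, 0.5, 0.5),
                                  voxel = 0.05))) {
    v_div <- measure_solid(s)$volume
    mc <- mc_volume(s, n = 2e5)
    # 4 sigma: three solids are checked against one fixed seed
    expect_lt(abs(mc$volume - v_div), 4 * mc$se)
  }
})

test_that("minimum distances are exact for separated, touching and overlapping solids", {
  s1 <- solid_sphere(1, c(0, 0, 0), segments = 64)
  s2 <- solid_sphere(1, c(3, 0, 0), segments = 64)
  expect_equal(as.numeric(min_distance(s1, s2)), 1, tolerance = 0.003)

  c1 <- solid_box(1, 1, 1)
  expect_equal(as.numeric(min_distance(c1, solid_box(1, 1, 1, center = c(1.5, 0, 0)))),
               0.5)
  d_touch <- min_distance(c1, solid_box(1, 1, 1, center = c(1, 0, 0)))
  expect_identical(as.numeric(d_touch), 0)
  expect_false(attr(d_touch, "overlap"))
  d_over <- min_distance(c1, solid_box(1, 1, 1, center = c(0.5, 0, 0)))
  expect_identical(as.numeric(d_over), 0)
  expect_true(attr(d_over, "overlap"))
  # full containment counts as overlap
  d_in <- min_distance(c1, solid_box(0.2, 0.2, 0.2))
  expect_true(attr(d_in, "overlap"))
})

test_that("planar sections report area, perimeter, extents and hole loops", {
  sl <- slice_solid(solid_box(2, 3, 4), c(0, 0, 0), c(0, 0, 1))
  expect_equal(sl$area, 6)
  expect_equal(sl$perimeter, 10)
  expect_equal(sl$extent[1:2], c(2, 3))
  expect_equal(length(sl$loops), 1)

  tube <- solid_difference(
    extrude(planar_profile(profile_circle(2), plane = "transverse"), 4),
    extrude(planar_profile(profile_circle(1), plane = "transverse",
                           origin = c(0, 0, -1)), 6),
    voxel = 0.06)
  sl2 <- slice_solid(tube, c(0, 0, 2), c(0, 0, 1))
  expect_equal(sl2$area, 3 * pi, tolerance = 0.01)
  expect_equal(length(sl2$loops), 2)
  areas <- vapply(sl2$loops, function(l) l$area, numeric(1))
  expect_equal(sum(areas > 0), 1)  # outer boundary
  expect_equal(sum(areas < 0), 1)  # the hole
  expect_equal(abs(areas[areas < 0]), pi, tolerance = 0.02)
})

test_that("edge rounding matches the opened-cube closed form and reduces sharpness", {
  cube <- solid_box(1, 1, 1)
  r <- 0.1
  f <- fillet_edges(cube, r, voxel = 0.02)
  mf <- measure_solid(f)
  expect_true(mf$watertight)
  expect_gt(mf$volume, 0.85)
  expect_lt(mf$volume, 1.0)
  expect_equal(mf$volume, rounded_cube_volume(1, r), tolerance = 0.015)
  expect_lt(max_convex_sharpness(f), max_convex_sharpness(cube))
  expect_lt(max_convex_sharpness(f), 60)

  # rounding twice at the same radius is nearly idempotent
  f2 <- fillet_edges(f, r, voxel = 0.02)
  expect_lt(abs(measure_solid(f2)$volume - mf$volume) / mf$volume, 0.01)

  expect_error(fillet_edges(cube, 0), class = "pedspine_validation_error")
  expect_error(fillet_edges(cube, 0.8), class = "pedspine_geometry_error")
})

test_that("every kernel output is watertight with positive volume", {
  fx <- fixture_profiles()
  outputs <- list(
    solid_box(1, 2, 3),
    extrude(fx$l_shape, 1.5),
    revolve(planar_profile(profile_rectangle(1, 2, center = c(1.5, 0)),
                           plane = "frontal"), sweep_angle = 200),
    solid_sphere(0.8),
    solid_union(fx$nested_boxes$outer,
                solid_box(1, 1, 1, center = c(0.8, 0, 0)), voxel = 0.04),
    solid_difference(fx$nested_boxes$outer, fx$nested_boxes$inner, voxel = 0.04),
    fillet_edges(solid_box(2, 2, 2), 0.2, voxel = 0.05))
  for (s in outputs) {
    m <- measure_solid(s)
    expect_true(m$watertight)
    expect_gt(m$volume, 0)
  }
})

test_that("rigid transforms preserve measures", {
  s <- extrude(fixture_profiles()$l_shape, 2)
  m0 <- measure_solid(s)
  s2 <- rotate_solid(translate_solid(s, c(3, -2, 5)), c(1, 1, 0), 37)
  m2 <- measure_solid(s2)
  expect_equal(m2$volume, m0$volume, tolerance = 1e-9)
  expect_equal(m2$area, m0$area, tolerance = 1e-9)
  s3 <- mirror_solid(s)
  expect_equal(measure_solid(s3)$volume, m0$volume, tolerance = 1e-9)
})
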