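# Intervertebral disc builder: wedge geometry, solved cavity fraction,
# nucleus containment, height ratios and scaling behaviour.

test_that("default disc meets the wedge and cavity contracts", {
  d <- disc_cached(1, "L3/4")
  r <- check_disc(d)
  get <- function(nm) r$measured[r$name == nm]
  expect_equal(get("wedge_angle"), 7, tolerance = 0.5 / 7)
  expect_lt(get("top_face_planarity"), 0.05)
  expect_lt(get("bottom_face_planarity"), 0.05)
  expect_equal(get("cavity_fraction"), 0.5, tolerance = 0.1)
  expect_lt(abs(get("cavity_fraction") - 0.5), 0.05)
  expect_equal(get("nucleus_contained"), 1)
  expect_gt(get("nucleus_clearance"), 0)
  expect_lte(get("nucleus_clearance"), 0.1)
  expect_true(all(r$pass, na.rm = TRUE))
})

test_that("disc heights follow the group ratio over adjacent PVBH", {
  # newborn: disc as tall as the bodies
  expect_equal(disc_height(1, "L3/4"), mean(c(7.2, 7.3)))
  # linear in the ratio
  cfg <- pedspine_config(disc = list(height_ratio = c(0.5, 0.8, 0.6, 0.4, 0.3)))
  expect_equal(disc_height(1, "L3/4", cfg), 0.5 * mean(c(7.2, 7.3)))
  # preadolescent discs are relatively low
  expect_lt(disc_height(5, "L3/4"),
            mean(c(get_dimensions(5, "L3")$PVBH, get_dimensions(5, "L4")$PVBH)))
  expect_error(disc_height(1, "L9/10"), class = "pedspine_lookup_error")
})

test_that("a zero wedge gives parallel faces", {
  d0 <- build_disc(1, "L3/4", pedspine_config(disc = list(wedge_angle_deg = 0)))
  r <- check_disc(d0)
  expect_lt(r$measured[r$name == "wedge_angle"], 0.2)
})

test_that("annulus and nucleus are disjoint and their union conserves volume", {
  d <- disc_cached(1, "L3/4")
  ann <- d$annulus$solid
  nuc <- d$nucleus$solid
  va <- pedspine:::solid_volume(ann)
  vn <- pedspine:::solid_volume(nuc)
  u <- solid_union(ann, nuc, voxel = 0.15)
  expect_equal(measure_solid(u)$volume, va + vn, tolerance = 0.001 * (va + vn))
  # a displaced nucleus violates containment
  d_bad <- d
  d_bad$nucleus$solid <- translate_solid(nuc, c(0, 5, 0))
  r <- check_disc(d_bad)
  expect_equal(r$measured[r$name == "nucleus_contained"], 0)
})

test_that("disc volume scales as footprint area (prism behaviour)", {
  h <- 6
  # parallel faces: exact prism, volume scales with the footprint area
  v1 <- pedspine:::solid_volume(pedspine:::disc_envelope_solid(20, 14, h, 0, 1))
  v2 <- pedspine:::solid_volume(pedspine:::disc_envelope_solid(40, 28, h, 0, 1))
  expect_equal(v2 / v1, 4, tolerance = 0.01)
  # wedged: volume is area x height at the footprint centroid, which grows
  # with the doubled depth
  w1 <- pedspine:::solid_volume(pedspine:::disc_envelope_solid(20, 14, h, 7, 1))
  w2 <- pedspine:::solid_volume(pedspine:::disc_envelope_solid(40, 28, h, 7, 1))
  yc <- pedspine:::polygon_centroid(pedspine:::body_profile_shape(1))[2]
  k <- tan(7 * pi / 180)
  expect_equal(w2 / w1, 4 * (h + k * yc * 28) / (h + k * yc * 14),
               tolerance = 0.01)
})

test_that("cavity solving converges across groups and pairs", {
  for (gp in list(c(1, "L1/2"), c(3, "L3/4"), c(5, "L5/S1"))) {
    d <- build_disc(as.integer(gp[1]), gp[2])
    frac <- d$cavity_volume / d$envelope_volume
    expect_lt(abs(frac - 0.5), 0.03)
    expect_true(measure_solid(d$annulus$solid)$watertight)
    expect_true(measure_solid(d$nucleus$solid)$watertight)
  }
})
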