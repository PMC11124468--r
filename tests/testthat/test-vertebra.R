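# Vertebra builder: age-dependent component architecture, tissue labels,
# dimension round-trips at the measurement stations, foramen and process
# morphology, determinism.

test_that("component counts and tissues follow the age-group architecture", {
  v1 <- vert_cached(1, "L3")
  expect_length(v1$components, 6)
  tissues <- vapply(v1$components, function(cp) cp$tissue$tissue, character(1))
  expect_equal(sum(tissues == "cortical bone"), 3)
  expect_equal(sum(tissues == "cartilage"), 3)

  expect_length(vert_cached(2, "L1")$components, 4)
  expect_length(vert_cached(3, "L3")$components, 4)
  expect_length(vert_cached(4, "L3")$components, 1)
  expect_length(vert_cached(5, "L3")$components, 1)
  expect_equal(vert_cached(4, "L3")$components[[1]]$tissue$tissue, "cortical bone")
})

test_that("all components are watertight single solids", {
  for (g in 1:5) {
    v <- vert_cached(g, "L3")
    for (cp in v$components) {
      m <- measure_solid(cp$solid)
      expect_true(m$watertight, label = sprintf("g%d %s watertight", g, cp$anatomical_name))
      expect_equal(m$components, 1)
      expect_gt(m$volume, 0)
    }
  }
})

test_that("body dimensions round-trip at the measurement stations", {
  for (g in c(1, 3, 5)) {
    v <- vert_cached(g, "L3")
    rr <- dim_rows(measure_vertebra(v))
    expect_equal(nrow(rr), 7)
    expect_true(all(rr$pass), label = sprintf("group %d L3 dimensions", g))
  }
  # spot values measured on the mesh
  r1 <- dim_rows(measure_vertebra(vert_cached(1, "L3")))
  expect_equal(r1$measured[r1$name == "MVBW"], 15.2, tolerance = 0.2 / 15.2)
  r5 <- dim_rows(measure_vertebra(vert_cached(5, "L3")))
  expect_equal(r5$measured[r5$name == "AVBH"], 23.0, tolerance = 0.3 / 23)
})

test_that("equal anterior and posterior heights give parallel endplates", {
  d <- get_dimensions(1, "L3")
  d$AVBH <- d$PVBH
  b <- build_body(d, 1)
  frame <- attr(b, "frame")
  expect_lt(abs(atan(frame$sup_k) * 180 / pi), 0.5)
  # measured on the mesh: plane fit of top vs bottom faces
  sets <- pedspine:::disc_face_sets(b)
  top <- pedspine:::fit_face_plane(b, sets$top)
  bot <- pedspine:::fit_face_plane(b, sets$bottom)
  ang <- acos(min(1, sum(top$normal * (-bot$normal)))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("the newborn vertebral foramen is near-circular", {
  f <- foramen_shape(vert_cached(1, "L3"))
  expect_gt(f$circularity, 0.9)
  expect_gt(f$area, 0)
})

test_that("older foramina are less circular (triangle-like canal)", {
  f1 <- foramen_shape(vert_cached(1, "L3"))
  f4 <- foramen_shape(vert_cached(4, "L3"))
  expect_lt(f4$circularity, f1$circularity)
})

test_that("spinous process orientation follows the age group", {
  # group 5: short strictly horizontal plate
  expect_lt(pedspine:::spinous_axis_angle(vert_cached(5, "L3")), 2)
  # group 4: subtly downward-slanting
  a4 <- pedspine:::spinous_axis_angle(vert_cached(4, "L3"))
  expect_gt(a4, 5)
  expect_lt(a4, 25)
})

test_that("oversized foramen parameters raise a geometry error", {
  d <- get_dimensions(1, "L3")
  arch <- derive_arch_parameters(d, 1)
  arch$foramen_frontal_diameter <- 2 * d$MVBW
  expect_error(build_posterior_elements(d, arch, 1),
               class = "pedspine_geometry_error")
})

test_that("bone components do not interpenetrate and cartilage bridges them", {
  v <- vert_cached(1, "L3")
  names(v$components) <- vapply(v$components, function(cp) cp$anatomical_name,
                                character(1))
  sol <- lapply(v$components, function(cp) cp$solid)
  vols <- vapply(sol, pedspine:::solid_volume, numeric(1))
  pairs <- utils::combn(names(sol), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ov <- pedspine:::overlap_volume(sol[[a]], sol[[b]], n = 2000)
    expect_lt(ov / min(vols[[a]], vols[[b]]), 0.001,
              label = sprintf("overlap %s | %s", a, b))
  }
  # each cartilage component touches both bony neighbours
  for (side in c("right", "left")) {
    ped <- sol[[paste(side, "pedicle cartilage")]]
    expect_lt(as.numeric(min_distance(ped, sol$body)), 0.05)
    expect_lt(as.numeric(min_distance(ped, sol[[paste(side, "semi-arch")]])), 0.05)
  }
  expect_lt(as.numeric(min_distance(sol[["midline cartilage"]],
                                    sol[["right semi-arch"]])), 0.05)
  expect_lt(as.numeric(min_distance(sol[["midline cartilage"]],
                                    sol[["left semi-arch"]])), 0.05)
})

test_that("total vertebra volume grows strictly with age at a fixed level", {
  vols <- vapply(1:5, function(g) pedspine:::total_volume(vert_cached(g, "L3")),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("bodies show a waist at mid-height where MVBW is minimal", {
  # the packaged preadolescent L1 record has MVBW below both SVBW and IVBW
  v <- vert_cached(5, "L1")
  d <- v$dims
  expect_true(d$MVBW <= d$SVBW && d$MVBW <= d$IVBW)
  rr <- dim_rows(measure_vertebra(v))
  mv <- rr$measured[rr$name == "MVBW"]
  expect_lte(mv, rr$measured[rr$name == "SVBW"] + 0.1)
  expect_lte(mv, rr$measured[rr$name == "IVBW"] + 0.1)
})

test_that("the group 2 L5 midline cartilage flag adds a fifth component", {
  cfg <- pedspine_config(arch = list(group2_l5_midline_cartilage = TRUE))
  v <- build_vertebra(2, "L5", cfg)
  expect_length(v$components, 5)
  expect_equal(sum(vapply(v$components, function(cp) cp$tissue$tissue,
                          character(1)) == "cartilage"), 3)
  # default stays at four components
  expect_length(vert_cached(2, "L5")$components, 4)
})

test_that("vertebra construction is deterministic", {
  a <- build_vertebra(2, "L2")
  b <- build_vertebra(2, "L2")
  expect_identical(a$components[[2]]$solid$vertices,
                   b$components[[2]]$solid$vertices)
  expect_identical(a$components[[2]]$solid$faces, b$components[[2]]$solid$faces)
})
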