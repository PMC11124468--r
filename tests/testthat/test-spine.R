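# Spine assembler: composition, ordering, contacts, lordosis handling and
# rigid-motion invariance.

test_that("the assembled spine has 5 vertebrae, 5 discs and the S1 endplate in order", {
  s <- spine_cached(1)
  counts <- pedspine:::spine_element_counts(s)
  expect_equal(unname(counts), c(5, 5, 1))
  expect_equal(vapply(s$elements, function(e) e$name, character(1)),
               c("L1", "disc L1/2", "L2", "disc L2/3", "L3", "disc L3/4",
                 "L4", "disc L4/5", "L5", "disc L5/S1", "S1 superior endplate"))
  expect_equal(s$lordosis_angle, 0)
})

test_that("adjacent elements touch without interpenetrating", {
  s <- spine_cached(1)
  expect_true(all(s$contact_gaps < 0.1))
  expect_true(all(s$contact_gaps >= 0))
  r <- spine_report(s, facets = FALSE)
  ip <- r[grepl("^interpenetration", r$name), ]
  expect_gt(nrow(ip), 0)
  expect_true(all(ip$measured < 0.001))
})

test_that("the straight newborn stack height equals the arithmetic sum", {
  s <- spine_cached(1)
  r <- spine_report(s, facets = FALSE)
  sh <- r[r$name == "stack_height", ]
  expected <- sum(vapply(vertebral_levels(), function(lv)
    get_dimensions(1, lv)$PVBH, numeric(1))) +
    sum(vapply(pedspine:::DISC_PAIRS, function(p) disc_height(1, p), numeric(1)))
  expect_equal(sh$measured, expected, tolerance = 0.5 / expected)
  # volume conservation across elements
  expect_true(r$pass[r$name == "total_volume"])
})

test_that("lordosis overrides distribute equally across the five segments", {
  cfg <- pedspine_config(spine = list(lordosis_deg = c(20, 0, 15, 25, 30)))
  s <- assemble_spine(1, cfg)
  expect_equal(sum(s$segment_angles), 20, tolerance = 1e-9)
  expect_equal(s$segment_angles, rep(4, 5))
  # the lordotic stack curves: L1 is displaced anteriorly relative to S1
  verts <- Filter(function(e) e$type == "vertebra", s$elements)
  y_l1 <- mean(verts[[1]]$solids[[1]]$solid$vertices[, 2])
  s0 <- spine_cached(1)
  verts0 <- Filter(function(e) e$type == "vertebra", s0$elements)
  y_l1_straight <- mean(verts0[[1]]$solids[[1]]$solid$vertices[, 2])
  expect_gt(abs(y_l1 - y_l1_straight), 1)
})

test_that("default lordosis is zero for infants and positive from toddlers on", {
  cfg <- pedspine_config()
  expect_equal(cfg$spine$lordosis_deg[1:2], c(0, 0))
  expect_true(all(cfg$spine$lordosis_deg[3:5] > 0))
})

test_that("facet gaps of adjacent vertebrae stay within the 0.5 mm cap", {
  s <- spine_cached(1)
  for (i in 1:4) {
    g <- pedspine:::spine_facet_gap(s, i)
    expect_gt(g, 0)
    expect_lte(g, 0.5)
  }
})

test_that("rigid motion leaves volumes and diagnostics unchanged", {
  s <- spine_cached(1)
  sol <- pedspine:::all_spine_solids(s)
  a <- sol[[1]]; b <- sol[[2]]
  va <- pedspine:::solid_volume(a)
  d0 <- as.numeric(min_distance(a, b))
  R <- function(s) rotate_solid(translate_solid(s, c(11, -4, 7)), c(1, 2, 3), 33)
  a2 <- R(a); b2 <- R(b)
  expect_equal(pedspine:::solid_volume(a2), va, tolerance = 1e-9 * va)
  expect_equal(as.numeric(min_distance(a2, b2)), d0, tolerance = 1e-6 + 1e-6 * d0)
})
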