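# Packaged osteometric tables, material registry and derived arch
# parameters.

test_that("dimension table has 25 complete records with the printed values", {
  tb <- lumbar_dimensions()
  expect_equal(nrow(tb), 25)
  expect_setequal(unique(tb$group), 1:5)
  expect_setequal(unique(tb$level), vertebral_levels())
  expect_true(all(is.finite(unlist(tb[dim_names]))))

  d <- get_dimensions(1, "L3")
  expect_equal(d$MVBW, 15.2)
  expect_equal(d$AVBH, 7.2)
  expect_equal(get_dimensions(5, "L2")$SVBW, 34.7)
  expect_equal(get_dimensions(5, "L3")$AVBH, 23.0)

  # widths exceed lengths in every packaged record
  expect_true(all(tb$SVBW > tb$SVBL & tb$SVBW > tb$IVBL))
  expect_true(all(tb$MVBW > tb$SVBL & tb$IVBW > tb$IVBL))
})

test_that("growth monotonicity holds across the packaged table", {
  tb <- lumbar_dimensions()
  for (lv in vertebral_levels()) {
    sub <- tb[tb$level == lv, ]
    sub <- sub[order(sub$group), ]
    # every dimension is non-decreasing from group 1 to group 2
    for (dn in dim_names) expect_gte(sub[[dn]][2], sub[[dn]][1])
    # AVBH, SVBL, SVBW are non-decreasing across all five groups
    for (dn in c("AVBH", "SVBL", "SVBW")) {
      expect_true(all(diff(sub[[dn]]) >= 0),
                  label = sprintf("%s monotone at %s", dn, lv))
    }
  }
})

test_that("lookups reject unknown groups, levels and tissues", {
  expect_error(get_dimensions(1, "L6"), class = "pedspine_lookup_error")
  expect_error(get_dimensions(7, "L3"), class = "pedspine_lookup_error")
  expect_error(get_material("enamel"), class = "pedspine_lookup_error")
})

test_that("material registry matches the packaged biomechanical table", {
  m <- tissue_materials()
  expect_equal(nrow(m), 5)
  expected <- data.frame(
    tissue = c("cortical bone", "trabecular bone", "cartilage",
               "nucleus pulposus", "annulus fibrosus"),
    E = c(12000, 100, 10, 1, 4.2),
    nu = c(0.30, 0.20, 0.40, 0.49, 0.45))
  expect_setequal(m$tissue, expected$tissue)
  for (i in seq_len(5)) {
    got <- get_material(expected$tissue[i])
    expect_identical(got$youngs_modulus_E, expected$E[i])
    expect_identical(got$poisson_ratio_nu, expected$nu[i])
  }
  # case-insensitive lookup
  expect_equal(get_material("Cortical Bone")$youngs_modulus_E, 12000)
})

test_that("age groups carry the specimen counts", {
  ag <- age_groups()
  expect_equal(ag$index, 1:5)
  expect_equal(ag$specimen_count, c(23, 12, 9, 7, 6))
})

test_that("arch parameters derive as documented fractions and accept overrides", {
  d <- get_dimensions(1, "L3")
  p <- derive_arch_parameters(d, 1)
  expect_equal(p$pedicle_width, 0.20 * 15.2)
  expect_equal(p$pedicle_height, 0.55 * d$PVBH)
  expect_equal(p$transverse_process_length, 0.45 * d$MVBW)
  expect_equal(p$spinous_process_length, 0.50 * d$SVBL)
  expect_equal(p$foramen_frontal_diameter, 0.45 * d$MVBW)  # newborn canal
  expect_equal(derive_arch_parameters(get_dimensions(3, "L3"), 3)$foramen_frontal_diameter,
               0.60 * get_dimensions(3, "L3")$MVBW)
  expect_equal(p$foramen_sagittal_diameter, 0.80 * d$IVBL)
  expect_true(p$foramen_frontal_diameter < d$MVBW)
  expect_true(all(unlist(p) > 0))

  p2 <- derive_arch_parameters(d, 1, overrides = list(pedicle_width = 4.0))
  expect_identical(p2$pedicle_width, 4.0)
  expect_error(derive_arch_parameters(d, 1, overrides = list(pedicle_width = -1)),
               class = "pedspine_validation_error")
  expect_error(derive_arch_parameters(d, 1, overrides = list(nonsense = 2)),
               class = "pedspine_validation_error")
})

test_that("the facet cutout is solved to the configured clearance", {
  p <- derive_arch_parameters(get_dimensions(1, "L3"), 1)
  gap <- p$facet_cutout_diameter / 2 - p$facet_ridge_radius
  expect_gt(gap, 0.2)
  expect_lte(gap, 0.45)
})

test_that("configuration validates, merges and round-trips through JSON", {
  cfg <- pedspine_config(disc = list(wedge_angle_deg = 5),
                         "spine.contact_gap_mm" = 0.03)
  expect_equal(cfg$disc$wedge_angle_deg, 5)
  expect_equal(cfg$spine$contact_gap_mm, 0.03)
  expect_error(pedspine_config(disc = list(wedge_angle_deg = 90)),
               class = "pedspine_validation_error")
  expect_error(pedspine_config(nonsense = list(a = 1)),
               class = "pedspine_validation_error")
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  expect_identical(unclass(read_config(f)), unclass(cfg))
})

test_that("user dimension tables are schema-checked", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": "something-else"}', f)
  expect_error(lumbar_dimensions(f), class = "pedspine_validation_error")
  # a corrupted value (zeroed) is rejected at the osteometry stage
  src <- system.file("extdata", "lumbar_dimensions.json", package = "pedspine")
  j <- jsonlite::read_json(src, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  j$groups[[1]]$levels$L3[2] <- 0
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, f2, auto_unbox = TRUE, digits = NA)
  expect_error(lumbar_dimensions(f2), class = "pedspine_validation_error")
})
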