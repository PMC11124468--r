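# Morphometric validation: report structure, perturbation sensitivity,
# facet gap measurement and the per-group validation driver.

test_that("measure_vertebra reports pass entries for a default build", {
  r <- measure_vertebra(vert_cached(1, "L3"))
  expect_s3_class(r, "measurement_report")
  expect_true(r$pass[r$name == "MVBW"])
  expect_equal(r$measured[r$name == "component_count"], 6)
  expect_true(all(r$pass[startsWith(r$name, "watertight")]))
  expect_true(glance(r)$pass)
})

test_that("a scaled model fails every dimension entry", {
  v <- vert_cached(1, "L3")
  v2 <- v
  v2$components <- lapply(v$components, function(cp) {
    cp$solid <- scale_solid(cp$solid, 2)
    cp
  })
  rr <- dim_rows(measure_vertebra(v2))
  expect_true(all(!rr$pass))
})

test_that("perturbing one packaged dimension beyond tolerance flips its entry", {
  # build from a perturbed record, compare against the packaged values
  d <- get_dimensions(2, "L3")
  d$MVBW <- d$MVBW + 3 * max(0.2, 0.02 * d$MVBW)
  arch <- derive_arch_parameters(d, 2)
  body <- build_body(d, 2)
  post <- build_posterior_elements(d, arch, 2)
  v <- split_and_label(body, post, 2, "L3", d, arch)
  rr <- dim_rows(measure_vertebra(v))
  expect_false(rr$pass[rr$name == "MVBW"])
  expect_true(rr$pass[rr$name == "PVBH"])
})

test_that("facet gap measurement matches a brute-force sampling oracle", {
  v3 <- vert_cached(1, "L3")
  v4 <- vert_cached(1, "L4")
  pitch <- v3$dims$PVBH + disc_height(1, "L3/4")
  pose <- list(R = diag(3), t = c(0, 0, pitch))
  g <- check_facet_gap(v3, v4, pose)
  expect_gt(as.numeric(g), 0)
  expect_lte(as.numeric(g), 0.5)
  # oracle: dense point sampling of both facet surfaces
  a <- pedspine:::apply_pose(pedspine:::facet_submesh(v3, "inferior"), pose)
  b <- pedspine:::facet_submesh(v4, "superior")
  sample_surface <- function(s, n = 40000) {
    f <- s$faces
    set.seed(9001)
    idx <- sample.int(nrow(f), n, replace = TRUE)
    u <- runif(n); w <- runif(n)
    flip <- u + w > 1
    u[flip] <- 1 - u[flip]; w[flip] <- 1 - w[flip]
    s$vertices[f[idx, 1], ] * (1 - u - w) +
      s$vertices[f[idx, 2], ] * u + s$vertices[f[idx, 3], ] * w
  }
  pa <- sample_surface(a); pb <- sample_surface(b)
  # nearest-pair distance via coarse binning on z
  dmin <- min(FNN_dist <- vapply(seq_len(200), function(i) {
    q <- pa[sample.int(nrow(pa), 1), ]
    min(sqrt(colSums((t(pb) - q)^2)))
  }, numeric(1)))
  expect_gte(dmin + 0.02, as.numeric(g))
})

test_that("separated vertebrae report a large facet gap", {
  v3 <- vert_cached(1, "L3")
  v4 <- vert_cached(1, "L4")
  g <- check_facet_gap(v3, v4, list(R = diag(3), t = c(0, 0, 30)))
  expect_gt(as.numeric(g), 5)
})

test_that("full validation passes for the newborn group", {
  r <- full_validation(1, spine = FALSE)
  expect_true(all(r$pass, na.rm = TRUE))
  expect_gt(sum(!is.na(r$pass)), 50)
})
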