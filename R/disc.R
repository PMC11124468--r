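# Intervertebral disc builder: a wedge-shaped annulus fibrosus (default
# sagittal inclination 7 degrees, opening anteriorly) whose internal cavity
# holds about half the disc volume, plus a separately built nucleus pulposus
# inserted into the cavity with a small uniform clearance. The cavity wall
# thickness is solved by bisection on the measured volume fraction rather
# than fixed.

DISC_PAIRS <- c("L1/2", "L2/3", "L3/4", "L4/5", "L5/S1")

parse_pair <- function(level_pair) {
  i <- match(level_pair, DISC_PAIRS)
  if (is.na(i))
    lookup_error("unknown disc level pair '%s' (valid: %s)", level_pair,
                 paste(DISC_PAIRS, collapse = ", "))
  list(index = i, upper = paste0("L", i),
       lower = if (i < 5) paste0("L", i + 1) else "S1")
}

#' Disc height from the group's disc-to-body height ratio
#'
#' Posterior disc height = group ratio x mean posterior body height (PVBH)
#' of the adjacent vertebrae (newborn discs are as tall as the bodies,
#' ratio 1; the ratio declines with age). For L5/S1 the L5 height is used
#' (no S1 body in the model).
#'
#' @param group age-group index 1-5.
#' @param level_pair one of `"L1/2"` ... `"L5/S1"`.
#' @param config a [pedspine_config()] (`disc$height_ratio`).
#' @return Height in mm.
#' @export
disc_height <- function(group, level_pair, config = pedspine_config()) {
  p <- parse_pair(level_pair)
  up <- get_dimensions(group, p$upper)$PVBH
  lo <- if (p$lower == "S1") up else get_dimensions(group, p$lower)$PVBH
  config$disc$height_ratio[[group]] * mean(c(up, lo))
}

# disc footprint: mean of the lower vertebra's superior and the upper
# vertebra's inferior endplate dimensions
disc_footprint <- function(group, pair) {
  up <- get_dimensions(group, pair$upper)
  if (pair$lower == "S1") {
    list(width = up$IVBW, depth = up$IVBL)
  } else {
    lo <- get_dimensions(group, pair$lower)
    list(width = mean(c(lo$SVBW, up$IVBW)), depth = mean(c(lo$SVBL, up$IVBL)))
  }
}

# a solid with an internal void: outer shell plus orientation-reversed
# inner shell (the inner solid must lie strictly inside the outer)
hollow_solid <- function(outer, inner, name = NULL) {
  v <- rbind(outer$vertices, inner$vertices)
  f <- rbind(outer$faces, inner$faces[, c(1, 3, 2)] + nrow(outer$vertices))
  tri_solid(v, f, name = name)
}

# wedge prism: group profile scaled to the footprint, flat inferior face at
# z = 0, superior plane z = h_post + tan(wedge) * y (posterior wall y = 0)
disc_envelope_solid <- function(width, depth, height_posterior,
                                wedge_angle_deg, group, inset = 0,
                                z_margin = 0, slope_bottom = 0,
                                name = NULL) {
  prof <- body_profile_shape(group)
  pts <- cbind(prof[, 1] * width, prof[, 2] * depth)
  if (inset > 0) {
    ctr <- polygon_centroid(pts)
    half <- sqrt(abs(polygon_area(pts)) / pi)  # effective radius
    s <- max(0.05, 1 - inset / half)
    pts <- sweep(sweep(pts, 2, ctr), 2, c(s, s), "*") +
      matrix(ctr, nrow(pts), 2, byrow = TRUE)
  }
  k_top <- tan(wedge_angle_deg * pi / 180 + atan(slope_bottom))
  bot <- slope_bottom * pts[, 2] + z_margin
  top <- height_posterior + k_top * pts[, 2] - z_margin
  if (any(top - bot <= 0.05))
    geometry_error("disc wedge/height combination yields non-positive thickness")
  ring1 <- cbind(pts, bot)
  ring2 <- cbind(pts, top)
  loft_sections(list(ring1, ring2), name = name)
}

#' Build an intervertebral disc model
#'
#' Wedge-shaped disc between two adjacent lumbar levels: the annulus
#' fibrosus with an internal cavity (anterior cavity plus posterior recess)
#' solved to hold `disc$cavity_fraction` (default 50%) of the disc volume,
#' and a nucleus pulposus built separately and inserted with a uniform
#' clearance.
#'
#' @param group age-group index 1-5.
#' @param level_pair one of `"L1/2"` ... `"L5/S1"`.
#' @param config a [pedspine_config()]; `disc$wedge_angle_deg` (default 7)
#'   and `disc$height_ratio` control the shape.
#' @param wedge_deg optional wedge-angle override (degrees), used by the
#'   spine assembler to match the per-segment lordosis rotation.
#' @param slope_bottom slope (dz/dy) of the inferior face, used by the
#'   assembler so the disc conforms to the endplate of the vertebra below.
#' @return A `disc_model`: `annulus` and `nucleus` labelled components,
#'   `wedge_angle`, `height_posterior`, `footprint`, `wall_thickness`.
#' @export
build_disc <- function(group, level_pair, config = pedspine_config(),
                       wedge_deg = NULL, slope_bottom = 0) {
  pair <- parse_pair(level_pair)
  fp <- disc_footprint(group, pair)
  h <- disc_height(group, level_pair, config)
  wedge <- wedge_deg %||% config$disc$wedge_angle_deg
  outer <- disc_envelope_solid(fp$width, fp$depth, h, wedge, group,
                               slope_bottom = slope_bottom,
                               name = "annulus envelope")
  v_out <- solid_volume(outer)
  target <- config$disc$cavity_fraction
  tol <- config$disc$cavity_tol
  cavity_at <- function(t) {
    disc_envelope_solid(fp$width, fp$depth, h, wedge, group,
                        inset = t, z_margin = t, slope_bottom = slope_bottom,
                        name = "cavity")
  }
  k_rel <- tan(wedge * pi / 180 + atan(slope_bottom)) - slope_bottom
  t_hi <- (min(h, h + k_rel * fp$depth) - 0.15) / 2
  t_lo <- 0.02
  f_of <- function(t) solid_volume(cavity_at(t)) / v_out
  for (i in 1:50) {
    t_mid <- (t_lo + t_hi) / 2
    f <- f_of(t_mid)
    if (abs(f - target) <= tol) { t_lo <- t_hi <- t_mid; break }
    if (f > target) t_lo <- t_mid else t_hi <- t_mid
    if (t_hi - t_lo < 1e-5) break
  }
  wall <- (t_lo + t_hi) / 2
  f_final <- f_of(wall)
  if (abs(f_final - target) > 5 * tol)
    geometry_error("cavity fraction %.3f not attainable (target %.2f)", f_final, target)
  cavity <- cavity_at(wall)
  # the cavity lies strictly inside the envelope, so the annulus is exactly
  # the envelope shell plus the inverted cavity shell (no remeshing)
  annulus <- hollow_solid(outer, cavity, name = "annulus fibrosus")
  cl <- config$disc$clearance_mm
  nucleus <- disc_envelope_solid(fp$width, fp$depth, h, wedge, group,
                                 inset = wall + cl, z_margin = wall + cl,
                                 slope_bottom = slope_bottom,
                                 name = "nucleus pulposus")
  structure(list(
    group = group, level_pair = level_pair,
    annulus = new_labeled_component(annulus, get_material("annulus fibrosus"),
                                    "annulus fibrosus"),
    nucleus = new_labeled_component(nucleus, get_material("nucleus pulposus"),
                                    "nucleus pulposus"),
    wedge_angle = wedge, height_posterior = h,
    footprint = fp, wall_thickness = wall,
    envelope_volume = v_out, cavity_volume = solid_volume(cavity),
    config = config), class = "disc_model")
}

#' @export
print.disc_model <- function(x, ...) {
  cat(sprintf(
    "<disc_model: group %d, %s, wedge %g deg, posterior height %.2f mm, cavity %.1f%%>\n",
    x$group, x$level_pair, x$wedge_angle, x$height_posterior,
    100 * x$cavity_volume / x$envelope_volume))
  invisible(x)
}

# ----------------------------------------------------------- disc checks

# area-weighted mean normal and max plane residual of a face subset
fit_face_plane <- function(s, keep) {
  f <- s$faces[keep, , drop = FALSE]
  v0 <- s$vertices[f[, 1], , drop = FALSE]
  v1 <- s$vertices[f[, 2], , drop = FALSE]
  v2 <- s$vertices[f[, 3], , drop = FALSE]
  cr <- cbind((v1[, 2] - v0[, 2]) * (v2[, 3] - v0[, 3]) - (v1[, 3] - v0[, 3]) * (v2[, 2] - v0[, 2]),
              (v1[, 3] - v0[, 3]) * (v2[, 1] - v0[, 1]) - (v1[, 1] - v0[, 1]) * (v2[, 3] - v0[, 3]),
              (v1[, 1] - v0[, 1]) * (v2[, 2] - v0[, 2]) - (v1[, 2] - v0[, 2]) * (v2[, 1] - v0[, 1]))
  n <- colSums(cr)
  n <- n / sqrt(sum(n^2))
  cen <- (v0 + v1 + v2) / 3
  area <- sqrt(rowSums(cr^2)) / 2
  p0 <- colSums(cen * area) / sum(area)
  res <- abs((cen - matrix(p0, nrow(cen), 3, byrow = TRUE)) %*% n)
  # boundary slivers of the re-triangulated surface sit slightly off-plane;
  # trim them and refit so the fit reflects the face proper
  keep2 <- res <= max(0.02, 3 * stats::median(res))
  cr <- cr[keep2, , drop = FALSE]; cen <- cen[keep2, , drop = FALSE]
  area <- area[keep2]
  n <- colSums(cr); n <- n / sqrt(sum(n^2))
  p0 <- colSums(cen * area) / sum(area)
  res <- abs((cen - matrix(p0, nrow(cen), 3, byrow = TRUE)) %*% n)
  list(normal = n, point = p0, max_residual = max(res))
}

disc_face_sets <- function(annulus) {
  f <- annulus$faces
  v0 <- annulus$vertices[f[, 1], , drop = FALSE]
  v1 <- annulus$vertices[f[, 2], , drop = FALSE]
  v2 <- annulus$vertices[f[, 3], , drop = FALSE]
  nx <- (v1[, 2] - v0[, 2]) * (v2[, 3] - v0[, 3]) - (v1[, 3] - v0[, 3]) * (v2[, 2] - v0[, 2])
  ny <- (v1[, 3] - v0[, 3]) * (v2[, 1] - v0[, 1]) - (v1[, 1] - v0[, 1]) * (v2[, 3] - v0[, 3])
  nz <- (v1[, 1] - v0[, 1]) * (v2[, 2] - v0[, 2]) - (v1[, 2] - v0[, 2]) * (v2[, 1] - v0[, 1])
  len <- sqrt(nx^2 + ny^2 + nz^2)
  nzu <- nz / pmax(len, 1e-300)
  cz <- (v0[, 3] + v1[, 3] + v2[, 3]) / 3
  zr <- range(annulus$vertices[, 3])
  span <- diff(zr)
  list(top = nzu > 0.9 & cz > zr[1] + 0.6 * span,
       bottom = nzu < -0.9 & cz < zr[1] + 0.3 * span)
}

#' Re-measure a disc model
#'
#' Plane-fits the superior and inferior annulus faces to report the sagittal
#' wedge angle (expected: configured angle, tolerance 0.5 deg), checks face
#' planarity (0.05 mm), the cavity volume fraction (expected 50 +- 5%,
#' derived from the annulus mesh: envelope shell volume minus annulus solid
#' volume), nucleus containment and clearance, and watertightness.
#'
#' @param d a `disc_model`.
#' @return A `measurement_report`.
#' @export
check_disc <- function(d) {
  ann <- d$annulus$solid
  nuc <- d$nucleus$solid
  sets <- disc_face_sets(ann)
  top <- fit_face_plane(ann, sets$top)
  bot <- fit_face_plane(ann, sets$bottom)
  ang <- acos(pmin(1, pmax(-1, sum(top$normal * (-bot$normal))))) * 180 / pi
  # envelope volume from the outer shell of the annulus mesh
  comp <- cpp_face_components(ann$vertices, ann$faces)
  vols <- vapply(unique(comp), function(ci) {
    sub <- structure(list(vertices = ann$vertices,
                          faces = ann$faces[comp == ci, , drop = FALSE]),
                     class = "tri_solid")
    solid_volume(sub)
  }, numeric(1))
  v_env <- max(vols)
  v_ann <- solid_volume(ann)
  frac <- (v_env - v_ann) / v_env
  # nucleus containment: all nucleus vertices inside the cavity (inside the
  # envelope but outside the annulus solid)
  dirv <- ray_dir()
  in_ann <- cpp_points_in_mesh(ann$vertices, ann$faces, nuc$vertices, dirv)
  contained <- !any(in_ann) &&
    as.numeric(min_distance(ann, nuc)) > 1e-6 &&
    all(nuc$vertices[, 3] > min(ann$vertices[, 3]))
  clearance <- as.numeric(min_distance(ann, nuc))
  mw <- measure_solid(ann); mn <- measure_solid(nuc)
  rows <- bind_rows(
    report_row("wedge_angle", ang, "deg", d$wedge_angle, 0.5),
    report_row("top_face_planarity", top$max_residual, "mm", 0, 0.05),
    report_row("bottom_face_planarity", bot$max_residual, "mm", 0, 0.05),
    report_row("cavity_fraction", frac, "ratio",
               d$config$disc$cavity_fraction, 0.05),
    report_row("nucleus_contained", as.numeric(contained), "flag", 1, 0),
    report_row("nucleus_clearance", clearance, "mm",
               d$config$disc$clearance_mm, 0.1),
    report_row("annulus_watertight", as.numeric(mw$watertight), "flag", 1, 0),
    report_row("nucleus_watertight",
               as.numeric(mn$watertight && mn$components == 1), "flag", 1, 0),
    report_row("posterior_height", d$height_posterior, "mm"))
  new_measurement_report(rows)
}
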