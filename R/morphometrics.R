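# Morphometric validation: re-measures generated solids against the
# packaged osteometric table and the geometric constraints of the
# construction. Measurement stations are slices parallel to the endplates
# (widths/depths) and frontal slices at the calibrated height stations, so
# that a correctly built model reproduces the packaged values exactly.

new_measurement_report <- function(tb) {
  structure(tb, class = c("measurement_report", class(tb)))
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("<measurement_report: %d entries, %s>\n", nrow(x),
              if (all(x$pass, na.rm = TRUE)) "PASS" else "FAIL"))
  NextMethod()
}

report_row <- function(name, measured, unit, expected = NA_real_,
                       tolerance = NA_real_) {
  tibble(name = name, measured = measured, unit = unit, expected = expected,
         tolerance = tolerance,
         pass = if (is.na(expected)) NA else
           is.finite(measured) && abs(measured - expected) <= tolerance)
}

dim_tolerance <- function(expected) pmax(0.2, 0.02 * expected)

# extents of a station slice restricted to the body region (y at or anterior
# of the posterior body wall)
station_extent <- function(shell, station, y_wall) {
  sl <- slice_solid(shell, station$point, station$normal)
  if (nrow(sl$points) == 0) return(c(NA_real_, NA_real_, NA_real_))
  pts <- sl$points[sl$points[, 2] >= y_wall - 0.01, , drop = FALSE]
  if (nrow(pts) == 0) return(c(NA_real_, NA_real_, NA_real_))
  apply(pts, 2, function(q) diff(range(q)))
}

#' Re-measure a vertebra model against the packaged dimensions
#'
#' Slices the generated body at the construction's measurement stations
#' (endplate-parallel planes for the three widths and two depths, frontal
#' planes at the calibrated anterior/posterior stations for the two
#' heights), and reports each dimension against the packaged value with
#' tolerance `max(0.2 mm, 2%)`, plus component count, per-component volume
#' and watertightness entries.
#'
#' @param v a `vertebra_model`.
#' @param expected optional `vertebral_dimensions` to compare against;
#'   defaults to the packaged record for the model's group/level.
#' @return A `measurement_report` tibble.
#' @export
measure_vertebra <- function(v, expected = NULL) {
  expected <- expected %||% get_dimensions(v$group, v$level)
  frame <- v$frame
  y_wall <- frame$y_wall
  st <- body_stations(frame)
  # stations were derived in the build frame (wall at y = 0); shift to the
  # model frame
  shift_station <- function(s) { s$point[2] <- s$point[2] + y_wall; s }
  st <- lapply(st, shift_station)
  shell <- if (length(v$components) == 1) v$components[[1]]$solid
           else v$components[[1]]$solid   # body is always the first component
  rows <- list()
  for (nm in c("top", "mid", "bottom")) {
    ext <- station_extent(shell, st[[nm]], y_wall)
    wdim <- st[[nm]]$width
    rows[[length(rows) + 1]] <-
      report_row(wdim, ext[1], "mm", expected[[wdim]], dim_tolerance(expected[[wdim]]))
    ddim <- st[[nm]]$depth
    if (!is.na(ddim)) {
      rows[[length(rows) + 1]] <-
        report_row(ddim, ext[2], "mm", expected[[ddim]], dim_tolerance(expected[[ddim]]))
    }
  }
  for (nm in c("post", "ant")) {
    ext <- station_extent(shell, st[[nm]], y_wall)
    hdim <- st[[nm]]$height
    rows[[length(rows) + 1]] <-
      report_row(hdim, ext[3], "mm", expected[[hdim]], dim_tolerance(expected[[hdim]]))
  }
  n_expect <- expected_component_count(v$group, v$config, v$level)
  rows[[length(rows) + 1]] <- report_row("component_count",
                                         length(v$components), "count",
                                         n_expect, 0)
  for (cp in v$components) {
    m <- measure_solid(cp$solid)
    rows[[length(rows) + 1]] <- report_row(
      paste0("watertight: ", cp$anatomical_name),
      as.numeric(m$watertight && m$components == 1 && m$volume > 0), "flag", 1, 0)
    rows[[length(rows) + 1]] <- report_row(
      paste0("volume: ", cp$anatomical_name), m$volume, "mm^3")
  }
  new_measurement_report(bind_rows(rows))
}

expected_component_count <- function(group, config, level = NULL) {
  if (group == 1) return(6)
  if (group %in% c(2, 3)) {
    if (group == 2 && identical(level, "L5") &&
        isTRUE(config$arch$group2_l5_midline_cartilage)) return(5)
    return(4)
  }
  1
}

# ---------------------------------------------------------------- facets

facet_submesh <- function(v, which = c("inferior", "superior")) {
  which <- match.arg(which)
  f <- v$facets
  pad_r <- if (which == "inferior") f$r_ridge + 0.6 else f$r_groove + 0.8
  zr <- if (which == "inferior") f$z_inferior else f$z_superior
  ylim <- c(f$y - 2.2 * f$r_groove - 0.5, f$y + pad_r)
  shell <- vertebra_shell(v)
  cen <- (shell$vertices[shell$faces[, 1], , drop = FALSE] +
          shell$vertices[shell$faces[, 2], , drop = FALSE] +
          shell$vertices[shell$faces[, 3], , drop = FALSE]) / 3
  keep <- (abs(abs(cen[, 1]) - f$x) <= pad_r + 0.5) &
    cen[, 2] >= ylim[1] & cen[, 2] <= ylim[2] &
    cen[, 3] >= zr[1] & cen[, 3] <= zr[2]
  if (!any(keep)) geometry_error("no facet surface found in the %s region", which)
  structure(list(vertices = shell$vertices,
                 faces = shell$faces[keep, , drop = FALSE],
                 name = paste(which, "facets")), class = "tri_solid")
}

apply_pose <- function(s, pose) {
  if (is.null(pose)) return(s)
  R <- pose$R %||% diag(3)
  t <- pose$t %||% c(0, 0, 0)
  s$vertices <- s$vertices %*% t(R) + matrix(t, nrow(s$vertices), 3, byrow = TRUE)
  s
}

#' Articular facet gap between adjacent vertebrae
#'
#' Minimum distance between the inferior articular surfaces of the upper
#' vertebra (posed) and the superior articular surfaces of the lower. The
#' construction keeps this at or under the 0.5 mm joint-gap cap.
#'
#' @param upper,lower `vertebra_model`s.
#' @param pose rigid pose of the upper vertebra relative to the lower:
#'   `list(R = 3x3 rotation, t = translation)`. Defaults to identity.
#' @return Gap in mm with attribute `overlap`.
#' @export
check_facet_gap <- function(upper, lower, pose = NULL) {
  a <- apply_pose(facet_submesh(upper, "inferior"), pose)
  b <- facet_submesh(lower, "superior")
  d <- cpp_min_distance(a$vertices, a$faces, b$vertices, b$faces)
  structure(d, overlap = FALSE)
}

# ------------------------------------------------------------- foramen

#' Vertebral foramen cross-section shape
#'
#' Slices the (unioned) vertebra at mid-arch height and isolates the
#' foramen as the interior hole of the section; returns its area, perimeter
#' and circularity (4 pi A / P^2; 1 = perfect circle).
#'
#' @param v a `vertebra_model`.
#' @return List with `area`, `perimeter`, `circularity`.
#' @export
foramen_shape <- function(v) {
  zc <- v$dims$PVBH / 2
  if (length(v$components) == 1) {
    u <- v$components[[1]]$solid
  } else {
    u <- solid_csg(add = lapply(v$components, function(cp) cp$solid),
                   voxel = v$config$kernel$fine_voxel, name = "union")
  }
  sl <- slice_solid(u, c(0, 0, zc), c(0, 0, 1))
  holes <- Filter(function(l) l$area < 0, sl$loops)
  if (length(holes) == 0)
    geometry_error("no foramen hole found in the mid-arch section")
  h <- holes[[which.max(vapply(holes, function(l) abs(l$area), numeric(1)))]]
  A <- abs(h$area); P <- h$perimeter
  list(area = A, perimeter = P, circularity = 4 * pi * A / P^2)
}

#' Full morphometric validation of one age group
#'
#' Builds all five vertebrae, all five discs and the assembled spine for an
#' age group and concatenates their measurement reports (dimension
#' round-trips, component architecture, watertightness, disc geometry,
#' spine composition, contacts and facet gaps).
#'
#' @param group age-group index 1-5.
#' @param config a [pedspine_config()].
#' @param spine include the assembled-spine checks (slowest part).
#' @return A `measurement_report` with an `element` column; attribute
#'   `pass` gives the overall outcome.
#' @export
full_validation <- function(group, config = pedspine_config(), spine = TRUE) {
  parts <- list()
  for (lv in vertebral_levels()) {
    r <- measure_vertebra(build_vertebra(group, lv, config))
    r$element <- paste("vertebra", lv)
    parts[[length(parts) + 1]] <- r
  }
  for (pr in DISC_PAIRS) {
    r <- check_disc(build_disc(group, pr, config))
    r$element <- paste("disc", pr)
    parts[[length(parts) + 1]] <- r
  }
  if (spine) {
    r <- spine_report(assemble_spine(group, config))
    r$element <- "spine"
    parts[[length(parts) + 1]] <- r
  }
  out <- new_measurement_report(bind_rows(parts))
  attr(out, "pass") <- all(out$pass, na.rm = TRUE)
  out
}

# principal-axis angle (degrees off horizontal) of the spinous process:
# PCA of the near-midline surface points posterior of the arch plate
spinous_axis_angle <- function(v) {
  y_base <- v$frame$y_wall -
    (v$arch$foramen_sagittal_diameter + v$arch$arch_plate_thickness) - 0.5
  shell <- vertebra_shell(v)
  pts <- shell$vertices[shell$vertices[, 2] < y_base &
                          abs(shell$vertices[, 1]) < 0.4 * v$arch$pedicle_width, ,
                        drop = FALSE]
  if (nrow(pts) < 10) geometry_error("no spinous process found")
  # mid-surface line: z-midpoint per y bin, then a straight-line fit
  bins <- cut(pts[, 2], breaks = 8)
  ymid <- tapply(pts[, 2], bins, mean)
  zmid <- tapply(pts[, 3], bins, function(z) (max(z) + min(z)) / 2)
  ok <- is.finite(ymid) & is.finite(zmid)
  fit <- stats::lm(zmid[ok] ~ ymid[ok])
  abs(atan(stats::coef(fit)[[2]]) * 180 / pi)
}
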