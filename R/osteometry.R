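# Osteometric data module: the packaged mean dimensions of 57 pediatric
# lumbar vertebrae across five age groups, the biomechanical material
# registry, and the derived vertebral-arch parameters that the builders
# consume. Tables ship as JSON (inst/extdata) in a documented schema and can
# be replaced by user files of the same schema.

the <- new.env(parent = emptyenv())

DIMENSION_NAMES <- c("AVBH", "PVBH", "SVBL", "IVBL", "SVBW", "MVBW", "IVBW")

#' Vertebral levels and age groups
#'
#' The five lumbar levels (L1-L5) and the five modelled age groups
#' (newborn, infant 0-1 yrs, toddler 1-3 yrs, middle childhood 4-7 yrs,
#' preadolescent 8-12 yrs) with the specimen counts underlying the packaged
#' mean dimensions.
#'
#' @return `vertebral_levels()`: character vector of admissible level names.
#' @export
vertebral_levels <- function() c("L1", "L2", "L3", "L4", "L5")

#' @rdname vertebral_levels
#' @return `age_groups()`: tibble with `index`, `label`, `specimen_count`.
#' @export
age_groups <- function() {
  tb <- dimension_data()
  tibble(
    index = map_dbl(tb$groups, "index"),
    label = map_chr(tb$groups, "label"),
    specimen_count = map_dbl(tb$groups, "specimen_count"))
}

dimension_data <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$dims)) {
      the$dims <- read_dimension_table(
        system.file("extdata", "lumbar_dimensions.json", package = "pedspine"))
    }
    return(the$dims)
  }
  read_dimension_table(path)
}

read_dimension_table <- function(path) {
  if (!file.exists(path)) lookup_error("dimension table '%s' not found", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(j$schema, "pedspine-dimensions-v1"))
    validation_error("dimension table '%s' does not declare schema 'pedspine-dimensions-v1'", path)
  if (!identical(unlist(j$dimension_names), DIMENSION_NAMES))
    validation_error("dimension table must list dimensions %s",
                     paste(DIMENSION_NAMES, collapse = ", "))
  for (g in j$groups) {
    if (!all(vertebral_levels() %in% names(g$levels)))
      validation_error("group %s is missing levels", g$index)
    for (lv in vertebral_levels()) {
      v <- unlist(g$levels[[lv]])
      if (length(v) != 7 || any(!is.finite(v)) || any(v <= 0) || any(v >= 50))
        validation_error("group %s %s: need 7 finite dimensions in (0, 50) mm",
                         g$index, lv)
    }
  }
  j
}

#' Packaged lumbar dimension table
#'
#' All 25 (age group x lumbar level) mean osteometric records in long-wide
#' form: one row per group/level with the seven body dimensions in mm
#' (AVBH/PVBH anterior/posterior body heights, SVBL/IVBL superior/inferior
#' body lengths, SVBW/MVBW/IVBW superior/middle/inferior body widths).
#'
#' @param path optional path to a user dimension table (JSON,
#'   schema `pedspine-dimensions-v1`) replacing the packaged one.
#' @return A tibble with 25 rows and columns `group`, `level`, then the
#'   seven dimensions.
#' @export
lumbar_dimensions <- function(path = NULL) {
  tb <- dimension_data(path)
  rows <- list()
  for (g in tb$groups) {
    for (lv in vertebral_levels()) {
      v <- as.numeric(unlist(g$levels[[lv]]))
      rows[[length(rows) + 1]] <- tibble(group = g$index, level = lv,
                                         !!!setNames(as.list(v), DIMENSION_NAMES))
    }
  }
  bind_rows(rows)
}

#' Look up the dimensions of one vertebral body
#'
#' Returns the packaged mean record for an age group and lumbar level,
#' exactly as printed in the dimension table.
#'
#' @param group age-group index, 1 to 5 (1 = newborn ... 5 = preadolescent).
#' @param level lumbar level, one of `"L1"` ... `"L5"`.
#' @param path optional user dimension table (JSON) of the packaged schema.
#' @return A `vertebral_dimensions` object: named list of the seven
#'   dimensions (mm) with `group` and `level` attributes.
#' @examples
#' get_dimensions(1, "L3")$MVBW  # 15.2 mm
#' @export
get_dimensions <- function(group, level, path = NULL) {
  tb <- dimension_data(path)
  gi <- vapply(tb$groups, function(g) g$index, numeric(1))
  if (!(is.numeric(group) && length(group) == 1 && group %in% gi))
    lookup_error("unknown age group '%s' (valid: %s)",
                 paste(group, collapse = ","), paste(gi, collapse = ", "))
  if (!(is.character(level) && length(level) == 1 && level %in% vertebral_levels()))
    lookup_error("unknown vertebral level '%s' (valid: %s)",
                 paste(level, collapse = ","), paste(vertebral_levels(), collapse = ", "))
  g <- tb$groups[[which(gi == group)]]
  v <- as.numeric(unlist(g$levels[[level]]))
  dims <- setNames(as.list(v), DIMENSION_NAMES)
  structure(dims, group = group, level = level, class = "vertebral_dimensions")
}

#' @export
print.vertebral_dimensions <- function(x, ...) {
  cat(sprintf("<vertebral_dimensions: group %s, %s>\n",
              attr(x, "group"), attr(x, "level")))
  print(unlist(x))
  invisible(x)
}

#' @export
as_tibble.vertebral_dimensions <- function(x, ...) {
  tibble(group = attr(x, "group"), level = attr(x, "level"),
         !!!setNames(as.list(unlist(x)), names(x)))
}

validate_dimensions <- function(dims) {
  v <- unlist(dims[DIMENSION_NAMES])
  if (length(v) != 7 || any(!is.finite(v)) || any(v <= 0))
    validation_error("all seven body dimensions must be positive and finite")
  invisible(dims)
}

# ----------------------------------------------------------------- materials

material_data <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$mats)) {
      the$mats <- jsonlite::read_json(
        system.file("extdata", "tissue_materials.json", package = "pedspine"),
        simplifyVector = TRUE, simplifyDataFrame = FALSE)
    }
    return(the$mats)
  }
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Biomechanical material registry
#'
#' Linear-elastic properties (Young's modulus E in MPa, Poisson's ratio)
#' for the five model tissues: cortical bone, trabecular bone, cartilage,
#' nucleus pulposus and annulus fibrosus. These travel with exported
#' geometry for finite-element preprocessing.
#'
#' @return A tibble with columns `tissue`, `youngs_modulus_E`,
#'   `poisson_ratio_nu`.
#' @export
tissue_materials <- function() {
  md <- material_data()
  tibble(
    tissue = map_chr(md$materials, "tissue"),
    youngs_modulus_E = map_dbl(md$materials, "youngs_modulus_E"),
    poisson_ratio_nu = map_dbl(md$materials, "poisson_ratio_nu"))
}

#' Look up one tissue material
#'
#' @param tissue tissue name (case-insensitive), one of the registry names.
#' @return A `tissue_material` object: list with `tissue`,
#'   `youngs_modulus_E` (MPa) and `poisson_ratio_nu`.
#' @examples
#' get_material("cortical bone")$youngs_modulus_E  # 12000 MPa
#' @export
get_material <- function(tissue) {
  reg <- tissue_materials()
  hit <- which(tolower(reg$tissue) == tolower(trimws(tissue)))
  if (length(hit) != 1)
    lookup_error("unknown tissue '%s'; valid tissues: %s",
                 tissue, paste(reg$tissue, collapse = ", "))
  m <- as.list(reg[hit, ])
  structure(m, class = "tissue_material")
}

#' @export
print.tissue_material <- function(x, ...) {
  cat(sprintf("<tissue_material: %s, E = %g MPa, nu = %g>\n",
              x$tissue, x$youngs_modulus_E, x$poisson_ratio_nu))
  invisible(x)
}

# -------------------------------------------------------- derived parameters

# Default fractions for the arch/process measurements the source osteometric
# study references but does not tabulate. One place, user-overridable.
ARCH_DEFAULT_FRACTIONS <- list(
  pedicle_width             = list(of = "MVBW", frac = 0.20),
  pedicle_height            = list(of = "PVBH", frac = 0.55),
  arch_plate_thickness      = list(of = "MVBW", frac = 0.12),
  transverse_process_length = list(of = "MVBW", frac = 0.45),
  spinous_process_length    = list(of = "SVBL", frac = 0.50),
  foramen_sagittal_diameter = list(of = "IVBL", frac = 0.80))

# frontal canal fraction of MVBW by age group: the newborn canal is nearly
# circular (frontal extent matched to the sagittal one), widening frontally
# with growth toward the triangle-like older form
FORAMEN_FRONTAL_FRAC <- c(0.45, 0.55, 0.60, 0.60, 0.60)

#' Derive vertebral-arch build parameters from body dimensions
#'
#' The construction steps for the posterior elements consume pedicle,
#' process and foramen measurements that the packaged osteometric table does
#' not print. Each is defaulted as a documented fraction of a printed body
#' dimension (preserving cross-age scaling), and each can be overridden:
#'
#' * `pedicle_width` = 0.20 x MVBW
#' * `pedicle_height` = 0.55 x PVBH
#' * `arch_plate_thickness` = 0.12 x MVBW
#' * `transverse_process_length` = 0.45 x MVBW
#' * `spinous_process_length` = 0.50 x SVBL
#' * `foramen_frontal_diameter` = 0.60 x MVBW (0.45 and 0.55 for the two
#'   youngest groups, where the canal is nearly circular)
#' * `foramen_sagittal_diameter` = 0.80 x IVBL
#' * `articular_process_length` = PVBH x (1 + disc height ratio) / 2 + 1 mm,
#'   sized so superior and inferior facets of adjacent vertebrae overlap
#'   across the disc space
#' * `fillet_radius` = 0.10 x min(pedicle_width, arch_plate_thickness)
#' * `facet_cutout_diameter` — solved, not defaulted: bisection on the
#'   measured facet gap (see [solve_facet_cutout()])
#'
#' @param dims a `vertebral_dimensions` record (see [get_dimensions()]).
#' @param group age-group index 1-5 (sets the disc-height ratio used for the
#'   articular process length).
#' @param overrides named list of parameter values replacing defaults.
#' @param config a [pedspine_config()] list.
#' @return A `derived_arch_parameters` named list (mm).
#' @export
derive_arch_parameters <- function(dims, group, overrides = list(),
                                   config = pedspine_config()) {
  validate_dimensions(dims)
  p <- lapply(ARCH_DEFAULT_FRACTIONS, function(d) d$frac * dims[[d$of]])
  p$foramen_frontal_diameter <- FORAMEN_FRONTAL_FRAC[[group]] * dims$MVBW
  ratio <- config$disc$height_ratio[[group]]
  # half the segment pitch plus overlap: guarantees the superior and
  # inferior facets of adjacent vertebrae overlap across the disc space
  p$articular_process_length <- dims$PVBH * (1 + ratio) / 2 + 1.0
  p$fillet_radius <- 0.10 * min(p$pedicle_width, p$arch_plate_thickness)
  # facet geometry: inferior process cylinder radius from pedicle width
  p$facet_ridge_radius <- 0.45 * p$pedicle_width
  known <- c(names(p), "facet_cutout_diameter")
  bad <- setdiff(names(overrides), known)
  if (length(bad) > 0)
    validation_error("unknown arch parameter override(s): %s",
                     paste(bad, collapse = ", "))
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0)
      validation_error("arch parameter override '%s' must be a positive number", nm)
    p[[nm]] <- val
  }
  if (p$foramen_frontal_diameter >= dims$MVBW)
    geometry_error("foramen frontal diameter (%.2f) must be smaller than MVBW (%.2f)",
                   p$foramen_frontal_diameter, dims$MVBW)
  if (p$foramen_sagittal_diameter >= dims$IVBL)
    geometry_error("foramen sagittal diameter (%.2f) must be smaller than IVBL (%.2f)",
                   p$foramen_sagittal_diameter, dims$IVBL)
  if (is.null(p$facet_cutout_diameter)) {
    p$facet_cutout_diameter <- solve_facet_cutout(
      p$facet_ridge_radius, target_gap = config$facet$target_gap_mm)
  }
  structure(p, class = "derived_arch_parameters", group = group)
}

#' Solve the articular facet cutout diameter
#'
#' The mating articular surfaces are a convex cylindrical ridge (inferior
#' articular process) seated in a concave cylindrical cutout (superior
#' articular process). The cutout diameter is not defaulted but solved by
#' bisection on the measured mesh-to-mesh gap of the mated pair until the
#' clearance reaches `target_gap` (a fraction of the 0.5 mm joint-gap cap,
#' leaving headroom for assembly tilts).
#'
#' @param ridge_radius radius of the convex facet ridge, mm.
#' @param target_gap desired radial clearance, mm (< 0.5).
#' @param tol bisection tolerance on the measured gap, mm.
#' @return Cutout diameter in mm.
#' @export
solve_facet_cutout <- function(ridge_radius, target_gap = 0.3, tol = 0.02) {
  if (target_gap <= 0 || target_gap > 0.5)
    validation_error("facet target gap must be in (0, 0.5] mm")
  # memoise: gap geometry depends only on (ridge_radius, target_gap)
  key <- sprintf("facet:%.6f:%.6f", ridge_radius, target_gap)
  if (!is.null(the$facet_cache[[key]])) return(the$facet_cache[[key]])
  h <- 4 * ridge_radius
  ridge <- extrude(planar_profile(profile_circle(ridge_radius, segments = 64),
                                  plane = "transverse"), h)
  gap_at <- function(D) {
    groove <- facet_groove_solid(D / 2, ridge_radius, h)
    as.numeric(min_distance(ridge, groove))
  }
  lo <- 2 * ridge_radius + 0.5 * target_gap
  hi <- 2 * ridge_radius + 4 * target_gap
  glo <- gap_at(lo); ghi <- gap_at(hi)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    g <- gap_at(mid)
    if (abs(g - target_gap) < tol) { lo <- hi <- mid; break }
    if (g < target_gap) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  D <- (lo + hi) / 2
  if (is.null(the$facet_cache)) the$facet_cache <- list()
  the$facet_cache[[key]] <- D
  D
}

# concave groove block: a slab carrying a cylindrical bite of radius
# r_groove about the origin, wrapping 120 degrees and facing +x (where the
# ridge cylinder sits, concentric); vertical extrusion
facet_groove_solid <- function(r_groove, ridge_radius, height,
                               wrap_deg = 120, origin = c(0, 0, 0)) {
  wrap <- wrap_deg * pi / 180
  th <- seq(pi - wrap / 2, pi + wrap / 2, length.out = 33)
  arc <- cbind(r_groove * cos(th), r_groove * sin(th))
  back <- -2 * r_groove
  poly <- rbind(arc,  # top -> bottom along the bite
                c(back, min(arc[, 2])),
                c(back, max(arc[, 2])))
  extrude(planar_profile(poly, plane = "transverse", origin = origin), height)
}
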