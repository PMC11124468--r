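# Configuration: every tunable default of the builders lives in one nested
# namespace, serialisable to/from JSON, with schema validation. Identical
# config + identical calls give byte-identical geometry (no randomness
# anywhere in the builders).

#' Build configuration
#'
#' Returns the full configuration namespace with every documented default,
#' optionally modified. Values (units in names or docs; all lengths mm,
#' angles degrees):
#'
#' * `kernel`: `voxel` boolean-field pitch (mm), `segments` facets per full
#'   revolution (chord error well under 0.05 mm at vertebral scales).
#' * `body`: `plateau` fraction of body height over which the width/depth
#'   profiles hold their endplate values; `fossa_depth_frac` and
#'   `fossa_width_frac` of the central endplate fossa cutouts;
#'   `step_depth_frac`/`step_inset_frac` of the preadolescent ring-apophysis
#'   "step" rebate (fractions of PVBH and of width); `notch_count` and
#'   `notch_depth_frac` of the endplate rim indentations for groups 3-5.
#' * `arch`: process scale factors per age group (`transverse_scale`,
#'   `spinous_scale`), spinous slant in degrees per group (negative = tipped
#'   caudally), `cartilage_thickness_frac` of pedicle width,
#'   `group2_l5_midline_cartilage` flag (the L5 exception; off by default so
#'   the four-component count holds).
#' * `disc`: `wedge_angle_deg` (7), `height_ratio` disc-to-body height per
#'   group, `cavity_fraction` (0.5) with `cavity_tol`, nucleus `clearance_mm`.
#' * `spine`: `lordosis_deg` total lordotic angle per group, `contact_gap_mm`
#'   target stacking clearance, `endplate_thickness_frac` of L5 PVBH for the
#'   S1 plate.
#' * `facet`: `target_gap_mm` nominal articular clearance (< 0.5).
#'
#' @param ... named overrides, either nested lists (`disc =
#'   list(wedge_angle_deg = 0)`) or dotted names (`"disc.wedge_angle_deg"`).
#' @return A nested list of class `pedspine_config`.
#' @export
pedspine_config <- function(...) {
  cfg <- list(
    kernel = list(
      voxel = 0.3,
      fused_voxel = 0.4,
      fine_voxel = 0.2,
      segments = 64),
    body = list(
      plateau = 0.15,
      fossa_depth_frac = 0.05,
      fossa_width_frac = 0.55,
      step_depth_frac = 0.05,
      step_inset_frac = 0.05,
      notch_count = 8,
      notch_depth_frac = 0.02),
    arch = list(
      transverse_scale = c(0.40, 0.50, 0.90, 1.00, 1.00),
      spinous_scale = c(0.00, 0.25, 0.35, 1.00, 1.00),
      spinous_slant_deg = c(0, 0, 0, -15, 0),
      cartilage_thickness_frac = 0.15,
      group2_l5_midline_cartilage = FALSE,
      fillet_groups = c(4, 5)),
    disc = list(
      wedge_angle_deg = 7,
      height_ratio = c(1.0, 0.8, 0.6, 0.4, 0.3),
      cavity_fraction = 0.5,
      cavity_tol = 0.005,
      clearance_mm = 0.05),
    spine = list(
      lordosis_deg = c(0, 0, 15, 25, 30),
      contact_gap_mm = 0.02,
      endplate_thickness_frac = 0.30),
    facet = list(
      target_gap_mm = 0.3))
  cfg <- modify_config(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = c("pedspine_config", "list"))
}

modify_config <- function(cfg, mods) {
  for (nm in names(mods)) {
    val <- mods[[nm]]
    if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2 || is.null(cfg[[parts[1]]]))
        validation_error("unknown config entry '%s'", nm)
      cfg[[parts[1]]][[parts[2]]] <- val
    } else if (is.list(val)) {
      if (is.null(cfg[[nm]])) validation_error("unknown config section '%s'", nm)
      for (sub in names(val)) cfg[[nm]][[sub]] <- val[[sub]]
    } else {
      validation_error("config overrides must be nested lists or dotted names (got '%s')", nm)
    }
  }
  cfg
}

validate_config <- function(cfg) {
  need5 <- function(x, nm) {
    if (length(x) != 5 || any(!is.finite(x)))
      validation_error("config '%s' needs 5 finite values (one per age group)", nm)
  }
  pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      validation_error("config '%s' must be a positive number", nm)
  }
  pos(cfg$kernel$voxel, "kernel.voxel")
  pos(cfg$kernel$fused_voxel, "kernel.fused_voxel")
  pos(cfg$kernel$fine_voxel, "kernel.fine_voxel")
  if (cfg$kernel$segments < 16) validation_error("kernel.segments must be >= 16")
  if (cfg$body$plateau <= 0 || cfg$body$plateau >= 0.5)
    validation_error("body.plateau must be in (0, 0.5)")
  need5(cfg$disc$height_ratio, "disc.height_ratio")
  if (any(cfg$disc$height_ratio <= 0 | cfg$disc$height_ratio > 1.5))
    validation_error("disc.height_ratio values must be in (0, 1.5]")
  if (cfg$disc$wedge_angle_deg < 0 || cfg$disc$wedge_angle_deg > 20)
    validation_error("disc.wedge_angle_deg must be in [0, 20] degrees")
  if (cfg$disc$cavity_fraction <= 0.1 || cfg$disc$cavity_fraction >= 0.9)
    validation_error("disc.cavity_fraction must be in (0.1, 0.9)")
  need5(cfg$spine$lordosis_deg, "spine.lordosis_deg")
  need5(cfg$arch$transverse_scale, "arch.transverse_scale")
  need5(cfg$arch$spinous_scale, "arch.spinous_scale")
  need5(cfg$arch$spinous_slant_deg, "arch.spinous_slant_deg")
  if (cfg$facet$target_gap_mm <= 0 || cfg$facet$target_gap_mm > 0.5)
    validation_error("facet.target_gap_mm must be in (0, 0.5]")
  invisible(cfg)
}

#' Read and write configuration files
#'
#' Configurations serialise to JSON; a written file read back yields an
#' identical configuration. Partial files are merged over the defaults.
#'
#' @param path file path.
#' @return `read_config()`: a validated `pedspine_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) lookup_error("config file '%s' not found", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j <- rapply(j, function(x) if (is.integer(x)) as.numeric(x) else x,
              how = "replace")
  j <- lapply(j, as.list)
  cfg <- pedspine_config()
  cfg <- modify_config(unclass(cfg), j)
  validate_config(cfg)
  structure(cfg, class = c("pedspine_config", "list"))
}

#' @rdname read_config
#' @param config a `pedspine_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
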