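# Vertebra builder: the 12-step construction realised as a parametric
# pipeline — lofted body with endplate features, posterior arch ring with
# pedicle limbs, transverse/spinous/articular processes, vertebral foramen,
# then age-dependent splitting into tissue-labelled components:
# newborn (6: body + two semi-arches, bridged by two pedicle cartilages and
# a midline cartilage), infant/toddler (4: body + arch + two cartilaginous
# pedicles), middle childhood/preadolescent (1 fused bony solid with edge
# rounding and, for preadolescents, the ring-apophysis "step" rebate).

box_xyz <- function(xlim, ylim, zlim, name = NULL) {
  solid_box(diff(xlim), diff(ylim), diff(zlim),
            center = c(mean(xlim), mean(ylim), mean(zlim)), name = name)
}

#' Build the vertebral body solid
#'
#' Lofted cross-sections scaled to the printed widths/depths (IVBW/MVBW/SVBW,
#' IVBL/SVBL) with a flat inferior face, a superior plane calibrated to the
#' printed heights (PVBH posteriorly, AVBH at the anterior station), central
#' endplate fossae cut into both faces, rim notches for groups 3-5 and the
#' marginal "step" rebate for group 5.
#'
#' @param dims a `vertebral_dimensions` record.
#' @param group age-group index 1-5.
#' @param config a [pedspine_config()].
#' @param raw if TRUE skip endplate cutouts (used internally when the body
#'   enters a fused union that applies them once).
#' @return A [tri_solid()] with attribute `frame` (the measurement frame).
#' @export
build_body <- function(dims, group, config = pedspine_config(), raw = FALSE) {
  validate_dimensions(dims)
  bl <- body_loft(dims, group, config)
  if (raw) {
    attr(bl$solid, "frame") <- bl$frame
    return(bl$solid)
  }
  tools <- body_cut_tools(dims, group, config, bl$frame)
  out <- solid_csg(add = list(bl$solid), subtract = tools,
                   voxel = config$kernel$voxel, name = "body")
  attr(out, "frame") <- bl$frame
  out
}

# endplate feature tools: fossae (all groups), rim notches (groups >= 3),
# step rebate rings (group 5)
body_cut_tools <- function(dims, group, config, frame) {
  tools <- list()
  yc_t <- frame$yc_frac * dims$SVBL
  yc_b <- frame$yc_frac * dims$IVBL
  depth <- config$body$fossa_depth_frac * dims$PVBH
  wfr <- config$body$fossa_width_frac
  a_t <- wfr * min(dims$SVBW, dims$SVBL) / 2
  a_b <- wfr * min(dims$IVBW, dims$IVBL) / 2
  rs_t <- (a_t^2 + depth^2) / (2 * depth)
  rs_b <- (a_b^2 + depth^2) / (2 * depth)
  # centre the top sphere along the (inclined) superior-plane normal so the
  # cap is symmetric about the endplate
  nrm_t <- c(0, -frame$sup_k, 1) / sqrt(1 + frame$sup_k^2)
  tools$fossa_top <- solid_sphere(
    rs_t, c(0, yc_t, sup_z(frame, yc_t)) + nrm_t * (rs_t - depth), segments = 48)
  tools$fossa_bottom <- solid_sphere(rs_b, c(0, yc_b, depth - rs_b), segments = 48)
  if (group >= 3) {
    nd <- max(0.6, config$body$notch_depth_frac * dims$PVBH * 2)
    prof <- body_profile_shape(group)
    # rim positions clear of the measured extremes: not at the anterior
    # apex (|x| small) and not at the lateral-most points (|x| near 1/2)
    arc <- prof[prof[, 2] > 0.25 & abs(prof[, 1]) > 0.08 &
                  abs(prof[, 1]) < 0.40, , drop = FALSE]
    idx <- round(seq(1, nrow(arc), length.out = config$body$notch_count + 2))
    idx <- unique(idx[c(-1, -length(idx))])
    for (i in idx) {
      px <- arc[i, 1] * dims$SVBW; py <- arc[i, 2] * dims$SVBL
      tools[[paste0("notch_t", i)]] <-
        solid_box(nd, nd, nd, center = c(px * 0.99, py * 0.99, sup_z(frame, py)))
      px <- arc[i, 1] * dims$IVBW; py <- arc[i, 2] * dims$IVBL
      tools[[paste0("notch_b", i)]] <-
        solid_box(nd, nd, nd, center = c(px * 0.99, py * 0.99, 0))
    }
  }
  if (frame$step_depth > 0) {
    tools <- c(tools, step_tools(dims, group, config, frame))
  }
  tools
}

# ring-apophysis rebate: an (inclined) slab over the endplate margin minus a
# centrally scaled prism, leaving a marginal "step" cut
step_tools <- function(dims, group, config, frame) {
  step <- frame$step_depth
  inset <- frame$step_inset
  vox <- config$kernel$voxel
  prof <- body_profile_shape(group)
  ctr <- polygon_centroid(prof)
  scale_about <- function(pts, s, c2) sweep(sweep(pts, 2, c2), 2, c(s, s), "*") +
    matrix(c2, nrow(pts), 2, byrow = TRUE)
  mk <- function(top) {
    w <- if (top) dims$SVBW else dims$IVBW
    d <- if (top) dims$SVBL else dims$IVBL
    inner2d <- scale_about(cbind(prof[, 1] * w, prof[, 2] * d), 1 - 2 * inset,
                           c(0, ctr[2] * d))
    if (top) {
      k <- frame$sup_k
      zlo <- frame$sup_z0 - step
      corners <- cbind(c(-w, w, w, -w) * 0.75, c(0.5, 0.5, d + 2, d + 2))
      ring1 <- cbind(corners, zlo + k * corners[, 2])
      ring2 <- cbind(corners, zlo + k * corners[, 2] + 4)
      slab <- loft_sections(list(ring1, ring2))
      inner <- extrude(planar_profile(inner2d, plane = "transverse",
                                      origin = c(0, 0, zlo - 2)), step + 10)
    } else {
      slab <- box_xyz(c(-w, w) * 0.75, c(0.5, d + 2), c(-3, step))
      inner <- extrude(planar_profile(inner2d, plane = "transverse",
                                      origin = c(0, 0, -4)), step + 8)
    }
    solid_difference(slab, inner, voxel = vox)
  }
  list(step_top = mk(TRUE), step_bottom = mk(FALSE))
}

# ------------------------------------------------------- posterior elements

# layout of the posterior elements in the build frame (posterior body wall
# at y = 0, arch centred at mid posterior height)
arch_geometry <- function(dims, arch, group, config) {
  if (arch$foramen_frontal_diameter >= dims$MVBW)
    geometry_error("foramen frontal diameter %.1f exceeds the body width %.1f",
                   arch$foramen_frontal_diameter, dims$MVBW)
  if (arch$foramen_sagittal_diameter >= dims$IVBL)
    geometry_error("foramen sagittal diameter %.1f exceeds the body length %.1f",
                   arch$foramen_sagittal_diameter, dims$IVBL)
  a <- arch$foramen_frontal_diameter / 2
  b <- arch$foramen_sagittal_diameter / 2
  pw <- arch$pedicle_width
  ph <- arch$pedicle_height
  ta <- arch$arch_plate_thickness
  zc <- dims$PVBH / 2
  phi_l <- 25 * pi / 180
  x_in <- a * sin(phi_l)
  x_out <- x_in + pw
  # penetration into the body: posterior wall height at the limb x-range
  prof <- body_profile_shape(group)
  w_mid <- dims$MVBW; d_mid <- (dims$SVBL + dims$IVBL) / 2
  wall <- prof[prof[, 2] < 0.5, , drop = FALSE]
  wx <- abs(wall[, 1]) * w_mid; wy <- wall[, 2] * d_mid
  sel <- wx >= x_in & wx <= x_out + 0.5
  y_pen <- (if (any(sel)) max(wy[sel]) else 0) + 0.6
  fr <- facet_reference(group, config)
  list(a = a, b = b, pw = pw, ph = ph, ta = ta, zc = zc,
       phi_l = phi_l, x_in = x_in, x_out = x_out, y_pen = y_pen,
       y_stub = -(1 - cos(phi_l)) * b - 0.25,
       s_apl = arch$articular_process_length,
       x_f = fr$x_f, y_f = fr$y_f,
       r_ridge = fr$r_ridge, r_groove = fr$r_groove,
       t_mid = config$arch$cartilage_thickness_frac * pw)
}

# facet joint geometry is uniform within an age group (anchored on the L3
# record), so facets of adjacent levels mate coaxially in the assembly
facet_reference <- function(group, config) {
  key <- sprintf("facetref:%d:%.4f", group, config$facet$target_gap_mm)
  if (!is.null(the$facet_cache[[key]])) return(the$facet_cache[[key]])
  d3 <- get_dimensions(group, "L3")
  a <- FORAMEN_FRONTAL_FRAC[[group]] * d3$MVBW / 2
  b <- 0.80 * d3$IVBL / 2
  pw <- 0.20 * d3$MVBW
  ta <- 0.12 * d3$MVBW
  r_ridge <- 0.45 * pw
  r_groove <- solve_facet_cutout(r_ridge,
                                 target_gap = config$facet$target_gap_mm) / 2
  x_f <- a * sin(25 * pi / 180) + 0.5 * pw
  ao <- a + pw; bo <- b + ta
  y_out <- -b - bo * cos(asin(min(0.99, x_f / ao)))
  # groove block must overlap the arch ring; ridge stays attached too
  fr <- list(x_f = x_f, y_f = y_out + 0.3 + 0.5 * r_groove,
             r_ridge = r_ridge, r_groove = r_groove)
  if (is.null(the$facet_cache)) the$facet_cache <- list()
  the$facet_cache[[key]] <- fr
  fr
}

# inner foramen boundary: ellipse for the rounded canal of groups 1-3, a
# tapered (triangle-like) canal for groups 4-5; phi = 0 at the top, pi at
# the posterior apex; x>0 branch for phi in (0, pi)
foramen_point <- function(phi, geo, group) {
  taper <- if (group >= 4) ((1 + cos(phi)) / 2)^0.55 else 1
  cbind(geo$a * sin(phi) * taper, -geo$b + geo$b * cos(phi))
}

foramen_polygon <- function(geo, group, n = 64) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  foramen_point(ifelse(phi <= pi, phi, phi - 2 * pi), geo, group)
}

# full foramen cutting prism: canal cross-section plus a chimney reaching
# (just short of) the posterior body wall between the pedicle limbs
foramen_prism <- function(geo, group, zlim) {
  phi <- seq(geo$phi_l, 2 * pi - geo$phi_l, length.out = 80)
  inner <- foramen_point(ifelse(phi <= pi, phi, phi - 2 * pi), geo, group)
  x_top <- inner[1, 1]
  poly <- rbind(c(x_top, -0.02), inner, c(-x_top, -0.02))
  poly <- poly[!duplicated(round(poly, 9)), , drop = FALSE]
  extrude(planar_profile(poly, plane = "transverse", origin = c(0, 0, zlim[1])),
          diff(zlim), name = "foramen")
}

# the arch ring prism: C-ring (groups 1-3, limbs replaced by cartilage) or
# full ring with limbs reaching into the body (groups 4-5)
arch_ring <- function(geo, group, config) {
  bo <- geo$b + geo$ta
  ao <- geo$a + geo$pw
  top_y <- if (group <= 3) geo$y_stub else geo$y_pen
  # inner attachment: on the canal boundary where it reaches top_y (C-ring)
  # or at the limb walls (full ring)
  if (group <= 3) {
    cphi <- max(-1, min(1, 1 + top_y / geo$b))
    phi_in <- acos(cphi)
    wall_in <- FALSE
  } else {
    phi_in <- geo$phi_l
    wall_in <- TRUE
  }
  phi_i <- seq(phi_in, 2 * pi - phi_in, length.out = 72)
  inner <- foramen_point(ifelse(phi_i <= pi, phi_i, phi_i - 2 * pi), geo, group)
  x_in_eff <- inner[1, 1]
  x_out <- x_in_eff + geo$pw
  phi_out <- asin(min(0.995, x_out / ao))
  phi_o <- seq(2 * pi - phi_out, phi_out, length.out = 72)
  outer <- cbind(ao * sin(ifelse(phi_o <= pi, phi_o, phi_o - 2 * pi)),
                 -geo$b + bo * cos(phi_o))
  pts <- rbind(
    c(x_in_eff, top_y),
    inner,
    c(-x_in_eff, top_y),
    c(-x_out, top_y),
    outer,
    c(x_out, top_y))
  pts <- pts[!duplicated(round(pts, 8)), , drop = FALSE]
  extrude(planar_profile(pts, plane = "transverse",
                         origin = c(0, 0, geo$zc - geo$ph / 2)),
          geo$ph, name = "arch ring")
}

#' Build the posterior vertebral elements
#'
#' Arch ring with pedicle limbs, transverse processes (parallelepipeds on
#' the lateral arch), spinous process (group-scaled; subtly downward-slanted
#' for group 4, a short horizontal plate for group 5), superior articular
#' processes carrying the concave facet cutouts, inferior articular ridges,
#' and the vertebral foramen cutting prism.
#'
#' @inheritParams build_body
#' @param arch derived arch parameters (see [derive_arch_parameters()]).
#' @return Named list of [tri_solid()]s (the `foramen` entry is the cutting
#'   tool, not a component) plus the `geometry` layout list.
#' @export
build_posterior_elements <- function(dims, arch, group,
                                     config = pedspine_config()) {
  geo <- arch_geometry(dims, arch, group, config)
  el <- list()
  el$ring <- arch_ring(geo, group, config)
  # transverse processes: parallelepipeds on the lateral aspect of the arch
  ao <- geo$a + geo$pw
  lt <- config$arch$transverse_scale[group] * arch$transverse_process_length
  tp_x0 <- ao - 0.8 * geo$pw
  el$tp_right <- box_xyz(c(tp_x0, ao + lt), -geo$b + c(-0.4, 0.4) * geo$pw,
                         geo$zc + c(-0.25, 0.25) * geo$ph, name = "transverse process")
  el$tp_left <- mirror_solid(el$tp_right)
  # spinous process (absent for group 1 by default)
  ls <- config$arch$spinous_scale[group] * arch$spinous_process_length
  if (ls > 0.1) {
    sp <- box_xyz(c(-0.35, 0.35) * geo$pw,
                  c(-(2 * geo$b + geo$ta + ls), -(2 * geo$b + geo$ta) + 1),
                  geo$zc + c(-0.35, 0.35) * geo$ph, name = "spinous process")
    slant <- config$arch$spinous_slant_deg[group]
    if (abs(slant) > 1e-9)
      sp <- rotate_solid(sp, axis = c(1, 0, 0), angle_deg = slant,
                         center = c(0, -(2 * geo$b + geo$ta), geo$zc))
    el$spinous <- sp
  }
  # articular processes: superior concave grooves, inferior convex ridges
  s <- geo$s_apl
  groove <- facet_groove_solid(geo$r_groove, geo$r_ridge, s)
  groove <- rotate_solid(groove, axis = c(0, 0, 1), angle_deg = 90)
  el$sup_process_right <- translate_solid(groove, c(geo$x_f, geo$y_f, geo$zc))
  el$sup_process_left <- mirror_solid(el$sup_process_right)
  ridge <- extrude(planar_profile(profile_circle(geo$r_ridge, segments = 64),
                                  plane = "transverse"), s)
  el$inf_process_right <- translate_solid(ridge, c(geo$x_f, geo$y_f, geo$zc - s))
  el$inf_process_left <- mirror_solid(el$inf_process_right)
  zlim <- c(geo$zc - geo$ph / 2 - s - 2, geo$zc + geo$ph / 2 + s + 2)
  el$foramen <- foramen_prism(geo, group, zlim)
  el$geometry <- geo
  el
}

# ------------------------------------------------------------- assembly

new_labeled_component <- function(solid, tissue, anatomical_name) {
  list(solid = solid, tissue = tissue, anatomical_name = anatomical_name)
}

#' Split posterior/body solids into tissue-labelled components
#'
#' Applies the age-dependent component architecture: six components for
#' newborns (three bone, three cartilage), four for infants/toddlers, one
#' fused bony solid (rounded, and with the marginal step rebate for
#' preadolescents) for groups 4-5.
#'
#' @param body the body solid from [build_body()] (raw, uncut, when group
#'   is 4 or 5).
#' @param posterior list from [build_posterior_elements()].
#' @inheritParams build_body
#' @param dims,arch the records used to build the inputs.
#' @param level vertebral level (metadata).
#' @return A `vertebra_model`.
#' @export
split_and_label <- function(body, posterior, group, level, dims, arch,
                            config = pedspine_config()) {
  geo <- posterior$geometry
  vox <- config$kernel$voxel
  frame <- attr(body, "frame")
  bone <- get_material("cortical bone")
  cart <- get_material("cartilage")
  comps <- list()
  right_side <- c("tp_right", "sup_process_right", "inf_process_right")
  left_side <- c("tp_left", "sup_process_left", "inf_process_left")
  if (group <= 3) {
    # clearance-dilated body keeps the bony arch off the body; cartilage
    # pedicles bridge the gap exactly
    bc <- cpp_offset(body$vertices, body$faces, 0.4, vox)
    body_clear <- tri_solid(bc$vertices, bc$faces, name = "body clearance")
    # cartilage conforms to the body with a hair of clearance so re-meshed
    # surfaces never interpenetrate
    bn <- cpp_offset(body$vertices, body$faces, 0.03, vox)
    body_near <- tri_solid(bn$vertices, bn$faces, name = "body near-offset")
    ped <- function(sgn) {
      bx <- box_xyz(sort(sgn * c(geo$x_in * 0.98, geo$x_out)),
                    c(geo$y_stub, geo$y_pen),
                    geo$zc + c(-0.5, 0.5) * geo$ph)
      solid_csg(add = list(bx), subtract = list(body_near, posterior$foramen),
                voxel = vox,
                name = paste(if (sgn > 0) "right" else "left", "pedicle cartilage"))
    }
    if (group == 1) {
      big <- 4 * dims$MVBW
      cutR <- box_xyz(c(-geo$t_mid / 2, big), c(-big, big), c(-big, big))
      cutL <- box_xyz(c(-big, geo$t_mid / 2), c(-big, big), c(-big, big))
      semi <- function(side) {
        adds <- c(list(posterior$ring), posterior[if (side > 0) right_side else left_side])
        solid_csg(add = adds,
                  subtract = list(posterior$foramen, body_clear,
                                  if (side > 0) cutL else cutR),
                  voxel = vox,
                  name = paste(if (side > 0) "right" else "left", "semi-arch"))
      }
      mid_cart <- box_xyz(c(-1, 1) * geo$t_mid / 2,
                          c(-(2 * geo$b + geo$ta) + 0.1, -2 * geo$b - 0.1),
                          geo$zc + c(-0.45, 0.45) * geo$ph,
                          name = "midline cartilage")
      comps <- list(
        new_labeled_component(body, bone, "body"),
        new_labeled_component(semi(1), bone, "right semi-arch"),
        new_labeled_component(semi(-1), bone, "left semi-arch"),
        new_labeled_component(ped(1), cart, "right pedicle cartilage"),
        new_labeled_component(ped(-1), cart, "left pedicle cartilage"),
        new_labeled_component(mid_cart, cart, "midline cartilage"))
    } else {
      midline_cart <- isTRUE(config$arch$group2_l5_midline_cartilage) &&
        group == 2 && identical(level, "L5")
      subs <- list(posterior$foramen, body_clear)
      if (midline_cart) {
        subs <- c(subs, list(box_xyz(c(-1, 1) * geo$t_mid / 2,
                                     c(-(2 * geo$b + geo$ta) - 1, -2 * geo$b + 0.5),
                                     geo$zc + c(-0.6, 0.6) * geo$ph)))
      }
      adds <- c(list(posterior$ring), posterior[right_side], posterior[left_side],
                posterior["spinous"])
      adds <- adds[!vapply(adds, is.null, logical(1))]
      arch_solid <- solid_csg(add = adds, subtract = subs, voxel = vox,
                              name = "vertebral arch")
      comps <- list(
        new_labeled_component(body, bone, "body"),
        new_labeled_component(arch_solid, bone, "vertebral arch"),
        new_labeled_component(ped(1), cart, "right pedicle cartilage"),
        new_labeled_component(ped(-1), cart, "left pedicle cartilage"))
      if (midline_cart) {
        comps <- c(comps, list(new_labeled_component(
          box_xyz(c(-1, 1) * geo$t_mid / 2,
                  c(-(2 * geo$b + geo$ta) + 0.1, -2 * geo$b - 0.1),
                  geo$zc + c(-0.45, 0.45) * geo$ph, name = "midline cartilage"),
          cart, "midline cartilage")))
      }
    }
  } else {
    tools <- body_cut_tools(dims, group, config, frame)
    adds <- c(list(body, posterior$ring), posterior[right_side],
              posterior[left_side], posterior["spinous"])
    adds <- adds[!vapply(adds, is.null, logical(1))]
    fvox <- config$kernel$fused_voxel %||% vox
    fused <- solid_csg(add = adds, subtract = c(list(posterior$foramen), tools),
                       voxel = fvox, name = "vertebra")
    fused <- fillet_edges(fused, arch$fillet_radius, voxel = fvox)
    fused$name <- "vertebra"
    comps <- list(new_labeled_component(fused, bone, "body and arch (fused)"))
  }
  # shift origin to the centroid of the body's inferior face
  prof <- body_profile_shape(group)
  ycb <- polygon_centroid(prof)[2] * dims$IVBL
  shift <- c(0, -ycb, 0)
  comps <- lapply(comps, function(cp) {
    cp$solid <- translate_solid(cp$solid, shift)
    cp
  })
  structure(list(
    group = group, level = level, dims = dims, arch = arch,
    components = comps,
    frame = c(frame, list(y_wall = -ycb)),
    facets = list(
      x = geo$x_f, y = geo$y_f - ycb,
      r_ridge = geo$r_ridge, r_groove = geo$r_groove,
      z_inferior = c(geo$zc - geo$s_apl - 0.5, geo$zc - geo$ph / 2 - 0.2),
      z_superior = c(geo$zc + geo$ph / 2 + 0.2, geo$zc + geo$s_apl + 0.5)),
    config = config), class = "vertebra_model")
}

#' Build a complete vertebra model
#'
#' @param group age-group index 1-5.
#' @param level vertebral level `"L1"` ... `"L5"`.
#' @param config a [pedspine_config()].
#' @param arch_overrides optional overrides for
#'   [derive_arch_parameters()].
#' @return A `vertebra_model`: tissue-labelled component assembly with the
#'   measurement frame and facet metadata. Deterministic: identical inputs
#'   give byte-identical geometry.
#' @export
build_vertebra <- function(group, level, config = pedspine_config(),
                           arch_overrides = list()) {
  dims <- get_dimensions(group, level)
  arch <- derive_arch_parameters(dims, group, overrides = arch_overrides,
                                 config = config)
  body <- build_body(dims, group, config, raw = group >= 4)
  post <- build_posterior_elements(dims, arch, group, config)
  split_and_label(body, post, group, level, dims, arch, config)
}

#' @export
print.vertebra_model <- function(x, ...) {
  cat(sprintf("<vertebra_model: group %d, %s, %d components>\n",
              x$group, x$level, length(x$components)))
  for (cp in x$components)
    cat(sprintf("  - %-28s [%s]\n", cp$anatomical_name, cp$tissue$tissue))
  invisible(x)
}

# all component meshes concatenated (not a boolean union; used for slicing
# and distance queries over the whole vertebra)
vertebra_shell <- function(v) {
  vs <- lapply(v$components, function(cp) cp$solid$vertices)
  fs <- list(); off <- 0L
  for (i in seq_along(v$components)) {
    fs[[i]] <- v$components[[i]]$solid$faces + off
    off <- off + nrow(vs[[i]])
  }
  structure(list(vertices = do.call(rbind, vs), faces = do.call(rbind, fs),
                 name = sprintf("vertebra g%d %s", v$group, v$level)),
            class = "tri_solid")
}

total_volume <- function(v) {
  sum(vapply(v$components, function(cp) solid_volume(cp$solid), numeric(1)))
}
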