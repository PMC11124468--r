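# Spine assembler: stacks the five lumbar vertebrae, five intervertebral
# discs and the superior endplate of S1 along an age-dependent lordosis
# curve. The total lordotic angle is distributed equally over the five
# motion segments as rigid rotations at the disc planes; each in-spine disc
# is built so its inferior face conforms to the endplate below and its
# superior face carries the segment rotation, and every interface is
# contact-solved to a small uniform clearance.

rot_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

pose_solid <- function(s, R, t) {
  s$vertices <- s$vertices %*% t(R) + matrix(t, nrow(s$vertices), 3, byrow = TRUE)
  s
}

# lower boundary solid of a posed element, for contact solving
element_contact_solid <- function(el) {
  if (el$type == "vertebra") el$solids[[1]]$solid else el$solids[[1]]$solid
}

#' Assemble a lumbar spine model
#'
#' Builds the five vertebrae (L1-L5), the five intervertebral discs (L1/2 -
#' L5/S1) and the S1 superior endplate for one age group and stacks them
#' caudally-to-cranially. The configured total lordosis (default 0 for
#' newborns and infants, increasing with age) is applied as equal rigid
#' rotations at the five disc planes; adjacent elements are contact-solved
#' to a small clearance (no interpenetration).
#'
#' @param group age-group index 1-5.
#' @param config a [pedspine_config()]; `spine$lordosis_deg[group]` sets the
#'   total angle.
#' @return A `spine_model`: ordered elements (L1 cranially to S1 caudally),
#'   each with posed, tissue-labelled solids; plus per-interface contact
#'   diagnostics.
#' @export
assemble_spine <- function(group, config = pedspine_config()) {
  lordosis <- config$spine$lordosis_deg[[group]]
  alpha <- lordosis / 5
  gap <- config$spine$contact_gap_mm
  vert <- lapply(vertebral_levels(), function(lv) build_vertebra(group, lv, config))
  names(vert) <- vertebral_levels()
  # S1 endplate: thin plate matching the L5/S1 disc footprint
  fp <- disc_footprint(group, parse_pair("L5/S1"))
  tpl <- config$spine$endplate_thickness_frac * vert$L5$dims$PVBH
  plate <- disc_envelope_solid(fp$width, fp$depth, tpl, 0, group,
                               name = "S1 superior endplate")
  elements <- list()
  contacts <- numeric(0)
  # caudal-to-cranial accumulation: R,t map element-local to world
  R <- diag(3); t <- c(0, 0, 0)
  s1_wall <- vert$L5$frame$y_wall
  el_plate <- list(
    type = "endplate", name = "S1 superior endplate",
    solids = list(new_labeled_component(
      pose_solid(plate, R, t + c(0, s1_wall, 0)),
      get_material("cortical bone"), "S1 superior endplate")))
  elements[[1]] <- el_plate
  prev_solid <- el_plate$solids[[1]]$solid
  prev_top_z_local <- tpl + max(0, 0) # plate top (local)
  z_cursor <- tpl
  for (i in 5:1) {
    lv <- paste0("L", i)
    pair <- DISC_PAIRS[i]
    # --- disc for this segment -------------------------------------------
    slope_bot <- if (i == 5) 0 else vert[[paste0("L", i + 1)]]$frame$sup_k
    disc <- build_disc(group, pair, config, wedge_deg = alpha -
                         atan(slope_bot) * 180 / pi,
                       slope_bottom = slope_bot)
    # one world wall line for the whole column: posterior body walls (and
    # with them the facet columns) stay aligned across levels
    y_align <- s1_wall
    placed <- place_on(list(disc$annulus$solid, disc$nucleus$solid),
                       R, t, y_align, z_cursor, prev_solid, gap)
    el_disc <- list(
      type = "disc", name = paste("disc", pair), model = disc,
      solids = list(
        new_labeled_component(placed$solids[[1]], disc$annulus$tissue,
                              paste("annulus fibrosus", pair)),
        new_labeled_component(placed$solids[[2]], disc$nucleus$tissue,
                              paste("nucleus pulposus", pair))))
    contacts <- c(contacts, placed$gap)
    elements[[length(elements) + 1]] <- el_disc
    prev_solid <- placed$solids[[1]]
    z_cursor <- placed$z_next + disc$height_posterior
    # segment rotation at the disc level; the pivot sits on the facet axis
    # of the vertebra below (where the articular surfaces mate), so facet
    # clearances are preserved under the lordotic tilt
    if (abs(alpha) > 1e-12) {
      last_vert <- Filter(function(e) e$type == "vertebra", elements)
      if (length(last_vert) > 0) {
        lv_el <- last_vert[[length(last_vert)]]
        f <- lv_el$model$facets
        # centre of the ~2 mm ridge/groove mating zone at the top of the
        # superior facet: tilting about this point keeps the joint
        # clearance nearly unchanged
        p_loc <- c(0, f$y, f$z_superior[2] - 1.5)
        ctr <- as.numeric(lv_el$pose$R %*% p_loc) + lv_el$pose$t
      } else {
        ctr <- colMeans(placed$solids[[1]]$vertices)
      }
      A <- rot_x(alpha)
      R <- A %*% R
      t <- as.numeric(A %*% (t - ctr)) + ctr
    }
    # --- vertebra above --------------------------------------------------
    # align the vertebra's posterior wall with the disc wall
    v <- vert[[lv]]
    vsol <- lapply(v$components, function(cp) cp$solid)
    placed <- place_on(vsol, R, t, y_align - v$frame$y_wall,
                       z_cursor, prev_solid, gap)
    el_vert <- list(
      type = "vertebra", name = lv, model = v,
      solids = purrr::map2(placed$solids, v$components, function(s, cp) {
        new_labeled_component(s, cp$tissue, paste(cp$anatomical_name, lv))
      }),
      pose = placed$pose)
    contacts <- c(contacts, placed$gap)
    elements[[length(elements) + 1]] <- el_vert
    prev_solid <- placed$solids[[1]]
    z_cursor <- placed$z_next + v$dims$PVBH
  }
  structure(list(
    group = group, config = config,
    lordosis_angle = lordosis, segment_angles = rep(alpha, 5),
    elements = rev(elements),
    contact_gaps = contacts), class = "spine_model")
}

# place a set of solids (one rigid body) with frame (R, t), local y offset
# y_align and nominal base height z_base, then slide along the local z axis
# until the first solid clears `against` by `gap`
place_on <- function(solids, R, t, y_align, z_base, against, gap) {
  up <- as.numeric(R %*% c(0, 0, 1))
  offset0 <- c(0, y_align, z_base + 0.8)
  posed <- lapply(solids, function(s)
    pose_solid(s, R, t + as.numeric(R %*% offset0)))
  shift <- 0
  move <- function(dz) {
    posed[[1]] <<- translate_solid(posed[[1]], up * dz)
    shift <<- shift + dz
  }
  d <- min_distance(posed[[1]], against)
  for (it in 1:60) {
    if (isTRUE(attr(d, "overlap")) || as.numeric(d) == 0) {
      # climb clear of the element below before descending to contact
      move(0.5)
      d <- min_distance(posed[[1]], against)
      next
    }
    delta <- as.numeric(d) - gap
    if (abs(delta) < 0.005) break
    move(-delta)
    d2 <- min_distance(posed[[1]], against)
    if (isTRUE(attr(d2, "overlap")) || as.numeric(d2) == 0) {
      # overshoot through an inclined face: back off halfway
      move(delta / 2)
      d2 <- min_distance(posed[[1]], against)
    }
    d <- d2
  }
  if (isTRUE(attr(d, "overlap")) || as.numeric(d) == 0)
    geometry_error("contact solving failed to separate adjacent elements")
  if (length(posed) > 1) {
    for (j in 2:length(posed)) {
      posed[[j]] <- translate_solid(posed[[j]], up * shift)
    }
  }
  list(solids = posed, gap = as.numeric(d),
       z_next = z_base + 0.8 + shift,
       pose = list(R = R, t = t + as.numeric(R %*% (offset0 + c(0, 0, shift)))))
}

#' @export
print.spine_model <- function(x, ...) {
  cat(sprintf("<spine_model: group %d, %d elements, lordosis %g deg>\n",
              x$group, length(x$elements), x$lordosis_angle))
  for (el in x$elements) cat("  -", el$name, sprintf("(%s)", el$type), "\n")
  invisible(x)
}

spine_element_counts <- function(s) {
  types <- vapply(s$elements, function(e) e$type, character(1))
  c(vertebrae = sum(types == "vertebra"), discs = sum(types == "disc"),
    endplates = sum(types == "endplate"))
}

all_spine_solids <- function(s) {
  unlist(lapply(s$elements, function(e) lapply(e$solids, function(cp) cp$solid)),
         recursive = FALSE)
}

#' Measurement report for an assembled spine
#'
#' Element counts and order, per-element volumes and volume conservation,
#' stack height, per-interface contact gaps and interpenetration
#' diagnostics, and the facet gaps of every adjacent vertebra pair.
#'
#' @param s a `spine_model`.
#' @param facets also measure facet gaps (slightly slower). Default TRUE.
#' @return A `measurement_report`.
#' @export
spine_report <- function(s, facets = TRUE) {
  counts <- spine_element_counts(s)
  rows <- list(
    report_row("n_vertebrae", counts[["vertebrae"]], "count", 5, 0),
    report_row("n_discs", counts[["discs"]], "count", 5, 0),
    report_row("n_endplates", counts[["endplates"]], "count", 1, 0))
  vols <- vapply(s$elements, function(e)
    sum(vapply(e$solids, function(cp) solid_volume(cp$solid), numeric(1))),
    numeric(1))
  total <- sum(vols)
  for (i in seq_along(s$elements)) {
    rows[[length(rows) + 1]] <- report_row(
      paste0("volume: ", s$elements[[i]]$name), vols[i], "mm^3")
  }
  rows[[length(rows) + 1]] <- report_row("total_volume", total, "mm^3",
                                         sum(vols), 0.001 * total)
  # stack height: top of the L1 body to the top of the S1 plate, along the
  # posterior line; compared with the arithmetic sum of posterior body
  # heights and posterior disc heights (straight stacks)
  verts <- Filter(function(e) e$type == "vertebra", s$elements)
  l1_body <- verts[[1]]$solids[[1]]$solid
  plate <- s$elements[[length(s$elements)]]$solids[[1]]$solid
  stack_height <- max(l1_body$vertices[, 3]) - max(plate$vertices[, 3])
  expected_height <- sum(vapply(verts, function(e) e$model$dims$PVBH, numeric(1))) +
    sum(vapply(Filter(function(e) e$type == "disc", s$elements),
               function(e) e$model$height_posterior, numeric(1)))
  rows[[length(rows) + 1]] <- report_row(
    "stack_height", stack_height, "mm",
    if (s$lordosis_angle == 0) expected_height else NA_real_,
    0.5)
  for (i in seq_along(s$contact_gaps)) {
    rows[[length(rows) + 1]] <- report_row(
      paste0("contact_gap_", i), s$contact_gaps[i], "mm", 0.05, 0.05)
  }
  # interpenetration between consecutive elements
  for (i in seq_len(length(s$elements) - 1)) {
    a <- s$elements[[i]]$solids[[1]]$solid
    b <- s$elements[[i + 1]]$solids[[1]]$solid
    ov <- overlap_volume(a, b, n = 2000)
    denom <- min(solid_volume(a), solid_volume(b))
    rows[[length(rows) + 1]] <- report_row(
      paste0("interpenetration_", s$elements[[i]]$name, "|",
             s$elements[[i + 1]]$name),
      ov / denom, "ratio", 0, 0.001)
  }
  if (facets) {
    for (i in 1:4) {
      up <- verts[[i]]; lo <- verts[[i + 1]]
      g <- spine_facet_gap(s, i)
      rows[[length(rows) + 1]] <- report_row(
        paste0("facet_gap_", up$name, "|", lo$name), g, "mm", 0.25, 0.25)
    }
  }
  new_measurement_report(bind_rows(rows))
}

# facet gap between the i-th vertebra (from the top) and the one below it,
# measured on the posed assembly meshes
spine_facet_gap <- function(s, i) {
  verts <- Filter(function(e) e$type == "vertebra", s$elements)
  up <- verts[[i]]; lo <- verts[[i + 1]]
  sub_roi <- function(el, which) {
    v <- el$model
    f <- v$facets
    zr <- if (which == "inferior") f$z_inferior else f$z_superior
    pad <- if (which == "inferior") f$r_ridge + 0.6 else f$r_groove + 0.8
    # build ROI box corners in the model frame, map with the element pose
    R <- el$pose$R; t0 <- el$pose$t
    meshes <- lapply(el$solids, function(cp) cp$solid)
    allv <- do.call(rbind, lapply(meshes, function(m) m$vertices))
    allf <- list(); off <- 0L
    for (m in meshes) { allf[[length(allf) + 1]] <- m$faces + off; off <- off + nrow(m$vertices) }
    allf <- do.call(rbind, allf)
    # work in the element's local frame
    loc <- (allv - matrix(t0, nrow(allv), 3, byrow = TRUE)) %*% R
    cen <- (loc[allf[, 1], ] + loc[allf[, 2], ] + loc[allf[, 3], ]) / 3
    keep <- (abs(abs(cen[, 1]) - f$x) <= pad + 0.5) &
      cen[, 2] >= f$y - 2.2 * f$r_groove - 0.5 & cen[, 2] <= f$y + pad &
      cen[, 3] >= zr[1] & cen[, 3] <= zr[2]
    if (!any(keep)) geometry_error("no facet surface in ROI")
    structure(list(vertices = allv, faces = allf[keep, , drop = FALSE]),
              class = "tri_solid")
  }
  a <- sub_roi(up, "inferior")
  b <- sub_roi(lo, "superior")
  cpp_min_distance(a$vertices, a$faces, b$vertices, b$faces)
}
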