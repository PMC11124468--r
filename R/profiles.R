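# Vertebral-body cross-section profiles and the lofted body construction.
#
# The body is built as a loft of planar cross-sections. Each section is a
# normalised 2D profile (posterior flat chord at y = 0, anterior arc to
# y = 1, x in [-1/2, 1/2]) scaled anisotropically to the width/depth of its
# station, then sheared onto an inclined section plane. The width blend
# holds plateau values near the endplates, passes exactly through MVBW at
# mid-height and produces the "waist" of the older groups whenever MVBW is
# the minimum of the three widths.

# normalised profile shapes per age group: "oval" (newborn), "disc sector"
# (infant/toddler), "cylinder sector" (middle childhood/preadolescent);
# chord_frac is the flat posterior fraction of the width
body_profile_shape <- function(group, n = 72) {
  chord_frac <- c(0.40, 0.75, 0.75, 0.85, 0.85)[group]
  cw <- chord_frac / 2
  if (group == 1) {
    # oval: ellipse with a short posterior flat
    b <- 0.5
    th0 <- asin(2 * cw)   # parameter where |x| = cw near the posterior pole
    th <- seq(th0, 2 * pi - th0, length.out = n)
    pts <- cbind(0.5 * sin(th), b - b * cos(th))
    pts <- rbind(pts, c(-cw, 0), c(cw, 0))
  } else {
    # sector of a disc/cylinder: chord at y = 0, circular arc through the
    # apex (0, 1); arc radius from the chord end and apex
    R <- (cw^2 + 1) / 2
    cy <- 1 - R
    th_end <- atan2(0 - cy, cw)        # angle of chord end
    th <- seq(th_end, pi - th_end, length.out = n)
    pts <- cbind(R * cos(th), cy + R * sin(th))
    # normalise width to 1 (max |x| = R can exceed 1/2)
    pts[, 1] <- pts[, 1] * (0.5 / max(abs(pts[, 1])))
  }
  # drop near-duplicate consecutive points and a duplicated closing point
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  if (sum((pts[1, ] - pts[nrow(pts), ])^2) < 1e-12)
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

# plateau-cosine blend of the three widths: IVBW at the bottom plateau,
# exactly MVBW at t = 0.5, SVBW at the top plateau
body_width_at <- function(t, dims, plateau) {
  p <- plateau
  w <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    w[i] <-
      if (ti <= p) dims$IVBW
      else if (ti < 0.5) dims$IVBW + (dims$MVBW - dims$IVBW) * smooth01((ti - p) / (0.5 - p))
      else if (ti <= 1 - p) dims$MVBW + (dims$SVBW - dims$MVBW) * smooth01((ti - 0.5) / (0.5 - p))
      else dims$SVBW
  }
  w
}

# plateau-cosine blend of the sagittal depths (IVBL at bottom, SVBL at top)
body_depth_at <- function(t, dims, plateau) {
  p <- plateau
  d <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    d[i] <-
      if (ti <= p) dims$IVBL
      else if (ti >= 1 - p) dims$SVBL
      else dims$IVBL + (dims$SVBL - dims$IVBL) * smooth01((ti - p) / (1 - 2 * p))
  }
  d
}

# measurement frame shared by the builder and the morphometric module: the
# superior plane is calibrated through the two height stations so that the
# heights measured there reproduce the packaged values exactly
body_frame <- function(dims, group, config) {
  prof <- body_profile_shape(group)
  # centroid depth fraction of the unit profile (for station placement)
  yc_frac <- polygon_centroid(prof)[2]
  step <- if (group %in% 5) config$body$step_depth_frac * dims$PVBH else 0
  inset <- config$body$step_inset_frac
  # posterior height station: just anterior of the step rebate's inner wall
  y_inner_post <- if (step > 0) yc_frac * dims$SVBL * 2 * inset + 0.4 else 0.5
  y_p <- max(0.5, y_inner_post)
  d_min <- min(dims$SVBL, dims$IVBL)
  # clear of the rounded anterior rims of both endplates
  y_a <- d_min - 0.8
  if (step > 0) {
    # stay inside both step rebates' inner walls (top and bottom endplates)
    inner_ant <- function(d) yc_frac * d + (1 - 2 * inset) * (d - yc_frac * d)
    y_a <- min(y_a, inner_ant(dims$SVBL) - 0.8, inner_ant(dims$IVBL) - 0.8)
  }
  k <- (dims$AVBH - dims$PVBH) / (y_a - y_p)
  z0 <- dims$PVBH - k * y_p      # superior-plane height at the posterior wall
  list(
    group = group,
    dims = dims,
    plateau = config$body$plateau,
    step_depth = step,
    step_inset = inset,
    y_station_post = y_p,
    y_station_ant = y_a,
    sup_k = k,                   # superior plane: z = z0 + k * y
    sup_z0 = z0,
    yc_frac = yc_frac,
    # endplate-parallel stations sit below the rounded rim but within the
    # width/depth plateaus of the profile blends
    delta = 0.6)
}

polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(seq_len(nrow(pts))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  cx <- sum((x + x[i2]) * cr) / (6 * a)
  cy <- sum((y + y[i2]) * cr) / (6 * a)
  c(cx, cy)
}

# superior plane height at depth y
sup_z <- function(frame, y) frame$sup_z0 + frame$sup_k * y

# the lofted (uncut) body solid in the build frame: posterior wall at y = 0,
# inferior face flat at z = 0, superior face on the calibrated plane
body_loft <- function(dims, group, config, n_sections = 41) {
  frame <- body_frame(dims, group, config)
  prof <- body_profile_shape(group)
  tt <- seq(0, 1, length.out = n_sections)
  rings <- vector("list", n_sections)
  for (i in seq_along(tt)) {
    t <- tt[i]
    w <- body_width_at(t, dims, frame$plateau)
    d <- body_depth_at(t, dims, frame$plateau)
    x <- prof[, 1] * w
    y <- prof[, 2] * d
    z <- t * sup_z(frame, y)
    rings[[i]] <- cbind(x, y, z)
  }
  list(solid = loft_sections(rings, name = "body"), frame = frame)
}

# measurement stations for the seven dimensions, in the build frame; slices
# parallel to the endplates so widths/depths invert the construction
body_stations <- function(frame) {
  dims <- frame$dims
  k <- frame$sup_k
  yc <- frame$yc_frac * body_depth_at(1, dims, frame$plateau)
  d <- frame$delta
  list(
    # widths/depths: plane point + normal (+ the dimension measured)
    top = list(point = c(0, 0, frame$sup_z0 - frame$step_depth - d),
               normal = c(0, -k, 1),
               width = "SVBW", depth = "SVBL"),
    mid = list(point = c(0, 0, frame$sup_z0 / 2),
               normal = c(0, -k / 2, 1),
               width = "MVBW", depth = NA),
    bottom = list(point = c(0, 0, frame$step_depth + d),
                  normal = c(0, 0, 1),
                  width = "IVBW", depth = "IVBL"),
    post = list(point = c(0, frame$y_station_post, 0), normal = c(0, 1, 0),
                height = "PVBH"),
    ant = list(point = c(0, frame$y_station_ant, 0), normal = c(0, 1, 0),
               height = "AVBH"))
}
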