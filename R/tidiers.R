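# broom-style tidiers and ggplot2 autoplot methods for the model and
# report objects.

#' @export
tidy.vertebra_model <- function(x, ...) {
  bind_rows(lapply(x$components, function(cp) {
    m <- measure_solid(cp$solid)
    tibble(component = cp$anatomical_name, tissue = cp$tissue$tissue,
           youngs_modulus_E = cp$tissue$youngs_modulus_E,
           poisson_ratio_nu = cp$tissue$poisson_ratio_nu,
           volume = m$volume, watertight = m$watertight,
           n_faces = m$n_faces)
  }))
}

#' @export
glance.vertebra_model <- function(x, ...) {
  td <- tidy(x)
  tibble(group = x$group, level = x$level,
         n_components = nrow(td),
         n_bone = sum(grepl("bone", td$tissue)),
         n_cartilage = sum(td$tissue == "cartilage"),
         total_volume = sum(td$volume),
         all_watertight = all(td$watertight))
}

#' @export
tidy.disc_model <- function(x, ...) {
  bind_rows(lapply(list(x$annulus, x$nucleus), function(cp) {
    m <- measure_solid(cp$solid)
    tibble(component = cp$anatomical_name, tissue = cp$tissue$tissue,
           youngs_modulus_E = cp$tissue$youngs_modulus_E,
           poisson_ratio_nu = cp$tissue$poisson_ratio_nu,
           volume = m$volume, watertight = m$watertight,
           n_faces = m$n_faces)
  }))
}

#' @export
glance.disc_model <- function(x, ...) {
  tibble(group = x$group, level_pair = x$level_pair,
         wedge_angle = x$wedge_angle,
         height_posterior = x$height_posterior,
         cavity_fraction = x$cavity_volume / x$envelope_volume,
         wall_thickness = x$wall_thickness)
}

#' @export
tidy.spine_model <- function(x, ...) {
  bind_rows(lapply(x$elements, function(e) {
    vols <- vapply(e$solids, function(cp) solid_volume(cp$solid), numeric(1))
    tibble(element = e$name, type = e$type,
           n_components = length(e$solids), volume = sum(vols))
  }))
}

#' @export
glance.spine_model <- function(x, ...) {
  counts <- spine_element_counts(x)
  tibble(group = x$group,
         n_vertebrae = counts[["vertebrae"]], n_discs = counts[["discs"]],
         n_endplates = counts[["endplates"]],
         lordosis_angle = x$lordosis_angle,
         max_contact_gap = max(x$contact_gaps))
}

#' @export
tidy.measurement_report <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.measurement_report <- function(x, ...) {
  tibble(n_checks = nrow(x),
         n_compared = sum(!is.na(x$pass)),
         n_failed = sum(!x$pass, na.rm = TRUE),
         pass = all(x$pass, na.rm = TRUE))
}

#' Plot a measurement report
#'
#' Deviation of each compared entry from its expected value, in units of
#' its tolerance; the shaded band marks the pass region.
#'
#' @param object a `measurement_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.measurement_report <- function(object, ...) {
  df <- as_tibble(unclass(object))
  df <- df[!is.na(df$expected) & !is.na(df$tolerance) & df$tolerance > 0, ]
  df$deviation <- (df$measured - df$expected) / df$tolerance
  ggplot(df, aes(x = .data$deviation, y = .data$name, colour = .data$pass)) +
    annotate("rect", xmin = -1, xmax = 1, ymin = -Inf, ymax = Inf,
             alpha = 0.12, fill = "steelblue") +
    geom_point(size = 2) +
    geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red")) +
    labs(x = "deviation (tolerance units)", y = NULL, colour = "pass") +
    theme_minimal()
}

#' Sagittal silhouette plot of a model
#'
#' Mid-sagittal (x = 0) cross-section of all components, coloured by
#' tissue — a quick visual check of the construction.
#'
#' @param model a `vertebra_model`, `disc_model` or `spine_model`.
#' @param plane slicing plane: `"sagittal"` (x = 0), `"frontal"` or
#'   `"transverse"` through the model bbox centre.
#' @return A ggplot object.
#' @export
plot_silhouette <- function(model, plane = c("sagittal", "frontal", "transverse")) {
  plane <- match.arg(plane)
  comps <- model_components(model)
  allv <- do.call(rbind, lapply(comps, function(cp) cp$solid$vertices))
  ctr <- colMeans(allv)
  nrm <- switch(plane, sagittal = c(1, 0, 0), frontal = c(0, 1, 0),
                transverse = c(0, 0, 1))
  p0 <- switch(plane, sagittal = c(0, ctr[2], ctr[3]), frontal = ctr,
               transverse = ctr)
  ax <- switch(plane, sagittal = c(2, 3), frontal = c(1, 3), transverse = c(1, 2))
  labs_xy <- c("x [mm]", "y [mm]", "z [mm]")
  segs <- list()
  for (cp in comps) {
    sl <- slice_solid(cp$solid, p0, nrm)
    if (nrow(sl$segments) == 0) next
    segs[[length(segs) + 1]] <- tibble(
      x = sl$segments[, ax[1]], y = sl$segments[, ax[2]],
      xend = sl$segments[, ax[1] + 3], yend = sl$segments[, ax[2] + 3],
      tissue = cp$tissue$tissue)
  }
  df <- bind_rows(segs)
  ggplot(df, aes(x = .data$x, y = .data$y, xend = .data$xend,
                 yend = .data$yend, colour = .data$tissue)) +
    geom_segment(linewidth = 0.3) +
    coord_equal() +
    labs(x = labs_xy[ax[1]], y = labs_xy[ax[2]], colour = "tissue") +
    theme_minimal()
}

#' @export
autoplot.vertebra_model <- function(object, ...) plot_silhouette(object)

#' @export
autoplot.disc_model <- function(object, ...) plot_silhouette(object)

#' @export
autoplot.spine_model <- function(object, ...) plot_silhouette(object)
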