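# Mesh export/import (STL binary+ASCII, OBJ, PLY) and the export bundle:
# one mesh file per tissue-labelled component plus a JSON manifest carrying
# the material properties (E, nu) for finite-element preprocessing.

#' Components of a model
#'
#' Flat list of the tissue-labelled components of a vertebra, disc or spine
#' model (the spine yields its posed solids).
#'
#' @param model a `vertebra_model`, `disc_model` or `spine_model`.
#' @return List of components (`solid`, `tissue`, `anatomical_name`).
#' @export
model_components <- function(model) {
  if (inherits(model, "vertebra_model")) return(model$components)
  if (inherits(model, "disc_model")) return(list(model$annulus, model$nucleus))
  if (inherits(model, "spine_model")) {
    return(unlist(lapply(model$elements, function(e) e$solids),
                  recursive = FALSE))
  }
  validation_error("not a pedspine model object")
}

EXPORT_FORMATS <- c("stl", "stl_ascii", "obj", "ply")

#' Export a model as mesh files with a material manifest
#'
#' Writes one mesh file per component (binary STL by default; ASCII STL,
#' OBJ or PLY on request) and a `manifest.json` listing component names,
#' tissues and their Young's modulus / Poisson ratio as packaged, so the
#' geometry travels with its material assignment.
#'
#' @param model a `vertebra_model`, `disc_model` or `spine_model`.
#' @param dir output directory (created if missing).
#' @param format one of `"stl"` (binary), `"stl_ascii"`, `"obj"`, `"ply"`.
#' @return An `export_bundle`: `manifest` tibble, `dir`, `format`.
#' @export
export_model <- function(model, dir, format = "stl") {
  if (!format %in% EXPORT_FORMATS)
    validation_error("unknown format '%s'; supported formats: %s", format,
                     paste(EXPORT_FORMATS, collapse = ", "))
  comps <- model_components(model)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- c(stl = "stl", stl_ascii = "stl", obj = "obj", ply = "ply")[[format]]
  rows <- list()
  for (i in seq_along(comps)) {
    cp <- comps[[i]]
    fname <- sprintf("%02d_%s.%s", i,
                     gsub("[^a-z0-9]+", "_", tolower(cp$anatomical_name)), ext)
    path <- file.path(dir, fname)
    write_mesh(cp$solid, path, format)
    rows[[i]] <- tibble(
      component = i, anatomical_name = cp$anatomical_name,
      tissue = cp$tissue$tissue,
      youngs_modulus_E = cp$tissue$youngs_modulus_E,
      poisson_ratio_nu = cp$tissue$poisson_ratio_nu,
      file = fname,
      n_vertices = nrow(cp$solid$vertices), n_faces = nrow(cp$solid$faces))
  }
  manifest <- bind_rows(rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, dir = dir, format = format),
            class = "export_bundle")
}

#' @export
print.export_bundle <- function(x, ...) {
  cat(sprintf("<export_bundle: %d %s files + manifest in %s>\n",
              nrow(x$manifest), x$format, x$dir))
  invisible(x)
}

#' Write and read a single mesh file
#'
#' @param s a [tri_solid()].
#' @param path output file.
#' @param format one of `"stl"` (binary), `"stl_ascii"`, `"obj"`, `"ply"`.
#' @export
write_mesh <- function(s, path, format = "stl") {
  switch(format,
    stl = write_stl_binary(s, path),
    stl_ascii = write_stl_ascii(s, path),
    obj = write_obj(s, path),
    ply = write_ply(s, path),
    validation_error("unknown format '%s'; supported formats: %s", format,
                     paste(EXPORT_FORMATS, collapse = ", ")))
  invisible(path)
}

#' @rdname write_mesh
#' @param weld weld duplicate vertices on import (STL files duplicate
#'   vertices per facet). Default TRUE.
#' @return `read_mesh()`: a [tri_solid()].
#' @export
read_mesh <- function(path, weld = TRUE) {
  ext <- tolower(tools::file_ext(path))
  s <- switch(ext,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path),
    validation_error("cannot infer mesh format from '%s'", path))
  if (weld) s <- weld_solid(s, tol = 1e-12)
  tri_solid(s$vertices, s$faces, name = s$name, validate = FALSE)
}

face_normals <- function(s) {
  f <- s$faces
  v0 <- s$vertices[f[, 1], , drop = FALSE]
  v1 <- s$vertices[f[, 2], , drop = FALSE]
  v2 <- s$vertices[f[, 3], , drop = FALSE]
  nx <- (v1[, 2] - v0[, 2]) * (v2[, 3] - v0[, 3]) - (v1[, 3] - v0[, 3]) * (v2[, 2] - v0[, 2])
  ny <- (v1[, 3] - v0[, 3]) * (v2[, 1] - v0[, 1]) - (v1[, 1] - v0[, 1]) * (v2[, 3] - v0[, 3])
  nz <- (v1[, 1] - v0[, 1]) * (v2[, 2] - v0[, 2]) - (v1[, 2] - v0[, 2]) * (v2[, 1] - v0[, 1])
  n <- cbind(nx, ny, nz)
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

write_stl_binary <- function(s, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("pedspine binary STL", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  nf <- nrow(s$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  nrm <- face_normals(s)
  f <- s$faces
  # interleave: normal, v1, v2, v3 (floats), attribute count (uint16)
  tri <- cbind(nrm,
               s$vertices[f[, 1], , drop = FALSE],
               s$vertices[f[, 2], , drop = FALSE],
               s$vertices[f[, 3], , drop = FALSE])
  floats <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  rec <- matrix(as.raw(0), 50, nf)
  rec[1:48, ] <- matrix(floats, 48, nf)
  writeBin(as.vector(rec), con)
  invisible(path)
}

write_stl_ascii <- function(s, path) {
  nrm <- face_normals(s)
  f <- s$faces
  num <- function(x) sprintf("%.17g", x)
  lines <- character(2 + 7 * nrow(f))
  lines[1] <- "solid pedspine"
  k <- 2
  for (i in seq_len(nrow(f))) {
    lines[k] <- sprintf("  facet normal %s %s %s", num(nrm[i, 1]), num(nrm[i, 2]), num(nrm[i, 3]))
    lines[k + 1] <- "    outer loop"
    for (j in 1:3) {
      v <- s$vertices[f[i, j], ]
      lines[k + 1 + j] <- sprintf("      vertex %s %s %s", num(v[1]), num(v[2]), num(v[3]))
    }
    lines[k + 5] <- "    endloop"
    lines[k + 6] <- "  endfacet"
    k <- k + 7
  }
  lines[k] <- "endsolid pedspine"
  writeLines(lines, path)
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  txt <- tryCatch(rawToChar(head[head != as.raw(0)]), error = function(e) "")
  if (grepl("^\\s*solid", txt) && is_ascii_stl(path)) read_stl_ascii(path)
  else read_stl_binary(path)
}

is_ascii_stl <- function(path) {
  x <- readLines(path, n = 3, warn = FALSE, skipNul = TRUE)
  any(grepl("facet|endsolid", x))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- matrix(readBin(con, "raw", nf * 50), 50, nf)
  floats <- readBin(as.vector(rec[1:48, ]), "numeric", nf * 12, size = 4,
                    endian = "little")
  tri <- matrix(floats, ncol = 12, byrow = TRUE)
  verts <- matrix(t(tri[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(nf * 3), ncol = 3, byrow = TRUE)
  structure(list(vertices = verts, faces = faces, name = NULL),
            class = "tri_solid")
}

read_stl_ascii <- function(path) {
  x <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", x, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  structure(list(vertices = nums, faces = faces, name = NULL),
            class = "tri_solid")
}

write_obj <- function(s, path) {
  num <- function(x) sprintf("%.17g", x)
  v <- sprintf("v %s %s %s", num(s$vertices[, 1]), num(s$vertices[, 2]),
               num(s$vertices[, 3]))
  f <- sprintf("f %d %d %d", s$faces[, 1], s$faces[, 2], s$faces[, 3])
  writeLines(c("# pedspine OBJ", v, f), path)
  invisible(path)
}

read_obj <- function(path) {
  x <- readLines(path, warn = FALSE)
  vl <- x[startsWith(x, "v ")]
  fl <- x[startsWith(x, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  structure(list(vertices = verts, faces = faces, name = NULL),
            class = "tri_solid")
}

write_ply <- function(s, path) {
  num <- function(x) sprintf("%.17g", x)
  header <- c("ply", "format ascii 1.0", "comment pedspine",
              sprintf("element vertex %d", nrow(s$vertices)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(s$faces)),
              "property list uchar int vertex_indices", "end_header")
  v <- sprintf("%s %s %s", num(s$vertices[, 1]), num(s$vertices[, 2]),
               num(s$vertices[, 3]))
  f <- sprintf("3 %d %d %d", s$faces[, 1] - 1L, s$faces[, 2] - 1L,
               s$faces[, 3] - 1L)
  writeLines(c(header, v, f), path)
  invisible(path)
}

read_ply <- function(path) {
  x <- readLines(path, warn = FALSE)
  he <- which(x == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", x, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", x, value = TRUE)))
  verts <- do.call(rbind, lapply(strsplit(x[he + seq_len(nv)], "\\s+"), function(p)
    as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(x[he + nv + seq_len(nf)], "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  structure(list(vertices = verts, faces = faces, name = NULL),
            class = "tri_solid")
}

#' Kernel test fixtures
#'
#' Deterministic sketch profiles and primitive solids with closed-form
#' areas/volumes, used by the test-suite and usable as examples:
#' `unit_square` (area 1), `circle_r2` (radius 2, 64 segments, area close
#' to 4 pi), `l_shape` (area 4), and `nested_boxes` (unit cube and a
#' co-centred half-size cube: difference volume 1 - 1/8 = 0.875).
#'
#' @return Named list of [planar_profile()]s and [tri_solid()]s.
#' @export
fixture_profiles <- function() {
  list(
    unit_square = planar_profile(profile_rectangle(1, 1), plane = "transverse"),
    circle_r2 = planar_profile(profile_circle(2, segments = 64),
                               plane = "transverse"),
    l_shape = planar_profile(rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1),
                                   c(1, 3), c(0, 3)), plane = "transverse"),
    nested_boxes = list(outer = solid_box(1, 1, 1),
                        inner = solid_box(0.5, 0.5, 0.5)))
}
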