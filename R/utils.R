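# Internal geometry helpers: planar polygon utilities, rotations, ear
# clipping for cap triangulation. All polygons are n x 2 matrices, implicitly
# closed (last vertex connects to first).

stopf <- function(fmt, ..., class = "pedspine_error") {
  abort(sprintf(fmt, ...), class = class)
}

geometry_error <- function(fmt, ...) {
  stopf(fmt, ..., class = c("pedspine_geometry_error", "pedspine_error"))
}

validation_error <- function(fmt, ...) {
  stopf(fmt, ..., class = c("pedspine_validation_error", "pedspine_error"))
}

lookup_error <- function(fmt, ...) {
  stopf(fmt, ..., class = c("pedspine_lookup_error", "pedspine_error"))
}

#' @noRd
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(seq_len(nrow(pts))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# orientation-enforcing helper: returns pts in CCW order
ccw <- function(pts) {
  if (polygon_area(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(pts[i, ], pts[idx(i + 1L), ],
                             pts[j, ], pts[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

# ear-clipping triangulation of a simple polygon; returns m x 3 indices into
# the input rows, with every triangle counter-clockwise in the given 2D
# coordinates regardless of input winding
ear_clip <- function(pts) {
  n <- nrow(pts)
  if (polygon_area(pts) < 0) {
    tr <- ear_clip(pts[rev(seq_len(n)), , drop = FALSE])
    return(matrix(n + 1L - tr, ncol = 3))
  }
  if (n == 3) return(matrix(1:3, nrow = 1))
  active <- seq_len(n)
  tris <- matrix(0L, nrow = n - 2, ncol = 3)
  nt <- 0L
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  in_tri <- function(p, a, b, c) {
    c1 <- cross2(a, b, p); c2 <- cross2(b, c, p); c3 <- cross2(c, a, p)
    (c1 >= -1e-12 && c2 >= -1e-12 && c3 >= -1e-12)
  }
  guard <- 0L
  while (length(active) > 3) {
    guard <- guard + 1L
    if (guard > 10 * n * n) geometry_error("ear clipping failed; polygon may be degenerate")
    m <- length(active)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- active[((k - 2L) %% m) + 1L]
      i1 <- active[k]
      i2 <- active[(k %% m) + 1L]
      a <- pts[i0, ]; b <- pts[i1, ]; c <- pts[i2, ]
      if (cross2(a, b, c) <= 1e-12) next
      ok <- TRUE
      for (q in active) {
        if (q %in% c(i0, i1, i2)) next
        if (in_tri(pts[q, ], a, b, c)) { ok <- FALSE; break }
      }
      if (ok) {
        nt <- nt + 1L
        tris[nt, ] <- c(i0, i1, i2)
        active <- active[-k]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) {
      # fall back: clip the least-reflex corner to make progress
      k <- 1L
      i0 <- active[((k - 2L) %% length(active)) + 1L]
      i1 <- active[k]; i2 <- active[(k %% length(active)) + 1L]
      nt <- nt + 1L
      tris[nt, ] <- c(i0, i1, i2)
      active <- active[-k]
    }
  }
  nt <- nt + 1L
  tris[nt, ] <- active
  tris[seq_len(nt), , drop = FALSE]
}

# rotation matrix about a unit axis (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# cosine ease between 0 and 1 (zero slope at both ends)
smooth01 <- function(t) (1 - cos(pi * pmin(pmax(t, 0), 1))) / 2

# deterministic low-discrepancy points in a box (Halton bases 2,3,5)
halton_points <- function(n, lower, upper) {
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  pts <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    pts[i, ] <- c(radical_inverse(i, 2), radical_inverse(i, 3), radical_inverse(i, 5))
  }
  sweep(sweep(pts, 2, upper - lower, "*"), 2, lower, "+")
}

# containment-test ray direction: deliberately incommensurate with the grid
# axes and cell diagonals of the boolean-field triangulations
ray_dir <- function() c(0.28108737, 0.61803399, 0.73205081)
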