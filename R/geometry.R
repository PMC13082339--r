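# Low-level 2D polygon geometry used by the tissue model.
# Polygons are n x 2 matrices of vertex positions, counter-clockwise,
# without a repeated closing vertex.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param p numeric matrix (n x 2) of polygon vertices.
#' @return signed area (model units squared).
#' @export
poly_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Polygon centroid (area-weighted)
#'
#' @param p numeric matrix (n x 2), counter-clockwise.
#' @return length-2 numeric vector.
#' @export
poly_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.xmin) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param pt length-2 point.
#' @param p polygon matrix (n x 2).
#' @return logical.
#' @export
point_in_poly <- function(pt, p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  x <- pt[1]; y <- pt[2]
  crosses <- (p[, 2] > y) != (p[j, 2] > y)
  if (!any(crosses)) return(FALSE)
  i <- which(crosses)
  xi <- p[i, 1] + (y - p[i, 2]) / (p[j[i], 2] - p[i, 2]) * (p[j[i], 1] - p[i, 1])
  sum(xi > x) %% 2 == 1
}

# Intersections of the infinite line c + t*d with the polygon boundary.
# Returns a data.frame with one row per crossing: t (line parameter),
# edge (index i of edge v_i -> v_{i+1}), s (parameter along the edge in [0,1)).
line_poly_crossings <- function(p, c0, d) {
  n <- nrow(p)
  j <- c(2:n, 1)
  ex <- p[j, 1] - p[, 1]
  ey <- p[j, 2] - p[, 2]
  # solve c0 + t d = v_i + s e_i
  den <- d[1] * ey - d[2] * ex
  rx <- p[, 1] - c0[1]
  ry <- p[, 2] - c0[2]
  t <- (rx * ey - ry * ex) / den
  s <- (d[1] * ry - d[2] * rx) / (-den)
  ok <- is.finite(t) & is.finite(s) & s >= 0 & s < 1
  data.frame(t = t[ok], edge = which(ok), s = s[ok])
}

# Chord of a polygon through an interior point c0 along direction d:
# the pair of boundary crossings bracketing t = 0.  Returns NULL when the
# line does not produce a valid bracketing pair (degenerate geometry).
poly_chord <- function(p, c0, d) {
  cr <- line_poly_crossings(p, c0, d)
  if (nrow(cr) < 2) return(NULL)
  neg <- cr[cr$t <= 0, , drop = FALSE]
  pos <- cr[cr$t > 0, , drop = FALSE]
  if (nrow(neg) == 0 || nrow(pos) == 0) return(NULL)
  a <- neg[which.max(neg$t), ]
  b <- pos[which.min(pos$t), ]
  p1 <- c0 + a$t * d
  p2 <- c0 + b$t * d
  ends <- rbind(p1, p2)
  dimnames(ends) <- NULL
  list(
    ends = ends,
    edge = c(a$edge, b$edge),
    s = c(a$s, b$s),
    length = sqrt(sum((p2 - p1)^2))
  )
}

# Ear-clipping triangulation of a simple polygon given as an index vector
# into a position matrix.  Returns an m x 3 matrix of indices.
ear_clip <- function(idx, pos) {
  ring <- idx
  tris <- matrix(integer(0), 0, 3)
  guard <- 0L
  area2 <- function(a, b, c) {
    (pos[b, 1] - pos[a, 1]) * (pos[c, 2] - pos[a, 2]) -
      (pos[c, 1] - pos[a, 1]) * (pos[b, 2] - pos[a, 2])
  }
  while (length(ring) > 3) {
    n <- length(ring)
    guard <- guard + 1L
    if (guard > 10L * length(idx)^2)
      stop("ear clipping failed to terminate on polygon")
    clipped <- FALSE
    for (k in seq_len(n)) {
      a <- ring[(k - 2) %% n + 1]
      b <- ring[(k - 1) %% n + 1]
      cc <- ring[k %% n + 1]
      if (area2(a, b, cc) <= 0) next
      # no other ring vertex strictly inside the candidate ear
      tri <- rbind(pos[a, ], pos[b, ], pos[cc, ])
      rest <- setdiff(ring, c(a, b, cc))
      bad <- FALSE
      for (v in rest) {
        if (point_in_poly(pos[v, ], tri)) { bad <- TRUE; break }
      }
      if (bad) next
      tris <- rbind(tris, c(a, b, cc))
      ring <- ring[ring != b]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("ear clipping failed: no ear found (degenerate polygon?)")
  }
  rbind(tris, ring)
}

# Rotation matrix for angle theta (radians), counter-clockwise.
rot2 <- function(theta) {
  cs <- cos(theta); sn <- sin(theta)
  matrix(c(cs, sn, -sn, cs), 2, 2)
}

# Unit vector perpendicular to v (rotated +90 degrees).
perp2 <- function(v) c(-v[2], v[1])
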