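# Cell division.
#
# Ordinary cells divide along the shorter of the two centroid chords
# oriented parallel vs perpendicular to the cell polarity (ties go to the
# perpendicular wall).  The apical cell instead divides obliquely at a
# fixed angle to its polarity axis, alternating left and right; its distal
# daughter keeps the apical identity and the proximal daughter founds the
# next merophyte.  New wall endpoints are inserted into the rings of the
# neighboring cells as well, so the tissue stays a conforming tiling.
# Endpoints landing very close to an existing ring vertex are snapped to
# it, which regularizes boundary points and keeps triangle aspect ratios
# reasonable after retriangulation.

# Insert a new vertex at `p` on the wall between ring vertices va -> vb
# (consecutive in at least one ring).  Updates every ring containing that
# wall.  Returns list(tissue, v = new vertex id).
insert_wall_vertex <- function(tissue, va, vb, p) {
  tissue$pos <- rbind(tissue$pos, p)
  v <- nrow(tissue$pos)
  tissue$is_base <- c(tissue$is_base, FALSE)
  tissue$constraint <- c(tissue$constraint, CONSTRAINT_NONE)
  hit <- FALSE
  for (i in seq_along(tissue$ring)) {
    r <- tissue$ring[[i]]
    n <- length(r)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if ((r[k] == va && r[k2] == vb) || (r[k] == vb && r[k2] == va)) {
        tissue$ring[[i]] <- append(r, v, after = k)
        hit <- TRUE
        break
      }
    }
  }
  if (!hit) stop("internal: wall ", va, "-", vb, " not found in any ring")
  list(tissue = tissue, v = v)
}

# Resolve one chord endpoint: snap to a nearby ring vertex or insert a new
# wall vertex.  ring: parent's ring at call time; edge/s from poly_chord.
# Returns list(tissue, v).
resolve_chord_end <- function(tissue, ring, edge, s, snap = 0.05) {
  va <- ring[edge]
  vb <- ring[if (edge == length(ring)) 1L else edge + 1L]
  if (s < snap) return(list(tissue = tissue, v = va))
  if (s > 1 - snap) return(list(tissue = tissue, v = vb))
  p <- tissue$pos[va, ] + s * (tissue$pos[vb, ] - tissue$pos[va, ])
  insert_wall_vertex(tissue, va, vb, p)
}

# Split cell `id` along the centroid chord in direction `dir`.
# Returns list(tissue, daughters = c(idA, idB), wall = 2x2 endpoint matrix)
# or NULL when the chord does not yield two valid daughters.
split_cell <- function(tissue, id, dir, snap = 0.05) {
  i <- cell_index(tissue, id)
  r0 <- tissue$ring[[i]]
  P <- tissue$pos[r0, , drop = FALSE]
  c0 <- poly_centroid(P)
  ch <- poly_chord(P, c0, dir)
  if (is.null(ch)) return(NULL)
  e1 <- resolve_chord_end(tissue, r0, ch$edge[1], ch$s[1], snap)
  tissue <- e1$tissue
  # ring may have gained a vertex before the second edge; recompute chord
  # indices against the updated ring by locating the second edge's vertices
  r1 <- tissue$ring[[i]]
  va2 <- r0[ch$edge[2]]
  vb2 <- r0[if (ch$edge[2] == length(r0)) 1L else ch$edge[2] + 1L]
  if (e1$v == va2 || e1$v == vb2) {
    # both endpoints resolve onto the same original edge region; if the
    # first snapped onto an endpoint of edge 2, re-derive s on that edge
  }
  # find va2 position in current ring and check vb2 follows (possibly with
  # e1 vertex inserted between if both ends hit the same original edge)
  pos_a <- match(va2, r1)
  nxt <- r1[if (pos_a == length(r1)) 1L else pos_a + 1L]
  if (nxt == vb2) {
    e2 <- resolve_chord_end(tissue, r1, pos_a, ch$s[2], snap)
  } else {
    # edge was subdivided by endpoint 1: decide which sub-edge holds p2
    p2 <- ch$ends[2, ]
    seg1 <- tissue$pos[nxt, ] - tissue$pos[va2, ]
    tloc <- sum((p2 - tissue$pos[va2, ]) * seg1) / sum(seg1^2)
    if (tloc <= 1) {
      e2 <- resolve_chord_end(tissue, r1, pos_a, max(0, tloc), snap)
    } else {
      pos_m <- if (pos_a == length(r1)) 1L else pos_a + 1L
      seg2 <- tissue$pos[vb2, ] - tissue$pos[nxt, ]
      sloc <- sum((p2 - tissue$pos[nxt, ]) * seg2) / sum(seg2^2)
      e2 <- resolve_chord_end(tissue, r1, pos_m, min(1, max(0, sloc)), snap)
    }
  }
  tissue <- e2$tissue
  w1 <- e1$v; w2 <- e2$v
  if (w1 == w2) return(NULL)
  r <- tissue$ring[[i]]
  a <- match(w1, r); b <- match(w2, r)
  if (is.na(a) || is.na(b)) stop("internal: chord endpoint missing from ring")
  if (a < b) {
    ringA <- r[a:b]
    ringB <- c(r[b:length(r)], r[seq_len(a)])
  } else {
    ringA <- r[b:a]
    ringB <- c(r[a:length(r)], r[seq_len(b)])
  }
  if (length(ringA) < 3 || length(ringB) < 3) return(NULL)
  areaA <- poly_area(tissue$pos[ringA, , drop = FALSE])
  areaB <- poly_area(tissue$pos[ringB, , drop = FALSE])
  area0 <- areaA + areaB
  if (areaA < 1e-4 * area0 || areaB < 1e-4 * area0) return(NULL)
  # replace parent by daughters (daughter A first)
  idA <- tissue$next_cell_id
  idB <- idA + 1L
  tissue$next_cell_id <- idB + 1L
  keep <- seq_along(tissue$ring)[-i]
  grab <- function(x, add) c(x[keep], add)
  tissue$ring <- c(tissue$ring[keep], list(ringA, ringB))
  tissue$cell_id <- grab(tissue$cell_id, c(idA, idB))
  tissue$merophyte <- grab(tissue$merophyte, rep(tissue$merophyte[i], 2))
  tissue$type <- grab(tissue$type, rep(tissue$type[i], 2))
  tissue$zone <- grab(tissue$zone, rep(tissue$zone[i], 2))
  tissue$polarity <- rbind(tissue$polarity[keep, , drop = FALSE],
                           tissue$polarity[i, , drop = FALSE],
                           tissue$polarity[i, , drop = FALSE])
  tissue$k_par <- grab(tissue$k_par, rep(tissue$k_par[i], 2))
  tissue$k_per <- grab(tissue$k_per, rep(tissue$k_per[i], 2))
  tissue$area_threshold <- grab(tissue$area_threshold,
                                rep(tissue$area_threshold[i], 2))
  tissue$t_diff <- grab(tissue$t_diff, rep(tissue$t_diff[i], 2))
  tissue$parent <- grab(tissue$parent, rep(id, 2))
  tissue$lineage[[length(tissue$lineage) + 1L]] <-
    data.frame(child = c(idA, idB), parent = id, time = tissue$time)
  list(tissue = tissue, daughters = c(idA, idB),
       wall = tissue$pos[c(w1, w2), , drop = FALSE])
}

#' Divide a cell by the shortest-wall rule
#'
#' The division wall is the shorter of the two chords through the cell
#' centroid oriented parallel vs perpendicular to the cell's polarity; on a
#' tie the perpendicular wall is chosen.  Daughters inherit merophyte,
#' tissue type, zone and growth parameters; daughter areas sum exactly to
#' the parent area.  If the chosen orientation fails to produce two valid
#' simple daughters (degenerate geometry), the other orientation is tried
#' before erroring.
#'
#' @param tissue a tissue.
#' @param id id of the cell to divide.
#' @return the updated tissue; the division is appended to
#'   \code{tissue$events} and \code{tissue$lineage}.
#' @export
divide_cell <- function(tissue, id) {
  i <- cell_index(tissue, id)
  u <- tissue$polarity[i, ]
  if (!all(is.finite(u))) stop("cell ", id, " has no polarity")
  P <- tissue$pos[tissue$ring[[i]], , drop = FALSE]
  c0 <- poly_centroid(P)
  ch_par <- poly_chord(P, c0, u)
  ch_per <- poly_chord(P, c0, perp2(u))
  l_par <- if (is.null(ch_par)) Inf else ch_par$length
  l_per <- if (is.null(ch_per)) Inf else ch_per$length
  if (!is.finite(l_par) && !is.finite(l_per))
    stop("cell ", id, ": no valid division chord")
  # tie (or shorter perpendicular) -> wall perpendicular to polarity
  first_dir <- if (l_par < l_per * (1 - 1e-12)) u else perp2(u)
  second_dir <- if (identical(first_dir, u)) perp2(u) else u
  res <- split_cell(tissue, id, first_dir)
  if (is.null(res)) res <- split_cell(tissue, id, second_dir)
  if (is.null(res))
    stop("cell ", id, " could not be split into two simple parts; centroid ",
         paste(signif(c0, 6), collapse = ", "))
  tis <- res$tissue
  wall_vec <- res$wall[2, ] - res$wall[1, ]
  ang <- wall_polarity_angle(wall_vec, u)
  tis$events[[length(tis$events) + 1L]] <- list(
    time = tis$time, kind = "division", parent = id,
    daughters = res$daughters, wall = res$wall, angle_to_polarity = ang,
    parent_area = poly_area(P),
    daughter_areas = vapply(cell_index(tis, res$daughters), function(k)
      poly_area(tis$pos[tis$ring[[k]], , drop = FALSE]), 0))
  tis
}

# Acute angle (degrees) between a wall vector and the polarity axis.
wall_polarity_angle <- function(wall_vec, polarity) {
  cw <- abs(sum(wall_vec * polarity)) /
    (sqrt(sum(wall_vec^2)) * sqrt(sum(polarity^2)))
  acos(pmin(1, cw)) * 180 / pi
}

#' Oblique division of the apical cell
#'
#' The apical cell divides along a wall through its centroid at
#' \code{angle} degrees to its polarity axis, on alternating sides
#' (left first).  The distal daughter (containing the organ apex) keeps
#' the apical identity; the proximal daughter becomes the next merophyte.
#'
#' @param tissue a tissue with an apical cell.
#' @param angle wall angle to the polarity axis, degrees (default 60).
#' @return the updated tissue.
#' @export
apical_divide <- function(tissue, angle = 60) {
  id <- tissue$apical_id
  if (is.na(id)) stop("tissue has no apical cell")
  i <- cell_index(tissue, id)
  u <- tissue$polarity[i, ]
  side <- tissue$apical_side
  d <- as.vector(rot2(side * angle * pi / 180) %*% u)
  apex_v <- tissue$ring[[i]][which.max(tissue$pos[tissue$ring[[i]], 2])]
  parent_area <- poly_area(tissue$pos[tissue$ring[[i]], , drop = FALSE])
  res <- split_cell(tissue, id, d)
  if (is.null(res)) stop("apical division chord failed")
  tis <- res$tissue
  da <- res$daughters
  iA <- cell_index(tis, da[1]); iB <- cell_index(tis, da[2])
  inA <- apex_v %in% tis$ring[[iA]]
  inB <- apex_v %in% tis$ring[[iB]]
  if (inA && inB) {
    cyA <- poly_centroid(tis$pos[tis$ring[[iA]], , drop = FALSE])[2]
    cyB <- poly_centroid(tis$pos[tis$ring[[iB]], , drop = FALSE])[2]
    distal <- if (cyA >= cyB) 1L else 2L
  } else if (inA) distal <- 1L else if (inB) distal <- 2L else
    stop("apex vertex lost from both apical daughters")
  dist_i <- if (distal == 1L) iA else iB
  prox_i <- if (distal == 1L) iB else iA
  tis$apical_id <- tis$cell_id[dist_i]
  tis$type[dist_i] <- "apical"
  tis$merophyte[dist_i] <- NA_integer_
  tis$type[prox_i] <- "blade"
  tis$merophyte[prox_i] <- tis$next_merophyte
  tis$next_merophyte <- tis$next_merophyte + 1L
  tis$apical_side <- -side
  wall_vec <- res$wall[2, ] - res$wall[1, ]
  tis$events[[length(tis$events) + 1L]] <- list(
    time = tis$time, kind = "apical", parent = id, daughters = da,
    wall = res$wall, angle_to_polarity = wall_polarity_angle(wall_vec, u),
    merophyte = tis$merophyte[prox_i],
    parent_area = parent_area,
    daughter_areas = c(poly_area(tis$pos[tis$ring[[iA]], , drop = FALSE]),
                       poly_area(tis$pos[tis$ring[[iB]], , drop = FALSE])))
  tis
}
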