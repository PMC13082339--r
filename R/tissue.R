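# The polygonal cell tissue: vertices shared between cells, cells as
# counter-clockwise vertex rings, plus the positional fields (distance,
# polarity) that drive growth and zonation.
#
# Coordinate convention: y is the longitudinal organ axis (base at y = 0,
# apex toward +y), x is mediolateral.  Lengths are nominally micrometres,
# time is in days.

CONSTRAINT_NONE <- 0L
CONSTRAINT_LONGITUDINAL <- 1L # y fixed (Dirichlet on the longitudinal axis)
CONSTRAINT_FIXED <- 2L        # both coordinates fixed (rigid-mode anchor)

#' Construct a tissue object
#'
#' A tissue bundles shared vertices, polygonal cells (counter-clockwise
#' vertex-id rings), per-cell identities and growth parameters, and the
#' simulation clock.  Vertices on the organ base carry a longitudinal
#' Dirichlet constraint; exactly one base vertex is fully fixed to remove
#' rigid-body modes.
#'
#' @param pos numeric matrix (n x 2) of vertex positions.
#' @param is_base logical vector: vertex belongs to the bottom-most set.
#' @param ring list of integer vectors, one counter-clockwise vertex ring
#'   per cell.
#' @param merophyte integer vector of clonal-sector indices (NA for the
#'   apical cell and the attachment zone).
#' @param type character vector in \code{c("apical","blade","midrib","attachment")}.
#' @param zone character vector in \code{c("attachment","proliferative","differentiation")}.
#' @param apical_id cell id of the apical cell (NA if none).
#' @param time simulation time (days after initiation).
#' @param phase developmental phase (1, 2 or 3).
#' @return an object of class \code{"tissue"}.
#' @export
new_tissue <- function(pos, is_base, ring,
                       merophyte = rep(NA_integer_, length(ring)),
                       type = rep("blade", length(ring)),
                       zone = rep("proliferative", length(ring)),
                       apical_id = NA_integer_,
                       time = 1.0, phase = 1L) {
  dimnames(pos) <- NULL
  n_v <- nrow(pos)
  n_c <- length(ring)
  constraint <- rep(CONSTRAINT_NONE, n_v)
  constraint[is_base] <- CONSTRAINT_LONGITUDINAL
  if (any(is_base)) {
    anchor <- min(which(is_base))
    constraint[anchor] <- CONSTRAINT_FIXED
  }
  tis <- structure(list(
    pos = pos,
    is_base = is_base,
    constraint = constraint,
    ring = ring,
    cell_id = seq_len(n_c),
    merophyte = as.integer(merophyte),
    type = type,
    zone = zone,
    polarity = matrix(rep(c(0, 1), each = n_c), n_c, 2),
    k_par = numeric(n_c),
    k_per = numeric(n_c),
    area_threshold = rep(Inf, n_c),
    t_diff = rep(NA_real_, n_c),
    parent = rep(NA_integer_, n_c),
    apical_id = apical_id,
    apical_side = 1L,            # +1 divides toward -x ("left") first
    next_cell_id = n_c + 1L,
    next_merophyte = max(c(0L, merophyte), na.rm = TRUE) + 1L,
    time = time,
    phase = as.integer(phase),
    lineage = list(),
    events = list(),
    fem = NULL
  ), class = "tissue")
  tis
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf(
    "<tissue> t = %.2f d, phase %d: %d cells, %d vertices, %d division events\n",
    x$time, x$phase, length(x$ring), nrow(x$pos), length(x$events)))
  tab <- table(x$type)
  cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a tissue
#'
#' @param tissue a tissue.
#' @return integer count.
#' @export
n_cells <- function(tissue) length(tissue$ring)

cell_index <- function(tissue, id) {
  i <- match(id, tissue$cell_id)
  if (anyNA(i)) stop("unknown cell id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Cell polygon as a coordinate matrix
#'
#' @param tissue a tissue.
#' @param id a cell id.
#' @return numeric matrix (n x 2), counter-clockwise.
#' @export
cell_polygon <- function(tissue, id) {
  tissue$pos[tissue$ring[[cell_index(tissue, id)]], , drop = FALSE]
}

#' Areas of all cells
#'
#' @param tissue a tissue.
#' @return numeric vector aligned with \code{tissue$cell_id}.
#' @export
cell_areas <- function(tissue) {
  vapply(tissue$ring, function(r) poly_area(tissue$pos[r, , drop = FALSE]), 0)
}

#' Centroids of all cells
#'
#' @param tissue a tissue.
#' @return numeric matrix (n_cells x 2).
#' @export
cell_centroids <- function(tissue) {
  t(vapply(tissue$ring, function(r) poly_centroid(tissue$pos[r, , drop = FALSE]),
           c(0, 0)))
}

# Directed ring edges of every cell: data.frame(cell_idx, v1, v2).
ring_edges <- function(tissue) {
  n <- lengths(tissue$ring)
  v1 <- unlist(tissue$ring, use.names = FALSE)
  v2 <- unlist(lapply(tissue$ring, function(r) r[c(2:length(r), 1)]),
               use.names = FALSE)
  data.frame(cell = rep(seq_along(tissue$ring), n), v1 = v1, v2 = v2)
}

#' Cell adjacency graph
#'
#' Two cells are adjacent iff they share at least one wall segment (a
#' boundary edge traversed in opposite directions by the two rings).  Each
#' adjacency is annotated with the total Euclidean length of the shared
#' wall.  A wall segment claimed by more than two cells is a structural
#' error (non-manifold tissue).
#'
#' @param tissue a tissue.
#' @return list with \code{edges}, a data.frame of cell-id pairs
#'   \code{a < b} and shared-wall \code{wall_length}, and \code{graph},
#'   the corresponding \code{igraph} object (vertices named by cell id).
#' @export
build_adjacency <- function(tissue) {
  re <- ring_edges(tissue)
  lo <- pmin(re$v1, re$v2)
  hi <- pmax(re$v1, re$v2)
  key <- paste(lo, hi)
  cnt <- table(key)
  if (any(cnt > 2)) {
    bad <- names(cnt)[cnt > 2][1]
    stop("non-manifold wall shared by >2 cells (vertex pair ", bad, ")")
  }
  dup <- key[duplicated(key)]
  edges <- NULL
  if (length(dup)) {
    shared <- re[key %in% dup, ]
    skey <- paste(pmin(shared$v1, shared$v2), pmax(shared$v1, shared$v2))
    o <- order(skey)
    shared <- shared[o, ]
    first <- shared[seq(1, nrow(shared), by = 2), ]
    second <- shared[seq(2, nrow(shared), by = 2), ]
    seglen <- sqrt(rowSums((tissue$pos[first$v1, , drop = FALSE] -
                            tissue$pos[first$v2, , drop = FALSE])^2))
    a <- pmin(first$cell, second$cell)
    b <- pmax(first$cell, second$cell)
    if (any(a == b)) stop("cell ring reuses an edge (self-adjacent cell)")
    agg <- stats::aggregate(seglen, by = list(a = a, b = b), FUN = sum)
    edges <- data.frame(a = tissue$cell_id[agg$a], b = tissue$cell_id[agg$b],
                        wall_length = agg$x)
  } else {
    edges <- data.frame(a = integer(0), b = integer(0), wall_length = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$a), to = as.character(edges$b),
                   wall_length = edges$wall_length),
    directed = FALSE,
    vertices = data.frame(name = as.character(tissue$cell_id)))
  list(edges = edges, graph = g)
}

#' Single-source distance field on the cell adjacency graph
#'
#' Graph shortest-path distances from a set of source cells.  Two flavors:
#' \code{"cell-count"} uses unit edge weights (distance in cells, as used
#' for the proliferative-zone rule), \code{"euclidean-wall-weight"} uses
#' centroid-to-centroid Euclidean distances between wall-sharing cells (the
#' absolute-distance dialect used by the quantification profiles).
#'
#' @param tissue a tissue.
#' @param source vector of source cell ids (distance 0).
#' @param flavor \code{"cell-count"} or \code{"euclidean-wall-weight"}.
#' @param adj optional precomputed \code{build_adjacency(tissue)}.
#' @return numeric vector of distances aligned with \code{tissue$cell_id};
#'   disconnected cells get \code{Inf}.
#' @export
distance_field <- function(tissue, source,
                           flavor = c("cell-count", "euclidean-wall-weight"),
                           adj = NULL) {
  flavor <- match.arg(flavor)
  if (length(source) == 0) stop("source cell set is empty")
  if (is.null(adj)) adj <- build_adjacency(tissue)
  g <- adj$graph
  if (flavor == "cell-count") {
    w <- rep(1, nrow(adj$edges))
  } else {
    cen <- cell_centroids(tissue)
    ia <- cell_index(tissue, adj$edges$a)
    ib <- cell_index(tissue, adj$edges$b)
    w <- sqrt(rowSums((cen[ia, , drop = FALSE] - cen[ib, , drop = FALSE])^2))
  }
  d <- igraph::distances(g, v = as.character(source), weights = w)
  out <- apply(d, 2, min)
  unname(out[match(as.character(tissue$cell_id), colnames(d))])
}

#' Per-cell polarity field from the apical distance field
#'
#' Polarity is the negative normalized gradient of the distance field from
#' the apical cell, so it points from the organ base toward the apex.  The
#' gradient at a cell is estimated by a weighted least-squares fit of a
#' linear function to the distance values of the cell and its wall-sharing
#' neighbors at their centroids, weighted by shared wall length (the cell
#' itself gets the mean neighbor weight).  Cells with a degenerate
#' neighborhood fall back to the global organ axis (0, 1).
#'
#' @param tissue a tissue.
#' @param dist optional precomputed apical distance field
#'   (euclidean-wall-weight flavor); computed from \code{tissue$apical_id}
#'   when missing.
#' @param adj optional precomputed adjacency.
#' @return matrix (n_cells x 2) of unit vectors, with attribute
#'   \code{"fallback"} marking cells where the fit was degenerate.
#' @export
polarity_field <- function(tissue, dist = NULL, adj = NULL) {
  if (is.null(adj)) adj <- build_adjacency(tissue)
  if (is.null(dist)) {
    if (is.na(tissue$apical_id)) stop("tissue has no apical cell")
    dist <- distance_field(tissue, tissue$apical_id,
                           "euclidean-wall-weight", adj = adj)
  }
  cen <- cell_centroids(tissue)
  nc <- n_cells(tissue)
  nbr <- vector("list", nc)
  wts <- vector("list", nc)
  ia <- cell_index(tissue, adj$edges$a)
  ib <- cell_index(tissue, adj$edges$b)
  for (k in seq_len(nrow(adj$edges))) {
    nbr[[ia[k]]] <- c(nbr[[ia[k]]], ib[k])
    nbr[[ib[k]]] <- c(nbr[[ib[k]]], ia[k])
    wts[[ia[k]]] <- c(wts[[ia[k]]], adj$edges$wall_length[k])
    wts[[ib[k]]] <- c(wts[[ib[k]]], adj$edges$wall_length[k])
  }
  out <- matrix(0, nc, 2)
  fallback <- logical(nc)
  for (i in seq_len(nc)) {
    js <- c(i, nbr[[i]])
    w <- c(mean(wts[[i]]), wts[[i]])
    d <- dist[js]
    ok <- is.finite(d)
    js <- js[ok]; w <- w[ok]; d <- d[ok]
    g <- NULL
    if (length(js) >= 3) {
      X <- cbind(1, cen[js, 1] - cen[i, 1], cen[js, 2] - cen[i, 2])
      XtW <- t(X * w)
      M <- XtW %*% X
      if (abs(det(M)) > 1e-12 * (sum(w) * max(1, max(abs(X))))^3) {
        beta <- tryCatch(solve(M, XtW %*% d), error = function(e) NULL)
        if (!is.null(beta)) g <- beta[2:3]
      }
    }
    if (is.null(g) || sqrt(sum(g^2)) < 1e-12) {
      out[i, ] <- c(0, 1)
      fallback[i] <- TRUE
    } else {
      out[i, ] <- -g / sqrt(sum(g^2))
    }
  }
  attr(out, "fallback") <- fallback
  out
}

#' Triangulate one cell into finite elements
#'
#' Cells that are star-shaped with respect to their centroid are fanned
#' from an added centroid node (the common case, and the decomposition used
#' by the simulator so that elements never cross cell boundaries); other
#' simple polygons are ear-clipped using boundary vertices only.
#'
#' @param p polygon coordinate matrix (n x 2), counter-clockwise.
#' @return list with \code{nodes} (polygon vertices, plus the centroid as
#'   the last row when fanned), \code{tri} (m x 3 index matrix into
#'   \code{nodes}) and \code{centroid_node} (index or NA).
#' @export
triangulate_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3) stop("polygon with fewer than 3 vertices")
  a_tot <- poly_area(p)
  if (a_tot <= 0) stop("polygon is not counter-clockwise or has no area")
  c0 <- poly_centroid(p)
  j <- c(2:n, 1)
  # fan triangle signed areas
  fa <- ((p[, 1] - c0[1]) * (p[j, 2] - c0[2]) -
         (p[j, 1] - c0[1]) * (p[, 2] - c0[2])) / 2
  if (all(fa > 1e-12 * a_tot)) {
    nodes <- rbind(p, c0)
    tri <- cbind(n + 1L, seq_len(n), j)
    return(list(nodes = nodes, tri = tri, centroid_node = n + 1L))
  }
  tri <- ear_clip(seq_len(n), p)
  list(nodes = p, tri = tri, centroid_node = NA_integer_)
}

#' Triangulate one cell of a tissue
#'
#' Convenience wrapper over \code{\link{triangulate_polygon}} for a cell
#' identified by id; triangles are tagged with the owning cell id.
#'
#' @param tissue a tissue.
#' @param id cell id.
#' @return as \code{triangulate_polygon}, plus \code{cell_id}.
#' @export
triangulate_cell <- function(tissue, id) {
  out <- tryCatch(triangulate_polygon(cell_polygon(tissue, id)),
                  error = function(e)
                    stop("triangulation failed for cell ", id, ": ",
                         conditionMessage(e)))
  out$cell_id <- id
  out
}

# Outer boundary area of the tissue: edges used by exactly one ring,
# summed with orientation (valid for a tiling whether or not the boundary
# is a single loop).
tissue_outline_area <- function(tissue) {
  re <- ring_edges(tissue)
  key <- paste(pmin(re$v1, re$v2), pmax(re$v1, re$v2))
  cnt <- table(key)
  outer <- re[cnt[key] == 1, ]
  p <- tissue$pos
  sum(p[outer$v1, 1] * p[outer$v2, 2] - p[outer$v2, 1] * p[outer$v1, 2]) / 2
}

#' Validate tissue invariants
#'
#' Checks ring simplicity/orientation, positive areas, tiling conservation
#' (sum of cell areas equals the area enclosed by the outer boundary), and
#' optionally pairwise interior disjointness (O(n^2), for small tissues).
#'
#' @param tissue a tissue.
#' @param full also run the pairwise overlap check.
#' @return invisibly TRUE; stops with a message on violation.
#' @export
validate_tissue <- function(tissue, full = FALSE) {
  if (!all(is.finite(tissue$pos))) stop("non-finite vertex positions")
  areas <- cell_areas(tissue)
  if (any(areas <= 0))
    stop("cell(s) with non-positive area: ",
         paste(tissue$cell_id[areas <= 0], collapse = ", "))
  if (sum(tissue$constraint == CONSTRAINT_FIXED) != 1)
    stop("exactly one vertex must be fully fixed")
  out_area <- tissue_outline_area(tissue)
  if (abs(sum(areas) - out_area) > 1e-9 * out_area)
    stop(sprintf("tiling violated: sum of cell areas %.12g != outline area %.12g",
                 sum(areas), out_area))
  # simplicity: no repeated vertex within a ring
  for (i in seq_along(tissue$ring)) {
    r <- tissue$ring[[i]]
    if (anyDuplicated(r))
      stop("cell ", tissue$cell_id[i], " ring repeats a vertex")
  }
  if (full) {
    cen <- cell_centroids(tissue)
    for (i in seq_along(tissue$ring)) {
      for (k in seq_along(tissue$ring)) {
        if (k == i) next
        if (point_in_poly(cen[i, ], tissue$pos[tissue$ring[[k]], , drop = FALSE]))
          stop("cell ", tissue$cell_id[i], " centroid inside cell ",
               tissue$cell_id[k], " (overlap)")
      }
    }
  }
  invisible(TRUE)
}

#' Organ aspect ratio (length over width)
#'
#' Longitudinal extent divided by the organ width, where width is the
#' largest mediolateral cross-section: the maximum over horizontal slices
#' of the x-extent of the tissue at that height.  Slicing makes the
#' measure robust to a slightly curved tip, which would inflate a
#' bounding-box width.  This is the scalar used to order scenario outcomes
#' from broad (wild type) to rod-like (auxin-treated pin mutant).
#'
#' @param tissue a tissue.
#' @param n_slices number of horizontal slices.
#' @return positive scalar.
#' @export
aspect_ratio <- function(tissue, n_slices = 101) {
  re <- ring_edges(tissue)
  p1 <- tissue$pos[re$v1, , drop = FALSE]
  p2 <- tissue$pos[re$v2, , drop = FALSE]
  used <- sort(unique(c(re$v1, re$v2)))
  yr <- range(tissue$pos[used, 2])
  len <- diff(yr)
  width <- 0
  for (y in seq(yr[1] + 1e-9 * len, yr[2] - 1e-9 * len,
                length.out = n_slices)) {
    cr <- (p1[, 2] > y) != (p2[, 2] > y)
    if (!any(cr)) next
    xi <- p1[cr, 1] + (y - p1[cr, 2]) / (p2[cr, 2] - p1[cr, 2]) *
      (p2[cr, 1] - p1[cr, 1])
    width <- max(width, diff(range(xi)))
  }
  len / width
}
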