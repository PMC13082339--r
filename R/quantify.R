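# Cellular quantification: the lineage-based measures applied identically
# to simulator output and to synthetic time-lapse fixtures — relative area
# expansion, division counts, new-wall orientation, absolute/normalized
# distance from the organ base, principal directions of growth from
# matched cell junctions, merophyte contributions, and binned basipetal
# profiles (median with interquartile range per bin).

#' Relative area expansion (percent)
#'
#' \code{((sum of daughter areas / parent area) - 1) * 100}: the relative
#' area increase of a parent cell's sector over one imaging interval.
#'
#' @param parent_area parent cell area at the earlier time point (> 0).
#' @param daughter_areas areas of its daughters at the later time point.
#' @return percent area increase.
#' @export
area_expansion <- function(parent_area, daughter_areas) {
  if (length(daughter_areas) == 0) stop("empty daughter set")
  if (parent_area <= 0) stop("parent area must be positive")
  (sum(daughter_areas) / parent_area - 1) * 100
}

#' Number of divisions in an interval
#'
#' The number of daughter cells at the next time point minus one.
#'
#' @param parent parent cell id (unused; kept for a uniform signature).
#' @param children vector of child ids at the next time point.
#' @return non-negative integer.
#' @export
division_count <- function(parent, children) {
  if (length(children) < 1) stop("parent with no children")
  length(children) - 1L
}

#' Classify a new wall as longitudinal or mediolateral
#'
#' The acute angle between the wall and the local longitudinal axis (the
#' base-distance gradient) below 45 degrees is longitudinal; 45 degrees or
#' more is mediolateral (a fixed-threshold replacement for manual scoring).
#'
#' @param wall 2 x 2 matrix of wall endpoints, or a length-2 direction.
#' @param axis length-2 local longitudinal axis.
#' @return \code{"longitudinal"} or \code{"mediolateral"}.
#' @export
classify_wall_orientation <- function(wall, axis) {
  v <- if (is.matrix(wall)) wall[2, ] - wall[1, ] else wall
  if (sum(v^2) == 0) stop("zero-length wall")
  if (sum(axis^2) == 0) stop("zero-length axis")
  ang <- wall_polarity_angle(v, axis)
  if (ang < 45) "longitudinal" else "mediolateral"
}

#' Distances from the organ base, normalized, and profile bins
#'
#' Euclidean-wall-weight graph distance from the base cell set, normalized
#' by the maximum distance at the same time point, and assigned to one of
#' 10 equal-length bins along the organ axis.
#'
#' @param tissue a tissue.
#' @param source base cell ids; defaults to the attachment cells.
#' @return data.frame with \code{cell_id}, \code{distance},
#'   \code{normalized}, \code{bin}.
#' @export
distance_profiles <- function(tissue, source = NULL) {
  if (is.null(source)) source <- tissue$cell_id[tissue$type == "attachment"]
  d <- distance_field(tissue, source, "euclidean-wall-weight")
  dmax <- max(d[is.finite(d)])
  if (dmax == 0) stop("maximum base distance is zero")
  nd <- d / dmax
  data.frame(cell_id = tissue$cell_id, distance = d, normalized = nd,
             bin = pmin(10L, pmax(1L, as.integer(ceiling(10 * nd)))))
}

#' Principal directions of growth from matched junctions
#'
#' Fits the least-squares affine map taking a cell's junction positions at
#' one time point to the next, takes the symmetric right stretch from the
#' polar decomposition, and reports principal stretch rates and the rates
#' projected on a supplied axis: \code{k = log(stretch) / dt} per day,
#' anisotropy \code{(l1 - l2) / (l1 + l2)}.
#'
#' @param P0 matrix (n x 2) of junction positions at the earlier time.
#' @param P1 matrix (n x 2) of the matched positions at the later time.
#' @param dt interval length (days).
#' @param axis local longitudinal axis at the earlier time (default (0,1)).
#' @return list with \code{k_max}, \code{k_min}, \code{k_par},
#'   \code{k_per}, \code{anisotropy}, \code{dir_max} (unit vector) and the
#'   fitted \code{F}.
#' @export
growth_tensor <- function(P0, P1, dt, axis = c(0, 1)) {
  if (nrow(P0) < 3 || nrow(P1) != nrow(P0))
    stop("need >= 3 matched junctions")
  Q0 <- sweep(P0, 2, colMeans(P0))
  Q1 <- sweep(P1, 2, colMeans(P1))
  M <- crossprod(Q0)
  if (abs(det(M)) < 1e-12 * (sum(diag(M)) / 2)^2)
    stop("rank-deficient junction set (collinear points)")
  Fm <- t(solve(M, crossprod(Q0, Q1)))    # P1 ~ P0 %*% t(Fm)
  sv <- svd(Fm)
  l1 <- sv$d[1]; l2 <- sv$d[2]
  a <- axis / sqrt(sum(axis^2))
  C <- crossprod(Fm)
  lam_par <- sqrt(drop(t(a) %*% C %*% a))
  pa <- perp2(a)
  lam_per <- sqrt(drop(t(pa) %*% C %*% pa))
  list(k_max = log(l1) / dt, k_min = log(l2) / dt,
       k_par = log(lam_par) / dt, k_per = log(lam_per) / dt,
       anisotropy = (l1 - l2) / (l1 + l2),
       dir_max = sv$v[, 1], F = Fm)
}

#' Per-merophyte area fractions
#'
#' Fraction of the organ area (cells carrying a merophyte label) in each
#' clonal sector; fractions sum to one.
#'
#' @param tissue a tissue.
#' @return data.frame with \code{merophyte}, \code{area}, \code{fraction}.
#' @export
merophyte_contribution <- function(tissue) {
  areas <- cell_areas(tissue)
  keep <- !is.na(tissue$merophyte)
  agg <- stats::aggregate(areas[keep],
                          by = list(merophyte = tissue$merophyte[keep]),
                          FUN = sum)
  data.frame(merophyte = agg$merophyte, area = agg$x,
             fraction = agg$x / sum(agg$x))
}

#' Binned median/interquartile profile
#'
#' Median and first/third quartiles of a value over the 10 equal-length
#' normalized-distance bins; empty bins are reported as NA.
#'
#' @param records data.frame with a \code{bin} column.
#' @param value_field name of the value column.
#' @return data.frame with \code{bin}, \code{n}, \code{median}, \code{q1},
#'   \code{q3}.
#' @export
binned_profile <- function(records, value_field) {
  v <- records[[value_field]]
  out <- data.frame(bin = 1:10, n = 0L, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_)
  for (b in 1:10) {
    x <- v[records$bin == b & !is.na(v)]
    if (length(x)) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      out[b, c("n", "median", "q1", "q3")] <- c(length(x), q[2], q[1], q[3])
    }
  }
  out
}

#' Build a lineage table from a simulated trajectory
#'
#' Extracts per-snapshot cell records, parent links across consecutive
#' snapshots (via the simulator's lineage log), and exact junction
#' correspondences (boundary vertices persist by id between snapshots).
#'
#' @param traj a \code{phyllid_trajectory}.
#' @return a \code{lineage_table}: \code{times}, \code{timepoints} (each
#'   with \code{id}, \code{poly}, \code{merophyte}, \code{axis}),
#'   \code{links} (interval, child, parent), \code{junctions} (per
#'   interval: cell, P0, P1).
#' @export
lineage_table <- function(traj) {
  snaps <- traj$snapshots
  parent_of <- integer(0)
  for (ln in traj$final$lineage)
    parent_of[as.character(ln$child)] <- ln$parent
  tp <- lapply(snaps, function(s) {
    list(id = s$cell_id,
         poly = lapply(s$ring, function(r) s$pos[r, , drop = FALSE]),
         merophyte = s$merophyte,
         axis = s$polarity)
  })
  links <- NULL; junctions <- list()
  for (iv in seq_len(length(snaps) - 1L)) {
    s0 <- snaps[[iv]]; s1 <- snaps[[iv + 1L]]
    anc <- vapply(s1$cell_id, function(cid) {
      while (!(cid %in% s0$cell_id)) {
        nxt <- parent_of[as.character(cid)]
        if (is.na(nxt)) return(NA_integer_)
        cid <- nxt
      }
      cid
    }, 0L)
    links <- rbind(links, data.frame(interval = iv, child = s1$cell_id,
                                     parent = anc))
    jv <- list()
    for (k in seq_along(s0$cell_id)) {
      r <- s0$ring[[k]]
      jv[[k]] <- list(cell = s0$cell_id[k],
                      P0 = s0$pos[r, , drop = FALSE],
                      P1 = s1$pos[r, , drop = FALSE])
    }
    junctions[[iv]] <- jv
  }
  structure(list(times = traj$times, timepoints = tp, links = links,
                 junctions = junctions, ground_truth = NULL),
            class = "lineage_table")
}

# Distance/normalized-distance/bin for one lineage-table time point:
# adjacency recovered by coordinate-matching shared polygon edges,
# euclidean-wall-weight shortest paths from the bottom-most cells.
lt_distance <- function(timepoint) {
  polys <- timepoint$poly
  n <- length(polys)
  cen <- t(vapply(polys, poly_centroid, c(0, 0)))
  key_of <- function(p) {
    m <- nrow(p)
    j <- c(2:m, 1)
    a <- paste(sprintf("%.6f", p[, 1]), sprintf("%.6f", p[, 2]))
    b <- a[j]
    paste(pmin(a, b), pmax(a, b))
  }
  keys <- lapply(polys, key_of)
  edge_cells <- split(rep(seq_len(n), lengths(keys)), unlist(keys))
  pairs <- unique(do.call(rbind, lapply(edge_cells, function(cs) {
    cs <- unique(cs)
    if (length(cs) == 2) matrix(sort(cs), 1) else NULL
  })))
  ymin <- min(vapply(polys, function(p) min(p[, 2]), 0))
  src <- which(vapply(polys, function(p) any(p[, 2] < ymin + 1e-6), TRUE))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(pairs) && nrow(pairs)) {
    w <- sqrt(rowSums((cen[pairs[, 1], , drop = FALSE] -
                       cen[pairs[, 2], , drop = FALSE])^2))
    g <- igraph::add_edges(g, t(pairs))
    d <- igraph::distances(g, v = src, weights = w)
  } else {
    d <- matrix(0, length(src), n)
  }
  dist <- apply(d, 2, min)
  dmax <- max(dist[is.finite(dist)])
  nd <- if (dmax > 0) dist / dmax else dist
  data.frame(distance = dist, normalized = nd,
             bin = pmin(10L, pmax(1L, as.integer(ceiling(10 * nd)))))
}

#' Per-cell per-interval growth records
#'
#' Applies the quantification formulas to every parent cell of every
#' interval of a lineage table: area expansion, division count, growth
#' rates from the junction-fit growth tensor projected on the local axis,
#' anisotropy, and (normalized) distance from the base with its profile
#' bin.  Cells whose junction fit is degenerate get NA rates.
#'
#' @param lt a \code{lineage_table}.
#' @return data.frame, one row per parent cell per interval.
#' @export
growth_records <- function(lt) {
  out <- NULL
  for (iv in seq_len(length(lt$times) - 1L)) {
    dt <- lt$times[iv + 1L] - lt$times[iv]
    tp0 <- lt$timepoints[[iv]]; tp1 <- lt$timepoints[[iv + 1L]]
    areas0 <- vapply(tp0$poly, poly_area, 0)
    areas1 <- vapply(tp1$poly, poly_area, 0)
    dd <- lt_distance(tp0)
    lk <- lt$links[lt$links$interval == iv, ]
    jmap <- lt$junctions[[iv]]
    jcells <- vapply(jmap, function(j) j$cell, 0L)
    for (k in seq_along(tp0$id)) {
      pid <- tp0$id[k]
      children <- lk$child[lk$parent == pid]
      if (!length(children)) next
      ci <- match(children, tp1$id)
      exp_pct <- area_expansion(areas0[k], areas1[ci])
      ndiv <- division_count(pid, children)
      axis <- if (!is.null(tp0$axis)) tp0$axis[k, ] else c(0, 1)
      jj <- match(pid, jcells)
      gt <- NULL
      if (!is.na(jj)) {
        gt <- tryCatch(growth_tensor(jmap[[jj]]$P0, jmap[[jj]]$P1, dt, axis),
                       error = function(e) NULL)
      }
      out <- rbind(out, data.frame(
        interval = iv, t0 = lt$times[iv], t1 = lt$times[iv + 1L],
        cell = pid, area = areas0[k],
        area_expansion_pct = exp_pct, n_divisions = ndiv,
        k_par = if (is.null(gt)) NA_real_ else gt$k_par,
        k_per = if (is.null(gt)) NA_real_ else gt$k_per,
        anisotropy = if (is.null(gt)) NA_real_ else gt$anisotropy,
        distance = dd$distance[k], normalized = dd$normalized[k],
        bin = dd$bin[k]))
    }
  }
  out
}

#' Division events as a table
#'
#' Flattens the simulator's event log: one row per division with time,
#' kind (ordinary or apical), parent and daughter ids, wall endpoints, the
#' wall's angle to the parent's polarity axis, and its orientation class.
#'
#' @param x a tissue or a \code{phyllid_trajectory}.
#' @return data.frame (zero rows when no divisions occurred).
#' @export
events_table <- function(x) {
  tis <- if (inherits(x, "phyllid_trajectory")) x$final else x
  if (!length(tis$events))
    return(data.frame(time = numeric(0), kind = character(0),
                      parent = integer(0), child1 = integer(0),
                      child2 = integer(0), wall_x1 = numeric(0),
                      wall_y1 = numeric(0), wall_x2 = numeric(0),
                      wall_y2 = numeric(0), angle_to_polarity = numeric(0),
                      orientation = character(0)))
  do.call(rbind, lapply(tis$events, function(e) data.frame(
    time = e$time, kind = e$kind, parent = e$parent,
    child1 = e$daughters[1], child2 = e$daughters[2],
    wall_x1 = e$wall[1, 1], wall_y1 = e$wall[1, 2],
    wall_x2 = e$wall[2, 1], wall_y2 = e$wall[2, 2],
    angle_to_polarity = e$angle_to_polarity,
    orientation = if (e$angle_to_polarity < 45) "longitudinal"
                  else "mediolateral")))
}
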