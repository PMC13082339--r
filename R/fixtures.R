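# Synthetic inputs: the day-1 primordium template that seeds simulations
# (standing in for a flattened, segmented day-1 mesh) and time-lapse-like
# lineage fixtures with known ground-truth growth for validating the
# quantification formulas.

#' Template specification
#'
#' Describes the initial day-1 primordium: an attachment row at the base,
#' two merophyte rows above it (each split into cell files), and a single
#' apical wedge cell at the tip.  Dimensions are in micrometres, matching
#' the tens-of-micrometre cell sizes of a day-1 primordium.
#'
#' @param basal_width organ width at the base.
#' @param attach_height height of the attachment row.
#' @param n_attach number of attachment cells.
#' @param row_height height of each merophyte row.
#' @param cells_per_merophyte cell files per merophyte row.
#' @param n_merophytes merophyte rows present at day 1 (default 2).
#' @param apex_height height of the apical wedge.
#' @param taper fractional width reduction from base to apex.
#' @param jitter standard deviation of vertex jitter (um); 0 gives an
#'   exactly mirror-symmetric template.
#' @param seed integer seed; fully determines the output.
#' @return a list of class \code{"template_spec"}.
#' @export
template_spec <- function(basal_width = 40, attach_height = 10, n_attach = 3,
                          row_height = 8, cells_per_merophyte = 2,
                          n_merophytes = 2, apex_height = 14, taper = 0.3,
                          jitter = 0, seed = 1L) {
  structure(as.list(environment()), class = "template_spec")
}

#' Generate the day-1 primordium template
#'
#' Builds a conforming polygon tiling: attachment cells whose bottom
#' vertices carry the longitudinal Dirichlet constraint (with the lowest-id
#' base vertex fully fixed), merophyte rows labeled 1..n from the base up,
#' and one apical cell at the tip.  Deterministic per seed; jitter that
#' produces an invalid tiling is retried with halved amplitude.
#'
#' @param spec a \code{\link{template_spec}}.
#' @return a valid \code{tissue}.
#' @export
make_template <- function(spec = template_spec()) {
  jit <- spec$jitter
  for (attempt in 1:6) {
    tis <- try(build_template(spec, jit), silent = TRUE)
    if (!inherits(tis, "try-error") &&
        !inherits(try(validate_tissue(tis), silent = TRUE), "try-error"))
      return(tis)
    jit <- jit / 2
    message("template jitter produced an invalid tiling; retrying with sd = ",
            signif(jit, 3))
  }
  stop("could not generate a valid template")
}

build_template <- function(spec, jitter) {
  n_rows <- 1L + spec$n_merophytes            # attachment + merophyte rows
  heights <- c(spec$attach_height, rep(spec$row_height, spec$n_merophytes))
  levels_y <- cumsum(c(0, heights))
  apex_y <- levels_y[length(levels_y)] + spec$apex_height
  width_at <- function(y) spec$basal_width * (1 - spec$taper * y / apex_y)
  n_cells_row <- c(spec$n_attach, rep(spec$cells_per_merophyte,
                                      spec$n_merophytes))
  # fractions (0..1) of each row's cell boundaries
  fr <- lapply(n_cells_row, function(n) seq(0, 1, length.out = n + 1))
  # per level: union of fractions of the rows below and above
  lev_fr <- vector("list", n_rows + 1L)
  for (j in seq_len(n_rows + 1L)) {
    f <- c(if (j > 1) fr[[j - 1]], if (j <= n_rows) fr[[j]])
    lev_fr[[j]] <- sort(unique(round(f, 12)))
  }
  # vertex table
  pos <- NULL
  vid <- vector("list", n_rows + 1L)
  for (j in seq_len(n_rows + 1L)) {
    w <- width_at(levels_y[j])
    xs <- (lev_fr[[j]] - 0.5) * w
    ids <- nrow0(pos) + seq_along(xs)
    pos <- rbind(pos, cbind(xs, levels_y[j]))
    vid[[j]] <- ids
  }
  apex_id <- nrow(pos) + 1L
  pos <- rbind(pos, c(0, apex_y))
  rings <- list(); mero <- integer(); type <- character(); zone <- character()
  for (j in seq_len(n_rows)) {
    f_lo <- lev_fr[[j]]; f_hi <- lev_fr[[j + 1]]
    for (k in seq_len(n_cells_row[j])) {
      a <- fr[[j]][k]; b <- fr[[j]][k + 1]
      lo <- vid[[j]][f_lo >= a - 1e-9 & f_lo <= b + 1e-9]
      hi <- vid[[j + 1]][f_hi >= a - 1e-9 & f_hi <= b + 1e-9]
      rings[[length(rings) + 1L]] <- c(lo, rev(hi))
      if (j == 1L) {
        mero <- c(mero, NA_integer_); type <- c(type, "attachment")
        zone <- c(zone, "attachment")
      } else {
        mero <- c(mero, j - 1L); type <- c(type, "blade")
        zone <- c(zone, "proliferative")
      }
    }
  }
  # apical wedge: full top level + apex point
  rings[[length(rings) + 1L]] <- c(vid[[n_rows + 1L]], apex_id)
  mero <- c(mero, NA_integer_); type <- c(type, "apical")
  zone <- c(zone, "proliferative")
  colnames(pos) <- NULL
  if (jitter > 0) {
    set.seed(spec$seed)
    noise <- matrix(stats::rnorm(length(pos), sd = jitter), nrow(pos), 2)
    noise[pos[, 2] == 0, 2] <- 0          # keep the base flat
    noise[apex_id, 1] <- 0                # keep the apex on the midline
    outer_x <- abs(abs(pos[, 1]) - width_at(pos[, 2]) / 2) < 1e-9
    noise[outer_x, 1] <- noise[outer_x, 1] / 2
    pos <- pos + noise
  }
  is_base <- pos[, 2] == 0
  new_tissue(pos, is_base, rings, merophyte = mero, type = type, zone = zone,
             apical_id = length(rings), time = 1.0, phase = 1L)
}

nrow0 <- function(x) if (is.null(x)) 0L else nrow(x)

#' Lineage fixture specification
#'
#' Ground truth for a synthetic time-lapse: a grid of cells deformed at
#' each interval by a known growth field (parallel rate optionally a linear
#' gradient in the normalized distance from the base, perpendicular rate
#' uniform), with optional scheduled divisions and junction-position noise.
#'
#' @param nx,ny grid size (cells).
#' @param cell_size cell edge length (um).
#' @param times snapshot times (days).
#' @param k_par_base parallel (longitudinal) rate at the base, per day.
#' @param k_par_slope linear increase of the parallel rate per unit
#'   normalized distance from the base.
#' @param k_per uniform perpendicular rate, per day.
#' @param rotation rigid rotation (radians) applied after each growth map.
#' @param divide_cells integer cell indices scheduled to divide once, at
#'   the first interval.
#' @param noise_sd junction-position noise (um).
#' @param seed integer seed.
#' @return list of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(nx = 4, ny = 6, cell_size = 10,
                         times = c(0, 0.5, 1.0),
                         k_par_base = 0.2, k_par_slope = 0, k_per = 0.1,
                         rotation = 0, divide_cells = integer(0),
                         noise_sd = 0, seed = 1L) {
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic lineage table with known growth
#'
#' Applies the ground-truth growth maps defined by \code{spec} to a cell grid at each
#' interval.  The vertical map integrates the (possibly graded) parallel
#' rate exactly, so the stored per-cell effective rates are exact; junction
#' correspondences are exact before the optional noise is added.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return a \code{lineage_table} (see \code{\link{lineage_table}}) with a
#'   \code{ground_truth} data.frame attached (interval, cell id, exact
#'   k_par and k_per per day).
#' @export
make_lineage_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  s <- spec$cell_size
  polys <- list(); ids <- integer()
  id <- 0L
  for (j in seq_len(spec$ny)) for (i in seq_len(spec$nx)) {
    id <- id + 1L
    x0 <- (i - 1) * s; y0 <- (j - 1) * s
    polys[[id]] <- rbind(c(x0, y0), c(x0 + s, y0),
                         c(x0 + s, y0 + s), c(x0, y0 + s))
    ids[id] <- id
  }
  next_id <- id + 1L
  tp <- list(list(id = ids, poly = polys))
  links <- NULL
  junctions <- list()
  gt <- NULL
  for (iv in seq_len(length(spec$times) - 1L)) {
    dt <- spec$times[iv + 1L] - spec$times[iv]
    H <- max(vapply(polys, function(p) max(p[, 2]), 0))
    a <- spec$k_par_base; b <- spec$k_par_slope
    # y' = integral_0^y exp((a + b s/H) dt) ds  (exact)
    ymap <- function(y) {
      if (abs(b) < 1e-15) return(y * exp(a * dt))
      H / (b * dt) * (exp((a + b * y / H) * dt) - exp(a * dt)) + y * 0
    }
    fmap <- function(p) {
      q <- cbind(p[, 1] * exp(spec$k_per * dt), ymap(p[, 2]))
      if (spec$rotation != 0) q <- q %*% t(rot2(spec$rotation))
      q
    }
    new_polys <- list(); new_ids <- integer()
    jv <- list()
    for (k in seq_along(polys)) {
      p0 <- polys[[k]]
      p1 <- fmap(p0)
      # junction set: corners plus wall midpoints (segmented cell outlines
      # carry junctions with every neighbor, not just the four corners)
      mid <- (p0 + p0[c(2:nrow(p0), 1), ]) / 2
      p0j <- rbind(p0, mid)
      y1 <- min(p0[, 2]); y2 <- max(p0[, 2])
      lam <- (ymap(y2) - ymap(y1)) / (y2 - y1)
      gt <- rbind(gt, data.frame(interval = iv, cell = ids[k],
                                 k_par = log(lam) / dt,
                                 k_per = spec$k_per))
      j1 <- fmap(p0j)
      if (spec$noise_sd > 0)
        j1 <- j1 + matrix(stats::rnorm(length(j1), sd = spec$noise_sd),
                          nrow(j1), 2)
      jv[[length(jv) + 1L]] <- list(cell = ids[k], P0 = p0j, P1 = j1)
      if (iv == 1L && k %in% spec$divide_cells) {
        ym <- (min(p1[, 2]) + max(p1[, 2])) / 2
        xr <- range(p1[, 1])
        lower <- rbind(p1[p1[, 2] <= ym + 1e-9 & p1[, 2] < ym, , drop = FALSE],
                       c(xr[2], ym), c(xr[1], ym))
        upper <- rbind(c(xr[1], ym), c(xr[2], ym),
                       p1[p1[, 2] > ym, , drop = FALSE])
        for (dgt in list(lower, upper)) {
          new_ids <- c(new_ids, next_id)
          new_polys[[length(new_polys) + 1L]] <- dgt
          links <- rbind(links, data.frame(interval = iv, child = next_id,
                                           parent = ids[k]))
          next_id <- next_id + 1L
        }
      } else {
        new_ids <- c(new_ids, ids[k])
        new_polys[[length(new_polys) + 1L]] <- p1
        links <- rbind(links, data.frame(interval = iv, child = ids[k],
                                         parent = ids[k]))
      }
    }
    junctions[[iv]] <- jv
    polys <- new_polys; ids <- new_ids
    tp[[iv + 1L]] <- list(id = ids, poly = polys)
  }
  structure(list(times = spec$times, timepoints = tp, links = links,
                 junctions = junctions, ground_truth = gt),
            class = "lineage_table")
}
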