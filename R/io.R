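# Plain-text serialization, configuration and SVG rendering.
#
# Tissue format (line-oriented, one record per line, '.' decimal,
# %.17g numbers so doubles round-trip bit-exactly):
#   # phyllidsim tissue v1 units um time days
#   T <time> <phase> <apical_id> <apical_side> <next_cell_id>
#     <next_merophyte> <apical_next> <midrib_done>
#   V <id> <x> <y> <is_base 0|1> <constraint 0|1|2>
#   C <id> <merophyte> <type> <zone> <t_diff> <k_par> <k_per>
#     <area_threshold> <px> <py> <parent> : <v1> <v2> ...
#   L <child> <parent> <time>
# Missing values are written as NA.  The division event log is runtime
# metadata and is exported separately (events_table / write_trajectory).

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
fmt_int <- function(x) ifelse(is.na(x), "NA", sprintf("%d", x))

#' Write a tissue to its text format
#'
#' @param tissue a tissue.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_tissue <- function(tissue, path) {
  con <- file(path, "wb")  # binary mode: fixed "\n", bit-exact round trip
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("# phyllidsim tissue v1 units um time days")
  w("T ", fmt_num(tissue$time), " ", tissue$phase, " ",
    fmt_int(tissue$apical_id), " ", tissue$apical_side, " ",
    tissue$next_cell_id, " ", tissue$next_merophyte, " ",
    fmt_num(if (is.null(tissue$apical_next)) NA_real_ else tissue$apical_next),
    " ", as.integer(isTRUE(tissue$midrib_done)))
  for (v in seq_len(nrow(tissue$pos)))
    w("V ", v, " ", fmt_num(tissue$pos[v, 1]), " ", fmt_num(tissue$pos[v, 2]),
      " ", as.integer(tissue$is_base[v]), " ", tissue$constraint[v])
  for (i in seq_along(tissue$ring))
    w("C ", tissue$cell_id[i], " ", fmt_int(tissue$merophyte[i]), " ",
      tissue$type[i], " ", tissue$zone[i], " ", fmt_num(tissue$t_diff[i]),
      " ", fmt_num(tissue$k_par[i]), " ", fmt_num(tissue$k_per[i]), " ",
      fmt_num(tissue$area_threshold[i]), " ", fmt_num(tissue$polarity[i, 1]),
      " ", fmt_num(tissue$polarity[i, 2]), " ", fmt_int(tissue$parent[i]),
      " : ", paste(tissue$ring[[i]], collapse = " "))
  for (ln in tissue$lineage)
    for (r in seq_len(nrow(ln)))
      w("L ", ln$child[r], " ", ln$parent[r], " ", fmt_num(ln$time[r]))
  invisible(path)
}

num_or_na <- function(s) ifelse(s == "NA", NA_real_, as.numeric(s))
int_or_na <- function(s) ifelse(s == "NA", NA_integer_, as.integer(s))

#' Read a tissue from its text format
#'
#' Validates all structural invariants on read; malformed records raise an
#' error naming the offending line or entity.
#'
#' @param path file written by \code{\link{write_tissue}}.
#' @return a tissue.
#' @export
read_tissue <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) stop("line ", i, ": ", why, " [", lines[i], "]")
  pos <- NULL; is_base <- logical(); constraint <- integer()
  vids <- integer()
  cid <- integer(); mero <- integer(); type <- character()
  zone <- character(); t_diff <- numeric(); k_par <- numeric()
  k_per <- numeric(); thr <- numeric(); px <- numeric(); py <- numeric()
  parent <- integer(); rings <- list()
  header <- NULL; lineage <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, " +")[[1]]
    tag <- f[1]
    if (tag == "T") {
      if (length(f) != 9) bad(i, "T record needs 8 fields")
      header <- f[-1]
    } else if (tag == "V") {
      if (length(f) != 6) bad(i, "V record needs 5 fields")
      vids <- c(vids, as.integer(f[2]))
      pos <- rbind(pos, c(as.numeric(f[3]), as.numeric(f[4])))
      is_base <- c(is_base, f[5] == "1")
      constraint <- c(constraint, as.integer(f[6]))
    } else if (tag == "C") {
      sep <- match(":", f)
      if (is.na(sep) || sep != 13) bad(i, "C record malformed")
      cid <- c(cid, as.integer(f[2]))
      mero <- c(mero, int_or_na(f[3]))
      type <- c(type, f[4]); zone <- c(zone, f[5])
      t_diff <- c(t_diff, num_or_na(f[6]))
      k_par <- c(k_par, as.numeric(f[7])); k_per <- c(k_per, as.numeric(f[8]))
      thr <- c(thr, num_or_na(f[9]))
      px <- c(px, as.numeric(f[10])); py <- c(py, as.numeric(f[11]))
      parent <- c(parent, int_or_na(f[12]))
      ring <- suppressWarnings(as.integer(f[(sep + 1):length(f)]))
      if (anyNA(ring)) bad(i, paste("cell", f[2], "has a corrupt vertex id"))
      rings[[length(rings) + 1L]] <- ring
    } else if (tag == "L") {
      if (length(f) != 4) bad(i, "L record needs 3 fields")
      lineage <- rbind(lineage,
                       data.frame(child = as.integer(f[2]),
                                  parent = as.integer(f[3]),
                                  time = as.numeric(f[4])))
    } else bad(i, paste("unknown record tag", tag))
  }
  if (is.null(header)) stop("missing T header record")
  if (!identical(vids, seq_along(vids)))
    stop("vertex ids must be consecutive from 1")
  n_v <- length(vids)
  for (k in seq_along(rings))
    if (any(rings[[k]] < 1 | rings[[k]] > n_v))
      stop("cell ", cid[k], " references an unknown vertex id")
  tis <- structure(list(
    pos = unname(pos), is_base = is_base, constraint = constraint,
    ring = rings, cell_id = cid, merophyte = mero, type = type, zone = zone,
    polarity = cbind(px, py, deparse.level = 0),
    k_par = k_par, k_per = k_per, area_threshold = thr, t_diff = t_diff,
    parent = parent,
    apical_id = int_or_na(header[3]),
    apical_side = as.integer(header[4]),
    next_cell_id = as.integer(header[5]),
    next_merophyte = as.integer(header[6]),
    time = as.numeric(header[1]), phase = as.integer(header[2]),
    lineage = if (is.null(lineage)) list() else list(lineage),
    events = list(), fem = NULL), class = "tissue")
  an <- num_or_na(header[7])
  if (!is.na(an)) tis$apical_next <- an
  if (header[8] == "1") tis$midrib_done <- TRUE
  validate_tissue(tis)
  tis
}

#' Save / load scenario parameters as YAML
#'
#' @param params a \code{scenario_params} list.
#' @param path file path.
#' @return \code{load_params} returns the parameter list.
#' @export
save_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  p <- yaml::read_yaml(path)
  if (is.null(p$solver$tol)) p$solver$tol <- NULL
  class(p) <- "scenario_params"
  p
}

render_fields <- c("merophyte", "zone", "tissue_type", "k_par", "k_per",
                   "areal_growth", "anisotropy", "distance")

#' Render a tissue snapshot to SVG
#'
#' Writes a deterministic standalone SVG: one polygon per cell, filled by
#' the requested field, with a simple legend.  Continuous fields use a
#' viridis ramp; categorical fields use a fixed qualitative palette.
#'
#' @param tissue a tissue.
#' @param path output .svg path.
#' @param color_by one of \code{merophyte}, \code{zone},
#'   \code{tissue_type}, \code{k_par}, \code{k_per}, \code{areal_growth},
#'   \code{anisotropy}, \code{distance}.
#' @return invisibly, the path.
#' @export
render_snapshot <- function(tissue, path, color_by = "merophyte") {
  if (!color_by %in% render_fields)
    stop("unknown color field '", color_by, "'; options: ",
         paste(render_fields, collapse = ", "))
  n <- n_cells(tissue)
  legend <- NULL
  if (color_by %in% c("merophyte", "zone", "tissue_type")) {
    val <- switch(color_by,
                  merophyte = tissue$merophyte,
                  zone = tissue$zone,
                  tissue_type = tissue$type)
    lev <- sort(unique(val[!is.na(val)]))
    pal <- grDevices::hcl.colors(max(3, length(lev)), "Dark 3")[seq_along(lev)]
    fill <- ifelse(is.na(val), "#bbbbbb", pal[match(val, lev)])
    legend <- data.frame(label = as.character(lev), color = pal)
  } else {
    val <- switch(color_by,
                  k_par = tissue$k_par,
                  k_per = tissue$k_per,
                  areal_growth = tissue$k_par + tissue$k_per,
                  anisotropy = {
                    s <- tissue$k_par + tissue$k_per
                    ifelse(s > 0, abs(tissue$k_par - tissue$k_per) / s, 0)
                  },
                  distance = distance_profiles(tissue)$distance)
    rng <- range(val[is.finite(val)])
    z <- if (diff(rng) > 0) (val - rng[1]) / diff(rng) else rep(0.5, n)
    ramp <- grDevices::colorRamp(grDevices::hcl.colors(64, "Viridis"))
    rgbm <- ramp(pmin(1, pmax(0, z)))
    fill <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                           maxColorValue = 255)
    legend <- data.frame(
      label = sprintf("%.3g", c(rng[1], mean(rng), rng[2])),
      color = grDevices::rgb(ramp(c(0, 0.5, 1)), maxColorValue = 255))
  }
  used <- sort(unique(unlist(tissue$ring)))
  xr <- range(tissue$pos[used, 1]); yr <- range(tissue$pos[used, 2])
  pad <- 0.05 * max(diff(xr), diff(yr), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'viewBox="%.3f %.3f %.3f %.3f">'),
            xr[1] - pad, -yr[2] - pad,
            diff(xr) + 2 * pad + 40, diff(yr) + 2 * pad))
  for (i in seq_len(n)) {
    p <- tissue$pos[tissue$ring[[i]], , drop = FALSE]
    pts <- paste(sprintf("%.3f,%.3f", p[, 1], -p[, 2]), collapse = " ")
    w(sprintf('<polygon points="%s" fill="%s" stroke="black" stroke-width="0.3"/>',
              pts, fill[i]))
  }
  x0 <- xr[2] + pad + 5
  for (k in seq_len(nrow(legend))) {
    y0 <- -yr[2] + (k - 1) * 8
    w(sprintf('<rect x="%.3f" y="%.3f" width="6" height="6" fill="%s"/>',
              x0, y0, legend$color[k]))
    w(sprintf('<text x="%.3f" y="%.3f" font-size="5">%s</text>',
              x0 + 8, y0 + 5, legend$label[k]))
  }
  w("</svg>")
  invisible(path)
}

#' Export a trajectory to a results directory
#'
#' Writes tissue snapshots (text format), per-snapshot per-cell table
#' \code{cells.csv}, division log \code{events.csv}, lineage links
#' \code{lineage.csv}, the resolved parameters \code{params.yaml}, and an
#' SVG render of the final snapshot.
#'
#' @param traj a \code{phyllid_trajectory}.
#' @param dir output directory (created if needed).
#' @param render color field for the final-snapshot SVG.
#' @return invisibly, \code{dir}.
#' @export
write_trajectory <- function(traj, dir, render = "merophyte") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- NULL
  for (k in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[k]]
    write_tissue(s, file.path(dir, sprintf("tissue_%03d.txt", k)))
    cen <- cell_centroids(s)
    cells <- rbind(cells, data.frame(
      time = s$time, cell_id = s$cell_id, merophyte = s$merophyte,
      tissue_type = s$type, zone = s$zone, area = cell_areas(s),
      centroid_x = cen[, 1], centroid_y = cen[, 2],
      k_par = s$k_par, k_per = s$k_per))
  }
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(events_table(traj), file.path(dir, "events.csv"),
                   row.names = FALSE)
  lin <- if (length(traj$final$lineage))
    do.call(rbind, traj$final$lineage)
  else data.frame(child = integer(0), parent = integer(0), time = numeric(0))
  utils::write.csv(lin, file.path(dir, "lineage.csv"), row.names = FALSE)
  save_params(traj$params, file.path(dir, "params.yaml"))
  render_snapshot(traj$final, file.path(dir, "final.svg"), render)
  invisible(dir)
}
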