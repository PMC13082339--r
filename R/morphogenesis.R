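# Developmental rules and the simulation loop.
#
# Development runs through three phases (times in days after initiation):
# phase 1, initiation (until t_phase12): slow, near-isotropic growth;
# phase 2, expansion (until t_phase23): fast anisotropic growth in the
# blade, very anisotropic in the midrib, divisions confined to a
# proliferative zone within a cell-count distance of the base;
# phase 3, maturation: all divisions cease and cells progressively stop
# growing after a transient elongation burst.
#
# Scenario presets re-parameterize this machinery: the pin-mutant scenario
# shrinks the proliferative zone, advances the phase-2/3 transition and
# raises the elongation rate; auxin treatment advances the transition
# further and raises elongation more (on the mutant, divisions are
# eliminated after phase 1 and anisotropy is increased further); the
# juvenile basal phyllid differs from wild type only by an earlier
# cessation of divisions.

#' Scenario parameter sets
#'
#' Returns the calibrated parameter list for one of the five scenarios.
#' Values are the package's calibrated defaults (rates per day, lengths in
#' micrometres, times in days after initiation).
#'
#' @param scenario one of \code{"wt_upper"}, \code{"pina_pinb"},
#'   \code{"auxin_wt"}, \code{"auxin_pina_pinb"}, \code{"basal"}.
#' @return a named list of parameters (class \code{"scenario_params"}).
#' @export
scenario_params <- function(scenario = c("wt_upper", "pina_pinb", "auxin_wt",
                                         "auxin_pina_pinb", "basal")) {
  scenario <- match.arg(scenario)
  p <- list(
    scenario = scenario,
    t_start = 1.0, t_end = 5.5, dt_days = 0.05, snapshot_every = 0.5,
    material = list(E_MPa = 100, nu = 0.3),
    solver = list(tol = NULL, max_iter = 5000L),
    t_phase12 = 1.5, t_phase23 = 4.0,
    apical = list(t_first = 1.05, period = 0.4, angle_deg = 60,
                  k_par = 0.55, k_per = 0.30),
    d_prolif_phase1 = Inf, d_prolif_phase2 = 5,
    area_threshold = 65,
    blade = list(k1 = 0.15,            # phase 1, isotropic
                 k2_par = 0.72, k2_per = 0.45,
                 # basal rate ramp within the zones: rates rise from
                 # ramp_floor up to cell row ramp_d0 to full at row
                 # ramp_d_full (cell-count distance from the base),
                 # mirroring the slow-base growth gradient
                 ramp_d0 = 2, ramp_d_full = 3, ramp_floor = 0.06),
    attachment = list(k = 0.02),
    midrib = list(t_onset = 2.0, max_dist_cells = 3, max_offset_um = 6,
                  k_per_factor = 0.15),
    differentiation = list(boost = 1.7, tau_e = 0.5, tau_d = 0.6)
  )
  if (scenario == "pina_pinb") {
    p$d_prolif_phase2 <- 4
    p$t_phase23 <- 3.75
    p$differentiation$boost <- 2.1
    p$blade$k2_par <- 0.80
    p$blade$k2_per <- 0.42
  } else if (scenario == "auxin_wt") {
    p$t_phase23 <- 2.6
    p$differentiation$boost <- 2.2
    p$differentiation$tau_d <- 0.8
    p$blade$k2_par <- 0.72
    p$blade$k2_per <- 0.22
  } else if (scenario == "auxin_pina_pinb") {
    p$d_prolif_phase2 <- 0          # divisions eliminated after phase 1
    p$t_phase23 <- 2.2
    p$differentiation$boost <- 2.6
    p$differentiation$tau_d <- 0.9
    p$blade$k2_par <- 0.80
    p$blade$k2_per <- 0.14
  } else if (scenario == "basal") {
    p$t_phase23 <- 3.2              # division cessation ~0.8 d earlier
  }
  class(p) <- "scenario_params"
  p
}

phase_of <- function(t, params) {
  if (t < params$t_phase12) 1L else if (t < params$t_phase23) 2L else 3L
}

d_prolif_of <- function(params, phase) {
  if (phase == 1L) params$d_prolif_phase1
  else if (phase == 2L) params$d_prolif_phase2
  else -Inf
}

#' Update cell zones from positional information
#'
#' Attachment cells keep the attachment zone.  Other cells whose cell-count
#' distance from the base is within the proliferative extent for the
#' current phase are proliferative; cells beyond it enter the
#' differentiation zone, recording the entry time.  Differentiation is
#' absorbing, and in phase 3 every non-attachment cell differentiates.
#'
#' @param tissue a tissue (with \code{$phase} current).
#' @param params scenario parameters.
#' @param d_cells cell-count distance field from the attachment cells
#'   (computed when missing).
#' @return the updated tissue.
#' @export
update_zones <- function(tissue, params, d_cells = NULL) {
  if (is.null(d_cells)) {
    src <- tissue$cell_id[tissue$type == "attachment"]
    d_cells <- distance_field(tissue, src, "cell-count")
  }
  dmax <- d_prolif_of(params, tissue$phase)
  apical_active <- !is.na(tissue$apical_id) && tissue$phase < 3L &&
    !(is.numeric(tissue$apical_next) && is.infinite(tissue$apical_next))
  for (i in seq_along(tissue$ring)) {
    if (tissue$zone[i] == "attachment") next
    if (tissue$zone[i] == "differentiation") next   # absorbing
    if (tissue$type[i] == "apical" && apical_active) {
      tissue$zone[i] <- "proliferative"   # the tip initial keeps cycling
      next
    }
    if (d_cells[i] > dmax) {
      tissue$zone[i] <- "differentiation"
      tissue$t_diff[i] <- tissue$time
    } else {
      tissue$zone[i] <- "proliferative"
    }
  }
  tissue
}

#' Specify the midrib
#'
#' At onset time, blade cells whose centroid lies within a mediolateral
#' offset of the organ midline and within a cell-count distance of the base
#' acquire midrib identity (heritable; mediolateral growth strongly
#' reduced thereafter).
#'
#' @param tissue a tissue.
#' @param params scenario parameters.
#' @param d_cells cell-count distance field from the attachment cells.
#' @return the updated tissue.
#' @export
assign_midrib <- function(tissue, params, d_cells = NULL) {
  if (is.null(d_cells)) {
    src <- tissue$cell_id[tissue$type == "attachment"]
    d_cells <- distance_field(tissue, src, "cell-count")
  }
  cen <- cell_centroids(tissue)
  midline <- if (!is.na(tissue$apical_id))
    cen[cell_index(tissue, tissue$apical_id), 1] else 0
  sel <- tissue$type == "blade" &
    abs(cen[, 1] - midline) <= params$midrib$max_offset_um &
    d_cells <= params$midrib$max_dist_cells
  if (!any(sel))
    warning("midrib specification selected no cells")
  tissue$type[sel] <- "midrib"
  tissue
}

#' Assign per-cell growth rates from type, zone and position
#'
#' Attachment cells grow very slowly and isotropically.  Proliferative
#' cells use the phase-1 isotropic rate or the phase-2 anisotropic blade
#' rates, scaled by a basal ramp (rates rise with cell-count distance from
#' the base, from \code{ramp_floor} up to row \code{ramp_d0} to full at row
#' \code{ramp_d_full}); midrib cells have
#' their mediolateral rate multiplied by a strong reduction factor.
#' Differentiated cells elongate transiently (parallel rate boosted for
#' \code{tau_e} days after differentiation onset) and then both rates decay
#' exponentially with timescale \code{tau_d}.  The apical cell grows at its
#' own rates while divisions continue.
#'
#' @param tissue a tissue.
#' @param params scenario parameters.
#' @param d_cells cell-count distance field from the attachment cells
#'   (computed when missing).
#' @return the updated tissue.
#' @export
assign_growth_rates <- function(tissue, params, d_cells = NULL) {
  if (is.null(d_cells)) {
    src <- tissue$cell_id[tissue$type == "attachment"]
    d_cells <- distance_field(tissue, src, "cell-count")
  }
  bl <- params$blade
  ramp <- bl$ramp_floor + (1 - bl$ramp_floor) *
    pmin(pmax((d_cells - bl$ramp_d0) / (bl$ramp_d_full - bl$ramp_d0), 0), 1)
  t <- tissue$time
  for (i in seq_along(tissue$ring)) {
    ty <- tissue$type[i]
    zo <- tissue$zone[i]
    if (ty == "attachment") {
      tissue$k_par[i] <- params$attachment$k
      tissue$k_per[i] <- params$attachment$k
      next
    }
    if (ty == "apical" && zo != "differentiation") {
      tissue$k_par[i] <- params$apical$k_par
      tissue$k_per[i] <- params$apical$k_per
      next
    }
    # positional base rates
    if (tissue$phase == 1L) {
      kp <- bl$k1; kq <- bl$k1
    } else {
      kp <- bl$k2_par * ramp[i]
      kq <- bl$k2_per * ramp[i]
    }
    if (ty == "midrib") kq <- kq * params$midrib$k_per_factor
    if (zo == "differentiation") {
      dtd <- t - tissue$t_diff[i]
      kp <- kp * params$differentiation$boost
      if (dtd > params$differentiation$tau_e) {
        f <- exp(-(dtd - params$differentiation$tau_e) /
                   params$differentiation$tau_d)
        kp <- kp * f
        kq <- kq * f
      }
    }
    tissue$k_par[i] <- kp
    tissue$k_per[i] <- kq
  }
  tissue
}

#' Advance the tissue by one growth step
#'
#' Sub-steps, in order: update phase from the clock; recompute distance
#' fields and polarity; update zones; specify the midrib at its onset;
#' assign growth rates; build elements and grow their rest configurations;
#' solve mechanical equilibrium; release residual stresses; perform a
#' scheduled apical division; divide every eligible cell (proliferative,
#' over the area threshold) in ascending cell-id order, at most once per
#' cell per step.
#'
#' @param tissue a tissue.
#' @param params scenario parameters.
#' @param dt step size in days (default \code{params$dt_days}).
#' @return the tissue at time + dt.
#' @export
step_tissue <- function(tissue, params, dt = params$dt_days) {
  t <- tissue$time
  tissue$phase <- phase_of(t, params)
  adj <- build_adjacency(tissue)
  src <- tissue$cell_id[tissue$type == "attachment"]
  d_cells <- distance_field(tissue, src, "cell-count", adj = adj)
  # polarity follows the apical distance field while cells are growing
  # toward the tip; a cell that differentiates stops re-reading the
  # apical field and elongates parallel to the main organ axis from then
  # on, which keeps the late elongation phase straight (the organ axis is
  # anchored by the base constraints)
  pol_apical <- unclass(polarity_field(tissue, adj = adj))
  was_diff <- tissue$zone == "differentiation"
  tissue <- update_zones(tissue, params, d_cells)
  is_diff <- tissue$zone == "differentiation"
  new_diff <- is_diff & !was_diff
  grow_pol <- !is_diff
  tissue$polarity[grow_pol, ] <- pol_apical[grow_pol, ]
  tissue$polarity[new_diff, 1] <- 0
  tissue$polarity[new_diff, 2] <- 1
  if (!isTRUE(tissue$midrib_done) && t >= params$midrib$t_onset - 1e-9) {
    tissue <- assign_midrib(tissue, params, d_cells)
    tissue$midrib_done <- TRUE
  }
  tissue <- assign_growth_rates(tissue, params, d_cells)
  if (dt > 0) {
    tissue <- fem_build(tissue, params$material$E_MPa, params$material$nu)
    tissue <- apply_growth(tissue, dt)
    tissue <- solve_equilibrium(tissue, tol = params$solver$tol,
                                max_iter = params$solver$max_iter)
    tissue <- release_residual_stress(tissue)
  }
  tissue$time <- t + dt
  # apical division schedule
  if (is.null(tissue$apical_next)) tissue$apical_next <- params$apical$t_first
  while (!is.na(tissue$apical_id) &&
         tissue$apical_next <= tissue$time + 1e-9) {
    if (tissue$apical_next >= params$t_phase23 - 1e-9) {
      tissue$apical_next <- Inf        # divisions ceased for good
      break
    }
    tissue <- apical_divide(tissue, params$apical$angle_deg)
    tissue$apical_next <- tissue$apical_next + params$apical$period
  }
  # ordinary divisions: snapshot of eligible cells, ascending id
  if (dt > 0) {
    areas <- cell_areas(tissue)
    elig <- tissue$zone == "proliferative" &
      tissue$type != "attachment" &
      tissue$cell_id != ifelse(is.na(tissue$apical_id), -1L, tissue$apical_id) &
      areas >= tissue$area_threshold
    ids <- sort(tissue$cell_id[elig])
    for (id in ids) tissue <- divide_cell(tissue, id)
  }
  tissue
}

#' Run a phyllid development scenario
#'
#' Simulates a scenario from a day-1 template to \code{t_end}, recording
#' snapshots at a fixed cadence (default every 0.5 days, matching the
#' imaging cadence the quantification pipeline expects).
#'
#' @param scenario scenario name (see \code{\link{scenario_params}});
#'   ignored when \code{params} is supplied.
#' @param params optional full parameter list.
#' @param template a tissue to start from; default
#'   \code{make_template(template_spec())}.
#' @param t_end end time (days); default from params.
#' @param quiet suppress progress output.
#' @return an object of class \code{"phyllid_trajectory"}: list with
#'   \code{snapshots} (tissues), \code{times}, \code{final} (last tissue,
#'   holding the full event and lineage logs) and \code{params}.
#' @export
simulate_phyllid <- function(scenario = "wt_upper", params = NULL,
                             template = NULL, t_end = NULL, quiet = TRUE) {
  if (is.null(params)) params <- scenario_params(scenario)
  if (is.null(t_end)) t_end <- params$t_end
  tissue <- if (is.null(template)) make_template(template_spec()) else template
  tissue$time <- params$t_start
  tissue$area_threshold <- rep(params$area_threshold, n_cells(tissue))
  n_steps <- round((t_end - params$t_start) / params$dt_days)
  snap_every <- max(1L, round(params$snapshot_every / params$dt_days))
  strip_fem <- function(s) { s$fem <- NULL; s }
  snapshots <- list(strip_fem(tissue))
  times <- tissue$time
  for (k in seq_len(n_steps)) {
    tissue <- step_tissue(tissue, params)
    if (k %% snap_every == 0 || k == n_steps) {
      snapshots[[length(snapshots) + 1L]] <- strip_fem(tissue)
      times <- c(times, tissue$time)
      if (!quiet)
        message(sprintf("t = %.2f d: %d cells", tissue$time, n_cells(tissue)))
    }
  }
  structure(list(snapshots = snapshots, times = times, final = tissue,
                 params = params),
            class = "phyllid_trajectory")
}

#' @export
print.phyllid_trajectory <- function(x, ...) {
  cat(sprintf(
    "<phyllid trajectory> scenario %s: %d snapshots, t = %.2f..%.2f d, %d final cells\n",
    x$params$scenario, length(x$snapshots), x$times[1],
    x$times[length(x$times)], n_cells(x$final)))
  invisible(x)
}

#' Count merophytes present in a tissue
#'
#' Distinct clonal-sector identities among the cells (the apical cell and
#' the attachment zone carry none).
#'
#' @param tissue a tissue.
#' @return integer count.
#' @export
count_merophytes <- function(tissue) {
  length(unique(tissue$merophyte[!is.na(tissue$merophyte)]))
}
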