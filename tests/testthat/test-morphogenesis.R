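test_that("zonation follows the cell-count threshold rule", {
  tis <- column_tissue(7)          # attachment + 6 blade cells at d = 1..6
  tis$apical_id <- 7L
  p <- stub_params(d_prolif_phase2 = 4)
  tis$phase <- 2L
  tis$time <- 3
  tis <- update_zones(tis, p)
  d <- distance_field(tis, 1, "cell-count")
  expect_equal(tis$zone[1], "attachment")
  expect_equal(tis$zone[d >= 1 & d <= 4], rep("proliferative", 4))
  expect_equal(tis$zone[d %in% c(5, 6)], rep("differentiation", 2))
  expect_true(all(!is.na(tis$t_diff[d %in% c(5, 6)])))
})

test_that("phase 3 ends all proliferation and differentiation is absorbing", {
  tis <- column_tissue(7)
  tis$phase <- 3L
  tis$time <- 4.2
  p <- stub_params()
  tis <- update_zones(tis, p)
  expect_true(all(tis$zone[tis$type != "attachment"] == "differentiation"))
  # reverting the phase must not revive any cell
  tis$phase <- 2L
  tis2 <- update_zones(tis, p)
  expect_identical(tis2$zone, tis$zone)
})

test_that("growth-rate assignment reflects type, zone, phase and position", {
  p <- stub_params()
  tis <- column_tissue(7)
  tis$apical_id <- 7L
  # phase 1: blade cells isotropic and slow
  tis$phase <- 1L; tis$time <- 1.2
  t1 <- assign_growth_rates(tis, p)
  blade <- which(t1$type == "blade")
  expect_equal(t1$k_par[blade], rep(p$blade$k1, length(blade)))
  expect_equal(t1$k_per[blade], rep(p$blade$k1, length(blade)))
  expect_equal(t1$k_par[1], p$attachment$k)
  # phase 2: anisotropic, ramped from the base
  tis$phase <- 2L; tis$time <- 2.5
  tis$zone[tis$type == "blade"] <- "proliferative"
  t2 <- assign_growth_rates(tis, p)
  d <- distance_field(tis, 1, "cell-count")
  full <- which(d >= p$blade$ramp_d_full & tis$type == "blade" &
                  tis$cell_id != tis$apical_id)
  expect_equal(t2$k_par[full], rep(p$blade$k2_par, length(full)))
  low <- which(d <= p$blade$ramp_d0 & tis$type == "blade")
  expect_equal(t2$k_par[low],
               rep(p$blade$k2_par * p$blade$ramp_floor, length(low)))
  # midrib: mediolateral rate strongly reduced
  tis$type[3] <- "midrib"
  t3 <- assign_growth_rates(tis, p)
  expect_equal(t3$k_per[3], t2$k_per[3] * p$midrib$k_per_factor)
  # differentiation: transient parallel boost, then exponential decay
  tis$type[3] <- "blade"
  tis$zone[5] <- "differentiation"
  tis$t_diff[5] <- 2.0
  tis$time <- 2.3    # within tau_e
  t4 <- assign_growth_rates(tis, p)
  expect_equal(t4$k_par[5], t2$k_par[5] * p$differentiation$boost)
  expect_equal(t4$k_per[5], t2$k_per[5])
  tis$time <- 2.0 + p$differentiation$tau_e + 3 * p$differentiation$tau_d
  t5 <- assign_growth_rates(tis, p)
  expect_equal(t5$k_par[5], t4$k_par[5] * exp(-3), tolerance = 1e-9)
  expect_lt(t5$k_par[5], exp(-3) * t4$k_par[5] * (1 + 1e-9))
})

test_that("midrib selection is mirror-symmetric and heritable", {
  tis <- make_template(template_spec(cells_per_merophyte = 3))
  p <- stub_params()
  tis <- assign_midrib(tis, p)
  sel <- which(tis$type == "midrib")
  expect_gt(length(sel), 0)
  cen <- cell_centroids(tis)
  expect_equal(sort(cen[sel, 1]), sort(-cen[sel, 1]), tolerance = 1e-9)
  # daughters of a midrib cell are midrib
  tis$polarity <- unclass(polarity_field(tis))
  id <- tis$cell_id[sel[1]]
  tis2 <- divide_cell(tis, id)
  e <- tis2$events[[1]]
  for (d in e$daughters)
    expect_equal(tis2$type[match(d, tis2$cell_id)], "midrib")
})

test_that("a zero-dt step changes nothing but bookkeeping", {
  tis <- make_template(template_spec())
  p <- stub_params()
  t2 <- step_tissue(tis, p, dt = 0)
  expect_identical(t2$pos, tis$pos)
  expect_identical(t2$ring, tis$ring)
  expect_equal(t2$time, tis$time)
})

test_that("a step with all rates zero leaves the geometry fixed", {
  tis <- make_template(template_spec())
  p <- stub_params(area_threshold = Inf)
  p$blade$k1 <- 0; p$blade$k2_par <- 0; p$blade$k2_per <- 0
  p$attachment$k <- 0
  p$apical$k_par <- 0; p$apical$k_per <- 0
  p$apical$t_first <- 99          # no apical divisions either
  t2 <- step_tissue(tis, p)
  expect_equal(t2$pos, tis$pos, tolerance = 1e-12)
  expect_equal(t2$time, tis$time + p$dt_days)
})

test_that("two half-steps approximate one full step without divisions", {
  tis <- make_template(template_spec())
  p <- stub_params(area_threshold = Inf)
  p$apical$t_first <- 99
  a <- step_tissue(tis, p, dt = 0.1)
  b <- step_tissue(step_tissue(tis, p, dt = 0.05), p, dt = 0.05)
  expect_equal(sort(cell_areas(a)), sort(cell_areas(b)), tolerance = 0.01)
})

test_that("short runs are deterministic and bookkeeping is exact", {
  t1 <- simulate_phyllid("wt_upper", t_end = 2.0)
  t2 <- simulate_phyllid("wt_upper", t_end = 2.0)
  expect_identical(t1$final$pos, t2$final$pos)
  expect_identical(t1$final$cell_id, t2$final$cell_id)
  expect_identical(events_table(t1), events_table(t2))
  # cell count = template count + logged divisions
  n0 <- n_cells(t1$snapshots[[1]])
  expect_equal(n_cells(t1$final), n0 + length(t1$final$events))
})

test_that("no cell ever reverts from differentiation in a run", {
  traj <- simulate_phyllid("wt_upper", t_end = 3.0)
  seen_diff <- character(0)
  for (s in traj$snapshots) {
    now_diff <- as.character(s$cell_id[s$zone == "differentiation"])
    # a previously differentiated cell must still be differentiated or
    # have been removed (cells are only removed by division, which
    # differentiated cells never undergo)
    alive <- intersect(seen_diff, as.character(s$cell_id))
    expect_true(all(alive %in% now_diff))
    seen_diff <- union(seen_diff, now_diff)
  }
})

test_that("merophyte identity is heritable across every lineage link", {
  traj <- simulate_phyllid("wt_upper", t_end = 3.0)
  lt <- lineage_table(traj)
  for (iv in seq_len(length(traj$snapshots) - 1)) {
    s0 <- traj$snapshots[[iv]]; s1 <- traj$snapshots[[iv + 1]]
    lk <- lt$links[lt$links$interval == iv, ]
    for (r in seq_len(nrow(lk))) {
      m_child <- s1$merophyte[match(lk$child[r], s1$cell_id)]
      m_parent <- s0$merophyte[match(lk$parent[r], s0$cell_id)]
      ty_parent <- s0$type[match(lk$parent[r], s0$cell_id)]
      if (ty_parent == "apical") next   # apical divisions found new sectors
      expect_identical(m_child, m_parent)
      if (ty_parent == "midrib")
        expect_equal(s1$type[match(lk$child[r], s1$cell_id)], "midrib")
    }
  }
})
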