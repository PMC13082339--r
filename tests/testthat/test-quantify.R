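test_that("area expansion is the relative increase in percent", {
  expect_equal(area_expansion(100, c(70, 80)), 50)
  expect_equal(area_expansion(100, c(50, 50)), 0)
  expect_equal(area_expansion(200, 100), -50)
  expect_error(area_expansion(100, numeric(0)), "empty")
  expect_error(area_expansion(0, 10), "positive")
})

test_that("division count is children minus one", {
  expect_equal(division_count(1, 7), 0)
  expect_equal(division_count(1, c(2, 3, 4)), 2)
  expect_error(division_count(1, integer(0)))
})

test_that("wall orientation uses the 45-degree convention", {
  axis <- c(0, 1)
  expect_equal(classify_wall_orientation(c(0, 2), axis), "longitudinal")
  expect_equal(classify_wall_orientation(c(1, 0), axis), "mediolateral")
  w45 <- c(sin(pi / 4), cos(pi / 4))
  expect_equal(classify_wall_orientation(w45, axis), "mediolateral")
  w44 <- c(sin(44 * pi / 180), cos(44 * pi / 180))
  expect_equal(classify_wall_orientation(w44, axis), "longitudinal")
  expect_error(classify_wall_orientation(c(0, 0), axis), "zero-length")
})

test_that("distance profiles normalize and bin as specified", {
  tis <- column_tissue(10, h = 10)   # centroids 5, 15, ..., 95
  dp <- distance_profiles(tis, source = 1)
  expect_equal(dp$distance, seq(0, 90, by = 10))
  expect_equal(dp$normalized, seq(0, 90, by = 10) / 90)
  expect_equal(dp$bin[1], 1)
  expect_equal(dp$bin[10], 10)
  expect_equal(dp$bin, pmax(1, ceiling(10 * dp$normalized)))
})

test_that("growth tensor recovers constructed maps exactly", {
  P0 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.3, 0.6))
  gt0 <- growth_tensor(P0, P0, dt = 1)
  expect_equal(gt0$k_max, 0, tolerance = 1e-12)
  expect_equal(gt0$k_min, 0, tolerance = 1e-12)
  expect_equal(gt0$anisotropy, 0, tolerance = 1e-12)
  # pure x scaling by e^0.2 over 1 day
  P1 <- P0 %*% diag(c(exp(0.2), 1))
  gt1 <- growth_tensor(P0, P1, dt = 1, axis = c(1, 0))
  expect_equal(gt1$k_par, 0.2, tolerance = 1e-12)
  expect_equal(gt1$k_per, 0, tolerance = 1e-12)
  # random affines composed with rigid rotations: parameter recovery
  set.seed(5)
  for (k in 1:20) {
    l1 <- exp(runif(1, 0, 0.5)); l2 <- exp(runif(1, -0.2, 0.4))
    if (l2 > l1) { tmp <- l1; l1 <- l2; l2 <- tmp }
    V <- phyllidsim:::rot2(runif(1, 0, pi))
    Fm <- phyllidsim:::rot2(runif(1, 0, 2 * pi)) %*% V %*% diag(c(l1, l2)) %*% t(V)
    P0 <- matrix(runif(12, 0, 10), 6, 2)
    P1 <- P0 %*% t(Fm) + matrix(runif(2), 6, 2, byrow = TRUE)
    gt <- growth_tensor(P0, P1, dt = 0.5)
    expect_equal(gt$k_max, log(l1) / 0.5, tolerance = 1e-9)
    expect_equal(gt$k_min, log(l2) / 0.5, tolerance = 1e-9)
    expect_equal(gt$anisotropy, (l1 - l2) / (l1 + l2), tolerance = 1e-9)
  }
  expect_error(growth_tensor(rbind(c(0, 0), c(1, 1), c(2, 2)),
                             rbind(c(0, 0), c(1, 1), c(2, 2)), 1),
               "rank-deficient|collinear")
})

test_that("merophyte contributions are fractions summing to one", {
  tis <- make_template(template_spec())
  mc <- merophyte_contribution(tis)
  expect_equal(sum(mc$fraction), 1, tolerance = 1e-9)
  expect_setequal(mc$merophyte, 1:2)
  # hand case: two sectors of area 30 and 70
  pos <- rbind(c(0, 0), c(10, 0), c(10, 3), c(10, 10), c(0, 10), c(0, 3))
  tis2 <- new_tissue(pos, is_base = pos[, 2] == 0,
                     ring = list(c(1, 2, 3, 6), c(6, 3, 4, 5)),
                     merophyte = c(1L, 2L))
  mc2 <- merophyte_contribution(tis2)
  expect_equal(mc2$fraction, c(0.3, 0.7), tolerance = 1e-12)
})

test_that("binned profiles match a sort-based quantile oracle", {
  set.seed(3)
  nd <- runif(5000)
  rec <- data.frame(normalized = nd, bin = pmax(1, ceiling(10 * nd)),
                    value = nd)
  bp <- binned_profile(rec, "value")
  expect_equal(bp$bin, 1:10)
  # dense uniform sampling: bin k median ~ (k - 0.5) / 10
  expect_equal(bp$median, (1:10 - 0.5) / 10, tolerance = 0.02)
  for (b in c(2, 5, 9)) {
    x <- sort(rec$value[rec$bin == b])
    expect_equal(bp$median[b], stats::median(x), tolerance = 1e-12)
    expect_equal(bp$q1[b], stats::quantile(x, 0.25, names = FALSE),
                 tolerance = 1e-12)
    expect_equal(bp$q3[b], stats::quantile(x, 0.75, names = FALSE),
                 tolerance = 1e-12)
  }
  # constant values give zero-width interquartile ranges
  rec$value <- 7
  bp2 <- binned_profile(rec, "value")
  expect_equal(bp2$median, rep(7, 10))
  expect_equal(bp2$q3 - bp2$q1, rep(0, 10))
  # empty bins are NA
  rec3 <- data.frame(bin = c(1, 1, 5), value = c(1, 2, 3))
  bp3 <- binned_profile(rec3, "value")
  expect_true(is.na(bp3$median[2]))
  expect_equal(bp3$n[c(1, 5)], c(2L, 1L))
})

test_that("zero-growth fixtures yield identical snapshots and zero rates", {
  lt <- make_lineage_fixture(fixture_spec(k_par_base = 0, k_par_slope = 0,
                                          k_per = 0))
  expect_equal(lt$timepoints[[1]]$poly, lt$timepoints[[2]]$poly,
               tolerance = 1e-12)
  gr <- growth_records(lt)
  expect_equal(max(abs(gr$k_par)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gr$k_per)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gr$area_expansion_pct)), 0, tolerance = 1e-9)
})

test_that("scheduled fixture divisions are counted and conserve area", {
  lt <- make_lineage_fixture(fixture_spec(divide_cells = c(3, 10)))
  gr <- growth_records(lt)
  expect_equal(sum(gr$n_divisions), 2)
  g3 <- gr[gr$cell == 3 & gr$interval == 1, ]
  expect_equal(g3$n_divisions, 1)
  # daughters jointly cover the grown parent: expansion equals the pure
  # growth factor of the interval
  gt <- lt$ground_truth
  k3 <- gt[gt$interval == 1 & gt$cell == 3, ]
  dt <- lt$times[2] - lt$times[1]
  expect_equal(g3$area_expansion_pct,
               100 * (exp((k3$k_par + k3$k_per) * dt) - 1), tolerance = 1e-6)
})

test_that("noiseless fixtures are recovered to numerical precision", {
  lt <- make_lineage_fixture(fixture_spec(k_par_base = 0.3, k_per = 0.12,
                                          rotation = 0.4))
  gr <- growth_records(lt)
  gt <- lt$ground_truth
  m <- merge(gr, gt, by = c("interval", "cell"), suffixes = c("", "_true"))
  expect_gt(nrow(m), 0)
  expect_equal(max(abs(m$k_par - m$k_par_true)), 0, tolerance = 1e-9)
  expect_equal(max(abs(m$k_per - m$k_per_true)), 0, tolerance = 1e-9)
})

test_that("junction noise of 0.5 um leaves rate recovery under 5 percent", {
  lt <- make_lineage_fixture(fixture_spec(nx = 5, ny = 8, cell_size = 20,
                                          times = c(0, 1),
                                          k_par_base = 0.3, k_per = 0.15,
                                          noise_sd = 0.5, seed = 21))
  gr <- growth_records(lt)
  gt <- lt$ground_truth
  m <- merge(gr, gt, by = c("interval", "cell"), suffixes = c("", "_true"))
  rel <- abs(m$k_par - m$k_par_true) / m$k_par_true
  expect_lt(mean(rel), 0.05)
})

test_that("a linear basal growth gradient is recovered by the binned profile", {
  lt <- make_lineage_fixture(fixture_spec(nx = 6, ny = 20, cell_size = 10,
                                          times = c(0, 0.5),
                                          k_par_base = 0.1, k_par_slope = 0.5,
                                          k_per = 0.05))
  gr <- growth_records(lt)
  bp <- binned_profile(gr, "k_par")
  ok <- !is.na(bp$median)
  fit <- stats::lm(bp$median[ok] ~ I((bp$bin[ok] - 0.5) / 10))
  slope <- unname(fit$coefficients[2])
  expect_equal(slope, 0.5, tolerance = 0.05 * 0.5)
  expect_equal(unname(fit$coefficients[1]), 0.1, tolerance = 0.02)
})

test_that("merophyte-level expansion equals the area-weighted cell aggregate", {
  traj <- simulate_phyllid("wt_upper", t_end = 2.5)
  lt <- lineage_table(traj)
  gr <- growth_records(lt)
  iv <- max(gr$interval)
  s0 <- traj$snapshots[[iv]]
  sel <- gr$interval == iv & gr$cell %in% s0$cell_id[!is.na(s0$merophyte)]
  g <- gr[sel, ]
  mero <- s0$merophyte[match(g$cell, s0$cell_id)]
  for (m in unique(mero)) {
    gi <- g[mero == m, ]
    agg <- sum(gi$area * (1 + gi$area_expansion_pct / 100)) / sum(gi$area)
    union_exp <- (agg - 1) * 100
    wavg <- sum(gi$area * gi$area_expansion_pct) / sum(gi$area)
    expect_equal(union_exp, wavg, tolerance = 1e-9)
  }
})
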