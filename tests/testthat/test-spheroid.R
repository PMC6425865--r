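# Spheroid frame measurement, migration index, treatment effects.

disc_mask <- function(side, radius, ctr = (side + 1) / 2) {
  ii <- matrix(rep(seq_len(side), side), nrow = side)
  (ii - ctr)^2 + (t(ii) - ctr)^2 <= radius^2
}

test_that("a perfect disc has equal core, front and edge radii", {
  m <- disc_mask(251, 100)
  fr <- measure_frame(m, pixel_size = 1)
  expect_equal(fr$core_radius, 100, tolerance = 1)
  expect_equal(fr$front_radius, 100, tolerance = 1)
  expect_equal(fr$edge_radius, 100, tolerance = 1)
  expect_gte(fr$edge_radius, fr$front_radius)
})

test_that("an isolated far pixel moves the edge but not the front", {
  m <- disc_mask(641, 100)
  base <- measure_frame(m, pixel_size = 1)
  m[321, 321 + 300] <- TRUE  # single cell 300 um east of the centre
  fr <- measure_frame(m, pixel_size = 1)
  expect_equal(fr$edge_radius, 300, tolerance = 1.5)
  expect_equal(fr$front_radius, base$front_radius, tolerance = 1)
})

test_that("measurement rejects empty and multi-spheroid images", {
  expect_error(measure_frame(matrix(FALSE, 10, 10), 1), "no foreground")
  two <- matrix(FALSE, 101, 101)
  two[disc_mask(101, 15, ctr = 25)] <- TRUE
  two[disc_mask(101, 15, ctr = 76)] <- TRUE
  expect_error(measure_frame(two, 1), "multiple large")
})

test_that("synthetic series radii and migration indexes round-trip", {
  spec <- spheroid_sim_spec(250, front_rate = 250 * 0.32 / 72,
                            edge_rate = 250 * 0.56 / 72, seed = 5)
  sim <- gen_spheroid_series(spec)
  ms <- measure_series(sim$masks, sim$truth$t_h, sim$pixel_size)
  # radii within one pixel of ground truth at every timepoint
  expect_true(all(abs(ms$front_radius - sim$truth$front_radius) <= sim$pixel_size))
  expect_true(all(abs(ms$edge_radius - sim$truth$edge_radius) <= sim$pixel_size))
  # MI at the final timepoint matches the calibrated preset (±0.02)
  expect_lt(abs(ms$mi_front[ms$t_h == 72] - 0.32), 0.02)
  expect_lt(abs(ms$mi_edge[ms$t_h == 72] - 0.56), 0.02)
  # MI identically zero at t = 0, and edge leads front throughout
  expect_identical(ms$mi_front[ms$t_h == 0], 0)
  expect_identical(ms$mi_edge[ms$t_h == 0], 0)
  expect_true(all(ms$mi_edge >= ms$mi_front - 1e-12))
})

test_that("migration index is zero without growth and linear in radius", {
  frames <- data.frame(t_h = c(0, 24, 48), core_radius = 200,
                       front_radius = 200, edge_radius = 200)
  s <- migration_index(frames)
  expect_equal(s$mi_front, rep(0, 3))
  expect_equal(s$mi_edge, rep(0, 3))

  frames$edge_radius <- c(200, 220, 240)
  s <- migration_index(frames)
  expect_equal(s$mi_edge[2], 0.10)

  expect_error(migration_index(frames[-1, ]), "t = 0")
})

test_that("migration index is invariant to pixel size and rotation", {
  spec1 <- spheroid_sim_spec(200, 1.5, 2.0, c(0, 24, 48), pixel_size = 2, seed = 9)
  spec2 <- spheroid_sim_spec(200, 1.5, 2.0, c(0, 24, 48), pixel_size = 4, seed = 9)
  s1 <- measure_series(gen_spheroid_series(spec1)$masks, c(0, 24, 48), 2)
  s2 <- measure_series(gen_spheroid_series(spec2)$masks, c(0, 24, 48), 4)
  expect_equal(s1$mi_front, s2$mi_front, tolerance = 0.03)
  expect_equal(s1$mi_edge, s2$mi_edge, tolerance = 0.03)

  sim <- gen_spheroid_series(spec1)
  rot <- measure_series(lapply(sim$masks, rot90), c(0, 24, 48), 2)
  expect_equal(rot$mi_front, s1$mi_front, tolerance = 1e-6)
  expect_equal(rot$mi_edge, s1$mi_edge, tolerance = 1e-6)
})

test_that("fitted MI slope recovers the outgrowth rate", {
  r0 <- 250; rate <- 2
  sim <- gen_spheroid_series(spheroid_sim_spec(r0, rate, rate + 1, seed = 3))
  ms <- measure_series(sim$masks, sim$truth$t_h, sim$pixel_size)
  slope <- coef(lm(mi_front ~ t_h, as.data.frame(ms)))[["t_h"]]
  expect_lt(abs(slope - rate / r0) / (rate / r0), 0.05)
})

test_that("treatment effects are tested and direction-flagged", {
  series_for <- function(rate, seed) {
    lapply(1:3, function(k) {
      sim <- gen_spheroid_series(spheroid_sim_spec(250, rate, rate + 1,
                                                   seed = seed + k))
      measure_series(sim$masks, sim$truth$t_h, sim$pixel_size,
                     spheroid_id = paste0("s", seed + k))
    })
  }
  ctl <- series_for(2, 100)
  same <- treatment_effect(list(a = ctl, b = ctl), timepoint = 72)
  expect_equal(same$comparisons$p_value, 1)
  expect_equal(same$comparisons$direction, "none")

  trt <- series_for(1, 200)
  eff <- treatment_effect(list(control = ctl, treated = trt), timepoint = 72)
  expect_lt(eff$summary$mean_mi[eff$summary$condition == "treated"],
            eff$summary$mean_mi[eff$summary$condition == "control"])
  expect_lt(eff$comparisons$p_value, 0.05)
  expect_match(eff$comparisons$direction, "anti-migratory")

  pro <- treatment_effect(list(control = trt, treated = ctl), timepoint = 72)
  expect_match(pro$comparisons$direction, "pro-migratory")

  w <- capture_warnings(treatment_effect(list(a = ctl, b = trt), timepoint = 60))
  expect_match(w, "nearest", all = TRUE)
  expect_error(treatment_effect(list(a = ctl[1:2], b = trt)), "at least 3")
})

test_that("the spheroid simulator validates its spec", {
  expect_error(spheroid_sim_spec(250, front_rate = 2, edge_rate = 1), "edge_rate")
  expect_error(spheroid_sim_spec(250, 1, 2, timepoints = c(0, 48, 24)),
               "strictly increasing")
  expect_error(spheroid_sim_spec(250, 1, 2, timepoints = c(24, 48)),
               "start at 0")
  # zero rates: no migration at any timepoint
  sim <- gen_spheroid_series(spheroid_sim_spec(150, 0, 0, seed = 2))
  ms <- measure_series(sim$masks, sim$truth$t_h, sim$pixel_size)
  expect_equal(ms$mi_front, rep(0, 4), tolerance = 1e-12)
  expect_equal(ms$mi_edge, rep(0, 4), tolerance = 1e-12)
})
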