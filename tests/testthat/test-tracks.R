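# Track statistics, CTCF, rose summaries, PRW generator recovery.

straight_track <- function(n = 10, step = 1) {
  data.frame(t_min = 0:n, x_um = step * (0:n), y_um = 0)
}

test_that("track statistics handle straight, closed and invalid tracks", {
  st <- track_stats(straight_track(10, 1))
  expect_equal(st$velocity, 0.1 * 10)  # 10 um over 10 min -> 1 um/min
  st <- track_stats(data.frame(t_min = seq(0, 100, by = 10),
                               x_um = seq(0, 10, by = 1), y_um = 0))
  expect_equal(st$velocity, 0.1)
  expect_equal(st$directionality, 1)

  # out and back: displacement and directionality are exactly zero
  ob <- data.frame(t_min = 0:2, x_um = c(0, 5, 0), y_um = 0)
  st <- track_stats(ob)
  expect_equal(st$displacement, 0)
  expect_equal(st$directionality, 0)
  expect_equal(st$path_length, 10)

  expect_error(track_stats(data.frame(t_min = 0, x_um = 0, y_um = 0)),
               "at least 2")
  expect_error(track_stats(data.frame(t_min = c(0, 0, 1), x_um = 0:2, y_um = 0)),
               "duplicate")
})

test_that("statistics are invariant under rigid motions and scale with units", {
  tr <- gen_tracks(prw_params(0.15, 40, 1, 120, n_cells = 5, seed = 21))
  base <- track_stats(tr)
  moved <- track_stats(transform_tracks(tr, angle = 1.1, dx = 50, dy = -20))
  for (col in c("path_length", "displacement", "velocity", "directionality")) {
    expect_equal(moved[[col]], base[[col]], tolerance = 1e-10)
  }
  scaled <- track_stats(transform_tracks(tr, scale = 2))
  expect_equal(scaled$velocity, 2 * base$velocity)
  expect_equal(scaled$directionality, base$directionality, tolerance = 1e-10)
  expect_true(all(base$directionality >= 0 & base$directionality <= 1))
  expect_true(all(base$displacement <= base$path_length + 1e-12))
})

test_that("ctcf implements the background-subtraction formula", {
  expect_equal(ctcf(1000, 100, 2), 800)
  expect_equal(ctcf(1000, 100, 0), 1000)
  expect_error(ctcf(10, -1, 1), "non-negative")
  expect_warning(ctcf(10, 100, 2), "negative")

  # affine identities on a grid (some cells go negative, hence the flag)
  grid <- expand.grid(id = c(0, 50, 500), a = c(0, 10, 40), b = c(0, 1, 3.5))
  suppressWarnings({
    expect_equal(ctcf(grid$id, grid$a, grid$b), grid$id - grid$a * grid$b)
    expect_equal(ctcf(grid$id + 7, grid$a, grid$b) - ctcf(grid$id, grid$a, grid$b),
                 rep(7, nrow(grid)))
  })

  # rendered-image oracle: recovers the deposited signal within 1%
  cell <- render_fluorescence_cell(noise_sd = 0.5, seed = 6)
  got <- ctcf(cell$integrated_density, cell$area, cell$background_mean)
  expect_lt(abs(got - cell$true_total_signal) / cell$true_total_signal, 0.01)
})

test_that("rose summary bins final angles into equal sectors", {
  mk <- function(angle) data.frame(t_min = 0:1, x_um = c(0, cos(angle)),
                                   y_um = c(0, sin(angle)))
  four <- do.call(rbind, Map(function(a, i) cbind(cell_id = paste0("c", i), mk(a)),
                             c(0, pi / 2, pi, 3 * pi / 2), 1:4))
  rs <- rose_summary(four, n_sectors = 4)
  expect_equal(unname(rs$counts), rep(1L, 4))

  east <- do.call(rbind, lapply(1:6, function(i) cbind(cell_id = paste0("c", i), mk(0))))
  rs <- rose_summary(east, n_sectors = 8)
  expect_equal(unname(rs$counts[1]), 6L)
  expect_equal(sum(rs$counts), 6)

  # zero-displacement tracks are counted separately, not binned
  still <- data.frame(cell_id = "s", t_min = 0:3, x_um = 0, y_um = 0)
  rs <- rose_summary(rbind(east, still), n_sectors = 8)
  expect_equal(sum(rs$counts), 6)
  expect_equal(rs$n_zero, 1)
  expect_error(rose_summary(east, n_sectors = 3), "n_sectors")
})

test_that("PRW directions are isotropic", {
  tr <- gen_tracks(prw_params(0.1, 20, 5, 300, n_cells = 400, seed = 31))
  rs <- rose_summary(tr, n_sectors = 8)
  unif <- suppressWarnings(chisq.test(rs$counts))
  expect_gt(unif$p.value, 0.01)
})

test_that("PRW generator recovers speed and responds to persistence", {
  expect_error(prw_params(0.1, 20, dt = 0, duration = 60), "dt")

  # speed = 0: stationary cells
  tr0 <- gen_tracks(prw_params(0, 20, 1, 30, n_cells = 3, seed = 1))
  st0 <- track_stats(tr0)
  expect_equal(st0$velocity, rep(0, 3))
  expect_equal(st0$path_length, rep(0, 3))

  # infinite persistence: straight lines, directionality exactly 1
  tri <- gen_tracks(prw_params(0.2, Inf, 1, 60, n_cells = 4, seed = 2))
  expect_equal(track_stats(tri)$directionality, rep(1, 4))

  # curvilinear speed equals the nominal speed by construction
  tr <- gen_tracks(prw_params(0.12, 30, 1, 720, n_cells = 40, seed = 3))
  st <- track_stats(tr)
  expect_lt(abs(mean(st$velocity) - 0.12) / 0.12, 0.05)

  # directionality increases with persistence time (fixed seeds)
  mean_dir <- vapply(c(5, 50, 500), function(pt) {
    mean(track_stats(gen_tracks(prw_params(0.12, pt, 1, 720, 60, seed = 17)))$directionality)
  }, numeric(1))
  expect_true(all(diff(mean_dir) > 0))
})

test_that("PRW mean-squared displacement crosses over from ballistic to diffusive", {
  p <- prw_params(0.1, persistence_time = 100, dt = 1, duration = 2000,
                  n_cells = 300, seed = 41)
  msd <- msd_curve(gen_tracks(p), lags = c(2, 4, 500, 1000))
  slope_short <- log(msd$msd_um2[2] / msd$msd_um2[1]) / log(2)
  slope_long <- log(msd$msd_um2[4] / msd$msd_um2[3]) / log(2)
  expect_gt(slope_short, 1.8)  # ~t^2 below the persistence time
  expect_lt(slope_long, 1.3)   # ~t well above it
})

test_that("condition report summarizes and tests per-condition velocities", {
  tr <- gen_tracks(prw_params(0.15, 30, 1, 240, n_cells = 10, seed = 51))
  same <- condition_report(list(a = tr, b = tr))
  expect_equal(same$comparisons$p_value, 1)

  ctl <- gen_tracks(prw_params(0.2, 30, 1, 720, n_cells = 50, seed = 52))
  trt <- gen_tracks(prw_params(0.1, 30, 1, 720, n_cells = 50, seed = 53))
  rep <- condition_report(list(control = ctl, treated = trt))
  expect_lt(rep$summary$mean_velocity[rep$summary$condition == "treated"],
            rep$summary$mean_velocity[rep$summary$condition == "control"])
  expect_lt(rep$comparisons$p_value, 0.01)

  solo <- condition_report(list(only = ctl))
  expect_null(solo$comparisons)
  expect_message(condition_report(list(ok = ctl, tiny = ctl[ctl$cell_id == "cell_0001", ])),
                 "tiny")
})
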