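# Persistent-random-walk (PRW) trajectory generator.

#' Persistent-random-walk parameters
#'
#' The minimal trajectory model with independent speed and persistence
#' knobs: cells move with constant step length `speed * dt` while the
#' heading performs a Gaussian random walk whose per-step turn variance is
#' `2 * dt / persistence_time`, so the heading autocorrelation decays as
#' `exp(-t / persistence_time)`. `persistence_time = Inf` gives straight
#' lines; `speed = 0` gives stationary cells.
#'
#' @param speed cell speed in micrometres per minute (>= 0).
#' @param persistence_time heading persistence time in minutes (> 0, may be
#'   `Inf`).
#' @param dt frame interval in minutes (> 0).
#' @param duration track duration in minutes (>= dt).
#' @param n_cells number of cells to simulate.
#' @param seed integer seed.
#' @return an object of class `prw_params`.
#' @export
prw_params <- function(speed, persistence_time, dt = 1, duration,
                       n_cells = 20L, seed = 1L) {
  stop_if_not_scalar(speed, "speed", 0)
  if (!(is.numeric(persistence_time) && length(persistence_time) == 1L &&
        persistence_time > 0)) {
    stop("`persistence_time` must be a single positive number (Inf allowed)",
         call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    stop("`dt` must be a single positive frame interval in minutes", call. = FALSE)
  }
  stop_if_not_scalar(duration, "duration", dt)
  stop_if_not_scalar(n_cells, "n_cells", 1)
  structure(list(speed = speed, persistence_time = persistence_time, dt = dt,
                 duration = duration, n_cells = as.integer(n_cells),
                 seed = as.integer(seed)),
            class = "prw_params")
}

#' Simulate persistent-random-walk cell tracks
#'
#' Each cell starts at the origin with a uniform random heading; at every
#' frame the heading turns by a centred Gaussian angle with variance
#' `2 * dt / persistence_time` and the cell advances by `speed * dt`.
#' Output is deterministic given the parameter object (seed included).
#'
#' @param params a [prw_params()].
#' @return a data frame with columns `cell_id`, `t_min`, `x_um`, `y_um`,
#'   one row per cell per frame (frames at `0, dt, ..., <= duration`).
#' @export
gen_tracks <- function(params) {
  stopifnot(inherits(params, "prw_params"))
  n_steps <- floor(params$duration / params$dt)
  step <- params$speed * params$dt
  turn_sd <- if (is.infinite(params$persistence_time)) 0 else
    sqrt(2 * params$dt / params$persistence_time)
  t_min <- seq(0, by = params$dt, length.out = n_steps + 1L)

  tracks <- withr::with_seed(params$seed, {
    lapply(seq_len(params$n_cells), function(i) {
      theta0 <- stats::runif(1, 0, 2 * pi)
      turns <- if (turn_sd > 0) stats::rnorm(n_steps - 1L, sd = turn_sd) else
        rep(0, max(n_steps - 1L, 0))
      theta <- theta0 + cumsum(c(0, turns))
      data.frame(cell_id = sprintf("cell_%04d", i),
                 t_min = t_min,
                 x_um = c(0, cumsum(step * cos(theta))),
                 y_um = c(0, cumsum(step * sin(theta))),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, tracks)
}

#' Ensemble mean-squared displacement of a set of tracks
#'
#' Averages the squared displacement from each track's starting point over
#' all tracks, at each requested lag time. For a persistent random walk the
#' curve is ballistic (`~ t^2`) for lags well below the persistence time and
#' diffusive (`~ t`) well above it.
#'
#' @param tracks track data frame (`cell_id`, `t_min`, `x_um`, `y_um`).
#' @param lags lag times (minutes) at which to evaluate; must exist in the
#'   track sampling grid.
#' @return data frame with columns `lag_min` and `msd_um2`.
#' @export
msd_curve <- function(tracks, lags) {
  per_cell <- split(tracks, tracks$cell_id)
  msd <- vapply(lags, function(lag) {
    d2 <- vapply(per_cell, function(tr) {
      i <- match(tr$t_min[1] + lag, tr$t_min)
      if (is.na(i)) return(NA_real_)
      (tr$x_um[i] - tr$x_um[1])^2 + (tr$y_um[i] - tr$y_um[1])^2
    }, numeric(1))
    mean(d2, na.rm = TRUE)
  }, numeric(1))
  data.frame(lag_min = lags, msd_um2 = msd)
}
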