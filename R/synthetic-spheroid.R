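# Synthetic spheroid time-lapse masks with known core/front/edge radii.

#' Specify a synthetic spheroid invasion series
#'
#' Ground truth follows linear outgrowth: the dense migration front grows as
#' `core_radius0 + front_rate * t` and the outermost single cells (the
#' migration edge) reach `core_radius0 + edge_rate * t`. At each timepoint a
#' binary mask is rasterized: a filled disc out to the front radius, plus
#' sparse isolated single-cell pixels scattered between front and edge, with
#' a few placed exactly on the edge radius so it is recoverable.
#'
#' @param core_radius0 initial spheroid core radius in micrometres (> 0).
#' @param front_rate,edge_rate linear outgrowth rates of the migration front
#'   and edge in micrometres per hour; `edge_rate >= front_rate >= 0`.
#' @param timepoints imaging times in hours, strictly increasing from 0.
#' @param pixel_size micrometres per pixel of the rasterized masks.
#' @param scatter_density fraction of annulus pixels between front and edge
#'   occupied by single cells; kept well below the front-detection
#'   threshold.
#' @param seed integer seed.
#' @return an object of class `spheroid_sim_spec`.
#' @export
spheroid_sim_spec <- function(core_radius0 = 250, front_rate = 1,
                              edge_rate = max(front_rate, 1),
                              timepoints = c(0, 24, 48, 72), pixel_size = 2,
                              scatter_density = 0.03, seed = 1L) {
  stop_if_not_scalar(core_radius0, "core_radius0", .Machine$double.eps)
  stop_if_not_scalar(front_rate, "front_rate", 0)
  stop_if_not_scalar(edge_rate, "edge_rate", front_rate)
  if (length(timepoints) < 1 || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0)) {
    stop("`timepoints` must start at 0 and be strictly increasing", call. = FALSE)
  }
  stop_if_not_scalar(pixel_size, "pixel_size", .Machine$double.eps)
  stop_if_not_scalar(scatter_density, "scatter_density", 0, 0.15)
  structure(list(core_radius0 = core_radius0, front_rate = front_rate,
                 edge_rate = edge_rate, timepoints = timepoints,
                 pixel_size = pixel_size, scatter_density = scatter_density,
                 seed = as.integer(seed)),
            class = "spheroid_sim_spec")
}

#' Generate a synthetic spheroid mask series with ground truth
#'
#' @param spec a [spheroid_sim_spec()].
#' @return a list with `truth` (data frame `t_h`, `core_radius`,
#'   `front_radius`, `edge_radius`, micrometres), `masks` (list of logical
#'   matrices, one per timepoint), `pixel_size`, and the `spec`.
#' @export
gen_spheroid_series <- function(spec) {
  stopifnot(inherits(spec, "spheroid_sim_spec"))
  ps <- spec$pixel_size
  t_h <- spec$timepoints
  front_r <- spec$core_radius0 + spec$front_rate * t_h
  edge_r <- spec$core_radius0 + spec$edge_rate * t_h

  side <- as.integer(2 * ceiling(max(edge_r) / ps * 1.08) + 1L)
  ctr <- (side + 1) / 2
  ix <- matrix(rep(seq_len(side), side), nrow = side)
  iy <- t(ix)
  dist_px <- sqrt((ix - ctr)^2 + (iy - ctr)^2)

  masks <- withr::with_seed(spec$seed, {
    lapply(seq_along(t_h), function(k) {
      fr_px <- front_r[k] / ps
      ed_px <- edge_r[k] / ps
      m <- dist_px <= fr_px
      if (ed_px > fr_px + 1) {
        annulus <- which(dist_px > fr_px + 1 & dist_px < ed_px - 1)
        n_scatter <- round(spec$scatter_density * length(annulus))
        if (n_scatter > 0) m[sample(annulus, n_scatter)] <- TRUE
        # anchor single cells exactly on the edge radius
        for (a in seq(0, 2 * pi, length.out = 9L)[-9L]) {
          i <- round(ctr + ed_px * cos(a)); j <- round(ctr + ed_px * sin(a))
          if (i >= 1 && i <= side && j >= 1 && j <= side) m[i, j] <- TRUE
        }
      }
      m
    })
  })

  truth <- data.frame(t_h = t_h, core_radius = spec$core_radius0,
                      front_radius = front_r, edge_radius = edge_r)
  list(truth = truth, masks = masks, pixel_size = ps, spec = spec)
}
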