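# Spheroid migration measurement: core/front/edge radii from binary masks
# and the migration index.

#' Measure core, front and edge radii of one spheroid frame
#'
#' Operationalizes the two measuring zones of a collagen invasion assay on
#' a binary cell mask:
#'
#' * `core_radius` — equivalent-circle radius of the largest connected
#'   component (`sqrt(area / pi)`), the dense spheroid body;
#' * `front_radius` — outer radius of the collectively migrating front:
#'   the largest radius out to which the angularly-averaged cell-pixel
#'   occupancy (per one-pixel annulus around the core centroid) stays at or
#'   above `front_density_threshold`;
#' * `edge_radius` — distance from the centroid to the farthest cell pixel,
#'   capturing the outermost individually migrating cells.
#'
#' A handful of isolated pixels far from the spheroid therefore moves the
#' edge but not the front.
#'
#' @param mask logical (or 0/1) matrix, `TRUE` for cell pixels; exactly one
#'   spheroid per image.
#' @param pixel_size micrometres per pixel (> 0).
#' @param front_density_threshold minimum annulus occupancy fraction for
#'   the front (default 0.2).
#' @return a one-row data frame: `core_radius`, `front_radius`,
#'   `edge_radius` in micrometres (invariantly
#'   `edge_radius >= front_radius`).
#' @export
measure_frame <- function(mask, pixel_size, front_density_threshold = 0.2) {
  stop_if_not_scalar(pixel_size, "pixel_size", .Machine$double.eps)
  stop_if_not_scalar(front_density_threshold, "front_density_threshold", 0, 1)
  m <- mask
  if (is.logical(m)) m <- m * 1
  if (!is.matrix(m)) stop("`mask` must be a matrix", call. = FALSE)
  if (sum(m) == 0) stop("no foreground pixels: nothing to measure", call. = FALSE)

  lab <- EBImage::bwlabel(m)
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  if (sum(areas >= 0.25 * areas[biggest]) > 1) {
    stop(paste("multiple large connected components found; crop the image to",
               "a single spheroid"), call. = FALSE)
  }
  core_px <- sqrt(areas[biggest] / pi)

  idx <- which(lab == biggest, arr.ind = TRUE)
  ci <- mean(idx[, 1]); cj <- mean(idx[, 2])

  fg <- which(m > 0, arr.ind = TRUE)
  dist_fg <- sqrt((fg[, 1] - ci)^2 + (fg[, 2] - cj)^2)
  edge_px <- max(dist_fg)

  # occupancy per 1-px annulus, scanned outward until it first drops below
  # the threshold; the front is the outer edge of the last dense annulus
  ii <- matrix(rep(seq_len(nrow(m)), ncol(m)), nrow = nrow(m))
  jj <- t(matrix(rep(seq_len(ncol(m)), nrow(m)), nrow = ncol(m)))
  dist_all <- sqrt((ii - ci)^2 + (jj - cj)^2)
  ring <- floor(dist_all)
  n_all <- tabulate(ring + 1L)
  n_fg <- tabulate(ring[m > 0] + 1L, nbins = length(n_all))
  occ <- n_fg / n_all
  below <- which(occ < front_density_threshold)
  front_px <- if (length(below) == 0) edge_px else max(below[1] - 1, 1)

  data.frame(core_radius = core_px * pixel_size,
             front_radius = min(front_px, edge_px) * pixel_size,
             edge_radius = edge_px * pixel_size)
}

#' Assemble a measured spheroid time series
#'
#' Runs [measure_frame()] on each timepoint's mask and attaches migration
#' indexes via [migration_index()].
#'
#' @param masks list of binary masks, one per timepoint.
#' @param timepoints times in hours, starting at 0, same length as `masks`.
#' @param pixel_size micrometres per pixel.
#' @param spheroid_id,condition identifiers carried into the result.
#' @param front_density_threshold passed to [measure_frame()].
#' @return a `spheroid_series` object (see [migration_index()]).
#' @export
measure_series <- function(masks, timepoints, pixel_size,
                           spheroid_id = "spheroid", condition = "control",
                           front_density_threshold = 0.2) {
  if (length(masks) != length(timepoints)) {
    stop("`masks` and `timepoints` lengths differ", call. = FALSE)
  }
  frames <- do.call(rbind, lapply(masks, measure_frame, pixel_size = pixel_size,
                                  front_density_threshold = front_density_threshold))
  frames <- cbind(t_h = timepoints, frames)
  migration_index(frames, spheroid_id = spheroid_id, condition = condition)
}

#' Migration index of a spheroid series
#'
#' The migration index of a zone (front or edge) at time t is the zone's
#' radius increase relative to the initial core radius:
#' `MI(t) = (radius(t) - radius(0)) / core_radius(0)`. Before any
#' outgrowth the zone radii coincide with the core, so the zone's own
#' t = 0 radius serves as the baseline — which makes MI identically 0 at
#' t = 0 even when core and zone radii are measured by different
#' estimators that disagree by a fraction of a pixel. MI is dimensionless
#' (so independent of pixel size) and `mi_edge >= mi_front` whenever the
#' radii grow in an ordered way. This definition is deliberately isolated
#' in one function so an alternative index can be swapped in.
#'
#' @param frames data frame with columns `t_h`, `core_radius`,
#'   `front_radius`, `edge_radius`; must contain a frame at `t_h = 0` with
#'   positive core radius.
#' @param spheroid_id,condition identifiers.
#' @return an object of class `spheroid_series`: the frames data frame with
#'   added `mi_front` and `mi_edge` columns, plus `spheroid_id` and
#'   `condition` attributes.
#' @export
migration_index <- function(frames, spheroid_id = "spheroid",
                            condition = "control") {
  need <- c("t_h", "core_radius", "front_radius", "edge_radius")
  if (!all(need %in% names(frames))) {
    stop("frames need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  frames <- frames[order(frames$t_h), , drop = FALSE]
  i0 <- which(frames$t_h == 0)
  if (length(i0) != 1) stop("exactly one frame at t = 0 is required", call. = FALSE)
  r0 <- frames$core_radius[i0]
  if (!is.finite(r0) || r0 <= 0) stop("core radius at t = 0 must be positive", call. = FALSE)
  frames$mi_front <- (frames$front_radius - frames$front_radius[i0]) / r0
  frames$mi_edge <- (frames$edge_radius - frames$edge_radius[i0]) / r0
  structure(frames, spheroid_id = spheroid_id, condition = condition,
            class = c("spheroid_series", "data.frame"))
}

#' @export
print.spheroid_series <- function(x, ...) {
  cat(sprintf("Spheroid series `%s` (condition: %s)\n",
              attr(x, "spheroid_id"), attr(x, "condition")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Treatment effect on spheroid migration at a timepoint
#'
#' Compares per-spheroid migration indexes between conditions at the
#' requested timepoint with unpaired t-tests ([compare_conditions()]), and
#' flags each pairwise effect as anti-migratory (treated mean below the
#' first condition's) or pro-migratory. If a series lacks the exact
#' timepoint its nearest frame is used, with a warning.
#'
#' @param series_by_condition named list; each element a list of
#'   `spheroid_series` (>= 3 per condition, as replicate spheroids).
#' @param timepoint hours (default 72).
#' @param zone `"front"` or `"edge"`.
#' @return a list with `summary` (per-condition MI mean, SE, n) and
#'   `comparisons` (pairwise t-tests with a `direction` column; `NULL` with
#'   a single condition).
#' @export
treatment_effect <- function(series_by_condition, timepoint = 72,
                             zone = c("front", "edge")) {
  zone <- match.arg(zone)
  col <- paste0("mi_", zone)
  mi_at <- function(series) {
    i <- which(series$t_h == timepoint)
    if (length(i) == 0) {
      i <- which.min(abs(series$t_h - timepoint))
      warning(sprintf("timepoint %g h missing for `%s`; using nearest frame (%g h)",
                      timepoint, attr(series, "spheroid_id"), series$t_h[i]))
    }
    series[[col]][i]
  }
  mis <- lapply(series_by_condition, function(lst) vapply(lst, mi_at, numeric(1)))
  small <- vapply(mis, length, integer(1)) < 3
  if (any(small)) {
    stop("each condition needs at least 3 replicate spheroids: ",
         paste(names(mis)[small], collapse = ", "), call. = FALSE)
  }
  summary <- do.call(rbind, lapply(names(mis), function(cond) {
    data.frame(condition = cond, n = length(mis[[cond]]),
               mean_mi = mean(mis[[cond]]), se_mi = se_mean(mis[[cond]]))
  }))
  comparisons <- NULL
  if (length(mis) >= 2) {
    pairs <- utils::combn(names(mis), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      cmp <- compare_conditions(mis[[a]], mis[[b]])
      data.frame(condition_a = a, condition_b = b, t = cmp$t, df = cmp$df,
                 p_value = cmp$p_value, mean_diff = cmp$mean_diff,
                 direction = if (cmp$mean_diff == 0) "none" else
                   if (cmp$mean_diff > 0) "anti-migratory (b < a)" else
                     "pro-migratory (b > a)")
    }))
  }
  list(summary = summary, comparisons = comparisons, zone = zone,
       timepoint = timepoint)
}
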