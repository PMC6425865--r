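# 2D cell-track migration statistics and fluorescence quantification.

validate_track <- function(tr) {
  if (nrow(tr) < 2) stop("a track needs at least 2 samples", call. = FALSE)
  if (any(duplicated(tr$t_min))) {
    stop("duplicate timestamps in track", call. = FALSE)
  }
  if (any(diff(tr$t_min) <= 0)) {
    stop("track times must be strictly increasing", call. = FALSE)
  }
  invisible(tr)
}

#' Per-cell migration statistics
#'
#' For each track: total path length (sum of consecutive step lengths), net
#' displacement (first to last position), duration, velocity (path length
#' over duration — curvilinear speed), directionality (displacement divided
#' by path length, the standard persistence ratio: 1 for straight-line
#' motion, 0 for a closed path, and 0 by convention for a stationary cell),
#' and the angle of the net displacement vector.
#'
#' @param tracks data frame with columns `cell_id`, `t_min`, `x_um`,
#'   `y_um`; a single track may omit `cell_id`.
#' @return data frame with one row per cell: `cell_id`, `path_length`,
#'   `displacement`, `duration`, `velocity`, `directionality`,
#'   `final_angle` (radians in (-pi, pi\]).
#' @examples
#' tr <- data.frame(t_min = 0:10, x_um = 0:10, y_um = 0)
#' track_stats(tr)  # velocity 1 um/min, directionality 1
#' @export
track_stats <- function(tracks) {
  need <- c("t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop("tracks need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"cell_id" %in% names(tracks)) tracks$cell_id <- "cell_0001"
  per_cell <- split(tracks, tracks$cell_id)
  rows <- lapply(names(per_cell), function(id) {
    tr <- per_cell[[id]][order(per_cell[[id]]$t_min), , drop = FALSE]
    validate_track(tr)
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    path <- sum(steps)
    dx <- tr$x_um[nrow(tr)] - tr$x_um[1]
    dy <- tr$y_um[nrow(tr)] - tr$y_um[1]
    disp <- sqrt(dx^2 + dy^2)
    dur <- tr$t_min[nrow(tr)] - tr$t_min[1]
    data.frame(cell_id = id,
               path_length = path,
               displacement = disp,
               duration = dur,
               velocity = path / dur,
               directionality = if (path > 0) disp / path else 0,
               final_angle = atan2(dy, dx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - area * mean background fluorescence`, the
#' standard background-corrected fluorescence of a hand-outlined cell.
#' Negative results (background brighter than the cell) are returned but
#' flagged with a warning.
#'
#' @param integrated_density sum of pixel intensities over the cell region.
#' @param area cell area in the same pixel units as the background mean
#'   (>= 0).
#' @param background_mean mean per-pixel background fluorescence.
#' @return numeric vector of CTCF values.
#' @examples
#' ctcf(1000, 100, 2)  # 800
#' @export
ctcf <- function(integrated_density, area, background_mean) {
  if (any(area < 0)) stop("`area` must be non-negative", call. = FALSE)
  out <- integrated_density - area * background_mean
  if (any(out < 0)) {
    warning(sum(out < 0), " CTCF value(s) negative: background exceeds cell signal")
  }
  out
}

#' Angular rose summary of track directions
#'
#' Bins each track's net-displacement angle into equal sectors over
#' \[0, 2 * pi), the tabulation behind a rose (wind-rose) plot of migration
#' directions. Tracks with zero displacement have no direction and are
#' counted separately.
#'
#' @param tracks track data frame (see [track_stats()]).
#' @param n_sectors number of equal angular sectors (>= 4, default 12).
#' @return a list with `counts` (named integer vector, one per sector,
#'   summing to the number of tracks with positive displacement),
#'   `breaks` (sector edges in radians) and `n_zero` (zero-displacement
#'   tracks).
#' @export
rose_summary <- function(tracks, n_sectors = 12L) {
  stop_if_not_scalar(n_sectors, "n_sectors", 4)
  stats <- track_stats(tracks)
  moving <- stats[stats$displacement > 0, , drop = FALSE]
  ang <- moving$final_angle %% (2 * pi)
  sector <- pmin(floor(ang / (2 * pi / n_sectors)), n_sectors - 1L)
  counts <- tabulate(sector + 1L, nbins = n_sectors)
  breaks <- seq(0, 2 * pi, length.out = n_sectors + 1L)
  names(counts) <- sprintf("[%.3f,%.3f)", breaks[-length(breaks)], breaks[-1])
  list(counts = counts, breaks = breaks,
       n_zero = nrow(stats) - nrow(moving))
}

#' Per-condition migration summary with pairwise tests
#'
#' Tabulates mean velocity and mean displacement (each with standard
#' error) per condition and runs pairwise unpaired t-tests
#' ([compare_conditions()]) on the per-cell velocities. Conditions with
#' fewer than 2 tracks are dropped with a message.
#'
#' @param tracks_by_condition named list of track data frames.
#' @param var_equal passed to [compare_conditions()].
#' @return a list with `summary` (one row per condition) and `comparisons`
#'   (one row per condition pair; empty when fewer than two conditions
#'   remain).
#' @export
condition_report <- function(tracks_by_condition, var_equal = TRUE) {
  stats_list <- lapply(tracks_by_condition, track_stats)
  keep <- vapply(stats_list, nrow, integer(1)) >= 2
  if (any(!keep)) {
    message("dropping condition(s) with < 2 tracks: ",
            paste(names(stats_list)[!keep], collapse = ", "))
  }
  stats_list <- stats_list[keep]
  if (length(stats_list) == 0) stop("no condition has >= 2 tracks", call. = FALSE)

  summary <- do.call(rbind, lapply(names(stats_list), function(cond) {
    s <- stats_list[[cond]]
    data.frame(condition = cond, n = nrow(s),
               mean_velocity = mean(s$velocity), se_velocity = se_mean(s$velocity),
               mean_displacement = mean(s$displacement),
               se_displacement = se_mean(s$displacement),
               mean_directionality = mean(s$directionality))
  }))

  comparisons <- NULL
  if (length(stats_list) >= 2) {
    pairs <- utils::combn(names(stats_list), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      cmp <- compare_conditions(stats_list[[a]]$velocity,
                                stats_list[[b]]$velocity, var_equal)
      data.frame(condition_a = a, condition_b = b, t = cmp$t, df = cmp$df,
                 p_value = cmp$p_value, mean_diff = cmp$mean_diff)
    }))
  }
  list(summary = summary, comparisons = comparisons)
}
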