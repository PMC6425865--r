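# Orchestration: image/CSV I/O shared across stages, a seeded end-to-end
# demo pipeline, and the run manifest that makes outputs reproducible.

#' Read an RGB image (PNG, or TIFF when the tiff package is available)
#'
#' @param path image path.
#' @return numeric array (h x w x 3) in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the tiff package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Read a single-channel 0/255 mask PNG as a logical matrix
#'
#' @param path mask path.
#' @return logical matrix (`TRUE` where the mask is set).
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write an RGB image or mask as PNG
#'
#' @param x RGB array in \[0, 1\] or a logical mask.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- x * 1
  png::writePNG(x, path)
  invisible(path)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Default demo configuration for [run_pipeline()]
#'
#' A small fully-synthetic study: a sampled two-class cohort tested for a
#' location association, a handful of stained cores scored at three
#' intensity levels, two track conditions (control vs slowed treatment)
#' and two spheroid conditions with different front rates.
#'
#' @param seed integer master seed for every stage.
#' @return a named list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(counts = matrix(c(33, 13, 50, 2), ncol = 2,
                                  dimnames = list(c("cerebrum", "cerebellum"),
                                                  c("low", "high"))),
                  covariate = "location", mode = "replay"),
    cores = list(intensity = c(0, 1, 2, 3), stained_fraction = c(0, 20, 45, 80),
                 core_diameter_px = 80, noise_sd = 0.01),
    tracks = list(conditions = c(control = 0.2, treated = 0.1),
                  persistence_time = 30, dt = 1, duration = 720, n_cells = 30),
    spheroids = list(conditions = c(control = 2, treated = 1),
                     edge_extra = 1.5, core_radius0 = 250, pixel_size = 2,
                     timepoints = c(0, 24, 48, 72), n_replicates = 4)
  )
}

#' Run the synthetic demo pipeline end to end
#'
#' Executes simulate -> score -> associate -> tracks -> spheroid on fully
#' synthetic data and writes one CSV per stage plus a JSON run manifest
#' (seed, configuration, file list, convention notes) to `out_dir`. Outputs
#' are byte-identical across runs with the same config and seed.
#'
#' @param config configuration list, see [demo_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the written `files` and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("gliomig_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  files <- character()

  # --- simulate + associate: cohort stage
  cs <- cohort_spec(config$cohort$counts, covariate = config$cohort$covariate,
                    mode = config$cohort$mode,
                    n = config$cohort$n, seed = seed)
  cohort <- gen_cohort(cs)
  files["cohort"] <- write_stage_csv(cohort, out_dir, "cohort.csv")
  tab <- build_table(cohort, config$cohort$covariate, "expression_class")
  assoc <- pearson_chi2(tab)
  assoc_df <- data.frame(row_var = tab$row_var, col_var = tab$col_var,
                         method = assoc$method, statistic = assoc$statistic,
                         df = assoc$df, p_value = assoc$p_value)
  files["association"] <- write_stage_csv(assoc_df, out_dir, "association.csv")

  # --- score: synthetic cores
  cores_cfg <- config$cores
  score_rows <- lapply(seq_along(cores_cfg$intensity), function(i) {
    spec <- core_image_spec(cores_cfg$intensity[i], cores_cfg$stained_fraction[i],
                            core_diameter_px = cores_cfg$core_diameter_px,
                            noise_sd = cores_cfg$noise_sd, seed = seed + i)
    core <- gen_core_image(spec)
    cbind(score_core_image(core$image, core$tissue_mask,
                           intensity = cores_cfg$intensity[i],
                           proportion_pct = cores_cfg$stained_fraction[i],
                           core_id = sprintf("synthetic_core_%02d", i)),
          true_fraction = cores_cfg$stained_fraction[i])
  })
  scores <- do.call(rbind, score_rows)
  files["scores"] <- write_stage_csv(scores, out_dir, "scores.csv")

  # --- tracks stage
  tr_cfg <- config$tracks
  tracks_by_cond <- lapply(seq_along(tr_cfg$conditions), function(i) {
    gen_tracks(prw_params(tr_cfg$conditions[i], tr_cfg$persistence_time,
                          tr_cfg$dt, tr_cfg$duration, tr_cfg$n_cells,
                          seed = seed + 100 + i))
  })
  names(tracks_by_cond) <- names(tr_cfg$conditions)
  trep <- condition_report(tracks_by_cond)
  files["track_summary"] <- write_stage_csv(trep$summary, out_dir, "track_summary.csv")
  if (!is.null(trep$comparisons)) {
    files["track_comparisons"] <- write_stage_csv(trep$comparisons, out_dir,
                                                  "track_comparisons.csv")
  }

  # --- spheroid stage
  sp_cfg <- config$spheroids
  series_by_cond <- lapply(seq_along(sp_cfg$conditions), function(i) {
    lapply(seq_len(sp_cfg$n_replicates), function(k) {
      spec <- spheroid_sim_spec(sp_cfg$core_radius0, sp_cfg$conditions[i],
                                sp_cfg$conditions[i] + sp_cfg$edge_extra,
                                sp_cfg$timepoints, sp_cfg$pixel_size,
                                seed = seed + 200 + 10 * i + k)
      sim <- gen_spheroid_series(spec)
      measure_series(sim$masks, sim$truth$t_h, sim$pixel_size,
                     spheroid_id = sprintf("%s_%d", names(sp_cfg$conditions)[i], k),
                     condition = names(sp_cfg$conditions)[i])
    })
  })
  names(series_by_cond) <- names(sp_cfg$conditions)
  eff <- treatment_effect(series_by_cond, timepoint = max(sp_cfg$timepoints))
  files["spheroid_summary"] <- write_stage_csv(eff$summary, out_dir, "spheroid_summary.csv")
  if (!is.null(eff$comparisons)) {
    files["spheroid_comparisons"] <- write_stage_csv(eff$comparisons, out_dir,
                                                     "spheroid_comparisons.csv")
  }

  # --- run manifest
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   files = as.list(basename(files)),
                   conventions = attr(reproduce_tables(
                     tma_printed_tables()["t1_manual_sex"]), "conventions"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- file.path(out_dir, "run_manifest.json")

  invisible(list(files = files, cohort = cohort, association = assoc,
                 scores = scores, track_report = trep, spheroid_effect = eff,
                 out_dir = out_dir))
}

# matrices are not directly JSON-serializable with dimnames; flatten them
serialize_config <- function(config) {
  rapply(config, function(x) {
    if (is.matrix(x)) {
      list(values = as.vector(x), rows = rownames(x), cols = colnames(x))
    } else x
  }, how = "replace")
}
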