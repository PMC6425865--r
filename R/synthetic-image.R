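# Synthetic DAB/haematoxylin tissue-core images with pixel-level ground truth.

# DAB optical-density concentration assigned to each ordinal intensity level
# 0-3. Level 0 deposits no chromogen; levels 1-3 all clear the default
# positive-pixel threshold (0.15 OD) by a wide margin.
DAB_OD_LEVELS <- c(0, 0.35, 0.7, 1.05)
HEMATOXYLIN_OD <- 0.5          # counterstain concentration on unstained tissue
HEMATOXYLIN_OD_POSITIVE <- 0.2 # light counterstain mixed under the chromogen

#' Specify a synthetic stained tissue core
#'
#' Parameters for [gen_core_image()]: a circular tissue core on a white
#' background in which a controllable fraction of tissue pixels carries a
#' DAB-brown stain of controllable ordinal intensity, the remainder carrying
#' haematoxylin blue. Stains are mixed in optical-density space using the
#' same reference vectors as [separate_stains()], so recovery is exact (up
#' to 8-bit quantization) at `noise_sd = 0`.
#'
#' @param intensity_level ordinal staining intensity 0 (none) to 3 (strong).
#' @param stained_fraction percentage of tissue pixels stained, in \[0, 100\].
#' @param core_diameter_px core diameter in pixels.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param noise_sd standard deviation of Gaussian noise added per channel in
#'   OD units; 0 gives a noise-free core.
#' @param seed integer seed.
#' @return an object of class `core_image_spec`.
#' @export
core_image_spec <- function(intensity_level, stained_fraction,
                            core_diameter_px = 120L, pixel_size = 0.5,
                            noise_sd = 0, seed = 1L) {
  stop_if_not_scalar(intensity_level, "intensity_level", 0, 3)
  if (intensity_level != floor(intensity_level)) {
    stop("`intensity_level` must be one of 0, 1, 2, 3", call. = FALSE)
  }
  stop_if_not_scalar(stained_fraction, "stained_fraction", 0, 100)
  stop_if_not_scalar(core_diameter_px, "core_diameter_px", 8)
  stop_if_not_scalar(pixel_size, "pixel_size", .Machine$double.eps)
  stop_if_not_scalar(noise_sd, "noise_sd", 0)
  structure(list(intensity_level = as.integer(intensity_level),
                 stained_fraction = stained_fraction,
                 core_diameter_px = as.integer(core_diameter_px),
                 pixel_size = pixel_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "core_image_spec")
}

#' Generate a synthetic stained core image with ground-truth masks
#'
#' Renders an 8-bit RGB image of a circular tissue core. A
#' `stained_fraction` percent of tissue pixels (chosen uniformly at random
#' under the spec's seed) carries DAB at the OD concentration mapped from
#' `intensity_level` plus a light haematoxylin counterstain; the remaining
#' tissue pixels carry haematoxylin only; the background is white. Per-pixel
#' ODs are converted to 8-bit values by the Beer–Lambert inverse of the
#' transform used in [separate_stains()].
#'
#' @param spec a [core_image_spec()].
#' @return a list with `image` (h x w x 3 array in \[0, 1\]), logical
#'   matrices `tissue_mask` and `positive_mask` (ground truth), the
#'   ground-truth `dab_od` concentration matrix, and the `spec`.
#' @export
gen_core_image <- function(spec) {
  stopifnot(inherits(spec, "core_image_spec"))
  r <- spec$core_diameter_px / 2
  side <- as.integer(ceiling(spec$core_diameter_px * 1.15))
  ctr <- (side + 1) / 2
  ix <- matrix(rep(seq_len(side), side), nrow = side)
  iy <- t(ix)
  tissue <- (ix - ctr)^2 + (iy - ctr)^2 <= r^2
  n_tissue <- sum(tissue)
  n_pos <- round(spec$stained_fraction / 100 * n_tissue)

  withr::with_seed(spec$seed, {
    pos_idx <- sample(which(tissue), n_pos)
    positive <- matrix(FALSE, side, side)
    positive[pos_idx] <- TRUE

    dab_conc <- matrix(0, side, side)
    hem_conc <- matrix(0, side, side)
    dab_conc[positive] <- DAB_OD_LEVELS[spec$intensity_level + 1L]
    hem_conc[positive] <- HEMATOXYLIN_OD_POSITIVE
    hem_conc[tissue & !positive] <- HEMATOXYLIN_OD

    sv <- stain_vectors_hdab()
    od <- cbind(as.vector(hem_conc), as.vector(dab_conc)) %*% sv[1:2, ]
    if (spec$noise_sd > 0) {
      od <- od + matrix(stats::rnorm(length(od), sd = spec$noise_sd), nrow = nrow(od))
    }
    od[!as.vector(tissue), ] <- 0  # white background
    od <- pmax(od, 0)
  })

  vals <- value_from_od(od)
  image <- array(vals / 255, dim = c(side, side, 3))
  list(image = image, tissue_mask = tissue, positive_mask = positive,
       dab_od = dab_conc, spec = spec)
}
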