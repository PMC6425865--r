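# IHC scoring: stain separation, positivity, manual composite and digital
# positivity scores, dichotomization, localization calls.

#' Separate haematoxylin and DAB stains of a brightfield RGB image
#'
#' Colour deconvolution in optical-density space (Ruifrok–Johnston): each
#' pixel's per-channel OD, `-log10((v + 1)/256)` for 8-bit value `v`, is
#' decomposed onto the configured stain basis and the per-stain
#' concentrations are returned, clamped to be non-negative.
#'
#' @param image RGB array (h x w x 3, values in \[0, 1\] as returned by
#'   [png::readPNG()] or [gen_core_image()]).
#' @param stains 3 x 3 stain matrix, rows = unit OD vectors; defaults to
#'   [stain_vectors_hdab()].
#' @return a list of h x w matrices `dab` and `hematoxylin` holding the
#'   per-pixel stain concentrations (OD units).
#' @export
separate_stains <- function(image, stains = stain_vectors_hdab()) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("`image` must be an RGB array (h x w x 3)", call. = FALSE)
  }
  od <- rgb_to_od(image)
  conc <- od %*% solve(stains)        # pixel x (hematoxylin, dab, residual)
  conc <- pmax(conc, 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  list(dab = matrix(conc[, 2], h, w),
       hematoxylin = matrix(conc[, 1], h, w))
}

#' Positive-pixel positivity of a core
#'
#' Percentage of tissue pixels whose DAB concentration exceeds the OD
#' threshold — the re-implemented analogue of a slide scanner's
#' positive-pixel-count "positivity" output.
#'
#' @param dab_od matrix of per-pixel DAB concentrations from
#'   [separate_stains()].
#' @param tissue_mask logical matrix marking tissue pixels; must contain at
#'   least one `TRUE` (cores without analysable tissue are excluded, as TMA
#'   practice dictates).
#' @param od_threshold DAB OD above which a pixel counts as positive
#'   (default 0.15).
#' @return positivity percentage in \[0, 100\].
#' @export
positivity <- function(dab_od, tissue_mask, od_threshold = 0.15) {
  if (!identical(dim(dab_od), dim(tissue_mask))) {
    stop("`dab_od` and `tissue_mask` dimensions differ", call. = FALSE)
  }
  n_tissue <- sum(tissue_mask)
  if (n_tissue == 0) {
    stop("no tissue present to analyse: empty tissue mask (core should be excluded)",
         call. = FALSE)
  }
  100 * sum(dab_od[tissue_mask] > od_threshold) / n_tissue
}

#' Digital positivity score (0–7)
#'
#' Maps positive-pixel positivity percentages onto the eight-point digital
#' score via the fixed interval table with edges 12.5, 25, 37.5, 50, 62.5,
#' 75, 87.5. Intervals are half-open on the left — \[0, 12.5\] scores 0,
#' (12.5, 25\] scores 1, and so on up to (87.5, 100\] scoring 7 — so the
#' mapping is total and monotone on \[0, 100\] while preserving the integer
#' anchors of the published table (e.g. 12.6–25 = 1).
#'
#' @param positivity_pct numeric vector of percentages in \[0, 100\].
#' @return integer vector of scores 0–7.
#' @export
digital_score <- function(positivity_pct) {
  if (any(is.na(positivity_pct)) || any(positivity_pct < 0 | positivity_pct > 100)) {
    stop("`positivity_pct` must lie in [0, 100]", call. = FALSE)
  }
  edges <- c(12.5, 25, 37.5, 50, 62.5, 75, 87.5)
  vapply(positivity_pct, function(p) sum(p > edges), integer(1))
}

#' Manual composite score: intensity plus proportion bin
#'
#' The by-eye TMA score: staining intensity graded 0 (none) to 3 (strong)
#' is added to a stained-proportion bin — 0 for no stained cells, then
#' 1–25% = 1, 26–50% = 2, 51–75% = 3, 76–100% = 4 (implemented as
#' left-open intervals (0,25], (25,50], (50,75], (75,100] so fractional
#' percentages are covered) — giving a composite score out of 7.
#'
#' @param intensity integer vector of intensity grades in 0–3.
#' @param proportion_pct numeric vector of stained-cell percentages in
#'   \[0, 100\]; recycled against `intensity`.
#' @return a data frame with columns `intensity`, `proportion_pct`,
#'   `proportion_bin` (0–4) and `composite` (0–7).
#' @export
manual_composite <- function(intensity, proportion_pct) {
  if (any(is.na(intensity)) || any(!intensity %in% 0:3)) {
    stop("`intensity` must be one of 0, 1, 2, 3", call. = FALSE)
  }
  if (any(is.na(proportion_pct)) ||
      any(proportion_pct < 0 | proportion_pct > 100)) {
    stop("`proportion_pct` must lie in [0, 100]", call. = FALSE)
  }
  n <- max(length(intensity), length(proportion_pct))
  intensity <- rep_len(as.integer(intensity), n)
  proportion_pct <- rep_len(proportion_pct, n)
  bin <- ifelse(proportion_pct == 0, 0L,
                vapply(proportion_pct, function(p) sum(p > c(25, 50, 75)) + 1L,
                       integer(1)))
  data.frame(intensity = intensity, proportion_pct = proportion_pct,
             proportion_bin = as.integer(bin),
             composite = intensity + as.integer(bin))
}

#' Dichotomize scores into low and high expression
#'
#' Scores at or above the cut-point are labelled `"high"`, the rest
#' `"low"`. The default cut-point is the sample median (so ties at the
#' median go to `"high"`), matching the usual post-hoc dichotomization of
#' TMA scores; a fixed numeric cut-point may be given instead. The 50%
#' proliferation/apoptosis split (high > 50% stained) corresponds to
#' `cutpoint = 50` on proportions with the strict-boundary convention
#' absorbed by the scores being integer percentages.
#'
#' @param scores non-empty numeric vector.
#' @param cutpoint `"median"` (default) or a single number.
#' @return a factor with levels `low`, `high`, one per score.
#' @export
dichotomize <- function(scores, cutpoint = "median") {
  if (length(scores) == 0 || any(is.na(scores))) {
    stop("`scores` must be a non-empty vector without missing values", call. = FALSE)
  }
  cut <- if (identical(cutpoint, "median")) stats::median(scores) else {
    stop_if_not_scalar(cutpoint, "cutpoint")
    cutpoint
  }
  factor(ifelse(scores >= cut, "high", "low"), levels = c("low", "high"))
}

#' Classify subcellular stain localization
#'
#' Operationalizes the negative / cytoplasmic / membranous call from two
#' region measurements: if both the membrane-ring and cytoplasm ODs fall
#' below `negative_threshold` the core is negative; otherwise it is
#' membranous when the ring-to-cytoplasm OD ratio reaches
#' `ratio_threshold`, else cytoplasmic. A positive ring over zero cytoplasm
#' is membranous by convention.
#'
#' @param membrane_ring_od,cytoplasm_od non-negative mean ODs of the
#'   membrane ring and the cytoplasm region (vectors, recycled).
#' @param negative_threshold OD below which staining counts as absent.
#' @param ratio_threshold minimum ring/cytoplasm ratio for a membranous
#'   call.
#' @return a factor with levels `negative`, `cytoplasmic`, `membranous`.
#' @export
classify_localization <- function(membrane_ring_od, cytoplasm_od,
                                  negative_threshold = 0.1,
                                  ratio_threshold = 1.5) {
  if (any(membrane_ring_od < 0) || any(cytoplasm_od < 0)) {
    stop("ODs must be non-negative", call. = FALSE)
  }
  n <- max(length(membrane_ring_od), length(cytoplasm_od))
  ring <- rep_len(membrane_ring_od, n)
  cyto <- rep_len(cytoplasm_od, n)
  call <- ifelse(ring < negative_threshold & cyto < negative_threshold,
                 "negative",
                 ifelse(cyto == 0 | ring / cyto >= ratio_threshold,
                        "membranous", "cytoplasmic"))
  factor(call, levels = c("negative", "cytoplasmic", "membranous"))
}

#' Score one core image end to end
#'
#' Runs stain separation and positivity on an RGB core image and assembles
#' the digital score; manual intensity/proportion inputs, when supplied,
#' are folded into the composite score.
#'
#' @param image RGB array in \[0, 1\].
#' @param tissue_mask logical matrix; if `NULL`, tissue is taken to be
#'   every pixel with total OD above 0.1 (i.e. not blank slide).
#' @param od_threshold positive-pixel OD threshold.
#' @param intensity,proportion_pct optional manual scores for the composite.
#' @param core_id identifier carried through to the output.
#' @return one-row data frame with `core_id`, `positivity_pct`,
#'   `digital_score`, and (when manual inputs are given) `intensity`,
#'   `proportion_bin`, `composite`.
#' @export
score_core_image <- function(image, tissue_mask = NULL, od_threshold = 0.15,
                             intensity = NULL, proportion_pct = NULL,
                             core_id = "core") {
  sep <- separate_stains(image)
  if (is.null(tissue_mask)) {
    tissue_mask <- sep$dab + sep$hematoxylin > 0.1
  }
  pos <- positivity(sep$dab, tissue_mask, od_threshold)
  out <- data.frame(core_id = core_id, positivity_pct = pos,
                    digital_score = digital_score(pos))
  if (!is.null(intensity) && !is.null(proportion_pct)) {
    mc <- manual_composite(intensity, proportion_pct)
    out <- cbind(out, mc[, c("intensity", "proportion_bin", "composite")])
  }
  out
}

#' Score a manifest of core images
#'
#' Batch driver behind the `score-tma` command-line subcommand. The
#' manifest must have columns `core_id` and `image_path` (PNG, or TIFF if
#' the tiff package is installed), and may carry `mask_path` plus manual
#' `intensity` and `proportion_pct` columns. Cores whose tissue mask is
#' empty are excluded from the output with a message, mirroring the
#' exclusion of unanalysable TMA cores.
#'
#' @param manifest data frame or path to a manifest CSV.
#' @param od_threshold positive-pixel OD threshold.
#' @param cutpoint passed to [dichotomize()] for the `expression_class`
#'   column.
#' @return data frame of per-core scores with an `expression_class` column.
#' @export
score_tma <- function(manifest, od_threshold = 0.15, cutpoint = "median") {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("core_id", "image_path")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(manifest$image_path[i])
    mask <- NULL
    if ("mask_path" %in% names(manifest) && nzchar(manifest$mask_path[i]) &&
        !is.na(manifest$mask_path[i])) {
      mask <- read_mask(manifest$mask_path[i])
    }
    manual_int <- if ("intensity" %in% names(manifest) &&
                      !is.na(manifest$intensity[i])) manifest$intensity[i]
    manual_prop <- if ("proportion_pct" %in% names(manifest) &&
                       !is.na(manifest$proportion_pct[i])) manifest$proportion_pct[i]
    res <- tryCatch(
      score_core_image(img, mask, od_threshold,
                       intensity = manual_int, proportion_pct = manual_prop,
                       core_id = manifest$core_id[i]),
      error = function(e) {
        message(sprintf("excluding core %s: %s", manifest$core_id[i],
                        conditionMessage(e)))
        NULL
      })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("no scorable cores in manifest", call. = FALSE)
  }
  out$expression_class <- dichotomize(out$digital_score, cutpoint)
  out
}
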