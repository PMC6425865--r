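# Synthetic cohort generator: replays or samples a (covariate x expression
# class) cross-tabulation as a per-core record table.

#' Specify a synthetic cohort
#'
#' A cohort spec holds one cross-tabulation of a clinical covariate against
#' an expression class (e.g. low/high FGFR1, or a localization call), plus
#' the generation mode. In `"replay"` mode [gen_cohort()] emits exactly the
#' given counts; in `"sample"` mode it draws `n` records from a multinomial
#' whose cell probabilities are proportional to the counts.
#'
#' @param counts non-negative integer matrix with `dimnames`; rows are
#'   covariate categories, columns are expression classes.
#' @param covariate name of the covariate column in the emitted cohort
#'   (e.g. `"age_group"`).
#' @param class_var name of the class column, default `"expression_class"`.
#' @param mode `"replay"` (exact counts) or `"sample"` (multinomial draw).
#' @param n number of records to draw in sample mode (ignored for replay).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `cohort_spec`.
#' @examples
#' counts <- matrix(c(23, 12, 25, 2, 5, 15), ncol = 2,
#'                  dimnames = list(c("membranous", "cytoplasmic", "negative"),
#'                                  c("malignant", "benign")))
#' spec <- cohort_spec(counts, covariate = "localization",
#'                     class_var = "tumor_type")
#' cohort <- gen_cohort(spec)
#' cross_tab(cohort, "localization", "tumor_type")
#' @export
cohort_spec <- function(counts, covariate, class_var = "expression_class",
                        mode = c("replay", "sample"), n = NULL, seed = 1L) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have row and column names (category labels)", call. = FALSE)
  }
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("count for cell (%s, %s) must be a non-negative integer",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  }
  if (mode == "sample") {
    stop_if_not_scalar(n, "n", lo = 0)
    if (sum(counts) == 0) stop("sample mode needs at least one positive count", call. = FALSE)
  }
  structure(list(counts = counts, covariate = covariate, class_var = class_var,
                 mode = mode, n = n, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of core records from a spec
#'
#' Replay mode is an exact inverse of cross-tabulation: tabulating the
#' output reproduces `spec$counts` cell for cell. Sample mode draws the
#' requested number of records from a multinomial with probabilities
#' proportional to the counts.
#'
#' @param spec a [cohort_spec()].
#' @return a data frame with columns `core_id`, the covariate and the class
#'   variable (both as factors with the spec's category order).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- spec$counts
  if (spec$mode == "replay") {
    cells <- counts
  } else {
    p <- as.vector(counts) / sum(counts)
    cells <- withr::with_seed(spec$seed,
      matrix(stats::rmultinom(1, size = spec$n, prob = p), nrow = nrow(counts)))
    dimnames(cells) <- dimnames(counts)
  }
  row_cat <- rep(rep(rownames(counts), ncol(counts)), as.vector(cells))
  col_cat <- rep(rep(colnames(counts), each = nrow(counts)), as.vector(cells))
  n_tot <- length(row_cat)
  out <- data.frame(
    core_id = if (n_tot > 0) sprintf("core_%04d", seq_len(n_tot)) else character(),
    row = factor(row_cat, levels = rownames(counts)),
    col = factor(col_cat, levels = colnames(counts)),
    stringsAsFactors = FALSE
  )
  names(out)[2:3] <- c(spec$covariate, spec$class_var)
  out
}

#' Cross-tabulate two cohort columns
#'
#' Counts records by the two named columns, preserving factor level order.
#' `cross_tab(gen_cohort(spec), ...)` recovers `spec$counts` exactly in
#' replay mode.
#'
#' @param cohort data frame of core records.
#' @param row,col column names to tabulate.
#' @return an integer matrix with dimnames.
#' @export
cross_tab <- function(cohort, row, col) {
  for (v in c(row, col)) {
    if (!v %in% names(cohort)) stop(sprintf("column `%s` not found in cohort", v), call. = FALSE)
  }
  tab <- table(cohort[[row]], cohort[[col]])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
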