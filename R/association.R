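# Contingency-table construction and association tests: uncorrected Pearson
# chi-squared and the Freeman-Halton r x c Fisher exact test, plus the
# unpaired t-test used for assay comparisons.

#' Build a labeled contingency table from a cohort
#'
#' Cross-tabulates two categorical columns of a cohort after dropping
#' records whose value in either column is listed in `exclude` (the
#' convention used for "unknown" tumour type or grade). Record conservation
#' holds: `sum(counts) + n_excluded` equals the cohort size.
#'
#' @param cohort data frame of per-core records.
#' @param row,col names of the row and column variables.
#' @param exclude character vector of category labels to drop.
#' @return an object of class `contingency_table`: a list with the integer
#'   `counts` matrix (dimnames = category labels), `row_var`, `col_var`,
#'   `exclude` and `n_excluded`.
#' @export
build_table <- function(cohort, row, col, exclude = NULL) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  for (v in c(row, col)) {
    if (!v %in% names(cohort)) {
      stop(sprintf("unknown covariate `%s`", v), call. = FALSE)
    }
  }
  keep <- !(as.character(cohort[[row]]) %in% exclude |
            as.character(cohort[[col]]) %in% exclude)
  kept <- cohort[keep, , drop = FALSE]
  kept[[row]] <- droplevels(factor(kept[[row]]))
  kept[[col]] <- droplevels(factor(kept[[col]]))
  counts <- cross_tab(kept, row, col)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("table collapses below 2 x 2 after exclusions", call. = FALSE)
  }
  new_contingency_table(counts, row, col, exclude, sum(!keep))
}

new_contingency_table <- function(counts, row_var = "row", col_var = "col",
                                  exclude = NULL, n_excluded = 0L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = counts, row_var = row_var, col_var = col_var,
                 exclude = exclude, n_excluded = as.integer(n_excluded)),
            class = "contingency_table")
}

#' Coerce a count matrix to a contingency table
#'
#' @param counts non-negative integer matrix.
#' @param row_var,col_var variable names for labeling output.
#' @return a `contingency_table`.
#' @export
as_contingency_table <- function(counts, row_var = "row", col_var = "col") {
  new_contingency_table(counts, row_var, col_var)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table: %s x %s", x$row_var, x$col_var), "\n")
  print(x$counts)
  if (x$n_excluded > 0) {
    cat(sprintf("(%d record(s) excluded: %s)\n", x$n_excluded,
                paste(x$exclude, collapse = ", ")))
  }
  invisible(x)
}

#' Column percentages of a contingency table
#'
#' Shares of each column's total, as percentages — the quantities printed
#' in parentheses in TMA cross-tabulations.
#'
#' @param table a `contingency_table` or count matrix.
#' @return numeric matrix of percentages.
#' @export
column_percentages <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else as.matrix(table)
  sweep(counts, 2, colSums(counts), "/") * 100
}

new_assoc_result <- function(method, statistic, df, p_value, table) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, table = table),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  lab <- c(pearson_chi2 = "Pearson chi-squared (no continuity correction)",
           fisher_exact = "Fisher exact (Freeman-Halton)")[x$method]
  cat(lab, "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  X-squared = %.4f, df = %d\n", x$statistic, x$df))
  }
  cat(sprintf("  p-value = %s\n", format_p(x$p_value)))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' The classical statistic `sum((O - E)^2 / E)` with expected counts
#' `row_total * col_total / N`, referred to a chi-squared distribution on
#' `(r - 1)(c - 1)` degrees of freedom. No continuity correction is
#' applied, matching the convention under which the published TMA
#' association p-values reproduce.
#'
#' @param table a `contingency_table` (or count matrix).
#' @return an `assoc_result` with `statistic`, `df` and `p_value`.
#' @export
pearson_chi2 <- function(table) {
  if (!inherits(table, "contingency_table")) table <- as_contingency_table(table)
  o <- table$counts
  rs <- rowSums(o); cs <- colSums(o); n <- sum(o)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column total; drop empty categories before testing",
         call. = FALSE)
  }
  e <- outer(rs, cs) / n
  stat <- sum((o - e)^2 / e)
  df <- (nrow(o) - 1L) * (ncol(o) - 1L)
  new_assoc_result("pearson_chi2", stat, df,
                   stats::pchisq(stat, df, lower.tail = FALSE), table)
}

#' Freeman–Halton Fisher exact test for r x c tables
#'
#' Exact test of independence conditional on both margins: enumerates every
#' table with the observed row and column totals, computes each table's
#' multivariate hypergeometric probability, and sums the probabilities of
#' all tables as or less probable than the observed one. Probabilities are
#' compared with a relative tolerance of 1e-7 so floating-point ties count
#' as ties. For 2 x 2 tables this reduces to Fisher's classical two-sided
#' test.
#'
#' @param table a `contingency_table` (or count matrix).
#' @param max_total guard on the grand total (default 500); larger tables
#'   are rejected with a suggestion to use [pearson_chi2()].
#' @return an `assoc_result`; `statistic` and `df` are `NA` (the test has
#'   no test statistic).
#' @export
fisher_exact_rxc <- function(table, max_total = 500) {
  if (!inherits(table, "contingency_table")) table <- as_contingency_table(table)
  o <- table$counts
  n <- sum(o)
  if (n == 0) stop("empty table", call. = FALSE)
  if (n > max_total) {
    stop(sprintf("N = %d exceeds the enumeration guard (%d); use pearson_chi2()",
                 n, max_total), call. = FALSE)
  }
  o <- o[rowSums(o) > 0, colSums(o) > 0, drop = FALSE]
  rs <- rowSums(o); cs <- colSums(o)
  lconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  lp_obs <- lconst - sum(lgamma(o + 1))
  tol <- log1p(1e-7)

  # Depth-first enumeration over cells in row-major order; the last cell of
  # each row and the whole last row are forced by the margins.
  r <- length(rs); cc <- length(cs)
  p_sum <- 0
  recurse <- function(i, j, row_rem, col_rem, lacc) {
    if (i == r) {                       # last row forced by column margins
      lp <- lacc + lconst - sum(lgamma(col_rem + 1))
      if (lp <= lp_obs + tol) p_sum <<- p_sum + exp(lp)
      return(invisible())
    }
    if (j == cc) {                      # last cell of row forced
      x <- row_rem
      if (x > col_rem[cc]) return(invisible())
      col_rem[cc] <- col_rem[cc] - x
      recurse(i + 1L, 1L, rs[i + 1L], col_rem, lacc - lgamma(x + 1))
      return(invisible())
    }
    for (x in 0:min(row_rem, col_rem[j])) {
      cr <- col_rem; cr[j] <- cr[j] - x
      recurse(i, j + 1L, row_rem - x, cr, lacc - lgamma(x + 1))
    }
  }
  if (r == 1L || cc == 1L) {
    p <- 1  # degenerate after dropping empty margins: only one table possible
  } else {
    recurse(1L, 1L, rs[1L], cs, 0)
    p <- min(p_sum, 1)
  }
  new_assoc_result("fisher_exact", NA_real_, NA_integer_, p, table)
}

#' Compare two assay condition samples with an unpaired t-test
#'
#' Two-sample t-test on per-cell or per-spheroid measurements (velocity,
#' displacement, migration index, CTCF). Equal variances are pooled by
#' default; set `var_equal = FALSE` for Welch's test. Degenerate input with
#' zero variance in both samples is handled explicitly: identical means
#' give p = 1, separated means p = 0.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param var_equal pool variances (default `TRUE`).
#' @return a list of class `condition_comparison` with `t`, `df`,
#'   `p_value`, `mean_diff` (mean_a - mean_b) and the group means.
#' @export
compare_conditions <- function(sample_a, sample_b, var_equal = TRUE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  diff <- mean(sample_a) - mean(sample_b)
  tol <- 1e-10 * max(abs(mean(sample_a)), abs(mean(sample_b)), 1)
  if (stats::sd(sample_a) <= tol && stats::sd(sample_b) <= tol) {
    near_zero <- abs(diff) <= tol
    res <- list(t = if (near_zero) 0 else sign(diff) * Inf,
                df = length(sample_a) + length(sample_b) - 2,
                p_value = if (near_zero) 1 else 0)
  } else {
    tt <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  structure(c(res, list(mean_diff = diff, mean_a = mean(sample_a),
                        mean_b = mean(sample_b), var_equal = var_equal)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Unpaired t-test (%s): t = %.3f, df = %.1f, p = %s\n",
              if (x$var_equal) "pooled variance" else "Welch",
              x$t, x$df, format_p(x$p_value)))
  cat(sprintf("  mean difference = %.4g (%.4g vs %.4g)\n",
              x$mean_diff, x$mean_a, x$mean_b))
  invisible(x)
}
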