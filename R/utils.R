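# Shared small helpers: rounding conventions, p-value formatting, input checks.

#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used when matching
#' p-values printed to a fixed number of decimals (base R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(0.025, 2)  # 0.03
#' round(0.025, 2)          # 0.02
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value the way result tables print it
#'
#' Three decimals by default, switching to scientific notation below 1e-4.
#'
#' @param p numeric vector of p-values.
#' @param digits decimals used for the fixed-notation range.
#' @return character vector.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(p < 1e-4,
         sprintf("%.2e", p),
         sprintf(paste0("%.", digits, "f"), round_half_up(p, digits)))
}

# Does computed p agree with a printed value such as "0.04" or "<0.001"?
# Matching is at the printed number of decimals, round half up.
p_matches_printed <- function(p, printed) {
  printed <- trimws(printed)
  if (is.na(printed) || printed == "" || toupper(printed) == "N/A") return(NA)
  if (startsWith(printed, "<")) {
    return(p < as.numeric(sub("^<", "", printed)))
  }
  digits <- nchar(sub("^[0-9]*\\.", "", printed))
  isTRUE(all.equal(round_half_up(p, digits), as.numeric(printed)))
}

stop_if_not_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lo, hi, x), call. = FALSE)
  }
  invisible(x)
}

# standard error of the mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
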