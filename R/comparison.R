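#' Bland-Altman agreement statistics
#'
#' Method agreement summarised on the per-pair ratio (`a/b`) or
#' difference (`a - b`): mean statistic, sample SD (n-1 denominator),
#' 95% confidence half-width of the mean (Student t,
#' `qt(0.975, n-1) * SD / sqrt(n)`), and 95% limits-of-agreement
#' half-width (`1.96 * SD`). Ratios require strictly positive
#' denominators; a difference is used instead when one method can
#' legitimately report zero (as the release rate k_b does).
#'
#' @param a,b Numeric vectors of equal length >= 3 (paired measurements
#'   of the same quantity by two methods).
#' @return List of class `"agreement"`: `n`, `mean_statistic`, `sd`,
#'   `ci95_halfwidth`, `loa95_halfwidth`, `kind`.
#' @examples
#' bland_altman_ratio(c(1.1, 2.2, 3.0), c(1, 2, 3))
#' @export
bland_altman_ratio <- function(a, b) {
  check_pairs(a, b)
  if (any(b <= 0)) {
    stop(sprintf("zero/negative denominator in pair %d",
                 which(b <= 0)[1L]), call. = FALSE)
  }
  agreement_summary(a / b, "ratio")
}

#' @rdname bland_altman_ratio
#' @export
bland_altman_difference <- function(a, b) {
  check_pairs(a, b)
  agreement_summary(a - b, "difference")
}

check_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite values in input series", call. = FALSE)
  }
  invisible(TRUE)
}

agreement_summary <- function(s, kind) {
  n <- length(s)
  sdv <- stats::sd(s)
  structure(list(n = n, mean_statistic = mean(s), sd = sdv,
                 ci95_halfwidth = stats::qt(0.975, n - 1) * sdv / sqrt(n),
                 loa95_halfwidth = 1.96 * sdv, kind = kind),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf(
    "<agreement> %s: mean %.4g +/- %.4g (95%% CI), LoA half-width %.4g (n=%d)\n",
    x$kind, x$mean_statistic, x$ci95_halfwidth, x$loa95_halfwidth, x$n))
  invisible(x)
}

#' Pearson correlation between paired series
#'
#' @param a,b Numeric vectors, equal length >= 3, each with non-zero
#'   variance.
#' @return Pearson R.
#' @export
pearson_r <- function(a, b) {
  check_pairs(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors, equal length >= 3, `x` with non-zero
#'   variance.
#' @return List with `slope`, `intercept`, `correlation`.
#' @export
ols_line <- function(x, y) {
  check_pairs(x, y)
  if (stats::sd(x) == 0) stop("degenerate x (zero variance)",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       correlation = stats::cor(x, y))
}

#' Column-wise mean and SD of a patient table
#'
#' Arithmetic mean and sample SD (n-1) of every numeric column except the
#' patient identifier, reproducing the summary rows of a per-patient
#' parameter table.
#'
#' @param records Data frame of patient records (see [table1_fixture()]).
#' @return Data frame with rows `mean` and `sd`.
#' @export
summarize_columns <- function(records) {
  num <- records[setdiff(names(records), "patient_id")]
  out <- rbind(mean = colMeans(num), sd = vapply(num, stats::sd, 0))
  as.data.frame(out)
}

#' Partition patients by trapping reversibility
#'
#' Splits the records on the fitted three-parameter release rate:
#' `kma3p_kb == 0` (irreversible trapping) versus `kma3p_kb > 0`
#' (reversible).
#'
#' @param records Data frame with a `kma3p_kb` column.
#' @return List with data frames `kb_zero` and `kb_positive`.
#' @export
split_by_reversibility <- function(records) {
  stopifnot("kma3p_kb" %in% names(records))
  pos <- records$kma3p_kb > 0
  list(kb_zero = records[!pos, , drop = FALSE],
       kb_positive = records[pos, , drop = FALSE])
}
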