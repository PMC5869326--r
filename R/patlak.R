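#' Patlak stretched-time transform
#'
#' Maps a tissue TAC onto Patlak coordinates using the fitted analytic
#' input function: for each tissue sample at time t,
#' `x = integral(A_p, 0..t) / A_p(t)` (the "stretched time", minutes) and
#' `y = A_T(t) / A_p(t)` (unitless). Under irreversible trapping the
#' points fall on a line with slope Ki and intercept V_b.
#'
#' Patlak theory contains no physical-decay term, so both curves are put
#' on the decay-corrected scale before transforming (conversion is applied
#' automatically whenever a flag differs). The running integral uses the
#' analytic model by default because the first frame only starts at
#' 5 min and the 0-5 min segment is unobserved; `integral = "trapezoid"`
#' instead accumulates trapezoids over the sampled IF values with the
#' analytic model filling in \[0, first sample\), for sensitivity checks.
#'
#' @param tissue Tissue [tac()].
#' @param model Fitted [if_model()].
#' @param constants [physical_constants()].
#' @param integral `"analytic"` (default) or `"trapezoid"`.
#' @return List of class `"patlak_points"` with `x`, `y`, `t` (original
#'   mid-times, minutes).
#' @export
stretched_time_transform <- function(tissue, model,
                                     constants = physical_constants(),
                                     integral = c("analytic", "trapezoid")) {
  stopifnot(inherits(tissue, "tac"), inherits(model, "if_model"))
  integral <- match.arg(integral)
  tissue <- decay_transform(tissue, constants, TRUE)
  model <- if_decay_transform(model, constants, TRUE)
  tt <- tissue$times
  ap <- eval_if(model, tt)
  if (any(ap <= 0)) stop("input function non-positive at a sample time",
                         call. = FALSE)
  if (integral == "analytic") {
    cum <- if_integral(model, tt)
  } else {
    head <- if_integral(model, tt[1L])  # analytic fill-in for [0, t1)
    cum <- head + c(0, cumsum(diff(tt) * (ap[-1L] + ap[-length(ap)]) / 2))
  }
  structure(list(x = cum / ap, y = tissue$activities / ap, t = tt),
            class = "patlak_points")
}

#' Patlak linear fit
#'
#' Ordinary least-squares line through the Patlak points; the slope is the
#' net influx constant Ki (mL/min/mL) and the intercept estimates V_b.
#'
#' @param points A `"patlak_points"` object from
#'   [stretched_time_transform()].
#' @return List of class `"patlak_fit"`: `Ki` (slope), `intercept`,
#'   `correlation` (Pearson R).
#' @examples
#' pts <- structure(list(x = 1:5, y = 0.04 * (1:5) + 0.01, t = 1:5),
#'                  class = "patlak_points")
#' patlak_fit(pts)$Ki
#' @export
patlak_fit <- function(points) {
  stopifnot(inherits(points, "patlak_points"))
  x <- points$x; y <- points$y
  if (length(x) < 3L) stop("need at least 3 Patlak points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate Patlak abscissa (zero variance)",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(Ki = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 correlation = stats::cor(x, y)),
            class = "patlak_fit")
}

#' One-call Patlak analysis of a tissue TAC
#'
#' Convenience wrapper: [stretched_time_transform()] followed by
#' [patlak_fit()].
#'
#' @inheritParams stretched_time_transform
#' @return A `"patlak_fit"` (with the points attached as attribute
#'   `"points"`).
#' @export
patlak_analysis <- function(tissue, model,
                            constants = physical_constants(),
                            integral = c("analytic", "trapezoid")) {
  pts <- stretched_time_transform(tissue, model, constants, integral)
  out <- patlak_fit(pts)
  attr(out, "points") <- pts
  out
}
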