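#' Tri-exponential input-function model
#'
#' The blood input function (IF) A_p(t) is modelled as a sum of three
#' decaying exponentials with fixed amplitude ratios 8.20 : 1.17 : 1 and a
#' fixed fast time constant alpha1 = 9.3363 /min (Hunter's whole-blood
#' values, on the decay-uncorrected scale):
#'
#'   A_p(t) = A0 * (8.20 exp(-9.3363 t) + 1.17 exp(-alpha2 t) + exp(-alpha3 t))
#'
#' Only A0 (virtual initial amplitude, kBq/mL) and the two slow time
#' constants alpha2 > alpha3 are patient-specific; the fast term carries
#' about 1% of the area under the curve, which is what justifies freezing
#' it at the population value.
#'
#' @param A0 Virtual initial amplitude, kBq/mL, > 0.
#' @param alpha2,alpha3 Slow time constants, 1/min, with
#'   `alpha1 > alpha2 > alpha3 > 0`.
#' @param alpha1 Fast time constant, 1/min. Fixed model constant; exposed
#'   only so a decay-state conversion can shift it.
#' @param amplitudes Amplitude triple. Fixed model constants.
#' @param decay_corrected Logical; the canonical form is decay-uncorrected
#'   (`FALSE`).
#' @return Object of class `"if_model"`.
#' @examples
#' m <- if_model(A0 = 16, alpha2 = 0.1574, alpha3 = 0.0145)
#' eval_if(m, 0)  # = 16 * (8.20 + 1.17 + 1) = 16 * 10.37
#' @export
if_model <- function(A0, alpha2, alpha3, alpha1 = 9.3363,
                     amplitudes = c(8.20, 1.17, 1.0),
                     decay_corrected = FALSE) {
  A0 <- as.numeric(A0)
  alphas <- as.numeric(c(alpha1, alpha2, alpha3))
  if (length(A0) != 1L || !is.finite(A0) || A0 <= 0) {
    stop("`A0` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(alphas)) || any(alphas <= 0) ||
      any(diff(alphas) >= 0)) {
    stop("time constants must satisfy alpha1 > alpha2 > alpha3 > 0",
         call. = FALSE)
  }
  if (length(amplitudes) != 3L || any(amplitudes <= 0)) {
    stop("`amplitudes` must be three positive numbers", call. = FALSE)
  }
  structure(list(A0 = A0, amplitudes = as.numeric(amplitudes),
                 alphas = alphas,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "if_model")
}

#' @export
print.if_model <- function(x, ...) {
  cat(sprintf(
    "<if_model> A0=%.4g kBq/mL, alphas=(%.4f, %.4f, %.4f)/min, decay-%s\n",
    x$A0, x$alphas[1], x$alphas[2], x$alphas[3],
    if (x$decay_corrected) "corrected" else "uncorrected"))
  invisible(x)
}

#' Convert an IF model between decay states
#'
#' Multiplying a sum of exponentials by `exp(+lambda t)` (decay
#' correction) shifts every time constant by `-lambda`, so the converted
#' model stays in the same family. All three shifted constants must remain
#' positive.
#'
#' @param model An [if_model()].
#' @param constants [physical_constants()].
#' @param target_state Desired `decay_corrected` flag.
#' @return An [if_model()] in the requested state.
#' @export
if_decay_transform <- function(model, constants, target_state) {
  stopifnot(inherits(model, "if_model"))
  if (identical(model$decay_corrected, isTRUE(target_state))) return(model)
  shift <- if (target_state) -constants$lambda_decay else
    +constants$lambda_decay
  a <- model$alphas + shift
  if (any(a <= 0)) {
    stop("decay transform would make a time constant non-positive",
         call. = FALSE)
  }
  if_model(model$A0, a[2], a[3], alpha1 = a[1],
           amplitudes = model$amplitudes,
           decay_corrected = isTRUE(target_state))
}

#' Evaluate the input function
#'
#' @param model An [if_model()].
#' @param t Times in minutes, all >= 0 (vectorised).
#' @return Activity concentration(s), kBq/mL.
#' @export
eval_if <- function(model, t) {
  stopifnot(inherits(model, "if_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  E <- exp(-outer(model$alphas, t))           # 3 x length(t)
  model$A0 * as.numeric(crossprod(model$amplitudes, E))
}

#' Running integral of the input function
#'
#' Analytic antiderivative `A0 * sum_i c_i (1 - exp(-alpha_i t))/alpha_i`;
#' `t = Inf` gives the total area under the curve.
#'
#' @inheritParams eval_if
#' @return Integral(s) from 0 to `t`, kBq/mL * min.
#' @export
if_integral <- function(model, t) {
  stopifnot(inherits(model, "if_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  G <- (1 - exp(-outer(model$alphas, t))) / model$alphas  # t=Inf -> 1/alpha
  model$A0 * as.numeric(crossprod(model$amplitudes, G))
}

#' Area-under-curve share of each exponential term
#'
#' Fraction of the total IF area (number of tracer molecules made
#' available to tissue) carried by each of the three exponentials:
#' `100 * (c_i/alpha_i) / sum_j (c_j/alpha_j)`.
#'
#' @param model An [if_model()].
#' @return Numeric vector of three percentages summing to 100.
#' @examples
#' # cohort-mean slow constants: fast term carries only ~1.1% of the AUC
#' if_auc_fractions(if_model(16, 0.1574, 0.0145))
#' @export
if_auc_fractions <- function(model) {
  stopifnot(inherits(model, "if_model"))
  w <- model$amplitudes / model$alphas
  100 * w / sum(w)
}

#' Fit the tri-exponential model to a measured input function
#'
#' Least-squares fit of (A0, alpha2, alpha3) to a decay-uncorrected blood
#' TAC; the amplitude ratios and alpha1 are held at their fixed values.
#' Residuals are unweighted. Box bounds (`alpha2` in \[0.02, 2\],
#' `alpha3` in \[0.001, 0.1\]) keep the two slow exponentials from
#' swapping roles.
#'
#' @param x A blood [tac()]. Converted to decay-uncorrected form if
#'   flagged corrected.
#' @param constants [physical_constants()], used only for decay
#'   conversion.
#' @param init Optional [if_model()] providing starting values.
#' @return List of class `"if_fit"`: `model` (fitted [if_model()]),
#'   `correlation` (Pearson R between fit and data), `residuals`
#'   (fitted - observed, kBq/mL), `converged`.
#' @export
fit_if <- function(x, constants = physical_constants(), init = NULL) {
  stopifnot(inherits(x, "tac"))
  if (length(x$times) < 4L) {
    stop("need at least 4 IF samples to fit 3 parameters", call. = FALSE)
  }
  x <- decay_transform(x, constants, FALSE)
  tt <- x$times
  yy <- x$activities
  lower <- c(1e-8, 0.02, 0.001)
  upper <- c(Inf, 2, 0.1)
  if (is.null(init)) {
    a3_0 <- 0.015
    a2_0 <- 0.15
    A0_0 <- max(yy[length(yy)], 1e-6) / exp(-a3_0 * tt[length(tt)])
    p0 <- c(A0_0, a2_0, a3_0)
  } else {
    stopifnot(inherits(init, "if_model"))
    p0 <- c(init$A0, init$alphas[2], init$alphas[3])
  }
  p0 <- pmin(pmax(p0, lower), upper)
  resid_fn <- function(p) {
    m <- p[1] * (8.20 * exp(-9.3363 * tt) + 1.17 * exp(-p[2] * tt) +
                   exp(-p[3] * tt))
    m - yy
  }
  fit <- lm_bounded(resid_fn, p0, lower, upper)
  # enforce the alpha2 > alpha3 ordering contract
  ok_order <- fit$par[2] > fit$par[3]
  model <- if_model(fit$par[1], max(fit$par[2], fit$par[3] + 1e-9),
                    min(fit$par[2], fit$par[3]))
  fitted <- eval_if(model, tt)
  structure(list(model = model,
                 correlation = fit_correlation(fitted, yy),
                 residuals = fitted - yy,
                 converged = fit$converged && ok_order),
            class = "if_fit")
}
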