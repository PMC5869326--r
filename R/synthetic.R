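#' Per-patient fitted-parameter table of the 21-patient lung cancer cohort
#'
#' The packaged transcription of the published per-patient fitting
#' results: input-function parameters (A0, alpha2, alpha3), Patlak Ki,
#' three-parameter model estimates (Ki, k_b, V_b) and five-parameter
#' model estimates (K1, k2, k3, k4, derived Ki and k_b, V_b) for all 21
#' patients. A checksum over every numeric entry guards the packaged file
#' against silent corruption.
#'
#' @return Data frame with 21 rows and 15 columns (`patient_id` plus 14
#'   numeric parameter columns).
#' @examples
#' head(table1_fixture())
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_patients.csv", package = "tackit",
                      mustWork = TRUE)
  d <- utils::read.csv(path)
  if (nrow(d) != 21L || ncol(d) != 15L ||
      abs(sum(as.matrix(d)) - 601.2722) > 1e-8) {
    stop("packaged patient table failed its checksum", call. = FALSE)
  }
  d
}

#' Noise model for synthetic TACs
#'
#' Multiplicative Gaussian noise: each sampled activity y is replaced by
#' `max(0, y * (1 + coefficient * Z))` with independent standard-normal
#' Z. Chosen over Poisson because TACs are calibrated concentrations, not
#' counts; the default coefficient 0.05 is a plausible stand-in for the
#' unknown measurement noise of small hot-voxel VOIs.
#'
#' @param kind `"none"` or `"multiplicative-gaussian"`.
#' @param coefficient Fractional SD (SD = coefficient * value), >= 0.
#' @param seed Integer RNG seed used by [generate_case()].
#' @return List of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("none", "multiplicative-gaussian"),
                        coefficient = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  if (coefficient < 0) stop("`coefficient` must be >= 0", call. = FALSE)
  structure(list(kind = kind, coefficient = as.numeric(coefficient),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic kinetic test case
#'
#' Bundles one generative truth (either a three-parameter
#' `c(Ki, k_b, V_b)` or a five-parameter `c(K1, k2, k3, k4, V_b)` set,
#' never both), an input-function model, a frame scheme and a noise
#' model.
#'
#' @param if_model An [if_model()].
#' @param truth_3p Numeric `c(Ki, k_b, V_b)`, or `NULL`.
#' @param truth_5p Numeric `c(K1, k2, k3, k4, V_b)`, or `NULL`.
#' @param scheme A [frame_scheme()]; defaults to the 11-frame late scheme
#'   for 3P truths and the dense bolus scheme for 5P truths.
#' @param noise A [noise_model()].
#' @param label Free-text case label.
#' @return List of class `"synthetic_case"`.
#' @export
synthetic_case <- function(if_model, truth_3p = NULL, truth_5p = NULL,
                           scheme = NULL, noise = noise_model("none"),
                           label = "") {
  stopifnot(inherits(if_model, "if_model"), inherits(noise, "noise_model"))
  if (is.null(truth_3p) == is.null(truth_5p)) {
    stop("give exactly one of `truth_3p` or `truth_5p`", call. = FALSE)
  }
  if (!is.null(truth_3p) && length(truth_3p) != 3L) {
    stop("`truth_3p` must be c(Ki, k_b, V_b)", call. = FALSE)
  }
  if (!is.null(truth_5p) && length(truth_5p) != 5L) {
    stop("`truth_5p` must be c(K1, k2, k3, k4, V_b)", call. = FALSE)
  }
  if (is.null(scheme)) {
    scheme <- if (is.null(truth_5p)) default_frame_scheme() else
      dense_frame_scheme()
  }
  structure(list(if_model = if_model, truth_3p = truth_3p,
                 truth_5p = truth_5p, scheme = scheme, noise = noise,
                 label = as.character(label)[1L]),
            class = "synthetic_case")
}

#' Generate a synthetic blood/tissue TAC pair
#'
#' Samples the input function and the corresponding tissue model (three-
#' or five-parameter, per the case truth) at the frame mid-times of the
#' case scheme, applies the case noise model with its seed (IF and tissue
#' noise independent), and returns both curves flagged decay-uncorrected.
#' Generation is deterministic given the seed, and the caller's RNG state
#' is left untouched.
#'
#' @param case A [synthetic_case()].
#' @param constants [physical_constants()].
#' @return List with elements `if_tac` and `tissue_tac`, both [tac()].
#' @export
generate_case <- function(case, constants = physical_constants()) {
  stopifnot(inherits(case, "synthetic_case"))
  tt <- case$scheme$mid
  if_clean <- eval_if(if_decay_transform(case$if_model, constants, FALSE),
                      tt)
  tissue_clean <- if (!is.null(case$truth_3p)) {
    tissue_model_3p(tt, case$truth_3p[1], case$truth_3p[2],
                    case$truth_3p[3], case$if_model, constants)
  } else {
    tissue_model_5p(tt, case$truth_5p[1], case$truth_5p[2],
                    case$truth_5p[3], case$truth_5p[4], case$truth_5p[5],
                    case$if_model, constants)
  }
  if (case$noise$kind == "none") {
    if_noisy <- if_clean
    tissue_noisy <- tissue_clean
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(case$noise$seed)
    cv <- case$noise$coefficient
    if_noisy <- pmax(0, if_clean * (1 + cv * stats::rnorm(length(tt))))
    tissue_noisy <- pmax(0, tissue_clean *
                           (1 + cv * stats::rnorm(length(tt))))
  }
  list(if_tac = tac(tt, if_noisy, decay_corrected = FALSE,
                    durations = case$scheme$duration,
                    label = paste0(case$label, " IF")),
       tissue_tac = tac(tt, tissue_noisy, decay_corrected = FALSE,
                        durations = case$scheme$duration,
                        label = paste0(case$label, " tissue")))
}

#' Build a synthetic cohort from the packaged patient table
#'
#' One three-parameter synthetic case per patient, using that row's
#' fitted (A0, alpha2, alpha3) as the input-function truth and its
#' (Ki, k_b, V_b) as the kinetic truth, on the default 11-frame scheme.
#' Each case gets a distinct deterministic seed derived from the noise
#' model's seed.
#'
#' @param noise A [noise_model()].
#' @return List of 21 [synthetic_case()] objects.
#' @export
cohort_from_fixture <- function(noise = noise_model("none")) {
  d <- table1_fixture()
  lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    ni <- noise
    ni$seed <- noise$seed + i
    synthetic_case(
      if_model(r$A0, r$alpha2, r$alpha3),
      truth_3p = c(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb),
      noise = ni,
      label = sprintf("patient %d", r$patient_id))
  })
}
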