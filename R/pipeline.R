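#' Reproduce the full cohort comparison
#'
#' Runs the package's two reproduction branches and returns one report.
#'
#' The *fixture branch* recomputes every cohort statistic directly from
#' the packaged 21-patient parameter table: Bland-Altman ratio agreement
#' of the three-parameter model's Ki against Patlak's Ki (whole cohort
#' and the irreversible-trapping subset), the five-parameter comparisons,
#' the Ki-ratio-versus-k_b correlation and regression line, and the
#' column summaries. Nothing in this branch depends on refitting.
#'
#' The *synthetic branch* forward-simulates each patient's TAC pair from
#' the table's parameters, refits the input function, Patlak line and
#' three-parameter model, and reports parameter-recovery errors plus the
#' Patlak-underestimation trend (correlation between generating k_b and
#' the 3P/Patlak Ki ratio of the refits).
#'
#' @param config List of options: `noise` (fractional noise coefficient,
#'   default 0 = noise-free), `seed` (integer), `include_5p` (logical;
#'   also refit the five-parameter model on dense synthetic data, slower),
#'   `half_life` (minutes).
#' @param out Optional path; when given the report is written as JSON.
#' @return List of class `"pipeline_report"` with elements `provenance`,
#'   `fixture_stats`, `synthetic` (per-patient refits and recovery
#'   summaries).
#' @export
run_reproduction <- function(config = list(), out = NULL) {
  cfg <- utils::modifyList(
    list(noise = 0, seed = 1L, include_5p = FALSE, half_life = 109.77),
    config)
  pc <- physical_constants(cfg$half_life)
  d <- table1_fixture()

  ratio_all <- bland_altman_ratio(d$kma3p_Ki, d$patlak_Ki)
  parts <- split_by_reversibility(d)
  sub <- parts$kb_zero
  ratio_sub <- bland_altman_ratio(sub$kma3p_Ki, sub$patlak_Ki)
  ki_ratio <- d$kma3p_Ki / d$patlak_Ki
  trend <- ols_line(d$kma3p_kb, ki_ratio)
  fixture_stats <- list(
    n = nrow(d),
    n_kb_positive = nrow(parts$kb_positive),
    ki_ratio_3p_patlak = unclass(ratio_all),
    ki_ratio_3p_patlak_kb_zero = unclass(ratio_sub),
    ki_ratio_vs_kb = trend,
    pearson_ki_3p_patlak = pearson_r(d$kma3p_Ki, d$patlak_Ki),
    pearson_ki_3p_5p = pearson_r(d$kma3p_Ki, d$ki_5p),
    ki_ratio_5p_patlak = unclass(bland_altman_ratio(d$ki_5p, d$patlak_Ki)),
    ki_ratio_3p_5p = unclass(bland_altman_ratio(d$kma3p_Ki, d$ki_5p)),
    kb_diff_3p_5p = unclass(bland_altman_difference(d$kma3p_kb, d$kb_5p)),
    column_summary = summarize_columns(d))

  noise <- if (cfg$noise > 0) {
    noise_model("multiplicative-gaussian", cfg$noise, cfg$seed)
  } else noise_model("none", seed = cfg$seed)
  cohort <- cohort_from_fixture(noise)
  per_patient <- lapply(seq_along(cohort), function(i) {
    case <- cohort[[i]]
    tacs <- generate_case(case, pc)
    iff <- fit_if(tacs$if_tac, pc)
    pk <- patlak_analysis(tacs$tissue_tac, iff$model, pc)
    f3 <- fit_3p(tacs$tissue_tac, iff$model, pc)
    row <- list(patient_id = d$patient_id[i],
                true_Ki = case$truth_3p[1], true_kb = case$truth_3p[2],
                true_Vb = case$truth_3p[3],
                if_R = iff$correlation,
                patlak_Ki = pk$Ki, kma3p_Ki = f3$Ki, kma3p_kb = f3$k_b,
                kma3p_Vb = f3$V_b, kma3p_R = f3$correlation)
    if (isTRUE(cfg$include_5p)) {
      r <- d[i, ]
      c5 <- synthetic_case(if_model(r$A0, r$alpha2, r$alpha3),
                           truth_5p = c(r$k1_5p, r$k2_5p, r$k3_5p,
                                        r$k4_5p, r$vb_5p),
                           noise = case$noise)
      t5 <- generate_case(c5, pc)
      f5 <- fit_5p(t5$tissue_tac, iff$model, pc)
      row$kma5p_Ki <- f5$Ki_macro
      row$kma5p_kb <- f5$kb_macro
    }
    row
  })
  pp <- do.call(rbind, lapply(per_patient, function(x)
    as.data.frame(x[!vapply(x, is.null, TRUE)])))
  rel_err <- abs(pp$kma3p_Ki - pp$true_Ki) / pp$true_Ki
  refit_ratio <- pp$kma3p_Ki / pp$patlak_Ki
  synthetic <- list(
    per_patient = pp,
    max_rel_err_Ki_3p = max(rel_err),
    underestimation_trend_r = stats::cor(pp$true_kb, refit_ratio,
                                         method = "spearman"))

  report <- structure(list(
    provenance = list(
      package = "tackit",
      version = as.character(utils::packageVersion("tackit")),
      seed = cfg$seed, config = cfg,
      generated = "deterministic given seed and config"),
    fixture_stats = fixture_stats,
    synthetic = synthetic), class = "pipeline_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  fs <- x$fixture_stats
  cat("== cohort reproduction report ==\n")
  cat(sprintf("patients: %d (%d with k_b > 0)\n", fs$n, fs$n_kb_positive))
  cat(sprintf("3P/Patlak Ki ratio: %.3f +/- %.3f (CI), LoA %.3f\n",
              fs$ki_ratio_3p_patlak$mean_statistic,
              fs$ki_ratio_3p_patlak$ci95_halfwidth,
              fs$ki_ratio_3p_patlak$loa95_halfwidth))
  cat(sprintf("  k_b = 0 subset:   %.3f +/- %.3f (CI), LoA %.3f\n",
              fs$ki_ratio_3p_patlak_kb_zero$mean_statistic,
              fs$ki_ratio_3p_patlak_kb_zero$ci95_halfwidth,
              fs$ki_ratio_3p_patlak_kb_zero$loa95_halfwidth))
  cat(sprintf("Ki ratio vs k_b: slope %.3f, intercept %.3f, R %.3f\n",
              fs$ki_ratio_vs_kb$slope, fs$ki_ratio_vs_kb$intercept,
              fs$ki_ratio_vs_kb$correlation))
  cat(sprintf("5P/Patlak ratio %.3f, 3P/5P ratio %.3f, |kb diff| %.5f\n",
              fs$ki_ratio_5p_patlak$mean_statistic,
              fs$ki_ratio_3p_5p$mean_statistic,
              abs(fs$kb_diff_3p_5p$mean_statistic)))
  cat(sprintf("synthetic refit: max rel. Ki error %.2e, trend rho %.2f\n",
              x$synthetic$max_rel_err_Ki_3p,
              x$synthetic$underestimation_trend_r))
  invisible(x)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `reproduce`, `simulate`, `fit-if`,
#' `fit-patlak`, `fit-3p`, `fit-5p` and `fixture`. Used by the installed
#' `exec/tackit` script; callable directly as
#' `tackit_cli(c("reproduce", "--out", "report.json"))`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
tackit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tackit <command> [options]",
    "  reproduce  [--noise x] [--seed n] [--out report.json]",
    "  simulate   --patient n [--noise x] [--seed n] --out-prefix p",
    "  fit-if     <tac.csv> [--out model.json]",
    "  fit-patlak <tissue.csv> --if-model model.json [--out fit.json]",
    "  fit-3p     <tissue.csv> --if-model model.json [--out fit.json]",
    "  fit-5p     <tissue.csv> --if-model model.json [--out fit.json]",
    "  fixture    [--out table1.csv]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (!length(i)) return(default)
    rest[i[1L] + 1L]
  }
  positional <- function() {
    flags <- grep("^--", rest)
    drop <- unique(c(flags, flags + 1L))
    p <- if (length(drop)) rest[-drop] else rest
    if (!length(p)) stop("missing input file argument", call. = FALSE)
    p[1L]
  }
  emit <- function(x, out) {
    if (is.null(out)) {
      cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE), "\n")
    } else {
      jsonlite::write_json(x, out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      message("wrote ", out)
    }
  }
  pc <- physical_constants()
  load_if_model <- function() {
    path <- opt("if-model")
    if (is.null(path)) stop("--if-model is required", call. = FALSE)
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if_model(j$A0, j$alpha2, j$alpha3)
  }
  status <- 0L
  switch(cmd,
    "reproduce" = {
      rep <- run_reproduction(
        list(noise = as.numeric(opt("noise", "0")),
             seed = as.integer(opt("seed", "1"))),
        out = opt("out"))
      print(rep)
    },
    "simulate" = {
      i <- as.integer(opt("patient"))
      noise_cv <- as.numeric(opt("noise", "0"))
      nm <- if (noise_cv > 0)
        noise_model("multiplicative-gaussian", noise_cv,
                    as.integer(opt("seed", "1"))) else noise_model("none")
      case <- {
        d <- table1_fixture()
        r <- d[d$patient_id == i, ]
        if (!nrow(r)) stop("no such patient", call. = FALSE)
        synthetic_case(if_model(r$A0, r$alpha2, r$alpha3),
                       truth_3p = c(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb),
                       noise = nm, label = sprintf("patient %d", i))
      }
      tacs <- generate_case(case, pc)
      prefix <- opt("out-prefix", sprintf("patient%d", i))
      write_tac(tacs$if_tac, paste0(prefix, "_if.csv"))
      write_tac(tacs$tissue_tac, paste0(prefix, "_tissue.csv"))
      message("wrote ", prefix, "_if.csv and ", prefix, "_tissue.csv")
    },
    "fit-if" = {
      res <- fit_if(read_tac(positional()), pc)
      emit(list(A0 = res$model$A0, alpha1 = res$model$alphas[1],
                alpha2 = res$model$alphas[2], alpha3 = res$model$alphas[3],
                amplitudes = res$model$amplitudes,
                correlation = res$correlation, converged = res$converged),
           opt("out"))
    },
    "fit-patlak" = {
      res <- patlak_analysis(read_tac(positional()), load_if_model(), pc,
                             integral = opt("integral", "analytic"))
      emit(res[c("Ki", "intercept", "correlation")], opt("out"))
    },
    "fit-3p" = {
      res <- fit_3p(read_tac(positional()), load_if_model(), pc)
      emit(res[c("Ki", "k_b", "V_b", "correlation", "converged")],
           opt("out"))
    },
    "fit-5p" = {
      res <- fit_5p(read_tac(positional()), load_if_model(), pc)
      emit(res[c("K1", "k2", "k3", "k4", "V_b", "Ki_macro", "kb_macro",
                 "correlation", "converged")], opt("out"))
    },
    "fixture" = {
      d <- table1_fixture()
      out <- opt("out")
      if (is.null(out)) print(d) else {
        utils::write.csv(d, out, row.names = FALSE)
        message("wrote ", out)
      }
    },
    {
      message("unknown command: ", cmd, "\n", usage)
      status <- 1L
    })
  invisible(status)
}
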