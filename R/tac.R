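#' Time-activity curve
#'
#' Container for a sampled tracer time-activity curve (TAC): activity
#' concentration (kBq/mL) versus frame mid-time (minutes post-injection).
#' The physical-decay state of the activities is always explicit; every
#' downstream analysis checks the flag and converts rather than assuming.
#'
#' @param times Frame mid-times in minutes post-injection, strictly
#'   increasing.
#' @param activities Activity concentrations in kBq/mL, non-negative, same
#'   length as `times`.
#' @param decay_corrected Logical flag: `TRUE` if the activities have been
#'   corrected for physical decay of the isotope, `FALSE` if they are raw
#'   (decaying) measurements. Mandatory; there is no default.
#' @param durations Optional frame durations in minutes (one per frame).
#' @param label Optional free-text label.
#' @return An object of class `"tac"`: a list with fields `times`,
#'   `activities`, `durations`, `decay_corrected`, `label`.
#' @examples
#' fs <- default_frame_scheme()
#' tac(fs$mid, exp(-0.01 * fs$mid) * 20, decay_corrected = FALSE,
#'     durations = fs$stop - fs$start, label = "demo")
#' @export
tac <- function(times, activities, decay_corrected, durations = NULL,
                label = "") {
  times <- as.numeric(times)
  activities <- as.numeric(activities)
  if (missing(decay_corrected) || length(decay_corrected) != 1L ||
      is.na(decay_corrected) || !is.logical(decay_corrected)) {
    stop("`decay_corrected` must be given explicitly as TRUE or FALSE",
         call. = FALSE)
  }
  if (length(times) != length(activities)) {
    stop("`times` and `activities` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty TAC", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(activities))) {
    stop("non-finite values in TAC", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (violated at sample %d)",
                 bad), call. = FALSE)
  }
  if (any(activities < 0)) {
    bad <- which(activities < 0)[1L]
    stop(sprintf("negative activity at sample %d", bad), call. = FALSE)
  }
  if (!is.null(durations)) {
    durations <- as.numeric(durations)
    if (length(durations) != length(times) || any(durations <= 0)) {
      stop("`durations` must be positive and one per frame", call. = FALSE)
    }
  }
  structure(list(times = times, activities = activities,
                 durations = durations,
                 decay_corrected = decay_corrected,
                 label = as.character(label)[1L]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, %.1f-%.1f min, decay-%s%s\n",
              length(x$times), min(x$times), max(x$times),
              if (x$decay_corrected) "corrected" else "uncorrected",
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Physical decay constants for the imaging isotope
#'
#' @param half_life Isotope half-life in minutes. Default 109.77 min, the
#'   standard value for fluorine-18.
#' @return List with `half_life` (min) and `lambda_decay` (1/min),
#'   `lambda_decay = log(2)/half_life`.
#' @examples
#' physical_constants()$lambda_decay  # ~0.006315 per minute
#' @export
physical_constants <- function(half_life = 109.77) {
  half_life <- as.numeric(half_life)
  if (length(half_life) != 1L || !is.finite(half_life) || half_life <= 0) {
    stop("`half_life` must be a single positive number (minutes)",
         call. = FALSE)
  }
  list(half_life = half_life, lambda_decay = log(2) / half_life)
}

#' Frame scheme
#'
#' A set of non-overlapping acquisition frames given by start/stop times;
#' samples are assigned the frame mid-time.
#'
#' @param start,stop Frame start and stop times in minutes.
#' @return List of class `"frame_scheme"` with `start`, `stop`, `mid` and
#'   `duration` vectors (minutes).
#' @export
frame_scheme <- function(start, stop) {
  start <- as.numeric(start); stop <- as.numeric(stop)
  if (length(start) != length(stop) || any(stop <= start)) {
    stop("each frame needs stop > start", call. = FALSE)
  }
  if (length(start) > 1L && any(start[-1L] < stop[-length(stop)])) {
    stop("frames must not overlap", call. = FALSE)
  }
  structure(list(start = start, stop = stop, mid = (start + stop) / 2,
                 duration = stop - start),
            class = "frame_scheme")
}

#' Default late dynamic frame scheme
#'
#' Eleven 5-minute frames covering 5-60 minutes post-injection, i.e. frame
#' mid-times 7.5, 12.5, ..., 57.5 min: the late-acquisition protocol the
#' Patlak and three-parameter analyses operate on.
#'
#' @return A [frame_scheme()] with 11 frames.
#' @examples
#' default_frame_scheme()$mid
#' @export
default_frame_scheme <- function() {
  start <- seq(5, 55, by = 5)
  frame_scheme(start, start + 5)
}

#' Dense early-sampling frame scheme
#'
#' Bolus-phase scheme used for five-parameter fits, which need the early
#' kinetics: 12 x 5 s, 6 x 10 s, 8 x 30 s, then 5-min frames to 60 min
#' (final frame 4 min). A typical clinical dynamic protocol; the precise
#' short-frame timing is a package choice.
#'
#' @return A [frame_scheme()] with 37 frames spanning 0-60 min.
#' @export
dense_frame_scheme <- function() {
  start <- c(seq(0, 55 / 60, by = 5 / 60),         # 12 x 5 s
             seq(1, 1 + 50 / 60, by = 10 / 60),    # 6 x 10 s
             seq(2, 5.5, by = 0.5),                # 8 x 30 s
             seq(6, 51, by = 5), 56)               # 5-min frames + tail
  stop <- c(start[-1L], 60)
  frame_scheme(start, stop)
}

#' Convert a TAC between decay-corrected and decay-uncorrected states
#'
#' Correcting multiplies activities by `exp(+lambda * t)`; uncorrecting by
#' `exp(-lambda * t)`, evaluated at the frame mid-times. If the TAC is
#' already in the requested state it is returned unchanged. The two
#' directions are exact inverses.
#'
#' @param x A [tac()].
#' @param constants A [physical_constants()] list.
#' @param target_state Logical: desired `decay_corrected` flag.
#' @return A [tac()] in the requested decay state.
#' @examples
#' pc <- physical_constants()
#' raw <- tac(30, 10, decay_corrected = FALSE)
#' decay_transform(raw, pc, TRUE)$activities  # 10 * exp(pc$lambda_decay * 30)
#' @export
decay_transform <- function(x, constants, target_state) {
  stopifnot(inherits(x, "tac"))
  if (!is.logical(target_state) || length(target_state) != 1L ||
      is.na(target_state)) {
    stop("`target_state` must be TRUE or FALSE", call. = FALSE)
  }
  if (identical(x$decay_corrected, target_state)) return(x)
  sign <- if (target_state) +1 else -1
  act <- x$activities * exp(sign * constants$lambda_decay * x$times)
  if (any(!is.finite(act))) {
    stop("non-finite activity after decay transform", call. = FALSE)
  }
  out <- x
  out$activities <- act
  out$decay_corrected <- target_state
  out
}

#' Read / write TAC files
#'
#' Plain CSV with columns `t_mid_min`, `frame_len_min` (optional),
#' `activity_kBq_per_mL`, preceded by comment metadata lines
#' `# decay_corrected: true|false` (mandatory) and `# label: ...`
#' (optional). Unknown columns are preserved through a read/write round
#' trip.
#'
#' @param path File path.
#' @return `read_tac()` returns a [tac()]; `write_tac()` returns `path`
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_tac(tac(c(1, 2), c(5, 4), decay_corrected = TRUE), p)
#' read_tac(p)
#' @export
read_tac <- function(path) {
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines)
  header <- lines[meta]
  get_meta <- function(key) {
    hit <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), header, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^\\s*#\\s*", key, "\\s*:\\s*"), "", hit[1L]))
  }
  dc <- get_meta("decay_corrected")
  if (is.null(dc) || !tolower(dc) %in% c("true", "false")) {
    stop(sprintf("%s: missing '# decay_corrected: true|false' metadata line",
                 path), call. = FALSE)
  }
  label <- get_meta("label")
  body <- if (length(meta)) lines[-meta] else lines
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  need <- c("t_mid_min", "activity_kBq_per_mL")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  # data line numbers in the original file, for error messages
  data_lines <- setdiff(seq_along(lines), meta)
  data_lines <- data_lines[nzchar(trimws(lines[data_lines]))][-1L]
  tvec <- df$t_mid_min
  if (any(diff(tvec) <= 0)) {
    bad <- which(diff(tvec) <= 0)[1L] + 1L
    stop(sprintf("%s line %d: times not strictly increasing", path,
                 data_lines[bad]), call. = FALSE)
  }
  if (any(df$activity_kBq_per_mL < 0)) {
    bad <- which(df$activity_kBq_per_mL < 0)[1L]
    stop(sprintf("%s line %d: negative activity", path, data_lines[bad]),
         call. = FALSE)
  }
  out <- tac(tvec, df$activity_kBq_per_mL,
             decay_corrected = identical(tolower(dc), "true"),
             durations = if ("frame_len_min" %in% names(df))
               df$frame_len_min else NULL,
             label = if (is.null(label)) "" else label)
  extra <- setdiff(names(df), c(need, "frame_len_min"))
  if (length(extra)) attr(out, "extra_columns") <- df[extra]
  out
}

#' @rdname read_tac
#' @param x A [tac()] to write.
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(t_mid_min = x$times, check.names = FALSE)
  if (!is.null(x$durations)) df$frame_len_min <- x$durations
  df$activity_kBq_per_mL <- x$activities
  extra <- attr(x, "extra_columns")
  if (!is.null(extra)) df <- cbind(df, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# tackit TAC v1",
               paste0("# decay_corrected: ",
                      if (x$decay_corrected) "true" else "false"),
               if (nzchar(x$label)) paste0("# label: ", x$label)), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
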