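# File I/O: an internal versioned CSV for traces and trial tables, plus a
# minimal EyeLink-ASC-like text dialect (tab-separated SAMPLES lines with
# MSG event markers, "." for signal loss during blinks).

TRACE_SCHEMA <- "gazebias-trace-v1"
TRIALS_SCHEMA <- "gazebias-trials-v1"

#' Write eye traces to the internal CSV format
#'
#' Columns `t_ms, x_deg, y_deg, trial_id` under a versioned schema header.
#'
#' @param traces A single [eye_trace()] or a named/numbered list of them.
#' @param path Output file.
#' @export
write_trace <- function(traces, path) {
  if (inherits(traces, "eye_trace")) traces <- list(traces)
  ids <- if (is.null(names(traces))) seq_along(traces) else names(traces)
  df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(t_ms = tr$t, x_deg = tr$x, y_deg = tr$y, trial_id = ids[i])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TRACE_SCHEMA, " | units: ms, deg"), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read eye traces from the internal CSV format
#'
#' @param path Input file written by [write_trace()].
#' @return A list of [eye_trace()] objects, one per `trial_id`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl(TRACE_SCHEMA, first, fixed = TRUE)) {
    stop("not a ", TRACE_SCHEMA, " file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_ms", "x_deg", "y_deg", "trial_id")
  if (!all(need %in% names(df))) {
    stop("trace file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$trial_id), function(d) {
    eye_trace(d$t_ms, d$x_deg, d$y_deg)
  })
}

#' Write a trial table to the internal CSV format
#'
#' @param trials Data frame of trial records.
#' @param path Output file.
#' @export
write_trials <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TRIALS_SCHEMA), con)
  utils::write.csv(trials, con, row.names = FALSE)
}

#' Read a trial table from the internal CSV format
#'
#' @param path Input file written by [write_trials()].
#' @return Data frame.
#' @export
read_trials <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl(TRIALS_SCHEMA, first, fixed = TRUE)) {
    stop("not a ", TRIALS_SCHEMA, " file: ", path, call. = FALSE)
  }
  utils::read.csv(path, comment.char = "#")
}

#' Write an eye trace in a minimal ASC-like dialect
#'
#' Tab-separated sample lines `time x y` with `MSG time label` marker lines
#' interleaved at the correct timestamps; lost samples (NA) are written as
#' `.` fields, as in blink records.
#'
#' @param trace An [eye_trace()].
#' @param path Output file.
#' @export
write_asc <- function(trace, path) {
  stopifnot(inherits(trace, "eye_trace"))
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.4f", v), ".")
  lines <- sprintf("%g\t%s\t%s", trace$t, fmt(trace$x), fmt(trace$y))
  if (length(trace$markers)) {
    msg <- sprintf("MSG\t%g\t%s", trace$markers, names(trace$markers))
    pos <- findInterval(trace$markers, trace$t)
    # insert after the sample at/just before each marker time
    out <- character(0)
    prev <- 0L
    ord <- order(pos)
    for (j in ord) {
      out <- c(out, lines[(prev + 1L):pos[j]], msg[j])
      prev <- pos[j]
    }
    if (prev < length(lines)) out <- c(out, lines[(prev + 1L):length(lines)])
    lines <- out
  }
  writeLines(lines, path)
}

#' Read the ASC-like dialect
#'
#' Tolerant of blink gaps (`.` fields become NA, flagged); malformed lines
#' raise an error naming the line number.
#'
#' @param path Input file.
#' @return An [eye_trace()] with markers restored; NA samples mark gaps.
#' @export
read_asc <- function(path) {
  raw <- readLines(path)
  if (length(raw) == 0L) stop("empty ASC file: ", path, call. = FALSE)
  is_msg <- startsWith(raw, "MSG")
  markers <- c()
  if (any(is_msg)) {
    parts <- strsplit(raw[is_msg], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) {
      stop("malformed MSG line ", which(is_msg)[bad[1]], " in ", path,
           call. = FALSE)
    }
    markers <- stats::setNames(
      as.numeric(vapply(parts, `[[`, "", 2L)),
      vapply(parts, `[[`, "", 3L))
  }
  samp <- raw[!is_msg]
  if (length(samp) < 2L) stop("truncated ASC file: ", path, call. = FALSE)
  parts <- strsplit(samp, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed sample line ", which(!is_msg)[bad[1]], " in ", path,
         call. = FALSE)
  }
  num <- function(i) {
    v <- vapply(parts, `[[`, "", i)
    out <- suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
    mal <- which(is.na(out) & v != ".")
    if (length(mal)) {
      stop("malformed numeric field on sample line ", which(!is_msg)[mal[1]],
           " in ", path, call. = FALSE)
    }
    out
  }
  t <- num(1L)
  if (anyNA(t)) stop("missing timestamps in ", path, call. = FALSE)
  eye_trace(t, num(2L), num(3L), markers = markers)
}
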