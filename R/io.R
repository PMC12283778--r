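# Trace file I/O: oscilloscope-export style delimited text (comma
# separated, dot decimal, LF, header row; time in seconds) plus an
# optional JSON metadata sidecar (<file>.json).

#' Write a trace to delimited text
#'
#' Writes `time_s,voltage_V,current_A` (header included) with
#' full-precision (`%.17g`) numbers so a read-back is bit-identical, and a
#' `<path>.json` sidecar carrying the sampling period and trace metadata.
#'
#' @param trace An `hfire_trace` with voltage and current channels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hfire_trace"))
  if (is.null(trace$current))
    stop("trace has no current channel", call. = FALSE)
  n <- length(trace$voltage)
  t_s <- (seq_len(n) - 1L) * trace$sampling_period * 1e-9
  lines <- c("time_s,voltage_V,current_A",
             sprintf("%.17g,%.17g,%.17g", t_s, trace$voltage,
                     trace$current))
  writeLines(lines, path)
  meta <- trace$meta
  meta$sampling_period_ns <- trace$sampling_period
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace from delimited text
#'
#' Reads a CSV written by [write_trace()] (or an oscilloscope export using
#' the same dialect), validating that all three columns are present and
#' that the timestamps are uniform: the maximum deviation of successive
#' time steps from the median step must be below 1% of that step, and the
#' first offending sample is named otherwise. Metadata is restored from a
#' `<path>.json` sidecar when present.
#'
#' @param path CSV path with columns `time_s`, `voltage_V`, `current_A`.
#' @return An `hfire_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_s", "voltage_V", "current_A")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trace file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         " (expected time_s, voltage_V, current_A)", call. = FALSE)
  if (nrow(df) < 2L) stop("trace has fewer than 2 samples", call. = FALSE)
  steps <- diff(df$time_s)
  dt <- stats::median(steps)
  if (dt <= 0) stop("non-increasing timestamps", call. = FALSE)
  bad <- which(abs(steps - dt) > 0.01 * dt)
  if (length(bad))
    stop("non-uniform sampling: time step ", bad[1], " (between samples ",
         bad[1], " and ", bad[1] + 1L, ") is ",
         signif(steps[bad[1]], 6), " s vs median ", signif(dt, 6), " s",
         call. = FALSE)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta$sampling_period_ns <- NULL
  }
  hfire_trace(sampling_period = dt * 1e9, voltage = df$voltage_V,
              current = df$current_A, meta = meta)
}
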