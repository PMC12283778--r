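# Oscilloscope-trace processing: first-order low-pass filter -> per-pulse
# maxima -> per-burst medians -> Ohm's-law resistance -> per-level average.

#' First-order digital low-pass filter
#'
#' Backward-Euler discretization of a first-order RC low-pass:
#' `y[1] = x[1]; y[n] = y[n-1] + alpha * (x[n] - y[n-1])` with
#' `alpha = dt / (tau + dt)`. Initializing at `x[1]` avoids a startup
#' transient contaminating the first pulse. DC gain is exactly 1. At the
#' sampling rates used here (dt on the order of ns, tau a third of a pulse
#' width) the backward-Euler alpha differs from the exact
#' `1 - exp(-dt/tau)` by under 0.01%.
#'
#' In the measurement pipeline `tau` is one-third of the pulse width,
#' which suppresses the capacitive charging transient at pulse onset while
#' the filtered output still reaches `1 - exp(-3)` (about 95%) of the
#' plateau by pulse end — identically on the voltage and current channels,
#' so the attenuation cancels in the resistance ratio.
#'
#' @param x Numeric samples.
#' @param dt Sampling interval (same time unit as `tau`).
#' @param tau Filter time constant (> 0).
#' @return Filtered samples, same length as `x`.
#' @export
lowpass_first_order <- function(x, dt, tau) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (dt <= 0 || tau <= 0)
    stop("'dt' and 'tau' must be positive", call. = FALSE)
  alpha <- dt / (tau + dt)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' Pulse windows of a recorded trace
#'
#' Segments a trace into its `2 * cycles` pulse windows using the protocol
#' timing (the recording is synchronized with the generator): positive
#' pulse `k` starts at `k * cycle_period`, the negative pulse follows after
#' `PW + d1`; boundaries are quantized to the sampling clock with
#' `round(time / dt)`.
#'
#' @param trace An `hfire_trace`.
#' @param protocol The [burst_protocol()] that produced it; its sampling
#'   period must match the trace's.
#' @return Data frame with columns `start`, `end` (1-based inclusive sample
#'   indices), `polarity` (+1/-1) and `cycle`; rows ordered and
#'   non-overlapping.
#' @export
segment_pulses <- function(trace, protocol) {
  stopifnot(inherits(trace, "hfire_trace"),
            inherits(protocol, "burst_protocol"))
  if (abs(trace$sampling_period - protocol$sampling_period) >
      1e-9 * protocol$sampling_period)
    stop("trace and protocol sampling periods differ", call. = FALSE)
  w <- .pulse_windows(protocol)
  if (w$end[nrow(w)] > length(trace$voltage))
    stop("trace shorter than the protocol's burst (", length(trace$voltage),
         " < ", w$end[nrow(w)], " samples); traces with missing trailing ",
         "pulses are rejected", call. = FALSE)
  w
}

#' Per-pulse plateau magnitudes
#'
#' For each pulse window, the maximum of the polarity-rectified filtered
#' samples (negative pulses: maximum of the negated signal). On a bipolar
#' waveform a plain maximum is only meaningful per polarity.
#'
#' @param filtered_samples Numeric vector (already low-pass filtered).
#' @param windows Window table from [segment_pulses()].
#' @return Numeric vector, one magnitude per pulse.
#' @export
pulse_magnitudes <- function(filtered_samples, windows) {
  stopifnot(is.data.frame(windows),
            all(c("start", "end", "polarity") %in% names(windows)))
  if (nrow(windows) == 0L) stop("no pulse windows", call. = FALSE)
  if (min(windows$start) < 1L || max(windows$end) > length(filtered_samples))
    stop("pulse window out of bounds (trace length ",
         length(filtered_samples), ")", call. = FALSE)
  vapply(seq_len(nrow(windows)), function(k) {
    max(windows$polarity[k] * filtered_samples[windows$start[k]:windows$end[k]])
  }, numeric(1))
}

#' Per-burst voltage, current and quasistatic resistance
#'
#' The full per-burst measurement chain: filter both channels with a
#' first-order low-pass of time constant `PW / 3`, extract per-pulse
#' rectified maxima, take the median across the burst's pulses for each
#' channel, and form the quasistatic Ohm's-law resistance
#' `R = V_burst / I_burst`. The median makes the estimate robust to a
#' corrupted pulse within the burst.
#'
#' @param trace An `hfire_trace` with voltage and current channels.
#' @param protocol The generating [burst_protocol()].
#' @return An object of class `burst_measurement`: list with `V` (V), `I`
#'   (A), `R` (ohm), `n_pulses`, and the trace's `level`/`burst`/
#'   `replicate` metadata if present.
#' @export
burst_metrics <- function(trace, protocol) {
  stopifnot(inherits(trace, "hfire_trace"))
  if (is.null(trace$current))
    stop("trace has no current channel", call. = FALSE)
  w <- segment_pulses(trace, protocol)
  dt_us <- trace$sampling_period / 1000
  tau <- protocol$pulse_width / 3
  vf <- lowpass_first_order(trace$voltage, dt_us, tau)
  cf <- lowpass_first_order(trace$current, dt_us, tau)
  V <- stats::median(pulse_magnitudes(vf, w))
  I <- stats::median(pulse_magnitudes(cf, w))
  if (!is.finite(I) || I <= 0)
    stop("non-positive burst current: degenerate trace ",
         "(open circuit or bad segmentation)", call. = FALSE)
  structure(list(V = V, I = I, R = V / I, n_pulses = nrow(w),
                 level = trace$meta$level, burst = trace$meta$burst,
                 replicate = trace$meta$replicate),
            class = "burst_measurement")
}

#' @export
print.burst_measurement <- function(x, ...) {
  cat(sprintf("<burst: V = %.4g V, I = %.4g A, R = %.4g ohm (%d pulses)>\n",
              x$V, x$I, x$R, x$n_pulses))
  invisible(x)
}

#' Average the bursts of one ramp level
#'
#' Per-level voltage, current and resistance are the simple averages of the
#' per-burst values (three bursts by convention); the per-burst values are
#' retained for dispersion reporting.
#'
#' @param bursts List of `burst_measurement` for one level.
#' @param level The level (V/cm) the bursts were delivered at; checked
#'   against each burst's metadata when present.
#' @param expected_n Required number of bursts (default 3; set `NULL` to
#'   accept any count >= 1).
#' @return An object of class `level_result`: list with `level`, `V`, `I`,
#'   `R` (means) and `bursts` (data frame of per-burst V/I/R).
#' @export
level_metrics <- function(bursts, level, expected_n = 3L) {
  if (!length(bursts) || !all(vapply(bursts, inherits, logical(1),
                                     "burst_measurement")))
    stop("'bursts' must be a list of burst_measurement", call. = FALSE)
  if (!is.null(expected_n) && length(bursts) != expected_n)
    stop("expected ", expected_n, " bursts per level, got ", length(bursts),
         call. = FALSE)
  lv <- unlist(lapply(bursts, `[[`, "level"))
  if (length(lv) && any(abs(lv - level) > 1e-9))
    stop("burst metadata level does not match 'level'", call. = FALSE)
  per <- data.frame(burst = seq_along(bursts),
                    V = vapply(bursts, `[[`, numeric(1), "V"),
                    I = vapply(bursts, `[[`, numeric(1), "I"),
                    R = vapply(bursts, `[[`, numeric(1), "R"))
  structure(list(level = level, V = mean(per$V), I = mean(per$I),
                 R = mean(per$R), bursts = per),
            class = "level_result")
}

#' Process a simulated or imported ramp into a tidy level table
#'
#' Runs [burst_metrics()] on every trace of a ramp and averages bursts
#' within each level.
#'
#' @param traces A list of `hfire_trace` (e.g. from [simulate_ramp()]),
#'   each carrying a `level` and `burst` in its metadata.
#' @param protocol The generating [burst_protocol()].
#' @return Data frame with one row per level: `level`, `V`, `I`, `R`,
#'   `n_bursts`; the per-burst table is attached as attribute `"bursts"`
#'   (columns `level`, `burst`, `V`, `I`, `R`).
#' @export
process_ramp <- function(traces, protocol) {
  stopifnot(length(traces) >= 1L)
  bm <- lapply(traces, burst_metrics, protocol = protocol)
  lv <- vapply(bm, function(b) b$level %||% NA_real_, numeric(1))
  if (anyNA(lv))
    stop("every trace needs a 'level' in its metadata", call. = FALSE)
  burst_tab <- data.frame(
    level = lv,
    burst = vapply(bm, function(b) b$burst %||% NA_integer_, numeric(1)),
    V = vapply(bm, `[[`, numeric(1), "V"),
    I = vapply(bm, `[[`, numeric(1), "I"),
    R = vapply(bm, `[[`, numeric(1), "R"))
  levels <- sort(unique(lv))
  out <- do.call(rbind, lapply(levels, function(l) {
    sel <- burst_tab[burst_tab$level == l, ]
    data.frame(level = l, V = mean(sel$V), I = mean(sel$I), R = mean(sel$R),
               n_bursts = nrow(sel))
  }))
  attr(out, "bursts") <- burst_tab
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
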