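#' Parameterize an H-FIRE burst
#'
#' An H-FIRE burst is a train of `cycles` repetitions of
#' \[positive pulse, interphase delay d1, negative pulse, interpulse delay d2\].
#' The field's shorthand for a waveform is the label `"PW-d1-PW-d2"`
#' (e.g. `"2-5-2-5"`: 2 us pulses with 5 us delays). All durations are in
#' microseconds except the oscilloscope sampling period, which is in
#' nanoseconds (2 ns gives at least 500 samples across the shortest, 1 us,
#' pulse used in practice).
#'
#' @param pulse_width Pulse width in microseconds (> 0); positive and
#'   negative phases share the same width.
#' @param interphase_delay Delay d1 between the positive and negative pulse
#'   of a cycle, microseconds (>= 0).
#' @param interpulse_delay Delay d2 after the negative pulse, before the next
#'   cycle, microseconds (>= 0).
#' @param cycles Number of cycles per burst. Default `NULL` chooses the
#'   smallest count giving at least 100 us of total on-time
#'   (see [cycles_for_ontime()]), the on-time conventionally matched to a
#'   single long monopolar IRE pulse.
#' @param n_bursts Number of bursts in the treatment train (metadata; one
#'   burst is synthesized at a time).
#' @param amplitude Pulse amplitude in volts.
#' @param sampling_period Virtual-oscilloscope sampling period in
#'   nanoseconds. Default 2 ns.
#' @param burst_interval Optional interval between bursts in seconds
#'   (metadata only).
#' @return An object of class `burst_protocol`.
#' @seealso [parse_protocol()], [protocol_label()], [build_burst()]
#' @examples
#' p <- burst_protocol(2, 5, 5, cycles = 2, amplitude = 1000)
#' protocol_label(p)
#' cycle_period(p)
#' @export
burst_protocol <- function(pulse_width, interphase_delay, interpulse_delay,
                           cycles = NULL, n_bursts = 1L, amplitude = 1,
                           sampling_period = 2, burst_interval = NULL) {
  if (!is.numeric(pulse_width) || length(pulse_width) != 1L || pulse_width <= 0)
    stop("'pulse_width' must be a single positive duration (us)", call. = FALSE)
  if (interphase_delay < 0 || interpulse_delay < 0)
    stop("delays d1 and d2 must be non-negative (us)", call. = FALSE)
  if (sampling_period <= 0)
    stop("'sampling_period' must be positive (ns)", call. = FALSE)
  if (is.null(cycles)) cycles <- cycles_for_ontime(pulse_width, 100)
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L)
    stop("'cycles' must be an integer >= 1", call. = FALSE)
  if (amplitude < 0)
    stop("'amplitude' must be non-negative (V)", call. = FALSE)
  structure(
    list(pulse_width = pulse_width,
         interphase_delay = interphase_delay,
         interpulse_delay = interpulse_delay,
         cycles = cycles,
         n_bursts = as.integer(n_bursts),
         amplitude = amplitude,
         sampling_period = sampling_period,
         burst_interval = burst_interval),
    class = "burst_protocol")
}

#' Canonical waveform label
#'
#' Formats a protocol as the conventional `"PW-d1-PW-d2"` string. The label
#' round-trips through [parse_protocol()].
#'
#' @param protocol A [burst_protocol()].
#' @return Character scalar, e.g. `"1-10-1-10"`.
#' @export
protocol_label <- function(protocol) {
  stopifnot(inherits(protocol, "burst_protocol"))
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  paste(num(protocol$pulse_width), num(protocol$interphase_delay),
        num(protocol$pulse_width), num(protocol$interpulse_delay),
        sep = "-")
}

#' Parse a waveform label
#'
#' Inverse of [protocol_label()]: `"2-5-2-5"` becomes a protocol with 2 us
#' pulses, d1 = d2 = 5 us. The two pulse-width fields of the label must
#' agree.
#'
#' @param label Character scalar `"PW-d1-PW-d2"`.
#' @param ... Remaining fields passed to [burst_protocol()]
#'   (cycles, amplitude, sampling_period, ...).
#' @return A [burst_protocol()].
#' @export
parse_protocol <- function(label, ...) {
  parts <- strsplit(trimws(label), "-", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("protocol label must have four '-'-separated fields (PW-d1-PW-d2): ",
         label, call. = FALSE)
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals))
    stop("non-numeric field in protocol label: ", label, call. = FALSE)
  if (vals[1] != vals[3])
    stop("positive and negative pulse widths differ in label: ", label,
         call. = FALSE)
  burst_protocol(pulse_width = vals[1], interphase_delay = vals[2],
                 interpulse_delay = vals[4], ...)
}

#' @export
format.burst_protocol <- function(x, ...) {
  sprintf("<burst_protocol %s | %d cycle%s, %g V, dt = %g ns>",
          protocol_label(x), x$cycles, if (x$cycles == 1L) "" else "s",
          x$amplitude, x$sampling_period)
}

#' @export
print.burst_protocol <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Duration of one waveform cycle
#'
#' One cycle spans the positive pulse, d1, the negative pulse and d2:
#' `2 * PW + d1 + d2` microseconds.
#'
#' @param protocol A [burst_protocol()].
#' @return Cycle period in microseconds.
#' @export
cycle_period <- function(protocol) {
  stopifnot(inherits(protocol, "burst_protocol"))
  2 * protocol$pulse_width + protocol$interphase_delay +
    protocol$interpulse_delay
}

#' Characteristic frequency of a waveform
#'
#' The fundamental frequency of the repeating cycle, `1 / cycle_period`.
#' For square bursts this coincides with the dominant nonzero-frequency
#' peak of the burst's magnitude spectrum (see [power_spectrum()]), e.g.
#' about 45 kHz for 1-10-1-10 and about 71 kHz for 2-5-2-5.
#'
#' @param protocol A [burst_protocol()].
#' @return Frequency in kilohertz.
#' @export
characteristic_frequency <- function(protocol) {
  cp <- cycle_period(protocol)
  if (cp <= 0) stop("cycle period must be positive", call. = FALSE)
  1000 / cp
}

#' Cycles needed to reach a target on-time
#'
#' Each cycle contributes `2 * PW` of energized time. Returns the smallest
#' cycle count whose total on-time reaches `target_ontime`, the convention
#' used to make a burst comparable with one long monopolar IRE pulse
#' (typically 100 us).
#'
#' @param pulse_width Pulse width, microseconds (> 0).
#' @param target_ontime Target total on-time, microseconds (> 0).
#' @return Integer cycle count.
#' @examples
#' cycles_for_ontime(1, 100)  # 50
#' cycles_for_ontime(3, 100)  # 17
#' @export
cycles_for_ontime <- function(pulse_width, target_ontime) {
  if (pulse_width <= 0 || target_ontime <= 0)
    stop("'pulse_width' and 'target_ontime' must be positive", call. = FALSE)
  as.integer(ceiling(target_ontime / (2 * pulse_width) - 1e-9))
}
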