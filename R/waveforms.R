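# Burst synthesis and spectral characterization.
#
# Sample-index bookkeeping: all pulse boundaries are quantized to the
# sampling clock with round(time/dt). Positive and negative windows share
# one rounded per-pulse sample count, so every synthesized burst is exactly
# charge balanced (sum of samples is identically zero) regardless of how
# the delay durations round.

# Pulse windows implied by protocol timing. 1-based inclusive [start, end]
# indices; one row per pulse, ordered in time.
.pulse_windows <- function(protocol) {
  dt <- protocol$sampling_period / 1000  # us per sample
  npw <- round(protocol$pulse_width / dt)
  if (npw < 1)
    stop("pulse width shorter than one sampling period", call. = FALSE)
  cp <- cycle_period(protocol)
  k <- seq_len(protocol$cycles) - 1L
  cyc_start <- round(k * cp / dt)                      # 0-based
  neg_off <- round((protocol$pulse_width + protocol$interphase_delay) / dt)
  pos_start <- cyc_start
  neg_start <- cyc_start + neg_off
  data.frame(
    start = as.integer(c(rbind(pos_start, neg_start)) + 1L),
    end = as.integer(c(rbind(pos_start + npw, neg_start + npw))),
    polarity = rep(c(1, -1), times = protocol$cycles),
    cycle = rep(seq_len(protocol$cycles), each = 2L))
}

.burst_n_samples <- function(protocol) {
  dt <- protocol$sampling_period / 1000
  n <- round(protocol$cycles * cycle_period(protocol) / dt)
  w <- .pulse_windows(protocol)
  max(n, w$end[nrow(w)])
}

#' Synthesize one ideal H-FIRE burst
#'
#' Builds the ideal square burst implied by a protocol: `cycles` repetitions
#' of \[+amplitude pulse, zero gap d1, -amplitude pulse, zero gap d2\],
#' uniformly sampled at the protocol's sampling period. The first pulse is
#' positive and the burst is exactly charge balanced (samples sum to zero).
#'
#' @param protocol A [burst_protocol()].
#' @return An object of class `hfire_trace` with elements `sampling_period`
#'   (ns), `voltage` (V), `current` (`NULL` for ideal waveforms) and `meta`.
#' @examples
#' tr <- build_burst(burst_protocol(2, 5, 5, cycles = 2, amplitude = 1))
#' length(tr$voltage)  # 14000 samples at 2 ns for a 28 us burst
#' @export
build_burst <- function(protocol) {
  stopifnot(inherits(protocol, "burst_protocol"))
  n <- .burst_n_samples(protocol)
  w <- .pulse_windows(protocol)
  v <- numeric(n)
  for (i in seq_len(nrow(w)))
    v[w$start[i]:w$end[i]] <- w$polarity[i] * protocol$amplitude
  hfire_trace(sampling_period = protocol$sampling_period, voltage = v,
              meta = list(protocol = protocol_label(protocol),
                          pulse_width = protocol$pulse_width,
                          d1 = protocol$interphase_delay,
                          d2 = protocol$interpulse_delay,
                          cycles = protocol$cycles,
                          amplitude = protocol$amplitude,
                          ideal = TRUE))
}

#' Construct a trace object
#'
#' Container for a uniformly sampled (virtual or imported) oscilloscope
#' record: a voltage series and, optionally, a simultaneously sampled
#' current series.
#'
#' @param sampling_period Sampling period in nanoseconds.
#' @param voltage Numeric vector of voltages (V).
#' @param current Optional numeric vector of currents (A), same length.
#' @param meta Named list of metadata (protocol label, geometry, ramp level,
#'   burst index, replicate, seed, ...).
#' @return An object of class `hfire_trace`.
#' @export
hfire_trace <- function(sampling_period, voltage, current = NULL,
                        meta = list()) {
  if (sampling_period <= 0)
    stop("'sampling_period' must be positive (ns)", call. = FALSE)
  if (!is.numeric(voltage) || length(voltage) == 0L)
    stop("'voltage' must be a non-empty numeric vector", call. = FALSE)
  if (!is.null(current) && length(current) != length(voltage))
    stop("'voltage' and 'current' must have the same length", call. = FALSE)
  structure(list(sampling_period = sampling_period, voltage = voltage,
                 current = current, meta = meta),
            class = "hfire_trace")
}

#' @export
print.hfire_trace <- function(x, ...) {
  dur_us <- length(x$voltage) * x$sampling_period / 1000
  cat(sprintf("<hfire_trace %d samples @ %g ns (%.3g us)%s%s>\n",
              length(x$voltage), x$sampling_period, dur_us,
              if (is.null(x$current)) ", voltage only" else ", V + I",
              if (length(x$meta$protocol))
                paste0(", ", x$meta$protocol) else ""))
  invisible(x)
}

#' Magnitude spectrum of a burst
#'
#' Discrete Fourier magnitude spectrum (one-sided) of a trace's voltage.
#' For a charge-balanced burst the DC bin is exactly zero, and for an ideal
#' square burst of several cycles the largest nonzero-frequency peak falls
#' at the waveform's characteristic frequency (within one bin).
#'
#' @param trace An `hfire_trace` (its voltage channel is analyzed), or a
#'   numeric vector together with `sampling_period`.
#' @param normalization `"none"` (raw `|FFT|/n`) or `"unit-energy"`
#'   (magnitudes scaled so their squares sum to one).
#' @param sampling_period Sampling period in ns; only needed when `trace`
#'   is a bare numeric vector.
#' @return A data frame of class `hfire_spectrum` with columns
#'   `frequency_hz` (strictly increasing, starting at 0) and `magnitude`
#'   (>= 0); the normalization is recorded in attribute `"normalization"`.
#' @export
power_spectrum <- function(trace, normalization = c("none", "unit-energy"),
                           sampling_period = NULL) {
  normalization <- match.arg(normalization)
  if (inherits(trace, "hfire_trace")) {
    x <- trace$voltage
    dt_ns <- trace$sampling_period
  } else {
    x <- as.numeric(trace)
    if (is.null(sampling_period))
      stop("'sampling_period' (ns) required for a bare numeric trace",
           call. = FALSE)
    dt_ns <- sampling_period
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for a spectrum", call. = FALSE)
  mag <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1L)] / n
  if (normalization == "unit-energy") {
    e <- sqrt(sum(mag^2))
    if (e > 0) mag <- mag / e
  }
  freq <- (seq_along(mag) - 1L) / (n * dt_ns * 1e-9)
  structure(data.frame(frequency_hz = freq, magnitude = mag),
            normalization = normalization,
            class = c("hfire_spectrum", "data.frame"))
}

#' Locate the dominant nonzero-frequency peak
#'
#' @param spectrum A spectrum from [power_spectrum()].
#' @return Frequency (Hz) of the largest magnitude excluding the DC bin.
#' @export
spectral_peak <- function(spectrum) {
  stopifnot(is.data.frame(spectrum), nrow(spectrum) >= 2L)
  nz <- spectrum[-1L, ]
  nz$frequency_hz[which.max(nz$magnitude)]
}

#' Export a spectrum as two-column delimited text
#'
#' Writes `frequency_Hz,magnitude` with a header row.
#'
#' @param spectrum A spectrum from [power_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  out <- data.frame(frequency_Hz = spectrum$frequency_hz,
                    magnitude = spectrum$magnitude)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
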