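# Virtual oscilloscope + tissue: seeded synthesis of voltage/current
# traces with the biophysical structure the analysis pipeline assumes.

#' Simulate one recorded burst
#'
#' Produces the voltage and current a virtual oscilloscope would record for
#' one burst delivered into homogeneous virtual tissue:
#' \itemize{
#'   \item voltage: the ideal square burst at the protocol amplitude,
#'     optionally smoothed by a first-order generator rise-time lag;
#'   \item current: `voltage / R`, with `R = 1 / (sigma * S)` from the
#'     geometry's shape factor and `sigma` from the tissue model evaluated
#'     at the distance-normalized applied field (amplitude / electrode
#'     gap); in mechanistic mode the conductivity evolves within each pulse
#'     with the membrane-charging time constant;
#'   \item an optional capacitive overshoot
#'     `cap_transient_frac * exp(-t/cap_transient_tau)` on each pulse
#'     onset of the current channel;
#'   \item additive zero-mean Gaussian noise with standard deviation
#'     `noise_rel` times the respective channel plateau, on both channels.
#' }
#' Delays d1/d2 affect only the timing of the waveform, never the tissue
#' model: the generator is delay-invariant by construction.
#'
#' @param protocol A [burst_protocol()]; its `amplitude` sets the applied
#'   voltage.
#' @param geometry A `geometry_spec`.
#' @param params A [tissue_params()].
#' @param seed Optional integer; when given, the trace is a deterministic
#'   function of it (RNG state is restored afterwards).
#' @param meta Extra metadata merged into the trace's `meta` list.
#' @return An `hfire_trace` with voltage and current channels. `meta`
#'   records the protocol label, geometry kind, applied field, the true
#'   model conductivity and resistance (for oracle checks), and the seed.
#' @export
simulate_trace <- function(protocol, geometry, params, seed = NULL,
                           meta = list()) {
  stopifnot(inherits(protocol, "burst_protocol"),
            inherits(geometry, "geometry_spec"),
            inherits(params, "tissue_params"))
  if (!is.null(seed))
    return(withr::with_seed(seed,
      simulate_trace(protocol, geometry, params, seed = NULL,
                     meta = c(meta, list(seed = seed)))))

  dt_us <- protocol$sampling_period / 1000
  E_app <- protocol$amplitude / .gap_cm(geometry)
  S <- .shape_factor(geometry)
  sigma <- apparent_conductivity(E_app, protocol$pulse_width, params) *
    .delay_multiplier(params, protocol)
  R <- 1 / (sigma * S)
  mem <- meta$ramp_memory_mult
  if (!is.null(mem)) R <- R * mem
  I_plateau <- protocol$amplitude / R

  ideal <- build_burst(protocol)
  v <- ideal$voltage
  w <- .pulse_windows(protocol)

  if (params$mode == "mechanistic") {
    i <- numeric(length(v))
    for (k in seq_len(nrow(w))) {
      idx <- w$start[k]:w$end[k]
      t_rel <- (seq_along(idx) - 1L) * dt_us
      sig_t <- mechanistic_conductivity(t_rel, E_app, params) *
        .delay_multiplier(params, protocol)
      if (!is.null(mem)) sig_t <- sig_t / mem
      i[idx] <- v[idx] * sig_t * S
    }
  } else {
    i <- v / R
  }

  if (params$cap_transient_frac > 0 && params$cap_transient_tau > 0) {
    for (k in seq_len(nrow(w))) {
      idx <- w$start[k]:w$end[k]
      t_rel <- (seq_along(idx) - 1L) * dt_us
      i[idx] <- i[idx] + w$polarity[k] * I_plateau *
        params$cap_transient_frac * exp(-t_rel / params$cap_transient_tau)
    }
  }

  if (params$rise_time > 0)
    v <- lowpass_first_order(v, dt_us, params$rise_time)

  if (params$noise_rel > 0) {
    n <- length(v)
    v <- v + stats::rnorm(n, 0, params$noise_rel * protocol$amplitude)
    i <- i + stats::rnorm(n, 0, params$noise_rel * I_plateau)
  }

  base_meta <- list(protocol = protocol_label(protocol),
                    pulse_width = protocol$pulse_width,
                    d1 = protocol$interphase_delay,
                    d2 = protocol$interpulse_delay,
                    cycles = protocol$cycles,
                    amplitude = protocol$amplitude,
                    geometry = geometry$kind,
                    E_app = E_app,
                    sigma_true = sigma,
                    R_true = R)
  base_meta[names(meta)] <- meta
  hfire_trace(protocol$sampling_period, v, i, meta = base_meta)
}

#' Simulate a voltage ramp
#'
#' A voltage ramp delivers a fixed number of bursts (three, by convention)
#' at each of a strictly increasing series of distance-normalized voltage
#' levels, without moving the electrodes. The virtual tissue has no memory
#' across levels: each burst's response depends only on its own applied
#' field, matching the bench observation that preceding lower-voltage
#' ramps do not change the resistance read at a later level. For plate
#' geometries with a positive `thickness_sd`, one per-sample thickness is
#' drawn (truncated normal) for the whole ramp, the level voltages are
#' computed from that measured thickness, and the realized geometry is
#' attached as attribute `"geometry"` of the result — mirroring the bench
#' caliper correction.
#'
#' @param protocol A [burst_protocol()]; its amplitude is overridden per
#'   level via [voltage_for_field()].
#' @param geometry A `geometry_spec`.
#' @param params A [tissue_params()].
#' @param levels Strictly increasing vector of levels, V/cm.
#' @param bursts_per_level Bursts delivered at each level (default 3).
#' @param seed Optional integer seed making the whole ramp reproducible.
#' @param replicate Replicate identifier stored in trace metadata.
#' @return A list of `hfire_trace` (class `hfire_ramp`), ordered by level
#'   then burst, with the realized `geometry_spec` in `attr(, "geometry")`.
#' @export
simulate_ramp <- function(protocol, geometry, params, levels,
                          bursts_per_level = 3L, seed = NULL,
                          replicate = 1L) {
  stopifnot(inherits(protocol, "burst_protocol"))
  if (length(levels) == 0L || any(diff(levels) <= 0))
    stop("'levels' must be strictly increasing (V/cm)", call. = FALSE)
  if (any(levels < 0)) stop("'levels' must be non-negative", call. = FALSE)
  if (!is.null(seed))
    return(withr::with_seed(seed,
      simulate_ramp(protocol, geometry, params, levels, bursts_per_level,
                    seed = NULL, replicate = replicate)))

  geom_actual <- geometry
  if (geometry$kind == "plate" && geometry$thickness_sd > 0) {
    th <- stats::rnorm(1, geometry$thickness, geometry$thickness_sd)
    while (th <= 0)
      th <- stats::rnorm(1, geometry$thickness, geometry$thickness_sd)
    geom_actual <- plate_geometry(th, geometry$diameter,
                                  geometry$thickness_sd)
  }

  mem <- params$ramp_memory_frac
  traces <- vector("list", length(levels) * bursts_per_level)
  k <- 0L
  for (j in seq_along(levels)) {
    p_lvl <- protocol
    p_lvl$amplitude <- voltage_for_field(levels[j], geom_actual)
    extra <- list(level = levels[j], replicate = replicate)
    if (mem != 0 && j > 1L) extra$ramp_memory_mult <- 1 + mem
    for (b in seq_len(bursts_per_level)) {
      k <- k + 1L
      traces[[k]] <- simulate_trace(p_lvl, geom_actual, params,
                                    meta = c(extra, list(burst = b)))
    }
  }
  structure(traces, geometry = geom_actual, levels = levels,
            class = c("hfire_ramp", "list"))
}
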