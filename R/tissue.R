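# Nonlinear tissue conductivity model driving the synthetic generator.
#
# Apparent conductivity is modelled phenomenologically as a smooth sigmoid
# in the applied field: a pulse-width-dependent bulk (non-electroporated)
# floor, a plateau after the electroporation transition, a transition
# centered at E_th with scale `transition_width`. The sigmoid is a
# compact-support C2 "smootherstep" on (E - E_th)/w in [-3, 3], so the
# floor and plateau are attained exactly (at E <= E_th - 3w and
# E >= E_th + 3w) while s = 0.5 exactly at E = E_th.

.smootherstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * u * (u * (u * 6 - 15) + 10)
}

# Interpolate a per-pulse-width map (named numeric vector, names = us) at
# pulse width pw; linear in log10(PW), clamped outside the tabulated range.
.interp_pw <- function(map, pw) {
  if (length(map) == 1L) return(unname(map))
  pws <- as.numeric(names(map))
  if (anyNA(pws)) stop("per-pulse-width maps need numeric names (us)",
                       call. = FALSE)
  o <- order(pws)
  stats::approx(log10(pws[o]), map[o], xout = log10(pw), rule = 2)$y
}

#' Synthetic tissue parameters
#'
#' Parameter set for the phenomenological / mechanistic conductivity model
#' used by the virtual-tissue generator ([simulate_trace()]).
#'
#' @param sigma_bulk_by_pw Named numeric vector mapping pulse width (us) to
#'   non-electroporated (bulk) apparent conductivity (S/m); intermediate
#'   pulse widths are interpolated linearly in log10(PW). Shorter pulses
#'   see a higher apparent conductivity because they end before the cell
#'   membranes fully charge.
#' @param sigma_max_by_pw Electroporated plateau conductivity (S/m); a
#'   scalar or a per-pulse-width named vector like `sigma_bulk_by_pw`.
#' @param E_th Transition (electroporation threshold) field, V/cm; the
#'   sigmoid midpoint.
#' @param transition_width Field scale `w` of the transition, V/cm; the
#'   sigmoid support spans `E_th - 3w` to `E_th + 3w`.
#' @param tau_mem Membrane-charging time constant, us (mechanistic mode).
#' @param cap_transient_frac Fractional capacitive current overshoot at each
#'   pulse onset (dimensionless).
#' @param cap_transient_tau Decay time of the capacitive overshoot, us.
#' @param noise_rel Relative (fraction of plateau) standard deviation of the
#'   additive Gaussian measurement noise on both channels.
#' @param mode `"phenomenological"` (quasistatic sigma(E), the contract
#'   surface) or `"mechanistic"` (adds an intra-pulse membrane-charging
#'   transient; qualitative).
#' @param delay_effect Diagnostic knob: fractional conductivity multiplier
#'   proportional to d2 (`1 + delay_effect * d2 / 100`), zero for the
#'   physical, delay-invariant model. Used to power-check delay statistics.
#' @param ramp_memory_frac Diagnostic knob: fractional resistance change
#'   applied to every ramp level after the first (e.g. -0.2 for a -20%
#'   memory effect); zero for the physical, memoryless model.
#' @param rise_time Optional generator rise time (us) applied as a
#'   first-order lag to the ideal voltage; 0 for perfect squares.
#' @return An object of class `tissue_params`.
#' @seealso [tissue_preset()] for shipped parameter sets.
#' @export
tissue_params <- function(sigma_bulk_by_pw,
                          sigma_max_by_pw,
                          E_th = 500,
                          transition_width = 150,
                          tau_mem = 1.0,
                          cap_transient_frac = 0.1,
                          cap_transient_tau = 0.2,
                          noise_rel = 0.01,
                          mode = c("phenomenological", "mechanistic"),
                          delay_effect = 0,
                          ramp_memory_frac = 0,
                          rise_time = 0) {
  mode <- match.arg(mode)
  if (any(sigma_bulk_by_pw <= 0) || any(sigma_max_by_pw <= 0))
    stop("conductivities must be positive (S/m)", call. = FALSE)
  if (E_th <= 0 || transition_width <= 0)
    stop("'E_th' and 'transition_width' must be positive (V/cm)",
         call. = FALSE)
  if (noise_rel < 0) stop("'noise_rel' must be non-negative", call. = FALSE)
  if (length(sigma_bulk_by_pw) > 1L && is.null(names(sigma_bulk_by_pw)))
    stop("'sigma_bulk_by_pw' needs pulse-width names (us)", call. = FALSE)
  if (length(sigma_max_by_pw) > 1L && is.null(names(sigma_max_by_pw)))
    stop("'sigma_max_by_pw' needs pulse-width names (us)", call. = FALSE)
  p <- structure(
    list(sigma_bulk_by_pw = sigma_bulk_by_pw,
         sigma_max_by_pw = sigma_max_by_pw,
         E_th = E_th, transition_width = transition_width,
         tau_mem = tau_mem,
         cap_transient_frac = cap_transient_frac,
         cap_transient_tau = cap_transient_tau,
         noise_rel = noise_rel, mode = mode,
         delay_effect = delay_effect,
         ramp_memory_frac = ramp_memory_frac,
         rise_time = rise_time),
    class = "tissue_params")
  pws <- if (is.null(names(sigma_bulk_by_pw))) 1 else
    as.numeric(names(sigma_bulk_by_pw))
  for (pw in pws)
    if (.interp_pw(sigma_max_by_pw, pw) < .interp_pw(sigma_bulk_by_pw, pw))
      stop("plateau conductivity must be >= bulk conductivity at every ",
           "pulse width", call. = FALSE)
  p
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "<tissue_params [%s]: bulk %s S/m, plateau %s S/m, E_th %g V/cm (w %g)>\n",
    x$mode,
    paste(signif(x$sigma_bulk_by_pw, 3), collapse = "/"),
    paste(signif(x$sigma_max_by_pw, 3), collapse = "/"),
    x$E_th, x$transition_width))
  invisible(x)
}

#' Apparent (quasistatic) conductivity at an applied field
#'
#' `sigma(E) = sigma_bulk(PW) + (sigma_max(PW) - sigma_bulk(PW)) * s(x)`,
#' with `x = (E - E_th) / w` and `s` the smootherstep sigmoid (see
#' [tissue_params()]). Monotone non-decreasing in `E`; equal to the bulk
#' value exactly at fields at or below `E_th - 3w` (in particular at
#' `E = 0` for the shipped presets), equal to the midpoint at `E = E_th`,
#' and saturating exactly at the plateau for `E >= E_th + 3w`. Interphase
#' and interpulse delays are deliberately not inputs: the model is
#' delay-invariant by construction.
#'
#' @param E_app Applied distance-normalized field, V/cm (vectorized, >= 0).
#' @param pulse_width Pulse width in us.
#' @param params A [tissue_params()].
#' @return Conductivity in S/m.
#' @export
apparent_conductivity <- function(E_app, pulse_width, params) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(E_app < 0)) stop("'E_app' must be non-negative (V/cm)",
                           call. = FALSE)
  sb <- .interp_pw(params$sigma_bulk_by_pw, pulse_width)
  sm <- .interp_pw(params$sigma_max_by_pw, pulse_width)
  x <- (E_app - params$E_th) / params$transition_width
  sb + (sm - sb) * .smootherstep((x + 3) / 6)
}

#' Time-resolved conductivity with membrane charging
#'
#' Mechanistic-mode conductivity at time `t` after a pulse onset:
#' `sigma(t, E) = sigma_ss(E) + (sigma_hf - sigma_ss(E)) * exp(-t/tau_mem)`.
#' The short-time (membrane-shunted) limit `sigma_hf` is the bulk
#' conductivity at the shortest tabulated pulse width; the steady state
#' `sigma_ss(E)` is [apparent_conductivity()] at the longest tabulated
#' pulse width. Qualitative: it rationalizes why short pulses read a higher
#' apparent conductivity, not a fitted cell-scale model.
#'
#' @param t Time since pulse onset, us (vectorized, >= 0).
#' @param E_app Applied field, V/cm.
#' @param params A [tissue_params()] with positive `tau_mem`.
#' @return Conductivity in S/m.
#' @export
mechanistic_conductivity <- function(t, E_app, params) {
  stopifnot(inherits(params, "tissue_params"))
  if (is.null(params$tau_mem) || params$tau_mem <= 0)
    stop("'tau_mem' must be positive (us)", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative (us)", call. = FALSE)
  pws <- as.numeric(names(params$sigma_bulk_by_pw))
  if (is.null(names(params$sigma_bulk_by_pw))) pws <- 1
  sigma_hf <- .interp_pw(params$sigma_bulk_by_pw, min(pws))
  sigma_ss <- apparent_conductivity(E_app, max(pws), params)
  sigma_ss + (sigma_hf - sigma_ss) * exp(-t / params$tau_mem)
}

# d2-dependent conductivity multiplier; identically 1 for the physical
# (delay-invariant) model.
.delay_multiplier <- function(params, protocol) {
  1 + params$delay_effect * protocol$interpulse_delay / 100
}

#' Shipped tissue parameter presets
#'
#' Loads a named preset from the package's YAML preset file. `"potato"` is
#' calibrated to published summary measurements of russet potato tissue
#' (bulk 0.13 / 0.04 S/m at 1 / 10 us pulse widths; electroporated plateaus
#' 0.55 / 0.67 S/m; transition centered at 500 V/cm). `"cardiac"` is a
#' synthetic, qualitative stand-in for ventricular myocardium (higher bulk
#' conductivity); its values are placeholders, not measurements.
#'
#' @param name Preset name; see `names(tissue_preset())` invisibly via
#'   `tissue_preset(NULL)`.
#' @param ... Overrides passed to [tissue_params()] (e.g. `noise_rel`,
#'   `mode`).
#' @return A [tissue_params()]; or, with `name = NULL`, the character
#'   vector of available preset names.
#' @export
tissue_preset <- function(name = "potato", ...) {
  path <- system.file("extdata", "tissue_presets.yaml",
                      package = "hfirebench", mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown tissue preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  p <- presets[[name]]
  args <- list(
    sigma_bulk_by_pw = unlist(p$sigma_bulk_by_pw),
    sigma_max_by_pw = unlist(p$sigma_max_by_pw),
    E_th = p$E_th, transition_width = p$transition_width,
    tau_mem = p$tau_mem,
    cap_transient_frac = p$cap_transient_frac,
    cap_transient_tau = p$cap_transient_tau,
    noise_rel = p$noise_rel)
  over <- list(...)
  args[names(over)] <- over
  do.call(tissue_params, args)
}

#' Shipped geometry presets
#'
#' Loads a named electrode geometry from the package's YAML preset file:
#' `"potato_plate"` (6 mm slice, 6 mm punch), `"potato_needle_1.0cm"` /
#' `"potato_needle_1.5cm"` (1 mm diameter monopolar probes, 1 cm exposure),
#' and `"cardiac_needle"` (0.45 mm acupuncture needles, 4 mm exposure; a
#' `"cardiac_needle_caption"` variant carries the alternative 5 mm exposure
#' / 10 mm insertion reported for the same setup).
#'
#' @param name Preset name, or `NULL` to list available names.
#' @return A `geometry_spec`, or the character vector of names.
#' @export
geometry_preset <- function(name = "potato_plate") {
  path <- system.file("extdata", "geometry_presets.yaml",
                      package = "hfirebench", mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown geometry preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  g <- presets[[name]]
  if (identical(g$kind, "plate")) {
    plate_geometry(thickness = g$thickness, diameter = g$diameter,
                   thickness_sd = if (is.null(g$thickness_sd)) 0 else
                     g$thickness_sd)
  } else {
    needle_pair_geometry(spacing = g$spacing, radius = g$radius,
                         exposure = g$exposure, insertion = g$insertion)
  }
}
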