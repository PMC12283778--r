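# Electrode geometries, distance-normalized voltage schedules, and
# shape-factor conductivity inversion.
#
# Unit conventions follow bench practice: plate thickness/diameter and
# electrode radii in mm, needle spacing and exposure in cm, fields in V/cm.
# All physics is done in SI internally; a geometry's shape factor S (m)
# satisfies R = 1 / (sigma * S).

#' Parallel-plate (prism) geometry
#'
#' A cylindrical tissue sample held between parallel flat plate electrodes:
#' thickness `l`, circular cross-section of the given diameter. The plates
#' deliver a uniform field, so the prism shape factor `S = A / l` applies
#' and conductivity can be inverted directly from resistance.
#'
#' @param thickness Sample thickness in mm (default 6, a standard biopsy
#'   slice).
#' @param diameter Sample diameter in mm (default 6, a 6 mm biopsy punch).
#' @param thickness_sd Standard deviation (mm) used by the synthetic
#'   generator when drawing per-sample thicknesses, mirroring bench caliper
#'   variation; 0 for a fixed thickness.
#' @return A `geometry_spec` of kind `"plate"`.
#' @export
plate_geometry <- function(thickness = 6, diameter = 6, thickness_sd = 0.2) {
  if (thickness <= 0 || diameter <= 0)
    stop("plate thickness and diameter must be positive (mm)", call. = FALSE)
  if (thickness_sd < 0)
    stop("'thickness_sd' must be non-negative", call. = FALSE)
  structure(list(kind = "plate", thickness = thickness, diameter = diameter,
                 thickness_sd = thickness_sd),
            class = "geometry_spec")
}

#' Needle-pair geometry
#'
#' Two parallel cylindrical monopolar electrodes inserted into bulk tissue.
#' The field is non-uniform; resistance is predicted through the
#' two-parallel-cylinder shape factor (see [needle_pair_shape_factor()]),
#' an infinite-medium approximation.
#'
#' @param spacing Center-to-center spacing in cm.
#' @param radius Electrode radius in mm.
#' @param exposure Energized (non-insulated) electrode length in cm.
#' @param insertion Optional insertion depth in mm (metadata only).
#' @return A `geometry_spec` of kind `"needle_pair"`.
#' @export
needle_pair_geometry <- function(spacing = 1.0, radius = 0.5, exposure = 1.0,
                                 insertion = NULL) {
  if (spacing <= 0 || radius <= 0 || exposure <= 0)
    stop("spacing, radius and exposure must be positive", call. = FALSE)
  if (spacing * 10 <= 2 * radius)
    stop("needle spacing must exceed the electrode diameter", call. = FALSE)
  structure(list(kind = "needle_pair", spacing = spacing, radius = radius,
                 exposure = exposure, insertion = insertion),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  if (x$kind == "plate") {
    cat(sprintf("<plate geometry: l = %g mm, diameter = %g mm>\n",
                x$thickness, x$diameter))
  } else {
    cat(sprintf(
      "<needle-pair geometry: spacing %g cm, radius %g mm, exposure %g cm>\n",
      x$spacing, x$radius, x$exposure))
  }
  invisible(x)
}

#' Circular plate area
#'
#' @param diameter Plate/sample diameter in meters.
#' @return Area in square meters, `pi * (d/2)^2`.
#' @export
plate_area <- function(diameter) {
  if (!is.numeric(diameter) || any(diameter <= 0))
    stop("'diameter' must be positive (m)", call. = FALSE)
  pi * (diameter / 2)^2
}

#' Prism shape-factor conductivity inversion
#'
#' For a uniform field across a prism of thickness `l` and cross-section
#' `A`, conductivity follows from the measured burst resistance:
#' `sigma = l / (A * R_B)`.
#'
#' @param R_B Measured burst resistance in ohms (> 0).
#' @param l Sample thickness in meters (> 0).
#' @param A Cross-sectional area in square meters (> 0).
#' @return Conductivity in S/m.
#' @examples
#' prism_conductivity(385.9, 6e-3, plate_area(6e-3))  # ~0.55 S/m
#' @export
prism_conductivity <- function(R_B, l, A) {
  if (any(R_B <= 0)) stop("'R_B' must be positive (ohm)", call. = FALSE)
  if (l <= 0 || A <= 0)
    stop("'l' and 'A' must be positive (SI units)", call. = FALSE)
  l / (A * R_B)
}

# Electrode gap used to normalize applied voltage to V/cm.
.gap_cm <- function(geom) {
  switch(geom$kind,
         plate = geom$thickness / 10,
         needle_pair = geom$spacing,
         stop("unknown geometry kind: ", geom$kind, call. = FALSE))
}

# Shape factor S (m) with R = 1/(sigma * S).
.shape_factor <- function(geom) {
  switch(geom$kind,
         plate = plate_area(geom$diameter / 1000) / (geom$thickness / 1000),
         needle_pair = needle_pair_shape_factor(geom),
         stop("unknown geometry kind: ", geom$kind, call. = FALSE))
}

#' Two-parallel-cylinder shape factor
#'
#' Infinite-medium shape factor for two parallel cylindrical electrodes of
#' radius `a`, center spacing `D`, exposure length `L`:
#' `S = pi * L / acosh(D / (2a))`, with predicted resistance
#' `R = 1 / (sigma * S)`. An approximation for needles in bulk tissue; it
#' ignores boundaries and insertion-depth end effects.
#'
#' @param geom A needle-pair [needle_pair_geometry()].
#' @return Shape factor in meters.
#' @examples
#' needle_pair_shape_factor(needle_pair_geometry(1.0, 0.5, 1.0)) # ~0.0105 m
#' @export
needle_pair_shape_factor <- function(geom) {
  stopifnot(inherits(geom, "geometry_spec"))
  if (geom$kind != "needle_pair")
    stop("shape factor defined for needle-pair geometries", call. = FALSE)
  D <- geom$spacing / 100      # m
  a <- geom$radius / 1000      # m
  L <- geom$exposure / 100     # m
  if (D <= 2 * a)
    stop("spacing must exceed electrode diameter", call. = FALSE)
  pi * L / acosh(D / (2 * a))
}

#' Voltage needed for a distance-normalized level
#'
#' Converts an applied-field level (V/cm, voltage normalized by electrode
#' gap) to the generator voltage: `level * thickness` for plates,
#' `level * spacing` for needle pairs. E.g. 100 V/cm across a 6 mm plate
#' sample requires 60 V.
#'
#' @param level Distance-normalized voltage in V/cm (>= 0).
#' @param geom A `geometry_spec`.
#' @return Voltage in volts.
#' @export
voltage_for_field <- function(level, geom) {
  if (any(level < 0)) stop("'level' must be non-negative", call. = FALSE)
  level * .gap_cm(geom)
}

#' Standard voltage-ramp level schedules
#'
#' Distance-normalized voltage schedules used on the bench. The 1.5 cm
#' needle spacing is capped at 1500 V/cm by generator current limits; the
#' plate schedule starts at 100 V/cm (60 V at 6 mm) because of the
#' generator's 50 V floor; cardiac ramps run 100-2500 V/cm.
#'
#' @param setting One of `"potato_1cm"`, `"potato_1.5cm"`, `"cardiac"`,
#'   `"plate"`.
#' @return Increasing numeric vector of levels in V/cm.
#' @export
ramp_levels <- function(setting = c("potato_1cm", "potato_1.5cm", "cardiac",
                                    "plate")) {
  setting <- match.arg(setting)
  base <- c(50, 100, 250, 500, 750, 1000, 1250, 1500, 1750, 2000)
  switch(setting,
         potato_1cm = base,
         "potato_1.5cm" = base[base <= 1500],
         cardiac = c(base[base >= 100], 2250, 2500),
         plate = base[base >= 100])
}

#' Conductivity versus applied field from ramp results
#'
#' Applies the prism inversion `sigma = l / (A * R)` to per-level mean
#' resistances. Valid only for the plate geometry, where the field is
#' uniform; needle-pair resistances fold in the non-uniform field and any
#' field-dependent conductivity change, so inverting them with a single
#' shape factor is refused unless explicitly overridden (the override uses
#' the infinite-medium cylinder-pair shape factor and is for exploratory
#' use only).
#'
#' @param results Data frame with columns `level` (V/cm) and `R` (ohm),
#'   e.g. from [process_ramp()].
#' @param geom A `geometry_spec`; for plates, its recorded (per-sample)
#'   thickness is used in the inversion.
#' @param allow_needle Set `TRUE` to force a shape-factor estimate for
#'   needle pairs despite the caveat above.
#' @return Data frame of class `conductivity_curve` with columns `level`
#'   and `sigma` (S/m).
#' @export
conductivity_curve <- function(results, geom, allow_needle = FALSE) {
  stopifnot(is.data.frame(results), all(c("level", "R") %in% names(results)))
  if (is.unsorted(results$level))
    results <- results[order(results$level), , drop = FALSE]
  if (geom$kind == "plate") {
    sigma <- prism_conductivity(results$R, geom$thickness / 1000,
                                plate_area(geom$diameter / 1000))
  } else if (isTRUE(allow_needle)) {
    sigma <- 1 / (results$R * needle_pair_shape_factor(geom))
  } else {
    stop("conductivity inversion requires the uniform-field plate geometry; ",
         "needle-pair resistances mix the non-uniform field with dynamic ",
         "conductivity. Use allow_needle = TRUE for an exploratory ",
         "shape-factor estimate.", call. = FALSE)
  }
  structure(data.frame(level = results$level, sigma = sigma),
            class = c("conductivity_curve", "data.frame"))
}
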