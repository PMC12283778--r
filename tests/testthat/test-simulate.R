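test_that("traces are bit-identical under the same seed", {
  pars <- tissue_preset("potato")   # 1% noise on
  p <- burst_protocol(1, 10, 10, cycles = 5, sampling_period = 20,
                      amplitude = 500)
  t1 <- simulate_trace(p, needle1cm(), pars, seed = 99)
  t2 <- simulate_trace(p, needle1cm(), pars, seed = 99)
  expect_identical(t1$voltage, t2$voltage)
  expect_identical(t1$current, t2$current)
  t3 <- simulate_trace(p, needle1cm(), pars, seed = 100)
  expect_false(identical(t1$current, t3$current))
  # seeding restores the RNG state
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_trace(p, needle1cm(), pars, seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("delays do not enter the tissue model", {
  pars <- quiet_params()
  geom <- needle1cm()
  base <- NULL
  for (d2 in c(1, 10, 100)) {
    p <- burst_protocol(1, 1, d2, cycles = 3, sampling_period = 20,
                        amplitude = 500)
    tr <- simulate_trace(p, geom, pars)
    w <- segment_pulses(tr, p)
    # raw mid-pulse plateau currents: identical for every delay
    mid <- tr$current[(w$start + w$end) %/% 2] * w$polarity
    bm <- burst_metrics(tr, p)
    if (is.null(base)) {
      base <- list(mid = mid, R = bm$R, sigma = tr$meta$sigma_true)
    } else {
      expect_identical(mid, base$mid)
      expect_identical(tr$meta$sigma_true, base$sigma)
      # filtered V and I share the burst's timing, so R is delay-invariant
      # even though individual filtered maxima depend on gap lengths
      expect_equal(bm$R, base$R, tolerance = 1e-9)
    }
  }
})

test_that("simulated current reflects the geometry and conductivity", {
  pars <- quiet_params(sigma_bulk = 0.2, sigma_max = 0.2)
  p <- burst_protocol(2, 5, 5, cycles = 3, amplitude = 900)
  tr <- simulate_trace(p, plate6(), pars)
  R_true <- 6e-3 / (0.2 * plate_area(6e-3))
  expect_equal(tr$meta$R_true, R_true)
  expect_equal(max(tr$current), 900 / R_true, tolerance = 1e-9)
  expect_equal(tr$meta$E_app, 900 / 0.6)
})

test_that("mechanistic mode shows intra-pulse current growth", {
  pars <- quiet_params(mode = "mechanistic")
  p <- burst_protocol(10, 10, 10, cycles = 2, amplitude = 600)
  tr <- simulate_trace(p, plate6(), pars)
  w <- segment_pulses(tr, p)
  i1 <- tr$current[w$start[1]:w$end[1]]
  # current rises toward steady state as membranes charge (sigma_ss > sigma_hf
  # here because 600 V over 6 mm = 1000 V/cm is well past the transition)
  expect_gt(i1[length(i1)], i1[1])
  expect_equal(i1[1], 600 / tr$meta$R_true * 0.13 /
                 tr$meta$sigma_true, tolerance = 1e-6)
})

test_that("ramps deliver 3 bursts per level with correct amplitudes", {
  pars <- quiet_params()
  p <- burst_protocol(1, 10, 10, cycles = 3, sampling_period = 20)
  lv <- ramp_levels("potato_1cm")
  ramp <- simulate_ramp(p, needle1cm(), pars, levels = lv, seed = 3)
  expect_length(ramp, 30L)   # 10 levels x 3 bursts
  # potato 1 cm preset: first level amplitude 50 V
  expect_equal(ramp[[1]]$meta$amplitude, 50)
  expect_equal(ramp[[30]]$meta$amplitude, 2000)
  expect_identical(vapply(ramp, function(t) t$meta$burst, numeric(1)),
                   rep(c(1, 2, 3), 10))
  expect_error(simulate_ramp(p, needle1cm(), pars, levels = c(100, 100)),
               "increasing")
})

test_that("ramps have no memory across levels", {
  pars <- quiet_params()
  p <- burst_protocol(1, 10, 10, cycles = 3, sampling_period = 20)
  geom <- needle1cm()
  full <- simulate_ramp(p, geom, pars, levels = ramp_levels("potato_1cm"))
  alone <- simulate_ramp(p, geom, pars, levels = 2000)
  final <- full[vapply(full, function(t) t$meta$level == 2000, logical(1))]
  for (b in 1:3)
    expect_identical(final[[b]]$current, alone[[b]]$current)
})

test_that("plate ramps draw and record a per-sample thickness", {
  pars <- quiet_params()
  geom <- geometry_preset("potato_plate")    # thickness_sd = 0.2 mm
  p <- burst_protocol(10, 10, 10, cycles = 2, sampling_period = 20)
  ramp <- simulate_ramp(p, geom, pars, levels = c(100, 500), seed = 11)
  th <- attr(ramp, "geometry")$thickness
  expect_false(identical(th, 6))
  expect_gt(th, 5); expect_lt(th, 7)
  # voltage computed from the realized thickness: E is exact
  expect_equal(ramp[[1]]$meta$amplitude, 100 * th / 10)
  expect_equal(ramp[[1]]$meta$E_app, 100)
  # inversion with the recorded thickness recovers sigma despite the draw
  cc <- conductivity_curve(process_ramp(ramp, p), attr(ramp, "geometry"))
  expect_equal(cc$sigma, apparent_conductivity(cc$level, 10, pars),
               tolerance = 0.01)
})

test_that("sub-electroporation resistance orders by pulse width and converges", {
  pars <- quiet_params()
  geom <- needle1cm()
  R_at <- function(pw, level) {
    p <- burst_protocol(pw, 10, 10, cycles = 3, sampling_period = 20,
                        amplitude = voltage_for_field(level, geom))
    burst_metrics(simulate_trace(p, geom, pars), p)$R
  }
  # at 50 V/cm: R(10) > R(5) > R(2) > R(1) (membranes intact, short pulses
  # read a higher apparent conductivity)
  R50 <- vapply(c(1, 2, 5, 10), R_at, numeric(1), level = 50)
  expect_true(all(diff(R50) > 0))
  # after electroporation the pulse widths converge: the relative spread
  # collapses from >100% at 50 V/cm to <10% at 500 V/cm
  R500 <- vapply(c(1, 2, 5, 10), R_at, numeric(1), level = 500)
  expect_gt((max(R50) - min(R50)) / min(R50), 1)
  expect_lt((max(R500) - min(R500)) / min(R500), 0.10)
})
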