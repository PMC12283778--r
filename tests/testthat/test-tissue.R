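test_that("apparent conductivity hits floor, midpoint and plateau exactly", {
  pars <- quiet_params()
  # E = 0: bulk exactly (sigmoid floor is reached at E_th - 3w = 50 V/cm)
  expect_identical(apparent_conductivity(0, 1, pars), 0.13)
  expect_identical(apparent_conductivity(0, 10, pars), 0.04)
  # E = E_th: midpoint
  expect_equal(apparent_conductivity(500, 1, pars), (0.13 + 0.55) / 2)
  expect_equal(apparent_conductivity(500, 10, pars), (0.04 + 0.67) / 2)
  # large E: plateau to 1e-6 S/m
  expect_equal(apparent_conductivity(5000, 1, pars), 0.55,
               tolerance = 1e-6 / 0.55)
  expect_equal(apparent_conductivity(2000, 10, pars), 0.67,
               tolerance = 1e-6 / 0.67)
  expect_error(apparent_conductivity(-1, 1, pars), "non-negative")
})

test_that("apparent conductivity is monotone in field and bounded", {
  pars <- quiet_params()
  E <- seq(0, 3000, by = 10)
  for (pw in c(1, 2, 5, 10)) {
    s <- apparent_conductivity(E, pw, pars)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= min(pars$sigma_bulk_by_pw) - 1e-12))
    expect_true(all(s <= max(pars$sigma_max_by_pw) + 1e-12))
  }
})

test_that("intermediate pulse widths interpolate between tabulated ones", {
  pars <- quiet_params()
  s1 <- apparent_conductivity(0, 1, pars)
  s10 <- apparent_conductivity(0, 10, pars)
  for (pw in c(2, 5)) {
    s <- apparent_conductivity(0, pw, pars)
    expect_gt(s, s10); expect_lt(s, s1)
  }
  # log10 interpolation ordering: bulk sigma decreases with pulse width
  ss <- vapply(c(1, 2, 5, 10), function(pw)
    apparent_conductivity(0, pw, pars), numeric(1))
  expect_true(all(diff(ss) < 0))
})

test_that("mechanistic conductivity follows the membrane-charging form", {
  pars <- quiet_params(mode = "mechanistic")
  sigma_hf <- 0.13                              # bulk at shortest PW
  sigma_ss <- apparent_conductivity(300, 10, pars)  # steady state at 10 us
  expect_identical(mechanistic_conductivity(0, 300, pars), sigma_hf)
  expect_equal(mechanistic_conductivity(pars$tau_mem, 300, pars),
               sigma_ss + (sigma_hf - sigma_ss) * exp(-1))
  expect_equal(mechanistic_conductivity(10 * pars$tau_mem, 100, pars),
               apparent_conductivity(100, 10, pars), tolerance = 1e-4)
  bad <- quiet_params(); bad$tau_mem <- 0
  expect_error(mechanistic_conductivity(1, 100, bad), "tau_mem")
  expect_error(mechanistic_conductivity(-1, 100, pars), "non-negative")
})

test_that("parameter validation catches inconsistent conductivities", {
  expect_error(tissue_params(c("1" = 0.5), c("1" = 0.3)), "plateau")
  expect_error(tissue_params(c("1" = -1), c("1" = 0.3)), "positive")
  expect_error(tissue_params(c("1" = 0.1), c("1" = 0.3), E_th = 0),
               "E_th")
  expect_error(tissue_params(c(0.1, 0.2), c(0.5, 0.5)), "names")
})

test_that("shipped presets load and carry the calibrated values", {
  pars <- tissue_preset("potato")
  expect_s3_class(pars, "tissue_params")
  expect_identical(apparent_conductivity(0, 1, pars), 0.13)
  expect_identical(apparent_conductivity(0, 10, pars), 0.04)
  expect_equal(apparent_conductivity(1e4, 1, pars), 0.55)
  expect_equal(apparent_conductivity(1e4, 10, pars), 0.67)
  expect_identical(pars$E_th, 500)
  expect_s3_class(tissue_preset("cardiac"), "tissue_params")
  expect_error(tissue_preset("granite"), "unknown")
  expect_true(all(c("potato", "cardiac") %in% tissue_preset(NULL)))
  # overrides pass through
  expect_identical(tissue_preset("potato", noise_rel = 0)$noise_rel, 0)
})

test_that("geometry presets load with the documented dimensions", {
  gp <- geometry_preset("potato_plate")
  expect_identical(gp$kind, "plate")
  expect_identical(gp$thickness, 6)
  gn <- geometry_preset("potato_needle_1.0cm")
  expect_identical(gn$spacing, 1)
  expect_identical(gn$radius, 0.5)
  gc <- geometry_preset("cardiac_needle")
  expect_identical(gc$radius, 0.225)
  expect_identical(gc$exposure, 0.4)
  # the figure-caption variant is shipped alongside, flagged by name
  expect_identical(geometry_preset("cardiac_needle_caption")$exposure, 0.5)
  expect_error(geometry_preset("nope"), "unknown")
})
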