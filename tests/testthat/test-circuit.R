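test_that("quarter-wave line reproduces its ABCD closed form", {
  m <- srr_model()
  f <- 3e9
  gam <- guvscan:::gamma_at(srr_model(loss_per_length = 0), f)
  beta <- Im(gam)
  len <- (pi / 2) / beta
  A <- guvscan:::abcd_line(50, complex(imaginary = beta), len)
  expect_lt(Mod(A$A), 1e-12)
  expect_lt(Mod(A$B - 50i), 1e-9)
  expect_lt(Mod(A$C - 1i / 50), 1e-12)
})

test_that("uncoupled lossless ring is invisible: |s21| = 1 on a grid", {
  m <- srr_model(coupling_capacitance = 0, loss_per_length = 0)
  sp <- s21_spectrum(m, seq(1e9, 10e9, length.out = 40))
  expect_true(all(abs(Mod(sp$s21) - 1) < 1e-12))
  ## with loss, the matched-line closed form |s21| = exp(-alpha * l) holds
  m2 <- srr_model(coupling_capacitance = 0, loss_per_length = 0.3)
  r <- network_response(m2, 5e9)
  expect_equal(Mod(r$s21), exp(-0.3 * m2$line_length), tolerance = 1e-12)
})

test_that("analytic dip frequencies agree with 10-kHz grid search", {
  m <- cal_model()
  for (f0 in m$mode_frequencies) {
    grid <- seq(f0 - 5e6, f0 + 5e6, by = 1e4)
    a <- Mod(network_response(m, grid)$s21)
    expect_lt(abs(grid[which.min(a)] - f0), 1e4 + 1e-6)
  }
})

test_that("calibrated model hits the working modes, phases and coupling band", {
  m <- cal_model()
  expect_equal(m$mode_frequencies[1], 2.7e9, tolerance = 1e-3)
  expect_equal(m$mode_frequencies[2], 7.9e9, tolerance = 1e-3)
  ph <- guvscan:::s21_phase_deg(m, c(2.7e9, 7.9e9))
  expect_lt(abs(guvscan:::wrap_deg(ph[1] - 103.9)), 0.5)
  expect_lt(abs(guvscan:::wrap_deg(ph[2] - 339.88)), 0.5)
  ## roughly half the probing energy couples into the resonator at f1
  d <- dissipated_fraction(m, m$mode_frequencies[1])
  expect_gt(d, 0.3)
  expect_lt(d, 0.6)
  ## spectrum over the band shows dips at both calibrated modes
  sp <- s21_spectrum(m, seq(1e9, 10e9, by = 5e6))
  a <- Mod(sp$s21)
  loc <- which(diff(sign(diff(a))) == 2) + 1
  near <- vapply(m$mode_frequencies, function(f)
    min(abs(sp$frequency[loc] - f)) / f, numeric(1))
  expect_true(all(near < 2e-3))
})

test_that("calibrating a model to its own dips is a fixed point", {
  m <- cal_model()
  m2 <- calibrate_srr(m, target_modes = m$mode_frequencies,
                      target_phases = guvscan:::s21_phase_deg(
                        m, m$mode_frequencies))
  expect_equal(m2$ring_circumference, m$ring_circumference,
               tolerance = 1e-6)
  expect_equal(m2$eps_eff_coef, m$eps_eff_coef, tolerance = 1e-6)
  expect_equal(m2$line_length, m$line_length, tolerance = 1e-6)
})

test_that("calibration beats an exhaustive coarse grid over the dispersion law", {
  m <- cal_model()
  targets <- c(2.7e9, 7.9e9)
  resid_of <- function(mm) {
    d <- tryCatch(dip_frequencies(mm, fmin = 1.5e9, fmax = 9.5e9),
                  error = function(e) NULL)
    if (is.null(d)) return(Inf)
    sum(((d - targets) / targets)^2)
  }
  grid_res <- Inf
  for (e0 in seq(2.2, 3.0, by = 0.2))
    for (e1 in seq(0.02, 0.08, by = 0.02)) {
      mm <- m; mm$eps_eff_coef <- c(e0, e1)
      grid_res <- min(grid_res, resid_of(mm))
    }
  expect_lte(resid_of(m), grid_res)
})

test_that("network is reciprocal and passive everywhere", {
  m <- cal_model()
  grid <- seq(1e9, 10e9, length.out = 400)
  r <- network_response(m, grid)
  expect_identical(r$s21, r$s12)          # reciprocity by construction
  expect_true(all(Mod(r$s11)^2 + Mod(r$s21)^2 <= 1 + 1e-9))
  ## AD - BC = 1 for the reciprocal cascade at a spot frequency
  gam <- guvscan:::gamma_at(m, 2.7e9)
  half <- guvscan:::abcd_line(m$line_impedance, gam, m$line_length / 2)
  yb <- guvscan:::branch_admittance(m, 2.7e9)
  mm <- guvscan:::abcd_mul(guvscan:::abcd_mul(half,
                                              guvscan:::abcd_shunt(yb)),
                           half)
  expect_lt(Mod(mm$A * mm$D - mm$B * mm$C - 1), 1e-9)
})

test_that("dip depth grows monotonically with coupling capacitance", {
  base <- cal_model()
  depths <- vapply(c(0.8, 0.9, 1, 1.1, 1.2), function(sc) {
    mm <- srr_model(ring_circumference = base$ring_circumference,
                    eps_eff_coef = base$eps_eff_coef,
                    coupling_capacitance = base$coupling_capacitance * sc,
                    loss_per_length = base$loss_per_length,
                    line_length = base$line_length)
    d1 <- dip_frequencies(mm, fmin = 2e9, fmax = 3.5e9, n_modes = 1)
    Mod(network_response(mm, d1)$s21)
  }, numeric(1))
  expect_true(all(diff(depths) < 0))   # |s21| at dip falls = deeper dip
})

test_that("delta_s21 is the finite-difference identity and locally linear", {
  m <- cal_model()
  f <- m$mode_frequencies[1]
  expect_identical(delta_s21(m, 0, f), 0 + 0i)
  dc <- 1e-4 * m$split_gap_capacitance
  d1 <- delta_s21(m, dc, f)
  fd <- network_response(m, f, delta_gap = dc)$s21 -
    network_response(m, f)$s21
  expect_lt(Mod(d1 - fd), 1e-12)
  ratio <- Mod(delta_s21(m, 2 * dc, f)) / Mod(d1)
  expect_gt(ratio, 1.98)
  expect_lt(ratio, 2.02)
  expect_error(delta_s21(m, m$split_gap_capacitance, f),
               "out of linear range")
})

test_that("model validation rejects unphysical parameters", {
  expect_error(srr_model(ring_circumference = -1), "strictly positive")
  expect_error(srr_model(eps_eff_coef = c(0.5, 0)), "e0 > 1")
  expect_error(srr_model(mode_frequencies = c(2e9, 2e9)),
               "strictly increasing")
  expect_error(s21_spectrum(cal_model(), numeric(0)), "non-empty")
  expect_error(network_response(cal_model(), -1), "finite and > 0")
})
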