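popc_cfg <- function(frequency = 2.7e9, elevation = 0)
  extraction_config(frequency, membrane_thickness = 4e-9,
                    elevation = elevation)
sm_cfg <- function(frequency = 2.7e9, elevation = 0)
  extraction_config(frequency, membrane_thickness = 5e-9,
                    elevation = elevation)

anchored <- function(cfg, eps, delta) {
  m <- cal_model(); geom <- default_geom()
  cfg$gain <- calibrate_gain(eps, delta, cfg, m, geom)
  cfg
}

test_that("forward model vanishes without dielectric contrast", {
  m <- cal_model(); geom <- default_geom()
  cfg <- popc_cfg(); cfg$gain <- 1 + 0i
  eps_w <- water_permittivity(2.7e9)
  expect_identical(forward_delta(eps_w, cfg, m, geom), 0 + 0i)
})

test_that("|delta-S21| grows with the real-part contrast against the medium", {
  m <- cal_model(); geom <- default_geom()
  cfg <- popc_cfg(); cfg$gain <- 1 + 0i
  epr <- c(40, 60, 80, 100)
  mags <- vapply(epr, function(e)
    Mod(forward_delta(complex(real = e, imaginary = -8), cfg, m, geom)),
    numeric(1))
  contrast <- abs(epr - Re(water_permittivity(2.7e9)))
  expect_identical(order(mags), order(contrast))
})

test_that("gain calibration reproduces its anchor and scales linearly", {
  m <- cal_model(); geom <- default_geom()
  eps <- complex_permittivity(73.64, 6.13)
  cfg <- anchored(popc_cfg(), eps, 4.09e-4)
  f <- forward_delta(eps, cfg, m, geom)
  expect_equal(Mod(f), 4.09e-4, tolerance = 1e-9)
  g2 <- calibrate_gain(eps, 2 * 4.09e-4, popc_cfg(), m, geom)
  expect_equal(Mod(g2) / Mod(cfg$gain), 2, tolerance = 1e-9)
  expect_error(calibrate_gain(water_permittivity(2.7e9), 4e-4,
                              popc_cfg(), m, geom), "degenerate anchor")
})

test_that("published permittivities round-trip through forward + invert", {
  m <- cal_model(); geom <- default_geom()
  p <- presets()$permittivity
  th <- c(SM = 5e-9, POPC = 4e-9)
  anchors <- presets()$fig3e
  for (i in seq_len(nrow(p))) {
    eps <- complex(real = p$eps_real[i], imaginary = -p$eps_imag[i])
    cfg <- extraction_config(p$frequency[i],
                             membrane_thickness = th[[p$lipid[i]]],
                             elevation = p$elevation_nm[i] * 1e-9)
    mu <- anchors$mu[anchors$lipid == p$lipid[i] &
                       abs(anchors$frequency - p$frequency[i]) < 1e6]
    cfg$gain <- calibrate_gain(eps, mu, cfg, m, geom)
    obs <- forward_delta(eps, cfg, m, geom)
    r <- extract_permittivity(obs, cfg, m, geom)
    expect_lt(abs(r$permittivity$real_part - p$eps_real[i]) /
                p$eps_real[i], 1e-3)
    expect_lt(abs(r$permittivity$imag_part - p$eps_imag[i]) /
                p$eps_imag[i], 1e-3)
    expect_identical(r$permittivity$orientation, "parallel")
    expect_lt(r$residual, cfg$tol * 10)
  }
})

test_that("round trips hold on a 9-point permittivity grid", {
  m <- cal_model(); geom <- default_geom()
  cfg <- anchored(popc_cfg(), complex_permittivity(73.64, 6.13), 4.09e-4)
  for (ep in c(60, 75, 90))
    for (epp in c(1, 8, 16)) {
      obs <- forward_delta(complex(real = ep, imaginary = -epp),
                           cfg, m, geom)
      r <- extract_permittivity(obs, cfg, m, geom)
      expect_lt(abs(r$permittivity$real_part - ep) / ep, 1e-3)
      expect_lt(abs(r$permittivity$imag_part - epp) / epp, 1e-3)
    }
})

test_that("zero observed signal recovers the Debye water permittivity", {
  m <- cal_model(); geom <- default_geom()
  for (f in c(2.7e9, 7.9e9)) {
    cfg <- anchored(sm_cfg(f), complex_permittivity(70, 5), 8e-4)
    r <- extract_permittivity(0 + 0i, cfg, m, geom)
    eps_w <- water_permittivity(f)
    expect_equal(r$permittivity$real_part, Re(eps_w), tolerance = 1e-6)
    expect_equal(r$permittivity$imag_part, -Im(eps_w), tolerance = 1e-6)
  }
  ## closed-form Debye check of the medium itself
  expect_equal(Re(water_permittivity(2.7e9)), 77.0, tolerance = 1e-3)
  expect_equal(Re(water_permittivity(7.9e9)), 67.8, tolerance = 1e-2)
})

test_that("elevation = 0 path is identical to the contact inversion", {
  m <- cal_model(); geom <- default_geom()
  cfg <- anchored(sm_cfg(), complex_permittivity(73.17, 1.34), 8.99e-4)
  obs <- forward_delta(complex_permittivity(73.17, 1.34), cfg, m, geom)
  r1 <- extract_permittivity(obs, cfg, m, geom)
  r2 <- extract_permittivity(obs, cfg, m, geom, elevation = 0)
  expect_identical(coef(r1), coef(r2))
})

test_that("recovered permittivity varies continuously with assumed elevation", {
  m <- cal_model(); geom <- default_geom()
  cfg <- anchored(sm_cfg(), complex_permittivity(73.17, 1.34), 8.99e-4)
  obs <- forward_delta(complex_permittivity(73.17, 1.34), cfg, m, geom)
  elevs <- seq(0, 100e-9, by = 25e-9)
  eps <- vapply(elevs, function(e) {
    r <- extract_permittivity(obs, cfg, m, geom, elevation = e)
    Mod(as.complex(r$permittivity))
  }, numeric(1))
  steps <- abs(diff(eps)) / eps[-length(eps)]
  expect_true(all(steps < 0.05 * 2.5))  # < 5% per 10 nm, 25 nm steps
})

test_that("inversion rejects missing gain and non-finite input", {
  m <- cal_model(); geom <- default_geom()
  expect_error(extract_permittivity(1e-4 + 0i, popc_cfg(), m, geom),
               "gain not calibrated")
  cfg <- anchored(popc_cfg(), complex_permittivity(73.64, 6.13), 4.09e-4)
  expect_error(extract_permittivity(NaN + 0i, cfg, m, geom), "finite")
  expect_error(extraction_config(1e9, membrane_thickness = -1))
  cfg_bad <- extraction_config(5e9)
  expect_error(forward_delta(complex_permittivity(70, 5), cfg_bad, m, geom),
               "not a calibrated mode")
})
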