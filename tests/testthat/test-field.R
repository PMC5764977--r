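fm_default <- NULL
get_fm_default <- function() {
  if (is.null(fm_default))
    fm_default <<- solve_potential(default_geom(), water_stack(),
                                   resolution = 24)
  fm_default
}

test_that("discrete solution conserves flux and is antisymmetric", {
  fm <- get_fm_default()
  expect_lt(fm$residual, 1e-8)
  nx <- length(fm$x)
  expect_lt(max(Mod(fm$phi + fm$phi[rev(seq_len(nx)), ])), 1e-10)
})

test_that("homogeneous symmetric solve has zero potential on the centreline", {
  fm <- solve_potential(sheet_geom(78), uniform_stack(78), resolution = 16)
  i0 <- which.min(abs(fm$x))
  expect_lt(max(Mod(fm$phi[i0, ])), 1e-12)
})

test_that("zero-thickness homogeneous limit matches the elliptic-integral capacitance", {
  s <- 500e-9
  fm <- solve_potential(sheet_geom(1), uniform_stack(1), resolution = 24,
                        extent_x = 10 * s, extent_above = 40 * s,
                        extent_below = 40 * s)
  cc <- Re(gap_capacitance(map = fm)$per_meter)
  cref <- coplanar_slot_capacitance(s, 10 * s, eps = 1)
  expect_lt(abs(cc - cref) / cref, 0.02)
})

test_that("centreline intensity matches the coplanar half-plane profile", {
  s <- 500e-9
  fm <- solve_potential(sheet_geom(1), uniform_stack(1), resolution = 64,
                        extent_x = 30 * s, extent_above = 30 * s,
                        extent_below = 30 * s)
  prof <- field_profile(fm)
  sel <- prof$y > 1e-9 & prof$y <= 2 * s
  ref <- 1 / (1 + (2 * prof$y[sel] / s)^2)
  expect_lt(max(abs(prof$ratio[sel] / ref - 1)), 0.02)
  ## spot value at y = s/2: analytic 0.5
  j <- which.min(abs(prof$y - s / 2))
  expect_equal(prof$ratio[j], 1 / (1 + (2 * prof$y[j] / s)^2),
               tolerance = 0.02)
  ## identity at the reference height
  expect_identical(prof$ratio[which.min(abs(prof$y))], 1)
})

test_that("capacitance converges under grid doubling at default resolution", {
  c1 <- gap_capacitance(default_geom(), water_stack(), resolution = 24)
  c2 <- gap_capacitance(default_geom(), water_stack(), resolution = 48)
  expect_lt(Mod(c2$per_meter - c1$per_meter) / Mod(c2$per_meter), 0.01)
  expect_equal(c1$total, c1$per_meter * default_geom()$slot_length)
})

test_that("capacitance is linear in a global permittivity scaling", {
  st1 <- uniform_stack(2)
  st2 <- uniform_stack(4)
  g <- sheet_geom(2); g2 <- sheet_geom(4)
  c1 <- Re(gap_capacitance(g, st1, resolution = 16)$per_meter)
  c2 <- Re(gap_capacitance(g2, st2, resolution = 16)$per_meter)
  expect_equal(c2 / c1, 2, tolerance = 1e-9)
})

test_that("adding a high-permittivity layer strictly increases capacitance", {
  base <- layer_stack(list(
    list(name = "membrane", thickness = 5e-9, permittivity = 10,
         analyte = TRUE),
    list(name = "bulk", thickness = Inf, permittivity = 10,
         analyte = FALSE)))
  rich <- layer_stack(list(
    list(name = "membrane", thickness = 5e-9, permittivity = 80,
         analyte = TRUE),
    list(name = "bulk", thickness = Inf, permittivity = 10,
         analyte = FALSE)))
  c0 <- Re(gap_capacitance(default_geom(), base, resolution = 16)$per_meter)
  c1 <- Re(gap_capacitance(default_geom(), rich, resolution = 16)$per_meter)
  expect_gt(c1, c0)
})

test_that("sensitivity kernel satisfies the Euler identity and predicts re-solves", {
  geom <- default_geom()
  st <- water_stack()
  fm <- get_fm_default()
  kern <- sensitivity_kernel(map = fm)
  cc <- gap_capacitance(map = fm)$per_meter
  eps_of <- function(L) {
    if (L == "substrate") return(complex(real = geom$substrate_permittivity))
    if (L == "cavity") return(st$permittivity[length(st$permittivity)])
    st$permittivity[match(L, st$name)]
  }
  euler <- sum(kern$per_meter * vapply(kern$layer, eps_of, complex(1)))
  expect_lt(Mod(euler - cc) / Mod(cc), 1e-10)
  expect_true(all(Re(kern$per_meter) >= 0))

  ## first-order prediction for +1 in the membrane layer vs full re-solve
  w <- kern$per_meter[kern$layer == "membrane"]
  st2 <- membrane_stack(2.7e9, membrane_thickness = 5e-9,
                        membrane_permittivity =
                          water_permittivity(2.7e9) + 1)
  c2 <- gap_capacitance(default_geom(), st2, resolution = 24)$per_meter
  expect_lt(Mod((c2 - cc) - w) / Mod(w), 0.03)
})

test_that("kernel weight attenuation under elevation tracks elevation_factor", {
  geom <- default_geom()
  fm <- get_fm_default()
  k0 <- sensitivity_kernel(map = fm)
  w0 <- Mod(k0$per_meter[k0$layer == "membrane"])
  st_e <- membrane_stack(2.7e9, membrane_thickness = 5e-9,
                         elevation = 100e-9)
  ke <- sensitivity_kernel(geom, st_e, resolution = 24)
  we <- Mod(ke$per_meter[ke$layer == "membrane"])
  ef <- elevation_factor(fm, 100e-9)
  expect_equal(we / w0, ef, tolerance = 0.05)
})

test_that("elevation factor is 1 at contact and strictly decreasing", {
  fm <- get_fm_default()
  expect_identical(elevation_factor(fm, 0), 1)
  ef <- elevation_factor(fm, c(50e-9, 100e-9, 200e-9))
  expect_true(all(diff(ef) < 0))
  expect_true(all(ef > 0 & ef < 1))
  expect_error(elevation_factor(fm, 1), "beyond the simulated domain")
  expect_error(elevation_factor(fm, -1e-9), ">= 0")
})

test_that("field profile decays monotonically and is much weaker at the channel top", {
  fm <- get_fm_default()
  prof <- field_profile(fm)
  expect_true(all(prof$intensity > 0))
  expect_true(all(diff(prof$intensity[prof$y >= 0]) <= 0))
  itop <- prof$intensity[which.min(abs(prof$y -
                                         default_geom()$channel_height))]
  expect_gt(prof$intensity[1] / itop, 10)
})

test_that("parallel energy fraction: >90% in the sensing region, ~1 between the side-walls", {
  fm <- get_fm_default()
  pf <- parallel_energy_fraction(fm)
  expect_gt(pf$parallel, 0.9)
  expect_equal(pf$parallel + pf$perpendicular, 1, tolerance = 1e-12)
  s <- default_geom()$slot_width; t <- default_geom()$metal_thickness
  slot <- parallel_energy_fraction(fm, region = list(
    x = c(-s / 2, s / 2), y = c(-0.9 * t, -0.1 * t)))
  expect_gt(slot$parallel, 0.99)
  expect_error(parallel_energy_fraction(fm, region = list(
    x = c(1e-3, 2e-3), y = c(1e-3, 2e-3))), "empty region")
})

test_that("input validation catches bad stacks and resolutions", {
  expect_error(solve_potential(default_geom(), water_stack(),
                               resolution = 8), "at least 16")
  expect_error(layer_stack(list()), "at least one layer")
  expect_error(layer_stack(list(
    list(name = "a", thickness = 1e-9, permittivity = 5, analyte = TRUE),
    list(name = "b", thickness = Inf, permittivity = 5, analyte = TRUE))),
    "exactly one layer")
  expect_error(sensor_geometry(slot_width = 30e-6), "smaller than")
})
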