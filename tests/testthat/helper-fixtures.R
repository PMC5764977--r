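# shared fixtures: the calibrated device model is cached inside the package
# environment, so repeated calls across test files are cheap
cal_model <- function() srr_model_calibrated()

default_geom <- function() sensor_geometry()

water_stack <- function(frequency = 2.7e9, thickness = 5e-9, elevation = 0)
  membrane_stack(frequency, membrane_thickness = thickness,
                 elevation = elevation)

# homogeneous zero-thickness-sheet configuration for the conformal-map
# oracles
sheet_geom <- function(eps = 1) {
  g <- sensor_geometry(substrate_permittivity = eps)
  g$metal_thickness <- 0
  g
}

uniform_stack <- function(eps = 1)
  layer_stack(list(list(name = "medium", thickness = Inf,
                        permittivity = eps, analyte = TRUE)))

EPS0 <- 8.8541878128e-12

# elliptic-integral capacitance of the coplanar slot in a zero-flux box of
# half-width Lx (per unit length, both half-spaces, homogeneous eps)
coplanar_slot_capacitance <- function(s, Lx, eps = 1) {
  k <- sin(pi * s / (4 * Lx))
  kk <- pracma::ellipke(k^2)$k
  kkp <- pracma::ellipke(1 - k^2)$k
  EPS0 * eps * kkp / kk
}
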