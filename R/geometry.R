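#' Sensor geometry of the split-ring-resonator scanning device
#'
#' Collects the printed device dimensions: the split gap that performs the
#' 1-D scan, the coupling gap to the feed line, the metal layer, and the
#' microfluidic channel cross-section the GUVs flow through.
#'
#' @param slot_width Width \code{s} of the split gap in metres (default 500 nm).
#' @param slot_length Length of the split gap in metres (default 100 um).
#' @param metal_thickness Thickness \code{t} of the metal layer in metres.
#' @param coupling_gap Feed-line coupling gap \code{g} in metres (metadata for
#'   the circuit model; it does not enter the electrostatic solve).
#' @param channel_height Microfluidic channel height in metres (18.8 um).
#' @param channel_width Microfluidic channel width in metres (25 um).
#' @param substrate_thickness Glass substrate thickness in metres.
#' @param pdms_thickness PDMS lid thickness in metres.
#' @param substrate_permittivity Relative permittivity of the substrate
#'   (borosilicate glass, default 4.6).
#' @param pdms_permittivity Relative permittivity of PDMS (default 2.7).
#'
#' @return An object of class \code{sensor_geometry}.
#' @export
#' @examples
#' geom <- sensor_geometry()
#' geom$slot_width
sensor_geometry <- function(slot_width = 500e-9,
                            slot_length = 100e-6,
                            metal_thickness = 0.54e-6,
                            coupling_gap = 3.5e-6,
                            channel_height = 18.8e-6,
                            channel_width = 25e-6,
                            substrate_thickness = 1e-3,
                            pdms_thickness = 3e-3,
                            substrate_permittivity = 4.6,
                            pdms_permittivity = 2.7) {
  g <- list(slot_width = slot_width,
            slot_length = slot_length,
            metal_thickness = metal_thickness,
            coupling_gap = coupling_gap,
            channel_height = channel_height,
            channel_width = channel_width,
            substrate_thickness = substrate_thickness,
            pdms_thickness = pdms_thickness,
            substrate_permittivity = substrate_permittivity,
            pdms_permittivity = pdms_permittivity)
  lens <- c(slot_width, slot_length, coupling_gap, channel_height,
            channel_width, substrate_thickness, pdms_thickness)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometry lengths must be finite and strictly positive")
  if (metal_thickness < 0) stop("metal_thickness must be >= 0")
  if (slot_width >= channel_width)
    stop("slot_width must be smaller than channel_width")
  if (metal_thickness >= channel_height)
    stop("metal_thickness must be smaller than channel_height")
  structure(g, class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat("SRR sensor geometry\n")
  cat(sprintf("  split gap:  %.0f nm wide, %.0f um long, metal t = %.2f um\n",
              x$slot_width * 1e9, x$slot_length * 1e6,
              x$metal_thickness * 1e6))
  cat(sprintf("  channel:    %.1f um high x %.1f um wide\n",
              x$channel_height * 1e6, x$channel_width * 1e6))
  cat(sprintf("  substrate:  eps_r = %.2f, PDMS eps_r = %.2f\n",
              x$substrate_permittivity, x$pdms_permittivity))
  invisible(x)
}

#' Complex relative permittivity of water (single-Debye model)
#'
#' Single-Debye relaxation for water at 25 C with static permittivity 78.4,
#' high-frequency limit 5.2 and relaxation time 8.27 ps. The 0.1 M
#' glucose-water carrier medium is modelled as pure water: glucose is
#' non-ionic and the correction at 0.1 M is negligible at these frequencies.
#'
#' @param frequency Frequency in Hz (vectorised).
#' @param eps_static Static relative permittivity.
#' @param eps_inf High-frequency relative permittivity.
#' @param tau Relaxation time in seconds.
#' @return Complex permittivity \code{eps' - 1i*eps''} (negative imaginary
#'   part encodes loss).
#' @export
#' @examples
#' water_permittivity(2.7e9)
water_permittivity <- function(frequency, eps_static = 78.4, eps_inf = 5.2,
                               tau = 8.27e-12) {
  stopifnot(all(frequency > 0))
  eps_inf + (eps_static - eps_inf) / (1 + 1i * 2 * pi * frequency * tau)
}

#' Complex membrane permittivity with orientation tag
#'
#' The split-gap field is in-plane, so extracted values refer to the
#' parallel component \code{eps_par}; the convention is
#' \code{eps = eps' - 1i*eps''} with \code{eps'' >= 0}.
#'
#' @param real_part Real relative permittivity (>= 1 for physical media).
#' @param imag_part Loss component \code{eps''} (>= 0).
#' @param orientation One of \code{"parallel"}, \code{"perpendicular"},
#'   \code{"isotropic"}.
#' @return Object of class \code{complex_permittivity}; arithmetic use via
#'   \code{as.complex}.
#' @export
complex_permittivity <- function(real_part, imag_part,
                                 orientation = c("parallel", "perpendicular",
                                                 "isotropic")) {
  orientation <- match.arg(orientation)
  if (!is.finite(real_part) || !is.finite(imag_part))
    stop("permittivity components must be finite")
  if (real_part < 1) stop("real part must be >= 1 for a physical medium")
  if (imag_part < 0) stop("loss component eps'' must be >= 0")
  structure(list(real_part = real_part, imag_part = imag_part,
                 orientation = orientation),
            class = "complex_permittivity")
}

#' @export
as.complex.complex_permittivity <- function(x, ...) {
  complex(real = x$real_part, imaginary = -x$imag_part)
}

#' @export
print.complex_permittivity <- function(x, ...) {
  cat(sprintf("complex permittivity (%s): %.4g - j%.4g\n",
              x$orientation, x$real_part, x$imag_part))
  invisible(x)
}

#' Layered dielectric stack above the electrode plane
#'
#' Ordered layers bottom-to-top starting at the top metal surface (y = 0).
#' Exactly one layer is flagged as the analyte (the membrane slab); the top
#' layer is treated as semi-infinite bulk medium. An optional water film
#' below the analyte represents membrane elevation by hydration layers.
#'
#' @param layers List of layers, each a list with fields \code{name},
#'   \code{thickness} (metres; \code{Inf} allowed for the final bulk layer),
#'   \code{permittivity} (complex or \code{complex_permittivity}), and
#'   logical \code{analyte}.
#' @return Object of class \code{layer_stack}.
#' @seealso [membrane_stack()] for the standard membrane-on-electrode stack.
#' @export
layer_stack <- function(layers) {
  if (!length(layers)) stop("stack needs at least one layer")
  nm <- vapply(layers, function(l) l$name, character(1))
  th <- vapply(layers, function(l) l$thickness, numeric(1))
  an <- vapply(layers, function(l) isTRUE(l$analyte), logical(1))
  if (any(th[-length(th)] <= 0) || any(!is.finite(th[-length(th)])))
    stop("layer thicknesses must be positive and finite (except bulk top)")
  if (sum(an) != 1) stop("exactly one layer must be flagged analyte")
  eps <- lapply(layers, function(l) {
    p <- l$permittivity
    if (inherits(p, "complex_permittivity")) p <- as.complex(p)
    p <- as.complex(p)
    if (Re(p) <= 0 || Im(p) > 1e-12)
      stop("layer permittivity must have positive real part and ",
           "non-positive imaginary part (eps' - j eps'')")
    p
  })
  structure(list(name = nm, thickness = th,
                 permittivity = unlist(eps), analyte = an),
            class = "layer_stack")
}

#' Standard membrane-on-electrode layer stack
#'
#' Builds the stack used throughout the extraction pipeline: an optional
#' elevation water film on the electrode plane, the membrane slab (analyte),
#' and semi-infinite bulk water above. All aqueous layers use the Debye
#' water model at the working frequency.
#'
#' @param frequency Working frequency in Hz.
#' @param membrane_thickness Membrane slab thickness in metres
#'   (defaults: 5.0 nm for SM-like, 4.0 nm for POPC-like membranes).
#' @param membrane_permittivity Complex membrane permittivity; defaults to
#'   the bulk water value (i.e. no dielectric contrast).
#' @param elevation Thickness of the water film below the membrane (metres).
#' @return A \code{layer_stack}.
#' @export
#' @examples
#' membrane_stack(2.7e9, membrane_thickness = 5e-9, elevation = 100e-9)
membrane_stack <- function(frequency, membrane_thickness = 5e-9,
                           membrane_permittivity = NULL, elevation = 0) {
  stopifnot(membrane_thickness > 0, elevation >= 0)
  eps_w <- water_permittivity(frequency)
  if (is.null(membrane_permittivity)) membrane_permittivity <- eps_w
  if (inherits(membrane_permittivity, "complex_permittivity"))
    membrane_permittivity <- as.complex(membrane_permittivity)
  layers <- list()
  if (elevation > 0)
    layers <- c(layers, list(list(name = "elevation_film",
                                  thickness = elevation,
                                  permittivity = eps_w, analyte = FALSE)))
  layers <- c(layers,
              list(list(name = "membrane", thickness = membrane_thickness,
                        permittivity = membrane_permittivity, analyte = TRUE),
                   list(name = "bulk_water", thickness = Inf,
                        permittivity = eps_w, analyte = FALSE)))
  layer_stack(layers)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("layer stack (bottom to top, y = 0 at electrode plane)\n")
  for (i in seq_along(x$name)) {
    cat(sprintf("  %-15s %-10s eps = %.3g - j%.3g%s\n", x$name[i],
                if (is.finite(x$thickness[i]))
                  sprintf("%.3g nm", x$thickness[i] * 1e9) else "bulk",
                Re(x$permittivity[i]), -Im(x$permittivity[i]),
                if (x$analyte[i]) "  [analyte]" else ""))
  }
  invisible(x)
}
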