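## Synthetic scan-trace generator. Presets encode the published cohort
## statistics (per-lipid delta-|S21| means and spreads at the two working
## frequencies), the two-domain section amplitudes, the baseline phases,
## and the scan-duration range, so the whole analysis pipeline can be
## exercised and validated by parameter recovery without any external
## data.

#' Published reference values as a machine-readable bundle
#'
#' Versioned tables of the printed measurement values: per-lipid cohort
#' (mu, sigma) of delta-|S21| at 2.7 and 7.9 GHz, the two-domain section
#' amplitudes with their lipid labels, the extracted membrane
#' permittivities (contact and 100-nm-elevated), the baseline phases
#' theta0, and the experimental constants (scan duration range, flow rate,
#' IFBW, membrane thickness conventions).
#'
#' @param file Optional path to an alternative bundle (JSON).
#' @return List with elements \code{fig3e}, \code{two_domain},
#'   \code{permittivity}, \code{theta0}, \code{constants}, \code{version}.
#' @export
#' @examples
#' p <- presets()
#' subset(p$fig3e, lipid == "SM" & frequency == 2.7e9)
presets <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.guvscan_env$presets)) return(.guvscan_env$presets)
    file <- system.file("extdata", "printed_values.json",
                        package = "guvscan")
    if (file == "")
      file <- file.path("inst", "extdata", "printed_values.json")
  }
  p <- jsonlite::fromJSON(file)
  .guvscan_env$presets <- p
  p
}

#' Scan-trace generator preset
#'
#' @param name Preset name: one of \code{"SM_2.7GHz"}, \code{"SM_7.9GHz"},
#'   \code{"POPC_2.7GHz"}, \code{"POPC_7.9GHz"}, or \code{NULL} to build a
#'   custom preset from the remaining arguments.
#' @param frequency Measurement frequency, Hz.
#' @param plateau_amplitude_mean,plateau_amplitude_sd Mean and spread of
#'   the planted plateau amplitude (delta-|S21| units); per-GUV amplitudes
#'   are drawn Normal(mean, sd) truncated at zero.
#' @param plateau_duration_range Plateau duration bounds, seconds (the
#'   published scan durations: 0.6 to 0.9 s).
#' @param baseline_level Baseline |S21| level (dimensionless).
#' @param noise_sd Per-quadrature additive Gaussian noise standard
#'   deviation on S21.
#' @param theta0 Baseline phase, degrees.
#' @param sample_rate Samples per second (default 500; the 1 kHz IFBW
#'   bounds the attainable point rate).
#' @return Object of class \code{trace_preset}.
#' @export
#' @examples
#' trace_preset("SM_2.7GHz")
trace_preset <- function(name = NULL, frequency = 2.7e9,
                         plateau_amplitude_mean = 8.99e-4,
                         plateau_amplitude_sd = 1.56e-4,
                         plateau_duration_range = c(0.6, 0.9),
                         baseline_level = 0.5, noise_sd = 0.5e-4,
                         theta0 = NULL, sample_rate = 500) {
  if (!is.null(name)) {
    p <- presets()
    mm <- regmatches(name, regexec("^(SM|POPC)_(2\\.7|7\\.9)GHz$", name))[[1]]
    if (length(mm) != 3)
      stop("unknown preset name '", name,
           "'; use e.g. \"SM_2.7GHz\", \"POPC_7.9GHz\"")
    frequency <- as.numeric(mm[3]) * 1e9
    row <- p$fig3e[p$fig3e$lipid == mm[2] &
                     abs(p$fig3e$frequency - frequency) < 1e6, ]
    plateau_amplitude_mean <- row$mu
    plateau_amplitude_sd <- row$sigma
  } else name <- "custom"
  if (is.null(theta0)) {
    th <- presets()$theta0
    i <- which.min(abs(th$frequency - frequency))
    theta0 <- th$theta0_deg[i]
  }
  stopifnot(plateau_amplitude_mean > 0, plateau_amplitude_sd >= 0,
            all(plateau_duration_range > 0),
            diff(plateau_duration_range) >= 0,
            baseline_level > 0, noise_sd >= 0, sample_rate > 0)
  structure(list(name = name, frequency = frequency,
                 plateau_amplitude_mean = plateau_amplitude_mean,
                 plateau_amplitude_sd = plateau_amplitude_sd,
                 plateau_duration_range = plateau_duration_range,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 theta0 = theta0, sample_rate = sample_rate),
            class = "trace_preset")
}

#' @export
print.trace_preset <- function(x, ...) {
  cat(sprintf("trace preset '%s': f = %.2f GHz, amp = %.3g +- %.3g, noise %.2g\n",
              x$name, x$frequency / 1e9, x$plateau_amplitude_mean,
              x$plateau_amplitude_sd, x$noise_sd))
  invisible(x)
}

## run expr under a local RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

## deterministic per-index seed derivation below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647) * 48271 %% 2147483647 +
               9973 * index) %% 2147483647L
}

baseline_signal <- function(preset, n) {
  rep(preset$baseline_level *
        exp(1i * preset$theta0 * pi / 180), n)
}

add_noise <- function(s, noise_sd) {
  if (noise_sd == 0) return(s)
  s + complex(real = stats::rnorm(length(s), 0, noise_sd),
              imaginary = stats::rnorm(length(s), 0, noise_sd))
}

finish_trace <- function(preset, mag, meta) {
  n <- length(mag)
  phase <- exp(1i * preset$theta0 * pi / 180)
  s <- add_noise(mag * phase, preset$noise_sd)
  scan_trace(time = seq(0, by = 1 / preset$sample_rate, length.out = n),
             s21 = s, frequency = preset$frequency,
             sample_rate = preset$sample_rate, theta0 = preset$theta0,
             metadata = meta)
}

#' Generate a single-GUV scan trace
#'
#' Baseline plus one plateau: the plateau amplitude is drawn
#' Normal(mean, sd) truncated at zero, its duration Uniform over the preset
#' range, and i.i.d. complex Gaussian noise is added throughout. A passing
#' membrane lowers |S21| by the plateau amplitude (the stored sign is a
#' convention; the analysis only uses magnitudes of the change).
#' Deterministic given \code{(preset, seed)}.
#'
#' @param preset A [trace_preset()].
#' @param seed Integer seed.
#' @param duration Total trace duration, seconds.
#' @return A [scan_trace()]; planted parameters are in
#'   \code{$metadata$planted}.
#' @export
#' @examples
#' tr <- gen_trace(trace_preset("SM_2.7GHz"), seed = 1)
#' print(tr)
gen_trace <- function(preset, seed, duration = 4) {
  stopifnot(inherits(preset, "trace_preset"), duration > 0)
  if (duration <= max(preset$plateau_duration_range) + 1.2)
    stop("duration too short for a plateau plus baseline margins")
  with_seed(seed, {
    n <- round(duration * preset$sample_rate)
    amp <- -1
    while (amp < 0)
      amp <- stats::rnorm(1, preset$plateau_amplitude_mean,
                          preset$plateau_amplitude_sd)
    pd <- stats::runif(1, preset$plateau_duration_range[1],
                       preset$plateau_duration_range[2])
    t0 <- stats::runif(1, 0.6, duration - pd - 0.6)
    mag <- rep(preset$baseline_level, n)
    i0 <- round(t0 * preset$sample_rate) + 1
    i1 <- min(n, i0 + round(pd * preset$sample_rate) - 1)
    mag[i0:i1] <- preset$baseline_level - amp
    finish_trace(preset, mag,
                 list(generator = "gen_trace", preset = preset$name,
                      seed = seed,
                      planted = list(amplitude = amp, duration = pd,
                                     start = t0)))
  })
}

#' Generate a two-domain GUV scan trace
#'
#' Two consecutive plateaus: Section I (the SM-rich, raft-like domain,
#' which rides at the GUV front in the channel flow) strictly first, then
#' Section II. Section durations are drawn so that each section exceeds
#' the default plateau minimum while the full scan stays within the
#' published single-GUV scan time.
#'
#' @param preset_I Preset for the leading (SM-rich) section.
#' @param preset_II Preset for the trailing (POPC-rich) section; must have
#'   the same frequency.
#' @param seed Integer seed.
#' @param duration Total trace duration, seconds.
#' @return A [scan_trace()] with planted parameters in metadata.
#' @export
gen_two_domain <- function(preset_I, preset_II, seed, duration = 4) {
  stopifnot(inherits(preset_I, "trace_preset"),
            inherits(preset_II, "trace_preset"))
  if (abs(preset_I$frequency - preset_II$frequency) >
      1e-6 * preset_I$frequency)
    stop("the two presets must share the same frequency")
  with_seed(seed, {
    n <- round(duration * preset_I$sample_rate)
    draw_amp <- function(p) {
      amp <- -1
      while (amp < 0)
        amp <- stats::rnorm(1, p$plateau_amplitude_mean,
                            p$plateau_amplitude_sd)
      amp
    }
    a1 <- draw_amp(preset_I); a2 <- draw_amp(preset_II)
    d1 <- stats::runif(1, 0.3, 0.45); d2 <- stats::runif(1, 0.3, 0.45)
    t0 <- stats::runif(1, 0.6, duration - d1 - d2 - 0.6)
    sr <- preset_I$sample_rate
    mag <- rep(preset_I$baseline_level, n)
    i0 <- round(t0 * sr) + 1
    i1 <- i0 + round(d1 * sr) - 1
    i2 <- min(n, i1 + round(d2 * sr))
    mag[i0:i1] <- preset_I$baseline_level - a1
    mag[(i1 + 1):i2] <- preset_I$baseline_level - a2
    finish_trace(preset_I, mag,
                 list(generator = "gen_two_domain",
                      preset = c(preset_I$name, preset_II$name), seed = seed,
                      planted = list(amplitude_I = a1, amplitude_II = a2,
                                     duration_I = d1, duration_II = d2,
                                     start = t0)))
  })
}

#' Generate a cohort of independent single-GUV traces
#'
#' Per-trace seeds are derived deterministically from the master seed by a
#' fixed affine congruential map, so cohorts are reproducible and
#' individual traces can be regenerated in isolation.
#'
#' @param preset A [trace_preset()].
#' @param n Number of GUVs (the published cohorts use n = 10).
#' @param seed Master seed.
#' @param duration Per-trace duration, seconds.
#' @return List of [scan_trace()] objects.
#' @export
gen_cohort <- function(preset, n, seed, duration = 4) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i)
    gen_trace(preset, derive_seed(seed, i), duration = duration))
}

#' Generate an anomalous scan trace
#'
#' \code{"small_spherical"}: a sub-channel spherical GUV gives a short
#' (< 0.3 s) transient of variable amplitude - its vertical position is
#' uncontrolled, so the signal is unstable. \code{"folded"}: a large GUV
#' folded over itself passes stacked membrane sections over the gap,
#' producing a nested multi-level excursion (single layer, double layer,
#' single layer).
#'
#' @param kind \code{"small_spherical"} or \code{"folded"}.
#' @param seed Integer seed.
#' @param preset Base preset (frequency, baseline, noise); default SM at
#'   2.7 GHz.
#' @param duration Total trace duration, seconds.
#' @return A [scan_trace()] with planted parameters in metadata.
#' @export
gen_anomaly <- function(kind = c("small_spherical", "folded"), seed,
                        preset = trace_preset("SM_2.7GHz"), duration = 4) {
  kind <- match.arg(kind)
  with_seed(seed, {
    sr <- preset$sample_rate
    n <- round(duration * sr)
    mag <- rep(preset$baseline_level, n)
    if (kind == "small_spherical") {
      pd <- stats::runif(1, 0.05, 0.2)
      amp <- preset$plateau_amplitude_mean * stats::runif(1, 0.3, 1.5)
      t0 <- stats::runif(1, 0.6, duration - pd - 0.6)
      i0 <- round(t0 * sr) + 1; i1 <- min(n, i0 + round(pd * sr) - 1)
      ## unstable vertical position: slow sub-threshold amplitude wobble
      w <- 1 + 0.02 * sin(seq(0, 2 * pi, length.out = i1 - i0 + 1))
      mag[i0:i1] <- preset$baseline_level - amp * w
      planted <- list(kind = kind, amplitude = amp, duration = pd,
                      start = t0)
    } else {
      a <- preset$plateau_amplitude_mean
      d <- c(stats::runif(1, 0.35, 0.45), stats::runif(1, 0.3, 0.4),
             stats::runif(1, 0.35, 0.45))
      t0 <- stats::runif(1, 0.6, duration - sum(d) - 0.6)
      lev <- preset$baseline_level - c(a, 1.8 * a, a)
      i <- round(t0 * sr) + 1
      for (k in 1:3) {
        j <- min(n, i + round(d[k] * sr) - 1)
        mag[i:j] <- lev[k]
        i <- j + 1
      }
      planted <- list(kind = kind, amplitude = a, durations = d,
                      start = t0)
    }
    finish_trace(preset, mag,
                 list(generator = "gen_anomaly", preset = preset$name,
                      seed = seed, planted = planted))
  })
}

#' Size regime of a GUV relative to the scanning channel
#'
#' GUVs below the channel width pass as spheres with uncontrolled vertical
#' position (unstable signal); GUVs slightly larger are flattened against
#' the gap surface and scan cleanly; still larger GUVs tend to fold or
#' break entering the channel.
#'
#' @param diameter GUV diameter, metres.
#' @param geometry A [sensor_geometry()].
#' @param upper_factor Upper bound of the scannable window as a multiple of
#'   the channel width (default 1.2).
#' @return One of \code{"sub_channel_spherical"},
#'   \code{"scannable_flattened"}, \code{"folding_or_breaking"}.
#' @export
#' @examples
#' size_regime(17.4e-6, sensor_geometry())
#' size_regime(26e-6, sensor_geometry())
#' size_regime(31e-6, sensor_geometry())
size_regime <- function(diameter, geometry = sensor_geometry(),
                        upper_factor = 1.2) {
  stopifnot(diameter > 0)
  w <- geometry$channel_width
  if (diameter < w) "sub_channel_spherical"
  else if (diameter <= upper_factor * w) "scannable_flattened"
  else "folding_or_breaking"
}

truncated_sphere_volume <- function(R, h) {
  ## sphere radius R truncated by planes at +-h/2 (caps removed)
  if (R <= h / 2) return(4 / 3 * pi * R^3)
  cap <- pi / 3 * (R - h / 2)^2 * (2 * R + h / 2)
  4 / 3 * pi * R^3 - 2 * cap
}

#' Flattened contact-patch estimate for a channel-confined GUV
#'
#' Constant-volume truncated-sphere model: a GUV of the given diameter is
#' squeezed between the channel floor and ceiling (separation = channel
#' height); the deformed shape is taken as a sphere of radius R truncated
#' by both planes, with R chosen to conserve the original volume. The
#' contact patch is the truncation disc, reported for both the flow-wise
#' length L and the transverse width (the model is isotropic in the plane;
#' see the vignette for why the in-plane anisotropy of a real confined GUV
#' is not captured).
#'
#' @param diameter GUV diameter, metres (> channel height for contact).
#' @param geometry A [sensor_geometry()].
#' @return Object of class \code{flatten_estimate}: \code{contact_length},
#'   \code{contact_width} (metres), \code{radius}, \code{model},
#'   \code{volume_residual}.
#' @export
#' @examples
#' flatten_estimate(25e-6, sensor_geometry())
flatten_estimate <- function(diameter, geometry = sensor_geometry()) {
  stopifnot(diameter > 0)
  h <- geometry$channel_height
  if (diameter <= h) {
    return(structure(list(contact_length = 0, contact_width = 0,
                          radius = diameter / 2,
                          model = "constant_volume_truncated_sphere",
                          volume_residual = 0),
                     class = "flatten_estimate"))
  }
  v0 <- pi / 6 * diameter^3
  f <- function(R) truncated_sphere_volume(R, h) - v0
  sol <- stats::uniroot(f, lower = h / 2 * (1 + 1e-12), upper = 10 * diameter,
                        tol = 1e-15 * diameter)
  R <- sol$root
  a <- sqrt(R^2 - (h / 2)^2)
  structure(list(contact_length = 2 * a, contact_width = 2 * a, radius = R,
                 model = "constant_volume_truncated_sphere",
                 volume_residual = abs(f(R)) / v0),
            class = "flatten_estimate")
}

#' @export
print.flatten_estimate <- function(x, ...) {
  cat(sprintf("flattened contact patch: L = %.3g um (flow), width = %.3g um (model: %s)\n",
              x$contact_length * 1e6, x$contact_width * 1e6, x$model))
  invisible(x)
}
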