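## Scan-trace analysis: a time series of complex S21 at fixed frequency is
## segmented into baseline / plateau / transient / folded sections by
## binary change-point segmentation on |S21|; each non-baseline section
## yields a delta-|S21| against the baseline mean, which is classified
## against the published lipid reference values and aggregated into cohort
## statistics.

#' Scan trace of complex S21 at fixed frequency
#'
#' @param time Sample times, seconds, uniformly spaced.
#' @param s21 Complex S21 per sample.
#' @param frequency Measurement frequency, Hz.
#' @param sample_rate Samples per second; inferred from \code{time} when
#'   omitted.
#' @param theta0 Display reference phase, degrees (see [detrend_phase()]).
#' @param metadata List of free-form metadata (flow rate, IFBW, generator
#'   provenance).
#' @return Object of class \code{scan_trace}.
#' @export
scan_trace <- function(time, s21, frequency, sample_rate = NULL,
                       theta0 = NULL, metadata = list()) {
  if (length(time) != length(s21)) stop("time and s21 lengths differ")
  if (length(time) < 2) stop("trace needs at least two samples")
  if (any(!is.finite(Re(s21))) || any(!is.finite(Im(s21))) ||
      any(!is.finite(time)))
    stop("trace values must be finite")
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt)))
    stop("trace must be uniformly sampled (relative tolerance 1e-9)")
  if (is.null(sample_rate)) sample_rate <- 1 / mean(dt)
  structure(list(time = as.numeric(time), s21 = as.complex(s21),
                 frequency = frequency, sample_rate = sample_rate,
                 theta0 = theta0, metadata = metadata),
            class = "scan_trace")
}

#' @export
print.scan_trace <- function(x, ...) {
  cat(sprintf("scan trace: %d samples at %.4g Hz, %.3g s, f = %.3g GHz\n",
              length(x$time), x$sample_rate,
              diff(range(x$time)), x$frequency / 1e9))
  cat(sprintf("  |s21|: mean %.6f, range [%.6f, %.6f]\n",
              mean(Mod(x$s21)), min(Mod(x$s21)), max(Mod(x$s21))))
  invisible(x)
}

#' @export
plot.scan_trace <- function(x, theta0 = x$theta0, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, Mod(x$s21), type = "l", xlab = "time (s)",
                 ylab = "|S21|", ...)
  ph <- detrend_phase(x, theta0 = if (is.null(theta0)) 0 else theta0)
  graphics::plot(x$time, ph, type = "l", xlab = "time (s)",
                 ylab = expression(phi ~ (deg)))
  invisible(x)
}

unwrap_deg <- function(ph) {
  d <- diff(ph)
  corr <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  ph + c(0, corr)
}

#' Detrended display phase of a scan trace
#'
#' \code{phi_i = unwrap(angle(s21_i)) - theta0} in degrees: subtracting the
#' baseline phase theta0 of the working mode centres the displayed phase
#' near zero.
#'
#' @param trace A [scan_trace()].
#' @param theta0 Reference phase in degrees (the calibrated baseline phase
#'   of the mode; defaults to the trace's own \code{theta0}, else 0).
#' @return Numeric vector of phases, degrees.
#' @export
detrend_phase <- function(trace, theta0 = NULL) {
  stopifnot(inherits(trace, "scan_trace"))
  if (is.null(theta0)) theta0 <- if (is.null(trace$theta0)) 0 else trace$theta0
  unwrap_deg(Arg(trace$s21) * 180 / pi) - theta0
}

## max-CUSUM split of y[lo:hi], leaving at least 2 samples on each side;
## returns k (last index of left part) and the bridge statistic
best_split <- function(y, lo, hi) {
  nn <- hi - lo + 1
  yy <- y[lo:hi]
  S <- cumsum(yy); tot <- S[nn]
  k <- 2:(nn - 2)
  mL <- S[k] / k; mR <- (tot - S[k]) / (nn - k)
  T <- sqrt(k * (nn - k) / nn) * abs(mL - mR)
  i <- which.max(T)
  list(k = lo + k[i] - 1, stat = T[i])
}

#' Segment a scan trace into baseline, plateau, transient and folded parts
#'
#' Recursive binary segmentation on |S21| (max-CUSUM mean-shift statistic
#' against a threshold of \code{sigma * (sqrt(2 log n) + 0.5)} scaled by
#' \code{sensitivity/4}, with sigma a robust noise estimate), followed by a
#' merge pass that removes level differences below \code{sensitivity}
#' standard errors of the difference of the adjacent segment means - so
#' detection sensitivity grows with plateau length rather than being a
#' fixed amplitude floor, and weak but long plateaus are kept. Levels are
#' then labelled: segments within \code{sensitivity} standard errors of
#' the dominant (longest) level are baseline; other levels are plateaus
#' when they last at least \code{min_plateau} seconds and transients
#' otherwise; runs of three or more stacked non-baseline levels are folded
#' (a membrane folded over itself passes multiple membrane layers over the
#' gap, nesting levels inside the excursion, while a two-domain scan steps
#' through exactly two levels).
#'
#' @param trace A [scan_trace()].
#' @param min_plateau Minimum plateau duration, seconds. Default 0.3 s:
#'   half the shortest published single-GUV scan duration, separating
#'   genuine membrane plateaus from sub-channel transients.
#' @param sensitivity Statistical sensitivity in standard-error units
#'   (default 4); larger values demand stronger evidence for a level
#'   change.
#' @return Object of class \code{segmentation}: a data frame of segments
#'   (\code{start}, \code{end}, \code{kind}, \code{mean_mag},
#'   \code{mean_s21}, \code{delta_magnitude}) plus baseline statistics.
#' @export
segment_trace <- function(trace, min_plateau = 0.3, sensitivity = 4) {
  stopifnot(inherits(trace, "scan_trace"))
  if (diff(range(trace$time)) <= 3 * min_plateau)
    stop("trace must be longer than 3 * min_plateau")
  a <- Mod(trace$s21)
  n <- length(a)
  sigma <- stats::mad(diff(a)) / sqrt(2)
  thr <- (sensitivity / 4) * sigma * (sqrt(2 * log(n)) + 0.5)
  floor_abs <- 1e-12 * max(abs(a), 1)   # exact-level tolerance, noiseless

  ## recursive binary segmentation -> change-point indices
  cps <- integer(0)
  recurse <- function(lo, hi) {
    if (hi - lo + 1 < 5) return()
    sp <- best_split(a, lo, hi)
    if (sp$stat <= thr || sp$stat == 0) return()
    cps <<- c(cps, sp$k)
    recurse(lo, sp$k)
    recurse(sp$k + 1, hi)
  }
  recurse(1, n)
  bounds <- sort(unique(c(0, cps, n)))

  ## merge adjacent segments whose level difference is below `sensitivity`
  ## standard errors of that difference
  repeat {
    if (length(bounds) <= 2) break
    m <- diff(bounds)
    lev <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(a[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    se <- sigma * sqrt(1 / m[-length(m)] + 1 / m[-1])
    d <- abs(diff(lev)) - pmax(sensitivity * se, floor_abs)
    if (!length(d) || min(d) >= 0) break
    i <- which.min(d)
    bounds <- bounds[-(i + 1)]
  }

  nseg <- length(bounds) - 1
  idx <- lapply(seq_len(nseg), function(i) (bounds[i] + 1):bounds[i + 1])
  lev <- vapply(idx, function(ii) mean(a[ii]), numeric(1))
  dur <- vapply(idx, function(ii) length(ii) / trace$sample_rate, numeric(1))

  ## baseline: the level of the longest segment, plus every segment whose
  ## level is statistically indistinguishable from it
  ib <- which.max(dur)
  base_lev <- lev[ib]
  se_b <- sigma * sqrt(1 / lengths(idx) + 1 / length(idx[[ib]]))
  is_base <- abs(lev - base_lev) < pmax(sensitivity * se_b, floor_abs)
  base_idx <- unlist(idx[is_base])
  base_mean <- mean(a[base_idx]); base_sd <- stats::sd(a[base_idx])

  kind <- ifelse(is_base, "baseline",
                 ifelse(dur >= min_plateau, "plateau", "transient"))
  ## folded: a run of >= 3 stacked non-baseline levels with genuinely
  ## nested depths (an inner level well beyond the outer ones), as when a
  ## folded membrane passes a double layer over the gap between single
  ## layers; a run of similar levels is just a split excursion and keeps
  ## its duration-based labels
  r <- rle(!is_base)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(r$values & r$lengths >= 3)) {
    dd <- abs(lev[starts[j]:ends[j]] - base_mean)
    if (max(dd) >= 1.3 * min(dd))
      kind[starts[j]:ends[j]] <- "folded"
  }

  segs <- data.frame(
    start = trace$time[bounds[-length(bounds)] + 1],
    end = trace$time[bounds[-1]],
    kind = kind,
    mean_mag = lev,
    delta_magnitude = abs(base_mean - lev),
    duration = dur)
  segs$mean_s21 <- vapply(idx, function(ii) mean(trace$s21[ii]), complex(1))
  structure(list(segments = segs,
                 baseline = list(mean = base_mean, sd = base_sd),
                 noise_sd = sigma, threshold = thr,
                 change_points = bounds[-c(1, length(bounds))],
                 min_plateau = min_plateau, sensitivity = sensitivity,
                 trace_n = n, sample_rate = trace$sample_rate),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  s <- x$segments
  cat(sprintf("segmentation: %d segments (noise sd %.3g)\n", nrow(s),
              x$noise_sd))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  [%6.3f, %6.3f] s  %-9s |s21| = %.6f  d|S21| = %.3g\n",
                s$start[i], s$end[i], s$kind[i], s$mean_mag[i],
                s$delta_magnitude[i]))
  invisible(x)
}

#' Per-section delta-|S21| of a segmented trace
#'
#' For each non-baseline section, in time order:
#' \code{|mean(|s21|, baseline) - mean(|s21|, section)|}. The first section
#' of a two-domain GUV scan is Section I (the raft-like, SM-rich domain
#' rides at the GUV front), the second Section II.
#'
#' @param trace A [scan_trace()].
#' @param segmentation Result of [segment_trace()].
#' @return Data frame with \code{section} (I, II, ...), \code{kind} and
#'   \code{delta} columns.
#' @export
section_deltas <- function(trace, segmentation) {
  stopifnot(inherits(segmentation, "segmentation"))
  s <- segmentation$segments
  if (!any(s$kind == "baseline"))
    stop("segmentation contains no baseline section")
  sel <- s$kind != "baseline"
  out <- s[sel, c("kind", "delta_magnitude")]
  names(out)[2] <- "delta"
  out$section <- as.character(utils::as.roman(seq_len(nrow(out))))
  rownames(out) <- NULL
  out[, c("section", "kind", "delta")]
}

#' Classify a delta-|S21| value against the lipid reference presets
#'
#' Nearest reference mean in z-score units among the published per-lipid
#' (mu, sigma) presets at the measurement frequency; when the two z-scores
#' differ by less than 0.5 the call is ambiguous.
#'
#' @param delta Observed delta-|S21| (dimensionless, e.g. 10.64e-4).
#' @param frequency Measurement frequency, Hz (2.7e9 or 7.9e9).
#' @param reference Reference table as returned in
#'   \code{presets()$fig3e}; rows \code{lipid}, \code{frequency},
#'   \code{mu}, \code{sigma}.
#' @return One of \code{"SM-rich"}, \code{"POPC-rich"}, \code{"ambiguous"}.
#' @export
#' @examples
#' classify_delta(10.64e-4, 2.7e9)  # SM-rich
#' classify_delta(4.55e-4, 2.7e9)   # POPC-rich
classify_delta <- function(delta, frequency, reference = NULL) {
  if (is.null(reference)) reference <- presets()$fig3e
  ref <- reference[abs(reference$frequency - frequency) <
                     1e-3 * frequency, ]
  if (nrow(ref) < 2)
    stop("no reference entries for frequency ", frequency, " Hz")
  z <- abs(delta - ref$mu) / ref$sigma
  zs <- z[ref$lipid == "SM"]; zp <- z[ref$lipid == "POPC"]
  if (abs(zs - zp) < 0.5) return("ambiguous")
  if (zs < zp) "SM-rich" else "POPC-rich"
}

#' Cohort statistics of delta-|S21| values
#'
#' Mean, standard deviation and the asymmetric error bars used for cohort
#' plots: \code{err_plus = max - mu} and \code{err_minus = mu - min}. The
#' default standard deviation is the population form (divide by n); the
#' sample form is also reported.
#'
#' @param deltas Numeric vector of delta-|S21| values (n >= 1).
#' @return Object of class \code{cohort_stats} with fields \code{n},
#'   \code{mean}, \code{sd} (population), \code{sd_sample},
#'   \code{err_plus}, \code{err_minus}.
#' @export
#' @examples
#' cohort_stats(c(1, 2, 3))
cohort_stats <- function(deltas) {
  if (!length(deltas)) stop("empty cohort")
  if (any(!is.finite(deltas))) stop("cohort values must be finite")
  n <- length(deltas)
  mu <- mean(deltas)
  structure(list(n = n, mean = mu,
                 sd = sqrt(mean((deltas - mu)^2)),
                 sd_sample = if (n > 1) stats::sd(deltas) else 0,
                 err_plus = max(deltas) - mu,
                 err_minus = mu - min(deltas)),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("cohort (n = %d): mu = %.4g, sigma = %.4g (+%.3g / -%.3g)\n",
              x$n, x$mean, x$sd, x$err_plus, x$err_minus))
  invisible(x)
}
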