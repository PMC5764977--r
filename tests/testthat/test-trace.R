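noiseless_preset <- function(mean, frequency = 2.7e9)
  trace_preset(NULL, frequency = frequency, plateau_amplitude_mean = mean,
               plateau_amplitude_sd = 0, noise_sd = 0)

test_that("phase detrending: identity at theta0 = 0 and exact cancellation", {
  tr <- scan_trace(seq(0, 1, by = 0.01),
                   rep(0.5 * exp(1i * 103.9 * pi / 180), 101),
                   frequency = 2.7e9)
  expect_equal(detrend_phase(tr, theta0 = 0),
               rep(103.9, 101), tolerance = 1e-10)
  expect_equal(detrend_phase(tr, theta0 = 103.9), rep(0, 101),
               tolerance = 1e-10)
})

test_that("the 7.9 GHz preset baseline phase is centred by its theta0", {
  tr <- gen_trace(trace_preset("SM_7.9GHz"), seed = 3)
  ph <- detrend_phase(tr, theta0 = 339.88)
  expect_lt(abs(guvscan:::wrap_deg(stats::median(ph))), 0.5)
})

test_that("noiseless planted steps are recovered with exact edges", {
  tr <- gen_trace(noiseless_preset(9e-4), seed = 11)
  seg <- segment_trace(tr)
  expect_identical(seg$segments$kind, c("baseline", "plateau", "baseline"))
  planted <- tr$metadata$planted
  sr <- tr$sample_rate
  i0 <- round(planted$start * sr) + 1
  i1 <- i0 + round(planted$duration * sr) - 1
  expect_true(all(abs(seg$change_points - c(i0 - 1, i1)) <= 1))
  expect_equal(seg$segments$delta_magnitude[2], planted$amplitude,
               tolerance = 1e-12)
})

test_that("pure-noise traces yield no plateau segments", {
  for (seed in 1:10) {
    p <- trace_preset("SM_2.7GHz")
    tr <- with(list(), {
      set.seed(seed + 500)
      n <- 2000
      scan_trace(seq(0, by = 1 / 500, length.out = n),
                 0.5 * exp(1i * 103.9 * pi / 180) +
                   complex(real = rnorm(n, 0, 0.5e-4),
                           imaginary = rnorm(n, 0, 0.5e-4)),
                 frequency = 2.7e9)
    })
    seg <- segment_trace(tr)
    expect_true(all(seg$segments$kind == "baseline"))
  }
})

test_that("degenerate constant trace gives a single baseline segment", {
  tr <- scan_trace(seq(0, 2, by = 0.002), rep(0.5 + 0i, 1001),
                   frequency = 2.7e9)
  seg <- segment_trace(tr)
  expect_identical(nrow(seg$segments), 1L)
  expect_identical(seg$segments$kind, "baseline")
})

test_that("two-domain traces give two plateaus in generated order", {
  pI <- noiseless_preset(10.64e-4); pII <- noiseless_preset(4.55e-4)
  for (seed in 1:25) {
    tr <- gen_two_domain(trace_preset(NULL, 2.7e9, 10.64e-4, 0,
                                      noise_sd = 0.5e-4),
                         trace_preset(NULL, 2.7e9, 4.55e-4, 0,
                                      noise_sd = 0.5e-4), seed = seed)
    seg <- segment_trace(tr)
    ds <- section_deltas(tr, seg)
    expect_identical(ds$kind, c("plateau", "plateau"))
    expect_gt(ds$delta[1], ds$delta[2])
  }
  expect_error(gen_two_domain(pI, noiseless_preset(4e-4, 7.9e9), 1),
               "same frequency")
})

test_that("section deltas are unbiased within the CLT bound", {
  amp <- 8.99e-4; noise <- 0.5e-4
  fails <- 0
  for (seed in 1:50) {
    p <- trace_preset(NULL, 2.7e9, amp, 0, noise_sd = noise)
    tr <- gen_trace(p, seed = seed)
    seg <- segment_trace(tr)
    ds <- section_deltas(tr, seg)
    m <- round(tr$metadata$planted$duration * tr$sample_rate)
    tol <- 4 * noise / sqrt(m)
    if (abs(ds$delta[1] - tr$metadata$planted$amplitude) > tol)
      fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("section delta is invariant to a global complex phase", {
  p <- trace_preset("SM_2.7GHz")
  tr <- gen_trace(p, seed = 5)
  tr2 <- scan_trace(tr$time, tr$s21 * exp(1i * 1.234),
                    frequency = tr$frequency)
  d1 <- section_deltas(tr, segment_trace(tr))$delta
  d2 <- section_deltas(tr2, segment_trace(tr2))$delta
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("section identical to baseline has zero delta", {
  tr <- gen_trace(noiseless_preset(9e-4), seed = 2)
  seg <- segment_trace(tr)
  base_rows <- seg$segments$kind == "baseline"
  expect_true(all(seg$segments$delta_magnitude[base_rows] < 1e-15))
})

test_that("published two-domain deltas classify to their lipid labels", {
  td <- presets()$two_domain
  for (i in seq_len(nrow(td))) {
    expect_identical(classify_delta(td$section_I[i], td$frequency[i]),
                     "SM-rich")
    expect_identical(classify_delta(td$section_II[i], td$frequency[i]),
                     "POPC-rich")
  }
  ## the reference means classify as themselves
  f3 <- presets()$fig3e
  for (i in seq_len(nrow(f3)))
    expect_identical(classify_delta(f3$mu[i], f3$frequency[i]),
                     paste0(f3$lipid[i], "-rich"))
})

test_that("a delta equidistant in z-score is ambiguous", {
  f3 <- presets()$fig3e
  sm <- f3[f3$lipid == "SM" & f3$frequency == 2.7e9, ]
  po <- f3[f3$lipid == "POPC" & f3$frequency == 2.7e9, ]
  ## solve |d - mu_sm|/sig_sm = |d - mu_po|/sig_po for d between the means
  d <- (sm$mu * po$sigma + po$mu * sm$sigma) / (sm$sigma + po$sigma)
  expect_identical(classify_delta(d, 2.7e9), "ambiguous")
  expect_error(classify_delta(5e-4, 1e9), "no reference entries")
})

test_that("cohort statistics: hand-computable cases and range identity", {
  cs <- cohort_stats(c(1, 2, 3))
  expect_identical(cs$mean, 2)
  expect_identical(cs$err_plus, 1)
  expect_identical(cs$err_minus, 1)
  expect_equal(cs$sd, sqrt(2 / 3))
  deg <- cohort_stats(rep(5, 4))
  expect_identical(deg$sd, 0)
  expect_identical(deg$err_plus, 0)
  expect_identical(deg$err_minus, 0)
  x <- rnorm(17)
  cx <- cohort_stats(x)
  expect_equal(max(x) - min(x), cx$err_plus + cx$err_minus)
  expect_error(cohort_stats(numeric(0)), "empty cohort")
})

test_that("trace validation enforces uniform sampling and finiteness", {
  expect_error(scan_trace(c(0, 1, 3), rep(0.5 + 0i, 3), 2.7e9),
               "uniformly sampled")
  expect_error(scan_trace(c(0, 1), c(NaN + 0i, 1i), 2.7e9), "finite")
  tr <- scan_trace(seq(0, 0.5, by = 0.002), rep(0.5 + 0i, 251), 2.7e9)
  expect_error(segment_trace(tr), "longer than")
})
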