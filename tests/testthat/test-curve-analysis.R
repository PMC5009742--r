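test_that("POI extraction recovers the true inflection of noiseless curves", {
  cv <- generate_curve(curve_model(poi_true = 7.19, noise_sd = 0),
                       seq(0, 30, 0.1))
  r <- extract_poi(cv)
  expect_true(r$amplified)
  expect_equal(r$poi, 7.19, tolerance = 0.1)
  # maximal slope of a logistic is amplitude * k / 4 (smoothing shrinks it
  # slightly but it must stay in that vicinity)
  expect_equal(r$max_slope, 100 * 1.2 / 4, tolerance = 0.2 * 30)

  # one-minute reads: recovery within one read interval
  cv1 <- generate_curve(curve_model(poi_true = 15.5, noise_sd = 0),
                        seq(0, 40, 1))
  expect_equal(extract_poi(cv1)$poi, 15.5, tolerance = 1)
})

test_that("flat and non-amplifying curves are flagged, not assigned a POI", {
  flat <- fluorescence_curve("F", 0:40, rep(100, 41))
  r <- extract_poi(flat)
  expect_false(r$amplified)
  expect_true(is.na(r$poi))
  expect_match(paste(r$qc_notes, collapse = " "), "no amplification")

  noisy_flat <- generate_curve(curve_model(amplitude = 1e-12, noise_sd = 2,
                                           poi_true = 90),
                               seq(0, 40, 0.5), seed = 5)
  expect_false(extract_poi(noisy_flat)$amplified)
})

test_that("POI is accurate under noise", {
  errs <- vapply(1:30, function(s) {
    cv <- generate_curve(curve_model(amplitude = 100, noise_sd = 2,
                                     poi_true = 12), seq(0, 30, 0.25),
                         seed = s)
    extract_poi(cv)$poi - 12
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.5)
})

test_that("POI extraction is shift-equivariant and affine-invariant", {
  t <- seq(0, 30, 0.25)
  cv <- generate_curve(curve_model(poi_true = 11, noise_sd = 1.5), t,
                       seed = 8)
  base <- extract_poi(cv)
  shifted <- fluorescence_curve(cv$well, cv$times + 4.5, cv$rfu)
  expect_equal(extract_poi(shifted)$poi, base$poi + 4.5, tolerance = 1e-9)

  scaled <- fluorescence_curve(cv$well, cv$times, 3.7 * cv$rfu + 250)
  rs <- extract_poi(scaled)
  expect_equal(rs$poi, base$poi, tolerance = 1e-9)
  expect_identical(rs$amplified, base$amplified)
  expect_equal(rs$max_slope, 3.7 * base$max_slope, tolerance = 1e-9)
})

test_that("tied maximal slopes resolve to the earliest time", {
  # two separated identical pulses: every derivative window around the
  # second rise sees bitwise the same values as around the first, so the
  # maximal slopes tie exactly
  t <- 0:40
  ramp <- function(t, from) pmin(pmax(t - from, 0), 5)
  pulse <- function(t, from) 10 * ramp(t, from) - 10 * ramp(t, from + 7)
  rfu <- pulse(t, 5) + pulse(t, 25)
  cv <- fluorescence_curve("T", t, rfu)
  r <- extract_poi(cv, min_slope = 1)
  expect_lt(r$poi, 15)
})

test_that("Tm calling resolves one and two transitions", {
  hairpin <- generate_melt_curve(66.61, widths = 1.2)
  expect_equal(as.numeric(call_tm(hairpin)), 66.61, tolerance = 0.3)

  two <- generate_melt_curve(c(59.9, 51.5), widths = 1.5)
  tms <- sort(as.numeric(call_tm(two)))
  expect_equal(tms, c(51.5, 59.9), tolerance = 0.5)

  flat <- fluorescence_curve("M", seq(45, 95, 0.5),
                             rep(500, 101), kind = "melt")
  expect_length(call_tm(flat), 0)
})

test_that("Tm recovery holds across widths and noise at SNR >= 20", {
  # every generated transition must be recovered within 0.5 degrees C, and
  # the two true peaks must outrank any residual noise peak in prominence;
  # the derivative filter support is matched to the transition width
  cases <- expand.grid(width = c(1, 1.5, 2), seed = 1:5)
  for (i in seq_len(nrow(cases))) {
    m <- generate_melt_curve(c(50.5, 64), widths = cases$width[i],
                             amplitudes = 100, noise_sd = 1,
                             seed = cases$seed[i])
    win <- if (cases$width[i] > 1.5) 21L else 11L
    tms <- call_tm(m, smooth_window = win)
    expect_gte(length(tms), 2)
    top2 <- sort(as.numeric(tms[1:2]))
    expect_lt(abs(top2[1] - 50.5), 0.5)
    expect_lt(abs(top2[2] - 64), 0.5)
  }
})

test_that("baseline correction removes background and drift", {
  t <- seq(0, 30, 0.25)
  plain <- generate_curve(curve_model(baseline = 100, drift = 0,
                                      poi_true = 15, noise_sd = 0), t)
  corr <- baseline_correct(plain)
  # residual leakage of the sigmoid tail into the baseline fit stays below
  # 1% of the amplitude
  expect_lt(max(abs(corr$rfu[t < 5])), 1)

  drifty <- fluorescence_curve("D", t, 50 + 0.8 * t)
  corr_d <- baseline_correct(drifty)
  expect_lt(max(abs(corr_d$rfu)), 1e-9)

  # POI is stable under correction of a drifting sigmoid
  sig <- generate_curve(curve_model(baseline = 100, drift = 0.5,
                                    poi_true = 14, noise_sd = 0), t)
  before <- extract_poi(sig)$poi
  after <- extract_poi(baseline_correct(sig))$poi
  expect_lt(abs(before - after), 0.2)

  # idempotent on already-corrected curves
  twice <- baseline_correct(corr)
  expect_equal(twice$rfu, corr$rfu, tolerance = 1e-8)
})

test_that("curve constructors and analysers reject malformed input", {
  expect_error(fluorescence_curve("A", 1:5, 1:5), "at least 10")
  expect_error(fluorescence_curve("A", c(1:10, 10), c(1:10, 10)),
               "strictly increasing")
  expect_error(fluorescence_curve("A", 1:10, c(1:9, NA)), "missing")
  cv <- generate_curve(curve_model(), seq(0, 30, 1))
  expect_error(extract_poi(cv, smooth_window = 6), "odd")
  melt <- generate_melt_curve(60)
  expect_error(extract_poi(melt), "amplification")
  expect_error(call_tm(cv), "melt")
})
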