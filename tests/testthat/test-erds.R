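test_that("window planning reproduces the 90%-overlap tiling", {
  plan <- planWindows(2, 1, 0.9, 250)
  expect_equal(plan@nSamples, 250L)
  expect_equal(length(plan@starts), 11L)       # starts 0, 25, ..., 250
  expect_equal(diff(plan@starts), rep(25L, 10L))
  expect_equal(plan@centers[1], 0.5)
  none <- planWindows(2, 1, 0, 250)
  expect_equal(length(none@starts), 2L)        # non-overlapping tiling
  one <- planWindows(2, 2, 0.9, 250)
  expect_equal(length(one@starts), 1L)         # tau = segment
  expect_error(planWindows(2, 3, 0.9, 250), "exceeds")
})

test_that("power course is zero for stationary signals and tracks a drop", {
  rate <- 250
  t <- (0:(7 * rate - 1)) / rate
  mk <- function(gain) {
    sig <- sin(2 * pi * 10 * t)
    sig[t >= 2.5 & t < 4.5] <- gain * sig[t >= 2.5 & t < 4.5]
    TrialSet(array(rep(sig, each = 2), c(2, 1, length(t))),
             c("left", "right"), 1 / rate,
             miWindow = c(2.5, 4.5), referenceWindow = c(0.5, 1.5))
  }
  flat <- suppressWarnings(powerErds(mk(1)))
  inMI <- timeAxis(flat) >= 2.6 & timeAxis(flat) < 4.4
  # the instantaneous squared amplitude ripples at 2f, but its MI-window
  # mean matches the baseline power for a stationary signal
  expect_lt(abs(mean(courseValues(flat)[1, inMI])), 0.01)
  # amplitude x sqrt(1/2) -> power halves -> zeta ~ -0.5
  drop <- suppressWarnings(powerErds(mk(sqrt(0.5))))
  expect_equal(mean(courseValues(drop)[1, inMI]), -0.5, tolerance = 0.01)
  # ratio form is invariant to channel gain
  scaled <- mk(sqrt(0.5))
  scaled@trials <- scaled@trials * 17
  drop2 <- suppressWarnings(powerErds(scaled))
  expect_equal(courseValues(drop2), courseValues(drop), tolerance = 1e-9)
})

test_that("power course demands a usable baseline", {
  ts <- tinyTrials()
  ts@referenceWindow <- c(NA_real_, NA_real_)
  expect_error(powerErds(ts), "reference")
  z <- TrialSet(array(0, c(1, 1, 500)), "left", 0.004,
                miWindow = c(1, 2), referenceWindow = c(0.1, 0.9))
  expect_error(suppressWarnings(powerErds(z)), "degenerate")
})

test_that("constant trials give an all-zero entropy course", {
  ts <- TrialSet(array(3, c(2, 2, 300)), c("left", "right"), 0.004)
  plan <- planWindows(trialDuration(ts), 0.4, 0.5, sampleRate(ts))
  for (est in c("sampen", "fuzzyen", "vqent")) {
    co <- quietCourse(ts, plan, entropyParams(2L, 0.3, est))
    expect_true(all(courseValues(co) == 0))
  }
})

test_that("white-noise trials give a flat course at the analytic level", {
  set.seed(43)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  ts <- TrialSet(array(rnorm(4 * 1 * 1500), c(4, 1, 1500)),
                 rep(c("left", "right"), 2), 0.004)
  plan <- planWindows(trialDuration(ts), 2, 0.5, sampleRate(ts))
  co <- quietCourse(ts, plan, entropyParams(2L, 0.2, "sampen"))
  v <- courseValues(co)
  expect_lt(abs(mean(v) - (-log(erf(0.1)))), 0.1)
  expect_lt(max(v) - min(v), 0.4)      # flat within estimator noise
})

test_that("the trial-averaged course is the mean of per-trial courses", {
  ts <- tinyTrials(n = 6L)
  plan <- planWindows(trialDuration(ts), 0.5, 0.5, sampleRate(ts))
  co <- quietCourse(ts, plan, entropyParams(2L, 0.3, "fuzzyen"))
  pt <- perTrialCourses(co)
  expect_equal(courseValues(co),
               apply(pt, c(2L, 3L), function(v) mean(v, na.rm = TRUE)))
  # single-trial courses of a subset average to the subset mean
  expect_equal(courseValues(co)[1, 1],
               mean(pt[, 1, 1]))
})

test_that("the contralateral entropy course dips inside the MI interval", {
  spec <- synthSpec(nTrialsPerClass = 8L, nChannels = 2L, seed = 47)
  tr <- bandpass(generateTrials(spec))
  seg <- extractWindow(tr, c(0.5, 6.5))      # ERD now at [2, 4) s
  plan <- planWindows(trialDuration(seg), 1, 0.5, sampleRate(seg))
  for (est in c("sampen", "fuzzyen", "vqent")) {
    co <- quietCourse(seg, plan, entropyParams(2L, 0.3, est))
    pt <- perTrialCourses(co)
    inMI <- timeAxis(co) >= 2.2 & timeAxis(co) < 3.8
    right <- trialLabels(seg) == "right"
    contra <- mean(pt[right, 1L, inMI], na.rm = TRUE)   # C3
    ipsi <- mean(pt[right, 2L, inMI], na.rm = TRUE)     # C4
    expect_lt(contra, ipsi)
  }
})

test_that("window plans outside the trials are rejected", {
  ts <- tinyTrials()
  plan <- planWindows(4, 1, 0.5, 250)        # 4 s plan on a 2 s trial
  expect_error(entropyErds(ts, plan, entropyParams()), "outside")
  tiny <- planWindows(trialDuration(ts), 0.012, 0, sampleRate(ts))
  expect_error(entropyErds(ts, tiny, entropyParams(3L)), "too short")
})
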