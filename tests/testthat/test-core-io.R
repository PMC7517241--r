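test_that("TrialSet validity enforces shape, labels and window ordering", {
  x <- array(rnorm(2 * 2 * 100), c(2, 2, 100))
  expect_s4_class(TrialSet(x, c("left", "right"), 0.004), "TrialSet")
  expect_error(TrialSet(x, "left", 0.004), "labels")
  expect_error(TrialSet(x, c("left", "right"), -1), "sampleInterval")
  expect_error(TrialSet(x, c("left", "right"), 0.004,
                        channelNames = c("a", "a")), "unique")
  # reference must precede the MI window
  expect_error(TrialSet(x, c("left", "right"), 0.004,
                        miWindow = c(0.05, 0.2),
                        referenceWindow = c(0.25, 0.35)), "precede")
})

test_that("JSON round-trip of a TrialSet is lossless", {
  ts <- tinyTrials()
  path <- withr::local_tempfile(fileext = ".json")
  writeTrials(ts, path)
  back <- readTrials(path)
  expect_identical(trialData(back), trialData(ts))
  expect_identical(trialLabels(back), trialLabels(ts))
  expect_identical(sampleInterval(back), sampleInterval(ts))
  expect_identical(miWindow(back), miWindow(ts))
  expect_identical(referenceWindow(back), referenceWindow(ts))
})

test_that("epoching cuts labeled cue events and drops the rest", {
  rate <- 250
  nS <- 50 * rate                       # 50 s continuous recording
  rec <- Recording(matrix(rnorm(3 * nS), 3, nS), 1 / rate,
                   c("C3", "10", "C4"))
  # 6 cue events placed so that all 7 s epochs fit
  cues <- c(3, 10, 17, 24, 31, 38)
  labs <- rep(c("left", "right"), 3)
  expect_message(
    ts <- epochRecording(rec, c(cues, 49.5, 20.5),
                         c(labs, "left", NA)),
    "2 event")                          # late epoch + unlabeled dropped
  expect_equal(nTrials(ts), 6L)
  expect_equal(nSamples(ts), 7 * rate)  # 7 s x 250 Hz = 1750
  expect_equal(as.character(trialLabels(ts)), labs)
  # the epoch content matches the source samples (bounds-checked cut)
  s0 <- as.integer(round((cues[1] - 2) * rate)) + 1L
  expect_identical(trialData(ts)[1, , ], rec@data[, s0:(s0 + 1749L)])
  # a standard 48-trial run epochs to N = 48
  cues48 <- 2 + 7 * (0:47)
  rec2 <- Recording(matrix(0, 1, (2 + 7 * 49) * rate), 1 / rate, "C3")
  ts48 <- epochRecording(rec2, cues48, rep(c("left", "right"), 24))
  expect_equal(nTrials(ts48), 48L)
  expect_error(epochRecording(rec, 49.9, "left"), "no labeled events")
})

test_that("recording files round-trip through epoching", {
  rate <- 250
  rec <- Recording(matrix(rnorm(2 * 20 * rate), 2, 20 * rate), 1 / rate)
  path <- withr::local_tempfile(fileext = ".json")
  writeRecording(rec, c(3, 11), c("left", "right"), path)
  ts <- readTrials(path)
  expect_equal(nTrials(ts), 2L)
  expect_equal(nSamples(ts), 7 * rate)
})

test_that("EDF/GDF formats raise a clear unsupported-format error", {
  expect_error(readTrials("x.edf"), "EDF")
  expect_error(readTrials("x.gdf"), "GDF")
  expect_error(readTrials(tempfile(fileext = ".json")), "not found")
})

test_that("course export writes the long CSV and round-trips JSON", {
  pt <- array(rnorm(3 * 1 * 11), c(3, 1, 11))
  pt[2, 1, 5] <- NaN
  course <- courseFromArray(pt, channels = "C3")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeCourse(course, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 11L)           # 1 channel x 11 windows
  expect_named(df, c("channel", "window_center_s", "value"))
  js <- withr::local_tempfile(fileext = ".json")
  writeCourse(course, js, format = "json")
  back <- readCourse(js)
  expect_identical(courseValues(back), courseValues(course))
  expect_identical(perTrialCourses(back), perTrialCourses(course))
  empty <- new("ErdsCourse", values = matrix(numeric(), 1, 0),
               timeAxis = numeric(), mode = "entropy", estimator = "sampen",
               channelNames = "C3", perTrial = array(numeric(), c(0, 0, 0)),
               diagnostics = list())
  expect_error(writeCourse(empty, csv), "empty")
})

test_that("default montage exposes the sensorimotor groups", {
  m <- defaultMontage()
  expect_setequal(sensorimotorChannels(m, "left"), c("C3", "9", "14", "15"))
  expect_setequal(sensorimotorChannels(m, "right"), c("C4", "11", "18", "17"))
  expect_setequal(sensorimotorChannels(m, "midline"), c("10", "16"))
  expect_length(sensorimotorChannels(m, "all"), 10L)
  expect_error(defaultMontage(c("C3", "XX")), "XX")
})

test_that("montage adjacency is symmetric with no self-neighbors", {
  for (mont in list(defaultMontage(),
                    synthMontage(synthSpec(nChannels = 6L)))) {
    for (ch in channelNames(mont)) {
      expect_false(ch %in% neighbors(mont, ch))
      for (nb in neighbors(mont, ch))
        expect_true(ch %in% neighbors(mont, nb))
    }
  }
  # user positions on a line: middle channel neighbors both ends
  pos <- cbind(c(0, 1, 2), c(0, 0, 0))
  lin <- defaultMontage(c("a", "b", "c"), positions = pos, k = 1L)
  expect_setequal(neighbors(lin, "b"), c("a", "c"))
})

test_that("channel subsetting preserves metadata", {
  ts <- tinyTrials(nCh = 3L)
  sub <- selectChannels(ts, c("ch3", "ch1"))
  expect_equal(channelNames(sub), c("ch3", "ch1"))
  expect_identical(sub@trials[, 1L, ], ts@trials[, 3L, ])
  expect_identical(miWindow(sub), miWindow(ts))
  expect_error(selectChannels(ts, "nope"), "unknown")
})
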