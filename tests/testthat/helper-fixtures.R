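# small in-code fixtures shared across test files

# deterministic tiny trial set: 2 channels, sinusoid + noise
tinyTrials <- function(n = 4L, nCh = 2L, nS = 500L, rate = 250,
                       seed = 1L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    t <- (seq_len(nS) - 1) / rate
    x <- array(0, c(n, nCh, nS))
    for (i in seq_len(n)) for (c in seq_len(nCh))
      x[i, c, ] <- sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) +
        0.3 * rnorm(nS)
    TrialSet(x, rep(c("left", "right"), length.out = n), 1 / rate,
             miWindow = c(1, 2), referenceWindow = c(0.1, 0.9))
  })
}

# ErdsCourse wrapper around a raw per-trial array
courseFromArray <- function(pt, timeAxis = NULL, channels = NULL,
                            estimator = "sampen") {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(pt)[2L]))
  if (is.null(timeAxis)) timeAxis <- seq_len(dim(pt)[3L]) / 10
  new("ErdsCourse",
      values = apply(pt, c(2L, 3L), function(v) mean(v, na.rm = TRUE)),
      timeAxis = timeAxis, mode = "entropy", estimator = estimator,
      channelNames = channels, perTrial = pt, diagnostics = list())
}

quietCourse <- function(...) suppressMessages(entropyErds(...))
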