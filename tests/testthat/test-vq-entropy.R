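test_that("greedy codebook admission follows the hand-traced loop", {
  # 1-D inputs 0, 10, 0.1 at tolerance 1 (squared distance): 10 is
  # admitted (100 > 1), 0.1 is rejected (0.01 <= 1)
  emb <- matrix(c(0, 10, 0.1), ncol = 1)
  cb <- buildCodebook(emb, 1)
  expect_equal(as.numeric(cb), c(0, 10))
  expect_equal(attr(cb, "index"), c(1L, 2L))
  # identical rows collapse to a single code
  expect_equal(nrow(buildCodebook(matrix(1, 20, 3), 0.5)), 1L)
  expect_error(buildCodebook(matrix(numeric(), 0, 2), 1), "empty")
  expect_error(buildCodebook(emb, 0), "positive")
})

test_that("codebook geometry: separation and coverage at the tolerance", {
  set.seed(13)
  for (i in 1:20) {
    w <- rnorm(sample(60:150, 1))
    m <- sample(1:3, 1)
    emb <- embedDelay(w, m)
    r <- runif(1, 0.1, 0.8) * sd(w)
    cb <- buildCodebook(emb, r)
    if (nrow(cb) > 1L) {
      d2 <- as.matrix(dist(cb))^2
      diag(d2) <- Inf
      expect_gt(min(d2), r)                    # all code pairs > rho apart
    }
    d2in <- outer(rowSums(emb^2), rep(1, nrow(cb))) +
      outer(rep(1, nrow(emb)), rowSums(cb^2)) - 2 * emb %*% t(cb)
    expect_lte(max(apply(d2in, 1, min)), r + 1e-12)  # coverage
  }
})

test_that("codebook size shrinks as the tolerance grows", {
  set.seed(17)
  w <- rnorm(200)
  emb <- embedDelay(w, 2L)
  qs <- vapply(seq(0.05, 0.9, by = 0.05) * sd(w),
               function(r) as.numeric(nrow(buildCodebook(emb, r))),
               numeric(1))
  expect_true(all(diff(qs) <= 0))
})

test_that("the fitted model is a proper probability model", {
  set.seed(19)
  for (i in 1:10) {
    w <- rnorm(120)
    emb <- embedDelay(w, 2L)
    r <- 0.3 * sd(w)
    mdl <- fitVQModel(emb, buildCodebook(emb, r), r)
    expect_lt(abs(sum(mdl@prior) - 1), 1e-9)
    expect_lt(abs(sum(mdl@posterior) - 1), 1e-9)
    expect_lt(max(abs(rowSums(mdl@membership) - 1)), 1e-9)
    expect_true(all(mdl@sigma2 >= 0))
  }
  # a single code takes all the posterior mass
  embC <- matrix(rnorm(30, sd = 1e-3), ncol = 1)
  cb1 <- buildCodebook(embC, 1)
  expect_equal(nrow(cb1), 1L)
  expect_equal(fitVQModel(embC, cb1, 1)@posterior, 1)
})

test_that("two balanced well-separated clusters split the posterior evenly", {
  set.seed(23)
  emb <- rbind(matrix(rnorm(100, mean = 0, sd = 0.01), ncol = 2),
               matrix(rnorm(100, mean = 10, sd = 0.01), ncol = 2))
  emb <- emb[sample(nrow(emb)), ]
  r <- 1
  cb <- buildCodebook(emb, r)
  expect_equal(nrow(cb), 2L)
  mdl <- fitVQModel(emb, cb, r)
  expect_equal(mdl@posterior, c(0.5, 0.5), tolerance = 0.02)
  # Shannon entropy of that posterior is ln 2
  h <- -sum(mdl@posterior * log(mdl@posterior))
  expect_equal(h, log(2), tolerance = 1e-3)
})

test_that("vqEntropy spans [0, ln Q'] and handles degenerate input", {
  expect_equal(as.numeric(vqEntropy(rep(1, 50))), 0)
  expect_equal(attr(vqEntropy(rep(1, 50)), "qPrime"), 1L)
  set.seed(29)
  for (i in 1:10) {
    h <- vqEntropy(rnorm(150), 2L, runif(1, 0.1, 0.8))
    expect_gte(as.numeric(h), 0)
    expect_lte(as.numeric(h), log(attr(h, "qPrime")) + 1e-9)
  }
  expect_error(vqEntropy(rnorm(3), 2L), "too short")
})

test_that("vqEntropy with the Euclidean admission rule is scale-invariant", {
  # the default admission rule compares the SQUARED distance to rho,
  # which ties the codebook to the amplitude scale; the Euclidean-mode
  # switch restores exact invariance under x -> a x
  set.seed(31)
  w <- rnorm(200)
  h0 <- as.numeric(vqEntropy(w, 2L, 0.3, squared = FALSE))
  h1 <- as.numeric(vqEntropy(3 * w, 2L, 0.3, squared = FALSE))
  expect_lt(abs(h1 - h0) / h0, 1e-6)
})

test_that("details mode returns the fitted model with the entropy attached", {
  set.seed(37)
  mdl <- vqEntropy(rnorm(100), 2L, 0.3, details = TRUE)
  expect_s4_class(mdl, "VQModel")
  expect_equal(attr(mdl, "entropy"),
               -sum(posteriorProbs(mdl) * log(posteriorProbs(mdl))),
               tolerance = 1e-12)
  expect_equal(qPrime(mdl), nrow(codebook(mdl)))
})

test_that("VQEnt drops during ERD relative to rest trials", {
  # right-hand trials suppress mu on C3 inside the MI interval; with the
  # tolerance anchored to the whole-trial sd the quantizer needs fewer
  # codes there, so the MI-window entropy is lower than in no-ERD trials
  erdSpec <- synthSpec(nTrialsPerClass = 26L, nChannels = 2L,
                       erdDepth = 0.6, seed = 41)
  restSpec <- synthSpec(nTrialsPerClass = 26L, nChannels = 2L,
                        erdDepth = 0, seed = 42)
  miMean <- function(spec) {
    tr <- bandpass(generateTrials(spec))
    tr <- subsetTrials(tr, trialLabels(tr) == "right")
    seg <- extractWindow(selectChannels(tr, "C3"), c(0.5, 6.5))
    plan <- planWindows(trialDuration(seg), 1, 0.5, sampleRate(seg))
    co <- quietCourse(seg, plan, entropyParams(2L, 0.3, "vqent"))
    inMI <- timeAxis(co) >= 2.2 & timeAxis(co) < 3.8
    apply(perTrialCourses(co)[, 1L, inMI], 1L, mean)
  }
  hErd <- miMean(erdSpec)
  hRest <- miMean(restSpec)
  expect_lt(t.test(hErd, hRest, alternative = "less")$p.value, 0.01)
})
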