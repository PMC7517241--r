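test_that("feature extraction lays out channels x windows with imputation", {
  pt <- array(rnorm(5 * 3 * 11), c(5, 3, 11))
  co <- courseFromArray(pt)
  f <- featuresFromCourses(co, channels = c("ch1", "ch3"))
  expect_equal(dim(f), c(5L, 22L))       # 2 channels x 11 windows
  expect_equal(featuresFromCourses(co, channels = "ch2",
                                   windowInterval = c(0.05, 0.15)) |> dim(),
               c(5L, 1L))
  # a NaN cell is replaced by the per-feature median over trials
  pt2 <- pt
  pt2[2, 1, 4] <- NaN
  f2 <- featuresFromCourses(courseFromArray(pt2), channels = "ch1")
  expect_equal(unname(f2[2, 4]), median(pt[-2, 1, 4]))
  expect_error(featuresFromCourses(co, channels = character()), "empty")
  expect_error(featuresFromCourses(co, channels = "zz"), "unknown")
})

test_that("LDA cross-validation separates what is separable", {
  set.seed(53)
  n <- 60
  lab <- rep(c("left", "right"), each = n / 2)
  sep <- rbind(matrix(rnorm(n / 2 * 4, 0), ncol = 4),
               matrix(rnorm(n / 2 * 4, 10), ncol = 4))
  expect_equal(ldaCvAccuracy(sep, lab, seed = 1L)$mean, 100)
  # shuffled labels on the same features sit at chance
  sh <- mean(vapply(1:5, function(s) {
    set.seed(100 + s)
    ldaCvAccuracy(sep, sample(lab), seed = s)$mean
  }, numeric(1)))
  expect_gt(sh, 30); expect_lt(sh, 70)
  # identical feature rows for both classes carry no information
  same <- matrix(rep(rnorm(4), each = n), nrow = n)
  noInfo <- ldaCvAccuracy(same, lab, seed = 1L)$mean
  expect_gt(noInfo, 30); expect_lt(noInfo, 70)
  expect_error(ldaCvAccuracy(sep, rep("left", n)), "two classes")
})

test_that("LDA accuracy is seed-deterministic and column-order invariant", {
  set.seed(59)
  X <- matrix(rnorm(40 * 6), 40)
  X[21:40, 1] <- X[21:40, 1] + 1.5
  lab <- rep(c("left", "right"), each = 20)
  a1 <- ldaCvAccuracy(X, lab, seed = 7L)
  a2 <- ldaCvAccuracy(X, lab, seed = 7L)
  expect_identical(a1, a2)
  a3 <- ldaCvAccuracy(X[, 6:1], lab, seed = 7L)
  expect_equal(a1$mean, a3$mean)
})

test_that("grid tuning keeps full bookkeeping and picks the argmax", {
  spec <- synthSpec(nTrialsPerClass = 10L, nChannels = 2L, snr = 3,
                    seed = 61)
  mi <- extractWindow(bandpass(generateTrials(spec)), c(2.5, 4.5))
  res <- tuneGrid(mi, taus = c(1, 2), ms = 2L, rhos = c(0.2, 0.5),
                  estimator = "fuzzyen", seed = 1L)
  expect_equal(nrow(res@grid), 4L)
  expect_equal(res@best$accMean, max(res@grid$accMean))
  # ties break toward the simpler model
  fake <- res
  fake@grid$accMean <- rep(80, 4)
  ord <- order(-fake@grid$accMean, fake@grid$m, fake@grid$rho,
               fake@grid$tau)
  expect_equal(fake@grid[ord[1], c("tau", "m", "rho")],
               data.frame(tau = 1, m = 2L, rho = 0.2),
               ignore_attr = TRUE)
})

test_that("trial similarity is a Gaussian kernel with the stated layout", {
  pt <- array(rnorm(8 * 1 * 10), c(8, 1, 10))
  lab <- rep(c("left", "right"), 4)
  co <- courseFromArray(pt, channels = "C3")
  sim <- trialSimilarity(co, co, channel = "C3", labels = lab)
  v <- sim@values
  expect_true(all(diag(v) == 1))
  expect_true(all(v > 0 & v <= 1))
  # hand-check one upper (right) and one lower (left) entry
  right <- which(lab == "right"); left <- which(lab == "left")
  expect_equal(v[1, 2],
               exp(-sum((pt[right[1], 1, ] - pt[right[2], 1, ])^2) /
                     sim@sigma2X))
  expect_equal(v[2, 1],
               exp(-sum((pt[left[1], 1, ] - pt[left[2], 1, ])^2) /
                     sim@sigma2X))
  # flat courses have zero trial-set variance: the kernel is undefined
  expect_error(trialSimilarity(courseFromArray(array(1, c(8, 1, 10)),
                                               channels = "C3"),
                               channel = "C3", labels = lab),
               "degenerate")
})

test_that("similarity decreases with course distance at the e^-1 mark", {
  base <- rnorm(12)
  pt <- array(NA_real_, c(4, 1, 12))
  for (i in 1:4) pt[i, 1, ] <- base + rnorm(12, sd = 0.8)
  co <- courseFromArray(pt, channels = "C3")
  lab <- c("left", "right", "left", "right")
  sim <- trialSimilarity(co, co, channel = "C3", labels = lab)
  d2 <- sum((pt[2, 1, ] - pt[4, 1, ])^2)
  expect_equal(sim@values[1, 2], exp(-d2 / sim@sigma2X))
  # an exact sigma2X^(1/2)-scaled offset lands on exp(-1)
  ptC <- pt
  ptC[4, 1, ] <- pt[2, 1, ] + sqrt(sim@sigma2X / 12)
  simC <- trialSimilarity(courseFromArray(ptC, channels = "C3"),
                          courseFromArray(ptC, channels = "C3"),
                          channel = "C3", labels = lab)
  expect_equal(simC@values[1, 2], exp(-sim@sigma2X / simC@sigma2X),
               tolerance = 1e-9)
})

test_that("channel relevance weights class-mean course differences", {
  set.seed(67)
  pt <- array(rnorm(20 * 3 * 8), c(20, 3, 8))
  lab <- rep(c("left", "right"), 10)
  pt[lab == "right", 2, ] <- pt[lab == "right", 2, ] + 2
  co <- courseFromArray(pt)
  rel <- channelRelevance(co, lab)
  expect_equal(channelRanking(rel)[1], "ch2")
  expect_true(all(relevanceWeights(rel) >= 0))
  # permutation invariance of the trial order
  perm <- sample(20)
  co2 <- courseFromArray(pt[perm, , , drop = FALSE])
  rel2 <- channelRelevance(co2, lab[perm])
  expect_equal(relevanceWeights(rel2), relevanceWeights(rel))
  # identical class means on a channel give weight ~ 0
  ptEq <- pt
  ptEq[, 3, ] <- rep(rnorm(8), each = 20)
  relEq <- channelRelevance(courseFromArray(ptEq), lab)
  expect_equal(unname(relevanceWeights(relEq)["ch3"]), 0)
  expect_error(channelRelevance(co, rep("left", 20)), "two classes")
})

test_that("incremental channel accuracy walks the relevance ranking", {
  set.seed(71)
  pt <- array(rnorm(40 * 4 * 6), c(40, 4, 6))
  lab <- rep(c("left", "right"), 20)
  pt[lab == "right", 1, ] <- pt[lab == "right", 1, ] + 3
  co <- courseFromArray(pt)
  rel <- channelRelevance(co, lab)
  curve <- incrementalChannelAccuracy(co, lab, rel, seed = 1L)
  expect_equal(nrow(curve), 4L)
  expect_equal(curve$channel[1], "ch1")
  expect_gt(curve$accMean[1], 90)
  restricted <- incrementalChannelAccuracy(co, lab, rel,
                                           channels = c("ch2", "ch3"),
                                           seed = 1L)
  expect_equal(nrow(restricted), 2L)
  expect_true(all(restricted$channel %in% c("ch2", "ch3")))
})

test_that("cluster permutation test localizes a programmed effect", {
  set.seed(73)
  chans <- c("C3", "C4", "10", "16")
  mont <- defaultMontage(chans)
  N <- 24; W <- 20
  pt <- array(rnorm(N * 4 * W), c(N, 4, W))
  lab <- rep(c("left", "right"), N / 2)
  # effect on C3, windows 8..12 only
  pt[lab == "right", 1, 8:12] <- pt[lab == "right", 1, 8:12] - 2
  co <- courseFromArray(pt, channels = chans,
                        timeAxis = seq_len(W) / 10)
  res <- clusterPermutationTest(co, lab, mont, nPermutations = 300L,
                                seed = 5L)
  expect_gt(nrow(res@clusters), 0L)
  top <- res@clusters[which.min(res@clusters$pValue), ]
  expect_lt(top$pValue, 0.05)
  expect_match(top$channels, "C3")
  expect_true(top$tMin <= 1.2 && top$tMax >= 0.8)  # overlaps windows 8..12
  # observed statistics equal the identity-permutation statistics
  expect_equal(dim(res@stat), c(4L, W))
  tHand <- apply(matrix(pt, nrow = N), 2L, function(col)
    t.test(col[lab == "left"], col[lab == "right"],
           var.equal = TRUE)$statistic)
  expect_equal(as.numeric(res@stat), as.numeric(tHand), tolerance = 1e-10)
})

test_that("cluster permutation test guards its preconditions", {
  chans <- c("C3", "C4")
  mont <- defaultMontage(chans)
  pt <- array(rnorm(12 * 2 * 5), c(12, 2, 5))
  co <- courseFromArray(pt, channels = chans)
  expect_error(clusterPermutationTest(co, rep(c("left", "right"), 6),
                                      mont, nPermutations = 10L),
               "200")
  small <- courseFromArray(pt[1:8, , , drop = FALSE], channels = chans)
  expect_error(clusterPermutationTest(small, rep(c("left", "right"), 4),
                                      mont), "5 trials")
})
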