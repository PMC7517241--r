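#' Classifier feature matrix from single-trial entropy courses
#'
#' Concatenates, per trial, the entropy values of the selected channels
#' over the windows whose centers fall inside \code{windowInterval}
#' (half-open), giving an N x F matrix with
#' F = channels x windows. Missing values (undefined SampEn windows)
#' are imputed by the per-feature median across trials.
#'
#' @param course an [ErdsCourse-class] with per-trial courses.
#' @param channels channel subset (default: all course channels).
#' @param windowInterval \code{c(t0, t1)} restriction on window centers
#'   in seconds (default: all windows).
#' @return N x F numeric matrix.
#' @export
featuresFromCourses <- function(course, channels = NULL,
                                windowInterval = NULL) {
  stopifnot(is(course, "ErdsCourse"))
  pt <- perTrialCourses(course)
  if (is.null(pt)) stop("course does not retain per-trial values")
  if (is.null(channels)) channels <- channelNames(course)
  if (length(channels) == 0L) stop("empty channel subset")
  miss <- setdiff(channels, channelNames(course))
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  ci <- match(channels, channelNames(course))
  wi <- if (is.null(windowInterval)) seq_along(course@timeAxis) else
    which(course@timeAxis >= windowInterval[1L] &
          course@timeAxis < windowInterval[2L])
  if (length(wi) == 0L) stop("no window centers inside the interval")
  N <- dim(pt)[1L]
  feats <- matrix(aperm(pt[, ci, wi, drop = FALSE], c(1L, 3L, 2L)),
                  nrow = N)
  colnames(feats) <- as.vector(outer(wi, channels,
                                     function(w, ch) paste0(ch, "@w", w)))
  for (j in seq_len(ncol(feats))) {
    bad <- !is.finite(feats[, j])
    if (any(bad))
      feats[bad, j] <- stats::median(feats[!bad, j])
  }
  feats
}

# stratified fold assignment, deterministic under the seed
.stratifiedFolds <- function(labels, folds, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated LDA accuracy
#'
#' Linear Discriminant Analysis under stratified k-fold
#' cross-validation, deterministic given the seed. Features that are
#' constant within the training part of a fold are dropped for that
#' fold; a fold whose classifier cannot be fitted falls back to the
#' training majority class.
#'
#' @param features N x F numeric matrix.
#' @param labels per-trial class labels (two classes).
#' @param folds number of folds (10 by default).
#' @param seed integer seed driving the fold assignment.
#' @return List with \code{mean} and \code{sd} of the fold accuracies on
#'   the 0-100 scale, and the fold-wise vector \code{perFold}.
#' @export
ldaCvAccuracy <- function(features, labels, folds = 10L, seed = 1L) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need two classes")
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (n < folds) stop("fewer trials than folds")
  fold <- .stratifiedFolds(labels, folds, seed)
  # with very small classes the tail folds can come out empty; they
  # carry no test trials and are dropped from the average
  useFolds <- sort(unique(fold))
  acc <- numeric(length(useFolds))
  for (k in useFolds) {
    tr <- fold != k
    te <- !tr
    ytr <- labels[tr]
    if (nlevels(droplevels(ytr)) < 2L) stop("a training fold lost a class")
    Xtr <- features[tr, , drop = FALSE]
    Xte <- features[te, , drop = FALSE]
    keep <- apply(Xtr, 2L, stats::sd) > 1e-12
    pred <- tryCatch({
      fit <- suppressWarnings(
        MASS::lda(x = Xtr[, keep, drop = FALSE], grouping = ytr))
      stats::predict(fit, Xte[, keep, drop = FALSE])$class
    }, error = function(e) {
      maj <- names(which.max(table(ytr)))
      factor(rep(maj, sum(te)), levels = levels(labels))
    })
    acc[k] <- 100 * mean(pred == labels[te])
  }
  list(mean = mean(acc), sd = stats::sd(acc), perFold = acc)
}

#' Exhaustive (tau, M, rho) parameter grid tuning
#'
#' Evaluates every combination of window length, embedding dimension
#' and tolerance (3 x 3 x 10 = 90 configurations with the default
#' grids) for one estimator: sliding-window entropy course, feature
#' extraction, stratified 10-fold LDA accuracy. The best configuration
#' is the accuracy argmax; ties break toward the simpler model (smaller
#' M, then rho, then tau).
#'
#' @param trials a [TrialSet-class], already preprocessed and cropped to
#'   the MI interval.
#' @param taus window lengths in seconds.
#' @param ms embedding dimensions.
#' @param rhos sigma-relative tolerances.
#' @param estimator estimator name.
#' @param overlap window overlap fraction.
#' @param folds,seed cross-validation controls.
#' @param scale tolerance scaling passed to [entropyErds()].
#' @return A [TuningResult-class].
#' @export
tuneGrid <- function(trials,
                     taus = c(1, 1.5, 2), ms = 1:3,
                     rhos = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7,
                              0.8, 0.9),
                     estimator = c("vqent", "sampen", "fuzzyen"),
                     overlap = 0.9, folds = 10L, seed = 1L,
                     scale = "trial") {
  stopifnot(is(trials, "TrialSet"))
  estimator <- match.arg(estimator)
  segLen <- trialDuration(trials)
  grid <- expand.grid(rho = rhos, m = ms, tau = taus,
                      KEEP.OUT.ATTRS = FALSE)[, c("tau", "m", "rho")]
  grid$accMean <- NA_real_
  grid$accSd <- NA_real_
  grid$qPrimeMedian <- NA_real_
  for (i in seq_len(nrow(grid))) {
    plan <- planWindows(segLen, grid$tau[i], overlap, sampleRate(trials))
    course <- suppressMessages(entropyErds(
      trials, plan,
      entropyParams(grid$m[i], grid$rho[i], estimator), scale = scale))
    feats <- featuresFromCourses(course)
    cv <- ldaCvAccuracy(feats, trialLabels(trials), folds = folds,
                        seed = seed)
    grid$accMean[i] <- cv$mean
    grid$accSd[i] <- cv$sd
    if (estimator == "vqent")
      grid$qPrimeMedian[i] <- course@diagnostics$qPrimeMedian
  }
  ord <- order(-grid$accMean, grid$m, grid$rho, grid$tau)
  new("TuningResult", grid = grid, best = grid[ord[1L], , drop = FALSE],
      estimator = estimator)
}

#' Trial-similarity matrix between two estimators' courses
#'
#' Gaussian similarity d(n, n') = exp(-||H_n - H_n'||^2 / sigma2X)
#' between single-trial entropy courses of estimators m and m' on one
#' channel, with sigma2X the single-trial course variance averaged
#' across the trial set. Entries above the diagonal compare right-label
#' trials, entries below left-label trials (the matrix side is the
#' smaller class count); the diagonal is 1.
#'
#' @param courseA,courseB [ErdsCourse-class] objects from the same trial
#'   set (may be the same object).
#' @param channel the channel whose courses are compared.
#' @param labels per-trial class labels (\code{left} / \code{right}).
#' @return A [SimilarityMatrix-class].
#' @export
trialSimilarity <- function(courseA, courseB = courseA, channel, labels) {
  stopifnot(is(courseA, "ErdsCourse"), is(courseB, "ErdsCourse"))
  labels <- factor(labels)
  ptA <- perTrialCourses(courseA)
  ptB <- perTrialCourses(courseB)
  if (is.null(ptA) || is.null(ptB))
    stop("both courses must retain per-trial values")
  if (!identical(dim(ptA)[c(1L, 3L)], dim(ptB)[c(1L, 3L)]))
    stop("courses must come from the same trial set and window plan")
  ca <- match(channel, channelNames(courseA))
  cb <- match(channel, channelNames(courseB))
  if (is.na(ca) || is.na(cb)) stop("unknown channel: ", channel)
  HA <- ptA[, ca, , drop = TRUE]
  HB <- ptB[, cb, , drop = TRUE]
  sigma2X <- mean(c(apply(HA, 1L, stats::var),
                    apply(HB, 1L, stats::var)), na.rm = TRUE)
  if (!is.finite(sigma2X) || sigma2X <= 0)
    stop("degenerate trial set: zero average course variance")
  right <- which(labels == "right")
  left <- which(labels == "left")
  K <- min(length(right), length(left))
  if (K < 2L) stop("need at least two trials per class")
  v <- diag(1, K)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      dR <- sum((HA[right[i], ] - HB[right[j], ])^2)
      dL <- sum((HA[left[i], ] - HB[left[j], ])^2)
      v[i, j] <- exp(-dR / sigma2X)
      v[j, i] <- exp(-dL / sigma2X)
    }
  }
  new("SimilarityMatrix", values = v, sigma2X = sigma2X,
      methods = c(courseA@estimator, courseB@estimator),
      channel = channel,
      convention = "upper = right-label pairs, lower = left-label pairs")
}

#' Channel relevance for class discrimination
#'
#' Per channel, the Euclidean distance between the class-mean entropy
#' time-courses (left vs right trials); channels whose courses differ
#' most between the classes rank first.
#'
#' @param course an [ErdsCourse-class] with per-trial courses.
#' @param labels per-trial class labels (two classes).
#' @return A [RelevanceMap-class].
#' @export
channelRelevance <- function(course, labels) {
  stopifnot(is(course, "ErdsCourse"))
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need two classes")
  pt <- perTrialCourses(course)
  if (is.null(pt)) stop("course does not retain per-trial values")
  cls <- levels(labels)
  m1 <- apply(pt[labels == cls[1L], , , drop = FALSE], c(2L, 3L),
              function(v) mean(v, na.rm = TRUE))
  m2 <- apply(pt[labels == cls[2L], , , drop = FALSE], c(2L, 3L),
              function(v) mean(v, na.rm = TRUE))
  w <- sqrt(rowSums((m1 - m2)^2))
  names(w) <- channelNames(course)
  new("RelevanceMap", weights = w,
      ranking = names(sort(w, decreasing = TRUE)))
}

#' Accuracy as channels are added in relevance order
#'
#' For k = 1...K, restricts the features to the k most relevant
#' channels and reports the cross-validated LDA accuracy, reproducing
#' the incremental channel-selection analysis (either over the whole
#' montage or restricted to the sensorimotor channels).
#'
#' @param course an [ErdsCourse-class] with per-trial courses.
#' @param labels per-trial class labels.
#' @param relevance a [RelevanceMap-class] covering the course channels.
#' @param channels optional restriction (e.g. the sensorimotor group);
#'   the ranking is filtered to it.
#' @param folds,seed cross-validation controls.
#' @param windowInterval optional window-center restriction in seconds.
#' @return data.frame with columns \code{k}, \code{channel} (the one
#'   added), \code{accMean}, \code{accSd}.
#' @export
incrementalChannelAccuracy <- function(course, labels, relevance,
                                       channels = NULL, folds = 10L,
                                       seed = 1L, windowInterval = NULL) {
  stopifnot(is(course, "ErdsCourse"), is(relevance, "RelevanceMap"))
  rank <- channelRanking(relevance)
  if (!is.null(channels)) rank <- rank[rank %in% channels]
  rank <- rank[rank %in% channelNames(course)]
  if (length(rank) == 0L) stop("no ranked channel present in the course")
  out <- data.frame(k = seq_along(rank), channel = rank,
                    accMean = NA_real_, accSd = NA_real_)
  for (k in seq_along(rank)) {
    feats <- featuresFromCourses(course, channels = rank[seq_len(k)],
                                 windowInterval = windowInterval)
    cv <- ldaCvAccuracy(feats, labels, folds = folds, seed = seed)
    out$accMean[k] <- cv$mean
    out$accSd[k] <- cv$sd
  }
  out
}

# two-sample pooled-variance t statistics for every course cell,
# given precomputed column sums/sums of squares
.tFromSums <- function(S1, Q1, n1, S, Q, n) {
  n2 <- n - n1
  S2 <- S - S1
  Q2 <- Q - Q1
  m1 <- S1 / n1
  m2 <- S2 / n2
  v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
  v2 <- (Q2 - S2^2 / n2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  sp2 <- pmax(sp2, .Machine$double.xmin)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# connected same-sign supra-threshold clusters on the channel x window
# grid; adjacency = temporal neighbors on a channel + montage-adjacent
# channels in the same window. Returns list(mass, members).
.clusterCells <- function(tmat, thr, adjIdx) {
  C <- nrow(tmat); W <- ncol(tmat)
  supra <- which(abs(tmat) > thr)
  if (length(supra) == 0L)
    return(list(masses = numeric(), members = list(),
                map = matrix(0L, C, W)))
  inSupra <- logical(C * W)
  inSupra[supra] <- TRUE
  map <- matrix(0L, C, W)
  masses <- numeric()
  members <- list()
  cid <- 0L
  for (cell in supra) {
    if (map[cell] != 0L) next
    cid <- cid + 1L
    queue <- cell
    map[cell] <- cid
    comp <- integer()
    sgn <- sign(tmat[cell])
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      comp <- c(comp, cur)
      ch <- ((cur - 1L) %% C) + 1L
      w <- ((cur - 1L) %/% C) + 1L
      cand <- integer()
      if (w > 1L) cand <- c(cand, cur - C)
      if (w < W) cand <- c(cand, cur + C)
      cand <- c(cand, (w - 1L) * C + adjIdx[[ch]])
      for (nx in cand) {
        if (inSupra[nx] && map[nx] == 0L && sign(tmat[nx]) == sgn) {
          map[nx] <- cid
          queue <- c(queue, nx)
        }
      }
    }
    masses[cid] <- sum(tmat[comp])
    members[[cid]] <- comp
  }
  list(masses = masses, members = members, map = map)
}

#' Cluster-based permutation test on entropy courses
#'
#' Nonparametric two-class test over the channel x window grid: a
#' two-sample t statistic per cell, cluster formation over temporal and
#' montage spatial adjacency among same-sign cells exceeding the
#' \code{alphaCluster}-level t threshold, cluster mass = summed t, and
#' a Monte-Carlo null of the maximum |mass| from label permutations.
#' The identity permutation reproduces the observed statistics, so
#' reported p-values are bounded below by 1 / (nPermutations + 1).
#'
#' @param course an [ErdsCourse-class] with per-trial courses (missing
#'   values imputed by the per-cell median).
#' @param labels per-trial class labels (two classes, >= 5 trials each).
#' @param montage a [Montage-class] covering the course channels.
#' @param nPermutations Monte-Carlo permutations (>= 200).
#' @param alphaCluster cluster-forming threshold level (0.02).
#' @param seed integer seed for the permutations.
#' @return A [ClusterTestResult-class].
#' @export
clusterPermutationTest <- function(course, labels, montage,
                                   nPermutations = 500L,
                                   alphaCluster = 0.02, seed = 1L) {
  stopifnot(is(course, "ErdsCourse"), is(montage, "Montage"))
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two classes")
  if (min(table(labels)) < 5L) stop("need at least 5 trials per class")
  if (nPermutations < 200L) stop("need at least 200 permutations")
  pt <- perTrialCourses(course)
  if (is.null(pt)) stop("course does not retain per-trial values")
  chans <- channelNames(course)
  miss <- setdiff(chans, channelNames(montage))
  if (length(miss))
    stop("montage does not cover channel(s): ", paste(miss, collapse = ", "))
  N <- dim(pt)[1L]; C <- dim(pt)[2L]; W <- dim(pt)[3L]
  X <- matrix(pt, nrow = N)               # N x (C*W), channel-fastest
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- stats::median(X[!bad, j])
  }
  adjIdx <- lapply(chans, function(ch)
    match(intersect(montage@adjacency[[ch]], chans), chans))
  n1 <- sum(labels == levels(labels)[1L])
  S <- colSums(X)
  Q <- colSums(X^2)
  idx1 <- which(labels == levels(labels)[1L])
  tObs <- matrix(.tFromSums(colSums(X[idx1, , drop = FALSE]),
                            colSums(X[idx1, , drop = FALSE]^2),
                            n1, S, Q, N), C, W)
  thr <- stats::qt(1 - alphaCluster / 2, df = N - 2L)
  obs <- .clusterCells(tObs, thr, adjIdx)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  nullMax <- numeric(nPermutations)
  for (p in seq_len(nPermutations)) {
    pid <- sample.int(N, n1)
    tp <- matrix(.tFromSums(colSums(X[pid, , drop = FALSE]),
                            colSums(X[pid, , drop = FALSE]^2),
                            n1, S, Q, N), C, W)
    cl <- .clusterCells(tp, thr, adjIdx)
    nullMax[p] <- if (length(cl$masses)) max(abs(cl$masses)) else 0
  }
  if (length(obs$masses)) {
    pvals <- vapply(obs$masses, function(m)
      (1 + sum(nullMax >= abs(m))) / (nPermutations + 1), numeric(1))
    chOf <- function(cells) unique(((cells - 1L) %% C) + 1L)
    wOf <- function(cells) ((cells - 1L) %/% C) + 1L
    clusters <- data.frame(
      id = seq_along(obs$masses),
      mass = obs$masses,
      size = lengths(obs$members),
      pValue = pvals,
      channels = vapply(obs$members, function(cc)
        paste(chans[chOf(cc)], collapse = "+"), character(1)),
      tMin = course@timeAxis[vapply(obs$members, function(cc)
        min(wOf(cc)), integer(1))],
      tMax = course@timeAxis[vapply(obs$members, function(cc)
        max(wOf(cc)), integer(1))]
    )
  } else {
    clusters <- data.frame(id = integer(), mass = numeric(),
                           size = integer(), pValue = numeric(),
                           channels = character(), tMin = numeric(),
                           tMax = numeric())
  }
  new("ClusterTestResult", clusters = clusters, stat = tObs,
      threshold = thr, clusterMap = obs$map, nullMax = nullMax)
}
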