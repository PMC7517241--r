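#' Greedy vector-quantized codebook of delay vectors
#'
#' Single online pass over the embedding rows in order: the first row
#' initializes the codebook and row q is admitted if and only if its
#' distance to every current code row exceeds the tolerance. By
#' construction all code pairs are more than \code{rhoAbs} apart and
#' every non-admitted row lies within \code{rhoAbs} of at least one
#' code. The default distance convention compares the squared Euclidean
#' norm against \code{rhoAbs}; \code{squared = FALSE} switches to the
#' plain Euclidean distance.
#'
#' @param emb Q x M embedding matrix (see [embedDelay()]).
#' @param rhoAbs admission tolerance (> 0).
#' @param squared compare the squared distance (default) or its root.
#' @return Q' x M matrix of admitted code vectors, with attribute
#'   \code{"index"} giving their 1-based source rows.
#' @export
buildCodebook <- function(emb, rhoAbs, squared = TRUE) {
  emb <- as.matrix(emb)
  if (nrow(emb) < 1L) stop("empty embedding")
  if (rhoAbs <= 0) stop("rhoAbs must be positive")
  idx <- .greedyCodebookIdx(emb, rhoAbs, squared)
  cb <- emb[idx, , drop = FALSE]
  attr(cb, "index") <- idx
  cb
}

#' Fit the Gaussian-similarity probabilistic model on a codebook
#'
#' One-pass fit of the stochastic pattern model: (i) memberships
#' p(x~_q = xbar_q') from the Gaussian similarity
#' exp(-||x~_q - xbar_q'||^2 / (2 rhoAbs^2)), normalized per input row;
#' (ii) per-code moments mu_q' (membership-weighted mean) and scalar
#' sigma2_q' (membership-weighted variance); (iii) the likelihood
#' p(X | xbar_q') as the mean Gaussian similarity of the inputs to the
#' code's moments; (iv) the prior p(xbar_q') as the mean membership;
#' (v) the Bayes posterior, normalized to sum 1. A collapsed code
#' (sigma2 = 0) is floored at 1e-12 times the squared data scale with a
#' warning.
#'
#' @param emb Q x M embedding matrix the codebook was built from.
#' @param cb codebook from [buildCodebook()].
#' @param rhoAbs the tolerance used to build the codebook (drives the
#'   Gaussian similarity bandwidth as the only available scale).
#' @param squared distance convention recorded in the model.
#' @return A [VQModel-class].
#' @export
fitVQModel <- function(emb, cb, rhoAbs, squared = TRUE) {
  emb <- as.matrix(emb)
  cb <- as.matrix(cb)
  qn <- nrow(emb)
  qp <- nrow(cb)
  # squared Euclidean distances input row -> code row
  d2 <- outer(rowSums(emb^2), rep(1, qp)) +
    outer(rep(1, qn), rowSums(cb^2)) - 2 * emb %*% t(cb)
  d2[d2 < 0] <- 0
  g <- exp(-d2 / (2 * rhoAbs^2))
  memb <- g / rowSums(g)
  w <- colSums(memb)                      # total membership mass per code
  mu <- t(memb) %*% emb / w
  sigma2 <- numeric(qp)
  for (k in seq_len(qp)) {
    dev2 <- rowSums((emb - matrix(mu[k, ], qn, ncol(emb), byrow = TRUE))^2)
    sigma2[k] <- sum(memb[, k] * dev2) / w[k]
  }
  scale2 <- mean(emb^2)
  if (scale2 == 0) scale2 <- 1
  zero <- sigma2 <= 0
  if (any(zero)) {
    warning(sum(zero), " code(s) with zero variance; floored")
    sigma2[zero] <- 1e-12 * scale2
  }
  # likelihood: mean Gaussian similarity of the inputs to each code's moments
  dmu2 <- outer(rowSums(emb^2), rep(1, qp)) +
    outer(rep(1, qn), rowSums(mu^2)) - 2 * emb %*% t(mu)
  dmu2[dmu2 < 0] <- 0
  lik <- colMeans(exp(-sweep(dmu2, 2L, 2 * sigma2, `/`)))
  prior <- w / qn
  post <- lik * prior
  if (sum(post) <= 0) post <- prior      # degenerate likelihood underflow
  post <- post / sum(post)
  new("VQModel", codebook = cb, rhoAbs = rhoAbs, squared = squared,
      membership = memb, mu = mu, sigma2 = sigma2,
      prior = prior / sum(prior), posterior = post)
}

#' Vector-quantized entropy (VQEnt) of a window
#'
#' The full pipeline of the quantized-pattern estimator: delay-embed
#' the window at dimension M, build the greedy codebook at tolerance
#' \code{rho * sd(window)} (or the supplied absolute tolerance), fit
#' the Gaussian-similarity model, and return the Shannon entropy of the
#' posterior over code vectors,
#' H = -sum_q' p(xbar_q' | X) ln p(xbar_q' | X).
#' The value lies in \[0, ln Q'\]; a constant window quantizes to a
#' single code and returns 0.
#'
#' @inheritParams sampleEntropy
#' @param squared distance convention of the codebook admission rule.
#' @param details return the fitted [VQModel-class] instead of the
#'   plain value (the entropy is then attached as attribute
#'   \code{"entropy"}).
#' @return Entropy in nats, with attribute \code{"qPrime"} (codebook
#'   size); or a [VQModel-class] when \code{details = TRUE}.
#' @export
vqEntropy <- function(window, m = 2L, rho = 0.3, rhoAbs = NULL,
                      squared = TRUE, details = FALSE) {
  if (length(window) < m + 2L)
    stop("window too short: need at least m + 2 = ", m + 2L, " samples")
  r <- .resolveRho(window, rho, rhoAbs)
  if (r == 0) {
    # constant window: a single code carries all the mass
    if (details) {
      emb <- embedDelay(window, m)
      mdl <- new("VQModel", codebook = emb[1L, , drop = FALSE],
                 rhoAbs = 0, squared = squared,
                 membership = matrix(1, nrow(emb), 1L),
                 mu = emb[1L, , drop = FALSE], sigma2 = 0,
                 prior = 1, posterior = 1)
      attr(mdl, "entropy") <- 0
      return(mdl)
    }
    return(structure(0, qPrime = 1L))
  }
  emb <- embedDelay(window, m)
  cb <- buildCodebook(emb, r, squared = squared)
  mdl <- fitVQModel(emb, cb, r, squared = squared)
  p <- mdl@posterior
  h <- -sum(p * log(pmax(p, .Machine$double.xmin)))
  if (details) {
    attr(mdl, "entropy") <- h
    return(mdl)
  }
  structure(h, qPrime = nrow(cb))
}
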