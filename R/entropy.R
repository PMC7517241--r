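#' Construct entropy estimator parameters
#'
#' @param m embedding dimension M.
#' @param rho tolerance as a multiple of the signal standard deviation.
#' @param estimator \code{"sampen"}, \code{"fuzzyen"} or \code{"vqent"}.
#' @return An [EntropyParams-class].
#' @export
entropyParams <- function(m = 2L, rho = 0.3,
                          estimator = c("vqent", "sampen", "fuzzyen")) {
  new("EntropyParams", m = as.integer(m), rho = as.numeric(rho),
      estimator = match.arg(estimator))
}

#' Delay-embed a window into its state-space matrix
#'
#' Builds the Q x M matrix of contiguous delay vectors
#' x~(q) = (x\[q\], ..., x\[q + M - 1\]), q = 1...Q, with the alphabet
#' size Q = N - M (N the window length). Every row is a contiguous
#' length-M slice of the window and the rows exhaust the window in
#' order.
#'
#' @param window numeric vector of length N > M.
#' @param m embedding dimension M.
#' @return Q x M numeric matrix.
#' @examples
#' embedDelay(c(1, 2, 3, 4), 2)  # rows (1,2) and (2,3)
#' @export
embedDelay <- function(window, m) {
  n <- length(window)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  q <- n - m
  if (q < 1L) stop("window length (", n, ") must exceed m (", m, ")")
  matrix(window[outer(seq_len(q), 0:(m - 1L), `+`)], nrow = q)
}

#' Template match probabilities at dimensions M and M + 1
#'
#' The mean pattern count over ordered pairs q != q': with the
#' Chebyshev distance, the proportion of pairs closer than the
#' tolerance (strict inequality); with the fuzzy distance, the mean
#' Gaussian membership exp(-d^2 / rhoAbs). \code{piM} is computed on
#' the dimension-M embedding and \code{piM1} by re-embedding the same
#' window at M + 1.
#'
#' @param window numeric vector of length >= M + 3.
#' @param m embedding dimension M.
#' @param rhoAbs absolute tolerance (same units as the signal).
#' @param distance \code{"chebyshev"} or \code{"fuzzy"}.
#' @return List with elements \code{piM} and \code{piM1}.
#' @export
patternCount <- function(window, m, rhoAbs,
                         distance = c("chebyshev", "fuzzy")) {
  distance <- match.arg(distance)
  if (length(window) < m + 3L)
    stop("window too short: need at least m + 3 = ", m + 3L, " samples")
  if (rhoAbs <= 0) stop("rhoAbs must be positive")
  f <- if (distance == "chebyshev") .chebMatchProportion else .fuzzyMatchMean
  list(piM = f(embedDelay(window, m), rhoAbs),
       piM1 = f(embedDelay(window, m + 1L), rhoAbs))
}

# resolve the absolute tolerance: rho is sigma-relative unless an
# absolute tolerance is passed down (the sliding-window course fixes
# rhoAbs from the whole-trial sd)
.resolveRho <- function(window, rho, rhoAbs) {
  if (!is.null(rhoAbs)) return(rhoAbs)
  rho * stats::sd(window)
}

#' Sample entropy of a window
#'
#' SampEn = -ln(pi(M+1) / pi(M)) with hard Chebyshev template matching
#' at tolerance \code{rho * sd(window)} and self-matches excluded. A
#' zero-variance (constant) window is perfectly regular and returns 0.
#' When no template pair matches at dimension M + 1 the ratio is
#' undefined and NaN is returned with a warning; sliding-window courses
#' treat such windows as missing.
#'
#' @param window numeric vector of length >= M + 3.
#' @param m embedding dimension M.
#' @param rho tolerance as a multiple of the window standard deviation.
#' @param rhoAbs optional absolute tolerance overriding \code{rho}
#'   scaling (used when the tolerance is fixed at the trial level).
#' @return Entropy in nats (>= 0), or NaN when undefined.
#' @export
sampleEntropy <- function(window, m = 2L, rho = 0.3, rhoAbs = NULL) {
  r <- .resolveRho(window, rho, rhoAbs)
  if (r == 0) return(0)
  pc <- patternCount(window, m, r, "chebyshev")
  if (is.na(pc$piM1) || pc$piM1 == 0 || pc$piM == 0) {
    warning("no template matches at dimension M + 1; SampEn undefined (NaN)")
    return(NaN)
  }
  -log(pc$piM1 / pc$piM)
}

#' Fuzzy entropy of a window
#'
#' As [sampleEntropy()] but with the hard match count replaced by the
#' Gaussian membership exp(-d^2 / rhoAbs) of the Chebyshev template
#' distance, so the estimate is always finite.
#'
#' @inheritParams sampleEntropy
#' @return Entropy in nats (non-negative up to numerical tolerance).
#' @export
fuzzyEntropy <- function(window, m = 2L, rho = 0.3, rhoAbs = NULL) {
  r <- .resolveRho(window, rho, rhoAbs)
  if (r == 0) return(0)
  pc <- patternCount(window, m, r, "fuzzy")
  -log(pc$piM1 / pc$piM)
}
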