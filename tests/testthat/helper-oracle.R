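# Literal double-loop oracles for the template-match probabilities,
# independent of the package's kernels: explicit embedding loop,
# explicit pairwise loop, no vectorization.

oracleEmbed <- function(window, m) {
  q <- length(window) - m
  emb <- matrix(NA_real_, q, m)
  for (i in seq_len(q)) for (j in seq_len(m)) emb[i, j] <- window[i + j - 1]
  emb
}

oracleMatchProportion <- function(window, m, rhoAbs,
                                  distance = c("chebyshev", "fuzzy")) {
  distance <- match.arg(distance)
  emb <- oracleEmbed(window, m)
  q <- nrow(emb)
  total <- 0
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) next
      d <- 0
      for (k in seq_len(ncol(emb))) {
        a <- abs(emb[i, k] - emb[j, k])
        if (a > d) d <- a
      }
      inc <- if (distance == "chebyshev") as.numeric(d < rhoAbs) else
        exp(-d^2 / rhoAbs)
      total <- total + inc
    }
  }
  total / (q * (q - 1))
}

oracleEntropy <- function(window, m, rho, distance) {
  rhoAbs <- rho * sd(window)
  piM <- oracleMatchProportion(window, m, rhoAbs, distance)
  piM1 <- oracleMatchProportion(window, m + 1L, rhoAbs, distance)
  # same degenerate convention as the estimators: an empty match set at
  # dimension M + 1 leaves the ratio undefined
  if (piM1 == 0 || piM == 0) return(NaN)
  -log(piM1 / piM)
}
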