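# Small simulated panels shared across tests. Everything is generated in
# code under fixed seeds; no stored fixtures.

makePanel <- function(n = 60, m = 300, seed = 1, structure = 0,
                      nSubpops = 1, freqRange = c(0.1, 0.9)) {
  simulateDosages(simulationConfig(
    nIndividuals = n, nMarkers = m, nSubpops = nSubpops,
    structureStrength = structure, alleleFreqRange = freqRange,
    seed = seed))
}

# additive trait on top of a panel: named phenotype + truth
makeTrait <- function(X, h2 = 0.5, seed = 1, nQtl = 100) {
  varE <- (1 - h2) / h2
  ph <- simulatePhenotypes(X, traitSpec(varAdditive = 1, varResidual = varE,
                                        nQtlAdditive = nQtl),
                           fieldLayoutSpec(rows = ceiling(nrow(dosages(X)) / 10),
                                           cols = 10),
                           seed = seed)
  g <- ph$truth$geneticValue
  set.seed(seed + 1000)
  y <- g + rnorm(length(g), 0, sqrt(varE))
  names(y) <- names(g)
  list(y = y, g = g, truth = ph$truth)
}

# independent closed-form one-kernel BLUP: dense grid search over the
# variance ratio maximising the restricted likelihood, then the standard
# conditional-mean predictor. Plain matrix algebra only.
oracleBLUP <- function(y, K, ratioGrid = exp(seq(-6, 6, length.out = 121))) {
  n <- length(y)
  ones <- rep(1, n)
  best <- NULL; bestLL <- -Inf
  for (r in ratioGrid) {   # r = s2g / s2e
    V <- r * K + diag(n)
    Vi <- solve(V)
    mu <- sum(Vi %*% y) / sum(Vi %*% ones)
    e <- y - mu
    rss <- drop(t(e) %*% Vi %*% e)
    s2e <- rss / (n - 1)
    ll <- -0.5 * (determinant(V, logarithm = TRUE)$modulus +
                    log(sum(Vi %*% ones)) + (n - 1) * (log(s2e) + 1))
    if (ll > bestLL) {
      bestLL <- ll
      best <- list(mu = mu, g = drop(r * K %*% Vi %*% e),
                   s2e = s2e, s2g = r * s2e)
    }
  }
  best
}
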