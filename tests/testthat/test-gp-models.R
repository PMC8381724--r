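test_that("Gibbs GBLUP agrees with an independent closed-form BLUP", {
  sim <- makePanel(n = 80, m = 500, seed = 71)
  tr <- makeTrait(sim$dosages, h2 = 0.5, seed = 72)
  GA <- additiveKinship(sim$dosages)
  fit <- fitGBLUP(tr$y, GA, gibbsConfig(nIter = 3000, burnIn = 1000,
                                        seed = 5))
  oracle <- oracleBLUP(tr$y, kinship(GA))
  expect_gt(cor(gebv(fit), oracle$mu + oracle$g), 0.99)
  # the (sigma2_a, sigma2_eps) split sits on a flat likelihood ridge at this
  # n, so compare the residual variance within the posterior spread and the
  # well-identified total variance more tightly
  expect_lt(abs(varComp(fit)["sigma2_eps"] - oracle$s2e),
            3 * sd(fit@details$varChain[, 2]))
  totGibbs <- sum(varComp(fit) * c(mean(diag(kinship(GA))), 1))
  totREML <- oracle$s2g * mean(diag(kinship(GA))) + oracle$s2e
  expect_lt(abs(totGibbs - totREML) / totREML, 0.15)
})

test_that("Gibbs chains are reproducible and scale-equivariant", {
  sim <- makePanel(n = 40, m = 200, seed = 73)
  tr <- makeTrait(sim$dosages, h2 = 0.5, seed = 74)
  GA <- additiveKinship(sim$dosages)
  cfg <- gibbsConfig(nIter = 500, burnIn = 100, seed = 11)
  f1 <- fitGBLUP(tr$y, GA, cfg)
  f2 <- fitGBLUP(tr$y, GA, cfg)
  expect_identical(gebv(f1), gebv(f2))

  f3 <- fitGBLUP(2 * tr$y, GA, cfg)
  expect_equal(gebv(f3) - f3@mu, 2 * (gebv(f1) - f1@mu), tolerance = 1e-9)
  expect_equal(unname(varComp(f3)), unname(4 * varComp(f1)),
               tolerance = 1e-9)
})

test_that("degenerate phenotypes give constant predictions and vanishing variances", {
  sim <- makePanel(n = 30, m = 100, seed = 75)
  y <- setNames(rep(3, 30), rownames(dosages(sim$dosages)))
  GA <- additiveKinship(sim$dosages)
  fit <- fitGBLUP(y, GA, gibbsConfig(nIter = 400, burnIn = 100, seed = 1))
  expect_lt(max(abs(gebv(fit) - 3)), 1e-3)
  expect_lt(varComp(fit)["sigma2_a"], 1e-6)
})

test_that("kernel/phenotype id mismatches are reported with offenders", {
  sim <- makePanel(n = 10, m = 50, seed = 76)
  GA <- additiveKinship(sim$dosages)
  y <- setNames(rnorm(3), c("Ind0001", "nobody1", "nobody2"))
  expect_error(fitGBLUP(y, GA), "nobody1")
})

test_that("additive + dominance model recovers the simulated variance ratio", {
  ratios <- vapply(1:8, function(s) {
    sim <- makePanel(n = 120, m = 500, seed = 900 + s)
    ph <- simulatePhenotypes(
      sim$dosages,
      traitSpec(varAdditive = 1, varDominance = 1, varResidual = 0.7),
      fieldLayoutSpec(rows = 12, cols = 10), seed = 950 + s)
    g <- ph$truth$geneticValue
    set.seed(990 + s)
    y <- setNames(g + rnorm(120, 0, sqrt(0.7)), names(g))
    GA <- additiveKinship(sim$dosages)
    GD <- dominanceKinship(sim$dosages)
    fit <- fitGBLUP(y, list(GA, GD),
                    gibbsConfig(nIter = 1500, burnIn = 500, seed = s))
    unname(varComp(fit)["sigma2_d"] / varComp(fit)["sigma2_a"])
  }, 0)
  expect_gte(median(ratios), 0.4)
  expect_lte(median(ratios), 2.5)
})

test_that("marker-effect ridge with matched penalty reproduces kernel BLUP", {
  sim <- makePanel(n = 100, m = 300, seed = 77)
  tr <- makeTrait(sim$dosages, h2 = 0.6, seed = 78)
  X <- dosages(sim$dosages)
  p <- alleleFreq(sim$dosages)
  Z <- sweep(X, 2, 4 * p)
  c0 <- sum(4 * p * (1 - p))
  GA <- additiveKinship(sim$dosages)
  fit <- fitGBLUP(tr$y, GA, engine = "reml")
  lam <- fit@varComp["sigma2_eps"] / fit@varComp["sigma2_a"]
  e <- tr$y - fit@mu
  bRidge <- solve(crossprod(Z) + diag(lam * c0, ncol(Z)), crossprod(Z, e))
  gRidge <- fit@mu + drop(Z %*% bRidge)
  expect_equal(unname(gebv(fit)), unname(gRidge), tolerance = 1e-6)
})

test_that("Bayesian marker models shrink under the null and are location-invariant", {
  sim <- makePanel(n = 80, m = 400, seed = 79)
  X <- dosages(sim$dosages)
  set.seed(80)
  y <- setNames(rnorm(80), rownames(X))
  cfg <- gibbsConfig(nIter = 1500, burnIn = 500, seed = 3)
  fit <- fitBayesMarker(y, sim$dosages, "BayesCpi", cfg)
  # pi is weakly identified under a null trait and its chain mixes slowly,
  # so average the zero-effect proportion over a few independent chains
  piZero <- vapply(1:3, function(s)
    fitBayesMarker(y, sim$dosages, "BayesCpi",
                   gibbsConfig(nIter = 4000, burnIn = 1000,
                               seed = s))@details$pi, 0)
  expect_gt(mean(piZero), 0.5)
  # shrinkage relative to single-marker OLS slopes
  Zc <- scale(X, scale = FALSE)
  ols <- abs(drop(crossprod(Zc, y - mean(y))) / colSums(Zc^2))
  expect_lt(mean(abs(fit@markerEffects)), mean(ols))

  # shifting y shifts mu and leaves effects untouched (same RNG stream)
  fitS <- fitBayesMarker(y + 7, sim$dosages, "BayesCpi", cfg)
  expect_equal(fitS@mu, fit@mu + 7, tolerance = 1e-9)
  expect_equal(fitS@markerEffects, fit@markerEffects, tolerance = 1e-9)
})

test_that("BayesC-pi ranks oligogenic QTL markers highly", {
  hits <- vapply(1:10, function(s) {
    sim <- makePanel(n = 120, m = 800, seed = 1100 + s)
    X <- dosages(sim$dosages)
    set.seed(1200 + s)
    qtl <- sample(800, 10)
    b <- rnorm(10, 0, 1)
    g <- drop(sweep(X[, qtl], 2, colMeans(X[, qtl])) %*% b)
    g <- g / sd(g)
    y <- setNames(g + rnorm(120, 0, sqrt(3 / 7)), rownames(X))  # h2 = 0.7
    fit <- fitBayesMarker(y, sim$dosages, "BayesCpi",
                          gibbsConfig(nIter = 1500, burnIn = 500, seed = s))
    top <- order(abs(fit@markerEffects), decreasing = TRUE)[1:40]  # top 5%
    mean(qtl %in% top)
  }, 0)
  # at least half the QTL in the top 5% for most seeds
  expect_gte(mean(hits >= 0.5), 0.8)
})

test_that("all three Bayesian priors fit and store their specific parameters", {
  sim <- makePanel(n = 60, m = 200, seed = 81)
  tr <- makeTrait(sim$dosages, h2 = 0.5, seed = 82)
  cfg <- gibbsConfig(nIter = 800, burnIn = 200, seed = 2)
  fa <- fitBayesMarker(tr$y, sim$dosages, "BayesA", cfg)
  fc <- fitBayesMarker(tr$y, sim$dosages, "BayesCpi", cfg)
  fl <- fitBayesMarker(tr$y, sim$dosages, "BayesL", cfg)
  for (f in list(fa, fc, fl)) {
    expect_gt(cor(gebv(f), tr$g), 0.3)
    expect_true(all(varComp(f) >= 0))
  }
  expect_true(fc@details$pi > 0 && fc@details$pi < 1)
  expect_gt(fl@details$lambda, 0)
  expect_error(fitBayesMarker(setNames(c(1, NA, Inf), names(tr$y)[1:3]),
                              sim$dosages, "BayesA", cfg), "finite")
})

test_that("RKHS selects a bandwidth near the generating one and handles the no-signal limit", {
  # moderate marker count keeps pairwise distances spread out; with many
  # markers the distances concentrate and the bandwidth is barely
  # identifiable (see the methods vignette)
  recovered <- vapply(1:10, function(s) {
    sim <- makePanel(n = 200, m = 100, seed = 1300 + s)
    K <- kinship(rkhsKernel(sim$dosages, 1))
    set.seed(1400 + s)
    L <- chol(K + diag(1e-8, 200))
    g <- drop(crossprod(L, rnorm(200)))
    y <- setNames(g + rnorm(200, 0, 0.3), rownames(K))
    fit <- fitRKHS(y, sim$dosages, thetaGrid = c(0.1, 0.25, 0.5, 1, 2, 5))
    fit@details$theta
  }, 0)
  grid <- c(0.1, 0.25, 0.5, 1, 2, 5)
  withinOne <- abs(match(recovered, grid) - match(1, grid)) <= 1
  expect_gte(sum(withinOne), 6)

  # profile likelihood finite everywhere
  sim <- makePanel(n = 40, m = 100, seed = 83)
  tr <- makeTrait(sim$dosages, h2 = 0.4, seed = 84)
  fit <- fitRKHS(tr$y, sim$dosages)
  expect_true(all(is.finite(fit@details$profile$logLik)))

  # vanishing heritability: predictions collapse to the grand mean
  set.seed(85)
  y0 <- setNames(rnorm(40), names(tr$y))
  f0 <- fitRKHS(y0, sim$dosages)
  expect_lt(var(gebv(f0)) / var(y0), 0.05)
})
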