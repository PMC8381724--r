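#' Gibbs sampler configuration
#'
#' @param nIter total Gibbs iterations (default 10000).
#' @param burnIn discarded warm-up iterations (default 2500).
#' @param thin keep every `thin`-th post-burn-in sample (default 1).
#' @param seed RNG seed; chains are bit-identical per seed.
#' @param df prior degrees of freedom of the scaled-inverse-chi-square
#'   variance hyperpriors.
#' @param R2 prior proportion of phenotypic variance assigned to the
#'   genetic terms when solving for hyperprior scales (equal split across
#'   terms; the residual receives `1 - R2`).
#' @return list of class `"GibbsConfig"`.
#' @export
gibbsConfig <- function(nIter = 10000, burnIn = 2500, thin = 1, seed = 1,
                        df = 5, R2 = 0.5) {
  stopifnot(burnIn < nIter, thin >= 1, df > 2, R2 > 0, R2 < 1)
  structure(list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 df = df, R2 = R2),
            class = "GibbsConfig")
}

# effective sample size from the initial-positive-sequence autocorrelations
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}

.modelTagFromFlavors <- function(flavors) {
  key <- paste(sort(flavors), collapse = "+")
  switch(key,
         "additive" = "Add",
         "additive+dominance_digenic" = "A+D",
         "additive+dominance_digenic+epistatic_AxA" = "A+D+Ep",
         "full_tetraploid" = "FT",
         "rkhs" = "RKHS",
         paste(flavors, collapse = "+"))
}

.vcName <- c(additive = "sigma2_a", dominance_digenic = "sigma2_d",
             epistatic_AxA = "sigma2_e", full_tetraploid = "sigma2_f",
             rkhs = "sigma2_g")

.checkKernelIds <- function(y, kernels) {
  ids <- names(y)
  if (is.null(ids)) stop("y must be a named vector of phenotypes")
  for (K in kernels) {
    kid <- rownames(K@values)
    missing <- setdiff(ids, kid)
    if (length(missing))
      stop("kernel/phenotype id mismatch; phenotyped individuals absent ",
           "from the ", K@flavor, " kernel: ",
           paste(head(missing, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Kernel-based GBLUP fitted by Gibbs sampling or REML
#'
#' Fits `y = mu + sum_k g_k + eps` with `g_k ~ N(0, K_k sigma_k^2)` for one
#' to three relationship matrices (additive; additive + dominance;
#' additive + dominance + epistatic; or a single full-tetraploid or RKHS
#' kernel). Individuals with `NA` phenotype are predicted from the joint
#' kernel rows connecting them to the training set.
#'
#' The default engine is a Gibbs sampler with scaled-inverse-chi-square
#' variance priors whose scales split a prior `R2` of the phenotypic
#' variance equally across the genetic terms. Sampling is performed in the
#' eigenbasis of each kernel's training block, which makes the conditional
#' updates independent and the chain cheap. `engine = "reml"` instead
#' maximises the restricted likelihood (exact profile REML for one kernel,
#' fixed-point REML for several) and returns the corresponding BLUPs --
#' useful when many fits are needed, e.g. inside cross-validation.
#'
#' @param y named numeric vector over all individuals; `NA` marks
#'   unphenotyped (validation) individuals.
#' @param kernels a [KinshipMatrix-class] or list of them, covering at least
#'   all phenotyped individuals (ideally all individuals, so predictions are
#'   available).
#' @param config a [gibbsConfig()].
#' @param engine `"gibbs"` (default) or `"reml"`.
#' @return A [GPFit-class]; `gebv(fit)` has one value per kernel individual.
#' @export
fitGBLUP <- function(y, kernels, config = gibbsConfig(),
                     engine = c("gibbs", "reml")) {
  engine <- match.arg(engine)
  if (is(kernels, "KinshipMatrix")) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1, length(kernels) <= 3,
            all(vapply(kernels, is, TRUE, "KinshipMatrix")))
  .checkKernelIds(y[!is.na(y)], kernels)
  flavors <- vapply(kernels, flavor, "")
  tag <- .modelTagFromFlavors(flavors)
  allIds <- rownames(kernels[[1]]@values)
  train <- names(y)[!is.na(y)]
  yt <- y[train]
  nt <- length(yt)
  if (nt < 3) stop("need at least 3 phenotyped individuals")
  nk <- length(kernels)
  Kt <- lapply(kernels, function(K) K@values[train, train, drop = FALSE])
  Kat <- lapply(kernels, function(K) K@values[allIds, train, drop = FALSE])
  vcn <- .vcName[flavors]

  if (engine == "reml") {
    fit <- .remlMultiKernel(yt, Kt)
    uAll <- 0
    for (k in seq_len(nk))
      uAll <- uAll + drop(fit$s2[k] * Kat[[k]] %*% fit$Vinv_r)
    vc <- setNames(c(fit$s2, fit$s2e), c(vcn, "sigma2_eps"))
    return(new("GPFit", model = tag, mu = fit$beta[1], varComp = vc,
               gebv = setNames(fit$beta[1] + uAll, allIds),
               gebvSD = setNames(rep(NA_real_, length(allIds)), allIds),
               markerEffects = numeric(0),
               details = list(engine = "reml", logLik = fit$logLik,
                              converged = fit$converged)))
  }

  set.seed(config$seed)
  vy <- var(yt)
  df0 <- config$df
  S0 <- vapply(Kt, function(K) {
    md <- mean(diag(K))
    vy * config$R2 / nk / max(md, 1e-12) * (df0 + 2) / df0
  }, 0)
  S0e <- vy * (1 - config$R2) * (df0 + 2) / df0
  if (vy == 0) { S0[] <- 1e-8; S0e <- 1e-8 }

  eg <- lapply(Kt, function(K) {
    es <- eigen(K, symmetric = TRUE)
    keep <- es$values > max(es$values) * 1e-10
    list(U = es$vectors[, keep, drop = FALSE], d = es$values[keep])
  })

  mu <- mean(yt)
  s2 <- pmax(rep(vy, nk) * config$R2 / nk, 1e-8)
  s2e <- max(vy * (1 - config$R2), 1e-8)
  a <- lapply(eg, function(e) rep(0, length(e$d)))
  g <- lapply(eg, function(e) rep(0, nt))

  nStore <- (config$nIter - config$burnIn) %/% config$thin
  varChain <- matrix(NA_real_, nStore, nk + 1)
  aSum <- lapply(eg, function(e) rep(0, length(e$d)))
  gSum <- rep(0, nt); gSqSum <- rep(0, nt)
  muSum <- 0; saved <- 0

  for (it in seq_len(config$nIter)) {
    resid <- yt - Reduce(`+`, g, accumulate = FALSE) - mu
    # intercept
    rbar <- mean(resid + mu)
    muNew <- rnorm(1, rbar, sqrt(s2e / nt))
    resid <- resid + mu - muNew
    mu <- muNew
    for (k in seq_len(nk)) {
      r <- resid + g[[k]]
      t_ <- drop(crossprod(eg[[k]]$U, r))
      pv <- 1 / (1 / s2e + 1 / (eg[[k]]$d * s2[k]))
      pm <- pv * t_ / s2e
      a[[k]] <- rnorm(length(pm), pm, sqrt(pv))
      gNew <- drop(eg[[k]]$U %*% a[[k]])
      resid <- r - gNew
      g[[k]] <- gNew
      dfk <- df0 + length(a[[k]])
      sck <- (df0 * S0[k] + sum(a[[k]]^2 / eg[[k]]$d)) / dfk
      s2[k] <- dfk * sck / rchisq(1, dfk)
    }
    dfe <- df0 + nt
    s2e <- dfe * ((df0 * S0e + sum(resid^2)) / dfe) / rchisq(1, dfe)

    if (it > config$burnIn && (it - config$burnIn - 1) %% config$thin == 0) {
      saved <- saved + 1
      varChain[saved, ] <- c(s2, s2e)
      for (k in seq_len(nk)) aSum[[k]] <- aSum[[k]] + a[[k]]
      gtot <- Reduce(`+`, g)
      gSum <- gSum + gtot; gSqSum <- gSqSum + gtot^2
      muSum <- muSum + mu
    }
  }

  muHat <- muSum / saved
  vcMean <- colMeans(varChain[seq_len(saved), , drop = FALSE])
  vc <- setNames(vcMean, c(vcn, "sigma2_eps"))
  # posterior-mean genotypic values for everyone via the joint kernel rows:
  # g_all = K[all, train] Ktt^{-1} g_train, applied per kernel in eigenspace
  uAll <- rep(0, length(allIds))
  for (k in seq_len(nk)) {
    abar <- aSum[[k]] / saved
    alpha <- drop(eg[[k]]$U %*% (abar / eg[[k]]$d))
    uAll <- uAll + drop(Kat[[k]] %*% alpha)
  }
  gSD <- sqrt(pmax(gSqSum / saved - (gSum / saved)^2, 0))
  sdAll <- setNames(rep(NA_real_, length(allIds)), allIds)
  sdAll[train] <- gSD
  ess <- apply(varChain[seq_len(saved), , drop = FALSE], 2, .ess)
  new("GPFit", model = tag, mu = muHat, varComp = vc,
      gebv = setNames(muHat + uAll, allIds), gebvSD = sdAll,
      markerEffects = numeric(0),
      details = list(engine = "gibbs", config = config,
                     varChain = varChain[seq_len(saved), , drop = FALSE],
                     essVar = setNames(ess, names(vc))))
}

#' Bayesian whole-genome marker regression
#'
#' Fits `y = mu + X b + eps` by Gibbs sampling with one of three prior
#' hierarchies on marker effects: `"BayesA"` (per-marker scaled-inverse-
#' chi-square variances, i.e. a scaled-t effect distribution), `"BayesCpi"`
#' (spike-and-slab mixture where a proportion `pi` of markers has exactly
#' zero effect, `pi` estimated from the data with a uniform prior) and
#' `"BayesL"` (Bayesian LASSO: double-exponential effects via the
#' exponential-mixture-of-normals hierarchy, with the sharpness parameter
#' lambda given a Gamma hyperprior and estimated from the data).
#'
#' Marker columns are centred by `4 p_j` using frequencies from all
#' individuals in `dosageMat`; unphenotyped individuals are predicted as
#' `mu + X b` with the posterior-mean effects.
#'
#' @param y named numeric vector; `NA` marks individuals to predict.
#' @param dosageMat complete [DosageMatrix-class] covering all individuals
#'   in `y`.
#' @param model `"BayesA"`, `"BayesCpi"` or `"BayesL"`.
#' @param config a [gibbsConfig()].
#' @return A [GPFit-class] with `markerEffects`, and `pi`/`lambda` in
#'   `details` where applicable.
#' @export
fitBayesMarker <- function(y, dosageMat,
                           model = c("BayesA", "BayesCpi", "BayesL"),
                           config = gibbsConfig()) {
  model <- match.arg(model)
  stopifnot(is(dosageMat, "DosageMatrix"))
  if (any(!is.finite(y[!is.na(y)]))) stop("non-finite phenotype values")
  ids <- rownames(dosageMat@dosages)
  if (is.null(names(y))) stop("y must be named")
  missing <- setdiff(names(y)[!is.na(y)], ids)
  if (length(missing))
    stop("phenotyped individuals absent from dosages: ",
         paste(head(missing, 5), collapse = ", "))
  p <- dosageMat@alleleFreq
  Xc <- sweep(dosageMat@dosages, 2, 4 * p)
  train <- names(y)[!is.na(y)]
  yt <- as.numeric(y[train])
  Xt <- Xc[train, , drop = FALSE]
  n <- length(yt); m <- ncol(Xt)
  vy <- var(yt)
  df0 <- config$df
  msx <- sum(colMeans(Xt^2))           # summed marker variances
  vb <- vy * config$R2 / max(msx, 1e-12)
  S0b <- max(vb, 1e-12) * (df0 + 2) / df0
  S0e <- max(vy * (1 - config$R2), 1e-12) * (df0 + 2) / df0
  lambda2 <- max(2 * (1 - config$R2) / config$R2 * msx, 1e-6)
  modelId <- match(model, c("BayesA", "BayesCpi", "BayesL")) - 1L

  set.seed(config$seed)
  res <- bayes_marker_gibbs(yt, Xt, modelId, config$nIter, config$burnIn,
                            config$thin, df0, S0b, df0, S0e,
                            lambda2, 1.1, 1.1 / lambda2)
  b <- setNames(res$b, colnames(Xc))
  gebvAll <- setNames(res$mu + drop(Xc %*% b), ids)
  vc <- c(sigma2_b = if (modelId == 2L) res$lambda else
            mean(res$varChain[, 1]),
          sigma2_eps = res$sigma2e)
  details <- list(engine = "gibbs", config = config,
                  varChain = res$varChain,
                  essVar = apply(res$varChain, 2, .ess),
                  centering = 4 * p)
  if (model == "BayesCpi") {
    details$pi <- res$pi
    details$inclusion <- setNames(res$inclusion, colnames(Xc))
  }
  if (model == "BayesL") details$lambda <- res$lambda
  new("GPFit", model = model, mu = res$mu, varComp = vc,
      gebv = gebvAll,
      gebvSD = setNames(rep(NA_real_, length(ids)), ids),
      markerEffects = b, details = details)
}

#' RKHS regression with maximum-likelihood bandwidth selection
#'
#' For each candidate bandwidth the Gaussian kernel is built from the dosage
#' profiles (of all individuals), the one-kernel restricted likelihood is
#' maximised through a spectral decomposition on the training block, and the
#' bandwidth with the highest profile likelihood wins. Predictions are BLUPs
#' at the chosen bandwidth using the joint kernel rows.
#'
#' @param y named numeric vector; `NA` marks individuals to predict.
#' @param dosageMat complete [DosageMatrix-class].
#' @param thetaGrid positive bandwidth candidates.
#' @return A [GPFit-class] with model `"RKHS"`; `details$theta` holds the
#'   selected bandwidth and `details$profile` the likelihood grid.
#' @export
fitRKHS <- function(y, dosageMat,
                    thetaGrid = c(0.1, 0.25, 0.5, 1, 2, 5)) {
  stopifnot(length(thetaGrid) >= 1, all(thetaGrid > 0))
  ids <- rownames(dosageMat@dosages)
  train <- names(y)[!is.na(y)]
  stopifnot(length(train) >= 3, all(train %in% ids))
  yt <- as.numeric(y[train])
  # scale-free squared-distance matrix, built once for the whole grid
  D <- as.matrix(stats::dist(dosageMat@dosages))^2
  off <- mean(D[upper.tri(D)])
  if (off > 0) D <- D / off
  best <- NULL; bestLL <- -Inf
  prof <- numeric(length(thetaGrid))
  for (i in seq_along(thetaGrid)) {
    K <- .newKinship(exp(-thetaGrid[i] * D), "rkhs", ncol(dosageMat@dosages),
                     theta = thetaGrid[i], ids = ids)
    Kt <- K@values[train, train]
    jit <- 0
    if (mean(Kt[upper.tri(Kt)]) > 1 - 1e-6) {
      warning("kernel nearly degenerate at theta = ", thetaGrid[i],
              "; adding ridge jitter 1e-8")
      jit <- 1e-8
    }
    fit <- .remlSpectral(yt, Kt, jitter = jit)
    prof[i] <- fit$logLik
    if (is.finite(fit$logLik) && fit$logLik > bestLL) {
      bestLL <- fit$logLik
      best <- list(theta = thetaGrid[i], fit = fit, K = K)
    }
  }
  f <- best$fit
  uAll <- drop(f$s2u * best$K@values[ids, train] %*% f$Vinv_r)
  new("GPFit", model = "RKHS", mu = f$beta[1],
      varComp = c(sigma2_g = f$s2u, sigma2_eps = f$s2e),
      gebv = setNames(f$beta[1] + uAll, ids),
      gebvSD = setNames(rep(NA_real_, length(ids)), ids),
      markerEffects = numeric(0),
      details = list(engine = "ml", theta = best$theta,
                     profile = data.frame(theta = thetaGrid,
                                          logLik = prof)))
}
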