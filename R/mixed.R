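# Mixed-model engines for kernel covariance structures.
#
# Two fitters cover everything downstream:
#   .remlSpectral  - exact profile REML for y = Xb + u + e, u ~ N(0, s2u K),
#                    via one eigendecomposition of K (used by RKHS theta
#                    selection, the GWAS null model, and single-kernel BLUP).
#   .remlMultiKernel - fixed-point REML for several kernel terms
#                    (used by the A+D and A+D+Ep BLUP oracles and CV).
# Both return variance components on the scale of y.

.remlSpectral <- function(y, K, X = NULL, jitter = 0) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  if (jitter > 0) K <- K + diag(jitter, n)
  es <- eigen(K, symmetric = TRUE)
  U <- es$vectors; s <- pmax(es$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  negREML <- function(logLambda) {
    lambda <- exp(logLambda)            # s2u / s2e
    v <- lambda * s + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + sum(log(v)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(negREML, c(-12, 12))
  lambda <- exp(opt$minimum)
  v <- lambda * s + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  s2e <- sum(w * r^2) / (n - p)
  s2u <- lambda * s2e
  # BLUP of u on the training individuals: s2u K V^{-1} (y - Xb)
  u <- U %*% ((lambda * s * w) * r)
  list(s2u = s2u, s2e = s2e, beta = drop(beta), u = drop(u),
       logLik = -opt$objective, lambda = lambda,
       eigen = es, Vinv_r = U %*% (w * r) / s2e)
}

.remlMultiKernel <- function(y, kernels, X = NULL, maxit = 800, tol = 1e-9) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  nk <- length(kernels)
  vy <- var(y)
  if (vy <= 0) {
    return(list(s2 = setNames(rep(0, nk), names(kernels)), s2e = 0,
                beta = rep(mean(y), ncol(X)),
                u = replicate(nk, rep(0, n), simplify = FALSE),
                logLik = NA_real_, converged = TRUE))
  }
  # direct REML maximisation on the log-variance scale (Nelder-Mead):
  # robust to the boundary collapse that plagues multiplicative
  # fixed-point updates when a component is small
  negREML <- function(logS2) {
    s2 <- exp(logS2)
    V <- diag(s2[nk + 1], n)
    for (k in seq_len(nk)) V <- V + s2[k] * kernels[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    beta <- solve(XtViX, crossprod(ViX, y))
    r <- y - X %*% beta
    0.5 * (2 * sum(log(diag(ch))) +
             determinant(XtViX, logarithm = TRUE)$modulus +
             drop(crossprod(r, Vi %*% r)))
  }
  start <- log(rep(vy / (nk + 1), nk + 1))
  opt <- stats::optim(start, negREML, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = tol))
  s2all <- exp(opt$par)
  s2 <- s2all[seq_len(nk)]; s2e <- s2all[nk + 1]
  conv <- opt$convergence == 0
  V <- diag(s2e, n)
  for (k in seq_len(nk)) V <- V + s2[k] * kernels[[k]]
  Vi <- solve(V)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  r <- y - X %*% beta
  Vir <- Vi %*% r
  u <- lapply(seq_len(nk), function(k) drop(s2[k] * kernels[[k]] %*% Vir))
  ll <- -0.5 * (determinant(V, logarithm = TRUE)$modulus +
                  determinant(XtViX, logarithm = TRUE)$modulus +
                  drop(crossprod(r, Vir)))
  list(s2 = setNames(s2, names(kernels)), s2e = s2e, beta = drop(beta),
       u = u, logLik = as.numeric(ll), converged = conv, Vinv_r = Vir)
}
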