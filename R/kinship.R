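#' Eigenvalue guard for relationship matrices
#'
#' Clips eigenvalues below `-1e-8 * lambda_max` to zero (with a warning);
#' smaller negative values are treated as numerical noise and left alone by
#' the callers, which only require PSD within tolerance.
#' @keywords internal
.psdGuard <- function(G) {
  ev <- eigen(G, symmetric = TRUE)
  tol <- -1e-8 * max(ev$values)
  if (min(ev$values) < tol) {
    warning("relationship matrix has eigenvalues below tolerance (min = ",
            signif(min(ev$values), 3), "); clipping to zero")
    lam <- pmax(ev$values, 0)
    G <- ev$vectors %*% (lam * t(ev$vectors))
    G <- (G + t(G)) / 2
  }
  G
}

.completeDosages <- function(dosageMat) {
  stopifnot(is(dosageMat, "DosageMatrix"))
  if (anyNA(dosageMat@dosages))
    stop("dosages contain missing values; impute first (imputeDosages)")
  dosageMat@dosages
}

#' Additive genomic relationship matrix for autotetraploids
#'
#' VanRaden-type construction at ploidy 4: dosage columns are centred by
#' `4 p_j` (alternative-allele frequency from the data, or supplied) and the
#' cross-product is normalised by `sum_j 4 p_j (1 - p_j)`, the expected
#' marker variance under tetrasomic Hardy-Weinberg equilibrium, so the mean
#' diagonal is close to 1 in an unstructured HWE population.
#'
#' @param dosageMat complete [DosageMatrix-class].
#' @param p optional externally fixed allele frequencies (one per marker);
#'   defaults to frequencies computed from the data. Fixing them makes
#'   kinship construction commute with subsetting individuals.
#' @return [KinshipMatrix-class] with flavor `"additive"`.
#' @examples
#' X <- DosageMatrix(matrix(c(0, 4), 2, 1))
#' kinship(additiveKinship(X))   # [[4,-4],[-4,4]] for one marker at p=0.5
#' @export
additiveKinship <- function(dosageMat, p = NULL) {
  X <- .completeDosages(dosageMat)
  if (is.null(p)) p <- colMeans(X) / 4
  stopifnot(length(p) == ncol(X))
  denom <- sum(4 * p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero normalisation")
  Z <- sweep(X, 2, 4 * p)
  G <- tcrossprod(Z) / denom
  .newKinship(.psdGuard(G), "additive", ncol(X), ids = rownames(X))
}

#' Exact variance of the digenic-dominance covariate
#'
#' Enumerates the five dosage outcomes under Binomial(4, p).
#' @keywords internal
.digenicVar <- function(p) {
  x <- 0:4
  w <- dbinom(x, 4, p)
  vapply(p, function(pj) {
    d <- choose(x, 2) - 3 * pj * x + 6 * pj^2
    wj <- dbinom(x, 4, pj)
    sum(wj * d^2) - sum(wj * d)^2
  }, 0)
}

#' Digenic dominance relationship matrix
#'
#' Per marker the digenic covariate is `d(x) = C(x,2) - 3 p x + 6 p^2`, the
#' count of allele pairs quadratic in dosage, HWE-centred by construction
#' (its Binomial(4, p) expectation is zero for every p). The cross-product
#' is normalised by the summed exact Binomial(4, p) variances of the
#' covariate, obtained by enumerating the five dosage outcomes.
#'
#' @inheritParams additiveKinship
#' @return [KinshipMatrix-class] with flavor `"dominance_digenic"`.
#' @export
dominanceKinship <- function(dosageMat, p = NULL) {
  X <- .completeDosages(dosageMat)
  if (is.null(p)) p <- colMeans(X) / 4
  D <- choose(X, 2) - sweep(3 * X, 2, p, `*`) + matrix(6 * p^2, nrow(X),
                                                       ncol(X), byrow = TRUE)
  denom <- sum(.digenicVar(p))
  if (denom <= 0) stop("all markers monomorphic: zero dominance variance")
  G <- tcrossprod(D) / denom
  .newKinship(.psdGuard(G), "dominance_digenic", ncol(X), ids = rownames(X))
}

#' Additive-by-additive epistatic relationship matrix
#'
#' The Hadamard (elementwise) square of the additive relationship matrix;
#' positive semi-definiteness is preserved by the Schur product theorem.
#'
#' @param GA additive [KinshipMatrix-class].
#' @return [KinshipMatrix-class] with flavor `"epistatic_AxA"`.
#' @export
epistasisKinship <- function(GA) {
  stopifnot(is(GA, "KinshipMatrix"))
  if (GA@flavor != "additive")
    stop("epistasisKinship expects an additive kinship matrix")
  .newKinship(GA@values * GA@values, "epistatic_AxA", GA@nMarkers,
              ids = rownames(GA@values))
}

#' Full-tetraploid (genotype-class) relationship matrix
#'
#' Each marker contributes five indicator columns, one per dosage class
#' (AAAA..BBBB), so every genotype class carries its own effect. The
#' indicator cross-product counts shared genotype classes and is scaled so
#' the mean diagonal equals 1; scaling only changes the units of the
#' attached variance component, not predictions.
#'
#' @inheritParams additiveKinship
#' @return [KinshipMatrix-class] with flavor `"full_tetraploid"`.
#' @export
fullTetraploidKinship <- function(dosageMat) {
  X <- .completeDosages(dosageMat)
  if (any(X != round(X)))
    stop("full-tetraploid coding needs integer dosages (mode imputation)")
  n <- nrow(X); m <- ncol(X)
  # G[i,j] = number of markers where i and j share the dosage class
  G <- matrix(0, n, n)
  for (k in 0:4) {
    Ik <- (X == k) * 1
    G <- G + tcrossprod(Ik)
  }
  G <- G / mean(diag(G))   # diag is m for every individual -> divide by m
  .newKinship(G, "full_tetraploid", m, ids = rownames(X))
}

#' Gaussian (RKHS) kernel between dosage profiles
#'
#' Squared Euclidean distances between dosage rows are divided by their mean
#' off-diagonal value, making the bandwidth `theta` dimension-free across
#' marker counts, and exponentiated: `K = exp(-theta * D)`. The diagonal is
#' exactly 1.
#'
#' @inheritParams additiveKinship
#' @param theta positive bandwidth; larger values make relationships decay
#'   faster with distance.
#' @return [KinshipMatrix-class] with flavor `"rkhs"`.
#' @export
rkhsKernel <- function(dosageMat, theta = 1) {
  X <- .completeDosages(dosageMat)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  D <- as.matrix(stats::dist(X))^2
  n <- nrow(D)
  off <- mean(D[upper.tri(D)])
  if (off > 0) D <- D / off
  K <- exp(-theta * D)
  .newKinship(K, "rkhs", ncol(X), theta = theta, ids = rownames(X))
}
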