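.codings <- c("additive", "1-dom-alt", "1-dom-ref", "2-dom-alt", "2-dom-ref")

#' Gene-action marker codings
#'
#' Recodes the dosage matrix under one of five gene-action assumptions.
#' Additive keeps the 0..4 dosage. The dominance codings are two-level
#' (0/4): simplex dominance switches the effect on with at least one copy
#' of the dominant allele, duplex dominance with at least two; `alt`/`ref`
#' says which allele is taken as dominant (the reference codings mirror the
#' alternative ones under dosage reversal `x -> 4 - x`).
#'
#' @param dosageMat complete [DosageMatrix-class].
#' @param coding one of `"additive"`, `"1-dom-alt"`, `"1-dom-ref"`,
#'   `"2-dom-alt"`, `"2-dom-ref"`.
#' @return list of class `"CodedMarkers"`: `coding`, `values` (matrix),
#'   `markerInfo`.
#' @examples
#' X <- DosageMatrix(matrix(0:4, 5, 1))
#' codeMarkers(X, "1-dom-alt")$values[, 1]  # 0 4 4 4 4
#' codeMarkers(X, "2-dom-alt")$values[, 1]  # 0 0 4 4 4
#' @export
codeMarkers <- function(dosageMat, coding = .codings) {
  coding <- match.arg(coding)
  X <- .completeDosages(dosageMat)
  M <- switch(coding,
    "additive"  = X,
    "1-dom-alt" = (X >= 1) * 4,
    "2-dom-alt" = (X >= 2) * 4,
    "1-dom-ref" = (X <= 3) * 4,
    "2-dom-ref" = (X <= 2) * 4)
  structure(list(coding = coding, values = M,
                 markerInfo = dosageMat@markerInfo),
            class = "CodedMarkers")
}

#' Effective number of independent tests (Li & Ji)
#'
#' Eigenvalues `lambda_i` of the marker-marker correlation matrix are
#' summarised as `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i -
#' floor(lambda_i)) ]`. The nonzero spectrum is obtained from the
#' individuals-by-individuals cross-product of the standardised marker
#' matrix, so the cost is driven by the panel size rather than the marker
#' count; zero eigenvalues contribute nothing.
#'
#' @param markers numeric matrix (individuals x markers), e.g. additively
#'   coded dosages.
#' @return effective number of tests (never exceeding `min(n, m)`).
#' @examples
#' liJiMeff(cbind(c(0, 2, 4), c(0, 2, 4)))  # duplicated marker: 1
#' @export
liJiMeff <- function(markers) {
  M <- as.matrix(markers)
  if (ncol(M) < 2) stop("need at least 2 markers")
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker(s) excluded from Meff")
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) < 2) stop("fewer than 2 polymorphic markers")
  }
  W <- scale(M)
  n <- nrow(W)
  lam <- eigen(tcrossprod(W) / (n - 1), symmetric = TRUE,
               only.values = TRUE)$values
  lam <- pmax(lam, 0)
  # snap eigenvalues sitting numerically on an integer: the fractional part
  # is discontinuous there and rounding noise would otherwise add ~1
  near <- abs(lam - round(lam)) < 1e-8
  lam[near] <- round(lam[near])
  sum((lam >= 1) + (lam - floor(lam)))
}

#' Multiple-testing significance threshold
#'
#' `-log10(alpha / Meff)`: the per-test level after dividing the
#' significance level by the effective number of independent tests.
#'
#' @param alpha genome-wide significance level in (0, 1).
#' @param meff effective number of tests (>= 1).
#' @param digits rounding of the reported threshold (default 2).
#' @return threshold on the -log10 p scale.
#' @examples
#' gwasThreshold(0.05, 222)  # 3.65
#' @export
gwasThreshold <- function(alpha, meff, digits = 2) {
  stopifnot(alpha > 0, alpha < 1, meff >= 1)
  round(-log10(alpha / meff), digits)
}

#' Mixed-model association scan under one gene-action coding
#'
#' Two-stage (P3D-style) scan of `y = mu + x beta + g + eps` with polygenic
#' covariance from the additive relationship matrix: the null model
#' (`mu + g`) is fitted once by REML, then each marker is tested by
#' generalised least squares at the fixed null variance components with a
#' Wald test. `perMarkerReml = TRUE` refits the variance components for
#' every marker (exact but slow; for small panels). Markers monomorphic
#' under the coding are skipped and flagged with `NA` score.
#'
#' @param y named phenotype vector (adjusted means).
#' @param coded a [codeMarkers()] result.
#' @param GA additive [KinshipMatrix-class] (used for the polygenic term
#'   whatever the coding under test).
#' @param alpha genome-wide significance level.
#' @param meff effective number of tests for the threshold; default computes
#'   Li-Ji Meff from the supplied coded matrix, but for a shared threshold
#'   across codings pass the additive-coding Meff explicitly.
#' @param perMarkerReml refit variance components per marker?
#' @return A [GWASScan-class]; `details` in the results attribute carry the
#'   genomic-control lambda.
#' @export
gwasScan <- function(y, coded, GA, alpha = 0.05, meff = NULL,
                     perMarkerReml = FALSE) {
  stopifnot(inherits(coded, "CodedMarkers"), is(GA, "KinshipMatrix"))
  ids <- names(y)[!is.na(y)]
  stopifnot(length(ids) >= 5, all(ids %in% rownames(GA@values)),
            all(ids %in% rownames(coded$values)))
  yt <- as.numeric(y[ids])
  K <- GA@values[ids, ids]
  Xm <- coded$values[ids, , drop = FALSE]
  m <- ncol(Xm)
  if (is.null(meff))
    meff <- if (m >= 2) liJiMeff(Xm) else 1
  thr <- gwasThreshold(alpha, meff)

  mono <- apply(Xm, 2, sd) == 0
  beta <- se <- score <- rep(NA_real_, m)

  null <- .remlSpectral(yt, K)
  U <- null$eigen$vectors
  v <- null$lambda * pmax(null$eigen$values, 0) + 1   # Var/(s2e)
  w <- 1 / v
  ys <- drop(crossprod(U, yt))
  ones <- drop(crossprod(U, rep(1, length(yt))))

  if (!perMarkerReml) {
    Xs <- crossprod(U, Xm[, !mono, drop = FALSE])
    s2e <- null$s2e
    Sww <- sum(w * ones^2)
    Swy <- sum(w * ys * ones)
    Swx <- drop(crossprod(Xs, w * ones))
    Sxy <- drop(crossprod(Xs, w * ys))
    Sxx <- colSums(Xs^2 * w)
    xvar <- pmax(Sxx - Swx^2 / Sww, 0)
    degen <- xvar < 1e-10 * pmax(Sxx, 1e-300)
    xvar[degen] <- NA_real_
    bhat <- (Sxy - Swx * Swy / Sww) / xvar
    vb <- s2e / xvar
    chi <- bhat^2 / vb
    beta[!mono] <- bhat
    se[!mono] <- sqrt(vb)
    score[!mono] <- -pchisq(chi, 1, lower.tail = FALSE, log.p = TRUE) /
      log(10)
  } else {
    idxs <- which(!mono)
    for (j in idxs) {
      f <- .remlSpectral(yt, K, X = cbind(1, Xm[, j]))
      # Wald from the GLS at the per-marker REML optimum
      vj <- f$lambda * pmax(f$eigen$values, 0) + 1
      Xs <- crossprod(f$eigen$vectors, cbind(1, Xm[, j]))
      XtWX <- crossprod(Xs, Xs / vj)
      covb <- solve(XtWX) * f$s2e
      beta[j] <- f$beta[2]
      se[j] <- sqrt(covb[2, 2])
      chi <- (beta[j] / se[j])^2
      score[j] <- -pchisq(chi, 1, lower.tail = FALSE, log.p = TRUE) / log(10)
    }
  }
  chiAll <- qchisq(10^(-pmin(score, 300)), 1, lower.tail = FALSE)
  lambdaGC <- median(chiAll, na.rm = TRUE) / qchisq(0.5, 1)
  res <- data.frame(marker = coded$markerInfo$marker,
                    chrom = coded$markerInfo$chrom,
                    pos = coded$markerInfo$pos,
                    beta = beta, se = se, score = score,
                    significant = !is.na(score) & score >= thr,
                    stringsAsFactors = FALSE)
  attr(res, "lambdaGC") <- lambdaGC
  attr(res, "nSkipped") <- sum(mono)
  new("GWASScan", results = res, coding = coded$coding,
      threshold = thr, meff = meff)
}

#' Variance explained by significant markers and population structure
#'
#' Ordinary least-squares R-squared of a set of nested regressions of the
#' phenotype: the first three principal components alone; PCs plus the
#' significant additively coded markers; PCs plus additive plus each
#' dominance coding's significant markers. Aliased columns are dropped
#' (and logged) before fitting, so R-squared is non-decreasing along the
#' nesting.
#'
#' @param y named phenotype vector.
#' @param pcScores matrix of the first principal-component scores
#'   (individuals x >= 3; the first three columns are used).
#' @param markerSets named list of coded marker matrices restricted to the
#'   significant columns per coding; must contain `"additive"` (possibly
#'   with zero columns); the remaining entries are treated as dominance
#'   codings.
#' @return data.frame `design`, `R2` (percent), `nMarkers`, plus attribute
#'   `dropped` naming aliased columns.
#' @export
varianceExplained <- function(y, pcScores, markerSets) {
  stopifnot("additive" %in% names(markerSets))
  PC <- as.matrix(pcScores)[, 1:3, drop = FALSE]
  colnames(PC) <- paste0("PC", 1:3)
  n <- length(y)
  dropped <- character(0)

  fitR2 <- function(Xlist, label) {
    X <- do.call(cbind, Xlist)
    if (ncol(X) >= n) stop("design for '", label, "' has p >= n; ",
                           "prune the marker sets")
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1) {
      keep <- q$pivot[seq_len(q$rank)]
      droppedCols <- colnames(cbind(`(Intercept)` = 1, X))[-keep]
      dropped <<- union(dropped, droppedCols)
      X <- cbind(1, X)[, keep, drop = FALSE][, -1, drop = FALSE]
    }
    summary(lm(y ~ X))$r.squared
  }

  addM <- as.matrix(markerSets$additive)
  out <- data.frame(design = "3 PCs only",
                    R2 = 100 * fitR2(list(PC), "PCs"),
                    nMarkers = 0, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(
    design = "3 PCs + Add markers",
    R2 = 100 * fitR2(list(PC, addM), "PCs+Add"),
    nMarkers = ncol(addM)))
  for (nm in setdiff(names(markerSets), "additive")) {
    dm <- as.matrix(markerSets[[nm]])
    out <- rbind(out, data.frame(
      design = paste0("3 PCs + Add + ", nm),
      R2 = 100 * fitR2(list(PC, addM, dm), nm),
      nMarkers = ncol(addM) + ncol(dm)))
  }
  attr(out, "dropped") <- dropped
  out
}
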