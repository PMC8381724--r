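#' Principal components of the dosage-based relationship matrix
#'
#' Eigendecomposition of the additive genomic relationship matrix; scores
#' are eigenvectors scaled by the square roots of their eigenvalues, so
#' inter-individual score distances reflect genomic relationships. The
#' first three components are the structure covariates used by the
#' variance-explained regressions.
#'
#' @param dosageMat complete [DosageMatrix-class] with at least two
#'   polymorphic markers.
#' @param nComp number of components to return (default 10).
#' @return list: `scores` (individuals x components), `explained`
#'   (non-increasing variance fractions), `values` (eigenvalues).
#' @export
dosagePCA <- function(dosageMat, nComp = 10) {
  vars <- apply(dosageMat@dosages, 2, var)
  if (sum(vars > 0, na.rm = TRUE) < 2)
    stop("need at least 2 polymorphic markers for PCA")
  GA <- additiveKinship(dosageMat)
  es <- eigen(GA@values, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  nComp <- min(nComp, sum(lam > 1e-12))
  scores <- es$vectors[, seq_len(nComp), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(nComp)]), nComp)
  rownames(scores) <- rownames(GA@values)
  colnames(scores) <- paste0("PC", seq_len(nComp))
  list(scores = scores, explained = lam[seq_len(nComp)] / sum(lam),
       values = lam)
}

# Weir-Cockerham-type theta for one pair of groups over all markers,
# haploid-count formulation with 4 allele draws per tetraploid individual;
# ratio-of-sums across markers.
.fstPair <- function(X1, X2) {
  n1 <- 4 * nrow(X1); n2 <- 4 * nrow(X2)
  p1 <- colMeans(X1) / 4; p2 <- colMeans(X2) / 4
  nTot <- n1 + n2
  nc <- (nTot - (n1^2 + n2^2) / nTot)      # r - 1 = 1 divisor folded in
  pbar <- (n1 * p1 + n2 * p2) / nTot
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2        # df = r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nTot - 2)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  poly <- pbar > 0 & pbar < 1
  sum(num[poly]) / sum(den[poly])
}

#' Pairwise F_ST between subpopulations
#'
#' Weir-Cockerham-type estimator on alternative-allele frequencies where
#' every tetraploid individual contributes four allele observations,
#' averaged over markers as a ratio of sums (numerators and denominators
#' summed separately, which is the standard low-bias aggregation). Groups
#' below the minimum size are excluded with a warning. Estimates are
#' clamped to \[0, 1\]; the raw value is kept alongside.
#'
#' @param dosageMat complete [DosageMatrix-class].
#' @param groups factor or character vector of group labels, one per
#'   individual.
#' @param minGroupSize smallest group retained (default 5).
#' @return data.frame `group1`, `group2`, `fst`, `fstRaw`, `n1`, `n2`.
#' @export
pairwiseFst <- function(dosageMat, groups, minGroupSize = 5) {
  X <- .completeDosages(dosageMat)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(X))
  sizes <- table(groups)
  small <- names(sizes)[sizes < minGroupSize]
  if (length(small))
    warning("group(s) below minimum size excluded: ",
            paste(small, collapse = ", "))
  keep <- setdiff(levels(groups), small)
  if (length(keep) < 2)
    stop("fewer than 2 groups meet the minimum size")
  pairs <- combn(keep, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    fst = NA_real_, fstRaw = NA_real_,
                    n1 = NA_integer_, n2 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    X1 <- X[groups == pairs[1, i], , drop = FALSE]
    X2 <- X[groups == pairs[2, i], , drop = FALSE]
    raw <- .fstPair(X1, X2)
    out$fstRaw[i] <- raw
    out$fst[i] <- min(max(raw, 0), 1)
    out$n1[i] <- nrow(X1); out$n2[i] <- nrow(X2)
  }
  out
}
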