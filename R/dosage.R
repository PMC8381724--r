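#' Dosage-class allele fractions under sequencing error
#'
#' For a tetraploid genotype with `k` copies of the alternative allele, the
#' expected fraction of alternative reads is `k/4` distorted by the
#' per-read error rate `e`: an alternative-allele read is observed either
#' from a true alternative copy read correctly or from a reference copy read
#' in error.
#'
#' @param e per-read sequencing error probability.
#' @return numeric length-5 vector: expected alt-read fraction for dosage
#'   classes 0..4.
#' @keywords internal
.classAltFraction <- function(e) {
  k <- 0:4
  (k / 4) * (1 - e) + (1 - k / 4) * e
}

.dosageClasses <- c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")

#' Posterior probabilities of the five tetraploid dosage classes
#'
#' Computes `P(dosage = k | ref, alt)` for `k = 0..4` from the binomial
#' likelihood of the alternative read count given the class allele fraction
#' adjusted for sequencing error, times a prior over classes. With no reads
#' the prior is returned unchanged.
#'
#' @param ref,alt reference and alternative allele read counts (scalars).
#' @param seqError per-read sequencing error probability (default 0.002).
#' @param prior prior over the five dosage classes; defaults to uniform.
#'   An alternative is a Hardy-Weinberg prior, `dbinom(0:4, 4, p)` for an
#'   assumed allele frequency `p`.
#' @return named numeric 5-vector over classes AAAA..BBBB, summing to 1.
#' @examples
#' round(genotypePosterior(15, 13), 2)  # concentrated on AABB
#' round(genotypePosterior(15, 0), 2)   # concentrated on AAAA
#' genotypePosterior(0, 0)              # no evidence: the prior
#' @export
genotypePosterior <- function(ref, alt, seqError = 0.002,
                              prior = rep(0.2, 5)) {
  stopifnot(length(ref) == 1L, length(alt) == 1L, ref >= 0, alt >= 0,
            seqError >= 0, seqError < 0.5, length(prior) == 5L,
            all(prior >= 0))
  prior <- prior / sum(prior)
  n <- ref + alt
  if (n == 0) return(setNames(prior, .dosageClasses))
  f <- .classAltFraction(seqError)
  # log-space for deep coverage
  ll <- dbinom(alt, n, f, log = TRUE)
  w <- log(prior) + ll
  w <- exp(w - max(w))
  setNames(w / sum(w), .dosageClasses)
}

#' Posterior probability array for a whole ReadCountSet
#'
#' Vectorised version of [genotypePosterior()]: returns an
#' individuals x markers x 5 array of class probabilities.
#'
#' @inheritParams callDosages
#' @return numeric array `c(n, m, 5)`.
#' @export
genotypePosteriorArray <- function(counts, seqError = 0.002,
                                   prior = rep(0.2, 5)) {
  stopifnot(is(counts, "ReadCountSet"))
  prior <- prior / sum(prior)
  refm <- counts@ref; altm <- counts@alt
  n <- refm + altm
  f <- .classAltFraction(seqError)
  ll <- array(NA_real_, c(nrow(refm), ncol(refm), 5))
  for (k in 1:5)
    ll[, , k] <- dbinom(altm, n, f[k], log = TRUE) + log(prior[k])
  mx <- pmax(ll[, , 1], ll[, , 2], ll[, , 3], ll[, , 4], ll[, , 5])
  w <- exp(ll - as.vector(mx))
  tot <- w[, , 1] + w[, , 2] + w[, , 3] + w[, , 4] + w[, , 5]
  w / as.vector(tot)
  # cells with zero depth get the prior: dbinom(0,0,f)=1 for all classes,
  # so the normalised weights equal the prior already.
}

#' Call allele dosages from read counts
#'
#' Each cell is assigned the dosage class with maximum posterior probability
#' provided that maximum reaches `probThreshold`; otherwise the cell is
#' missing. Posterior ties are broken toward the lower dosage class
#' (reference-allele conservative).
#'
#' @param counts a [ReadCountSet-class].
#' @param seqError per-read sequencing error probability.
#' @param probThreshold minimum posterior probability to accept a call,
#'   in (0, 1]. The stricter the threshold the more missingness.
#' @param prior prior over the five dosage classes (uniform default).
#' @return A [DosageMatrix-class] with `NA` where no class reached the
#'   threshold.
#' @examples
#' rc <- ReadCountSet(ref = matrix(c(15L, 15L), 1), alt = matrix(c(13L, 0L), 1))
#' dosages(callDosages(rc, probThreshold = 0.85))  # 2 and 0
#' @export
callDosages <- function(counts, seqError = 0.002, probThreshold = 0.85,
                        prior = rep(0.2, 5)) {
  stopifnot(probThreshold > 0, probThreshold <= 1)
  pp <- genotypePosteriorArray(counts, seqError, prior)
  n <- dim(pp)[1]; m <- dim(pp)[2]
  flat <- matrix(pp, n * m, 5)
  best <- max.col(flat, ties.method = "first") # first = lower dosage wins ties
  pmax <- flat[cbind(seq_len(n * m), best)]
  call <- ifelse(pmax >= probThreshold - 1e-12, best - 1L, NA_integer_)
  D <- matrix(call, n, m, dimnames = dimnames(counts@ref))
  DosageMatrix(D, counts@markerInfo)
}

#' Marker quality-control filter
#'
#' Applies the three marker-level filters in order: (1) per-marker mean read
#' depth inside `[depthMin, depthMax]`; (2) minor allele frequency (from the
#' called dosages of surviving markers) at least `mafMin`; (3) missing-call
#' fraction not exceeding `maxMissing` (markers missing in *more than* that
#' fraction of individuals are dropped). Upstream removal of multi-allelic
#' markers and repetitive-region markers is an alignment-level concern and is
#' outside this filter; the QC report notes this.
#'
#' @param counts the [ReadCountSet-class] the dosages were called from.
#' @param dosageMat the corresponding [DosageMatrix-class] (with missingness).
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param depthMin,depthMax accepted band of per-marker mean depth
#'   (defaults 10 and 100).
#' @param maxMissing maximum tolerated missing fraction per marker
#'   (default 0.25).
#' @return list with `dosages` (filtered [DosageMatrix-class]) and `report`,
#'   a list counting removals per rule in application order.
#' @export
filterMarkers <- function(counts, dosageMat, mafMin = 0.01,
                          depthMin = 10, depthMax = 100, maxMissing = 0.25) {
  stopifnot(is(counts, "ReadCountSet"), is(dosageMat, "DosageMatrix"),
            ncol(counts@ref) == ncol(dosageMat@dosages))
  m <- ncol(dosageMat@dosages)
  keep <- rep(TRUE, m)

  depth <- colMeans(counts@ref + counts@alt)
  failDepth <- depth < depthMin | depth > depthMax
  nDepth <- sum(failDepth)
  keep[failDepth] <- FALSE

  p <- colMeans(dosageMat@dosages, na.rm = TRUE) / 4
  maf <- pmin(p, 1 - p)
  failMaf <- keep & (is.na(maf) | maf < mafMin)
  nMaf <- sum(failMaf)
  keep[failMaf] <- FALSE

  missFrac <- colMeans(is.na(dosageMat@dosages))
  failMiss <- keep & missFrac > maxMissing
  nMiss <- sum(failMiss)
  keep[failMiss] <- FALSE

  if (!any(keep))
    stop("all markers removed by QC filters (depth=", nDepth,
         ", MAF=", nMaf, ", missingness=", nMiss, ")")
  report <- list(nInput = m,
                 removedDepth = nDepth,
                 removedMAF = nMaf,
                 removedMissing = nMiss,
                 nRetained = sum(keep),
                 params = list(mafMin = mafMin, depthMin = depthMin,
                               depthMax = depthMax, maxMissing = maxMissing),
                 note = paste("multi-allelic and repetitive-region marker",
                              "removal is assumed upstream (alignment level)"))
  list(dosages = dosageMat[, which(keep)], report = report)
}

#' Impute missing dosage calls
#'
#' Per-marker imputation of missing calls. `"mode"` (the default) fills with
#' the most frequent observed dosage at the marker, ties broken toward the
#' lower dosage; `"mean"` fills with the marker mean of the non-missing
#' calls, which leaves fractional values (a documented departure from the
#' integer dosage domain).
#'
#' @param dosageMat a [DosageMatrix-class] possibly containing `NA`.
#' @param method `"mode"` or `"mean"`.
#' @return A complete [DosageMatrix-class].
#' @export
imputeDosages <- function(dosageMat, method = c("mode", "mean")) {
  method <- match.arg(method)
  D <- dosageMat@dosages
  allMiss <- colSums(!is.na(D)) == 0
  if (any(allMiss))
    stop("marker(s) with no non-missing calls: ",
         paste(head(colnames(D)[allMiss]), collapse = ", "),
         " -- filter before imputing")
  for (j in which(colSums(is.na(D)) > 0)) {
    x <- D[, j]
    fill <- if (method == "mode") {
      tab <- tabulate(x[!is.na(x)] + 1L, nbins = 5L)
      which.max(tab) - 1L   # which.max takes the first max: lower dosage
    } else mean(x, na.rm = TRUE)
    D[is.na(x), j] <- fill
  }
  DosageMatrix(D, dosageMat@markerInfo)
}
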