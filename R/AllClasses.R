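#' Read-count container for tetraploid GBS genotyping
#'
#' Holds per-individual, per-marker reference and alternative allele read
#' depths, the raw evidence from genotyping-by-sequencing, together with
#' marker map information (chromosome, position).
#'
#' @slot ref integer matrix (individuals x markers) of reference-allele reads.
#' @slot alt integer matrix of the same shape with alternative-allele reads.
#' @slot markerInfo data.frame with one row per marker: `marker`, `chrom`,
#'   `pos` (1-based).
#'
#' @seealso [ReadCountSet()], [callDosages()], [simulateReadCounts()]
#' @export
setClass("ReadCountSet",
  slots = c(ref = "matrix", alt = "matrix", markerInfo = "data.frame"))

setValidity("ReadCountSet", function(object) {
  msg <- character()
  if (!all(dim(object@ref) == dim(object@alt)))
    msg <- c(msg, "ref and alt matrices must have identical dimensions")
  if (any(object@ref < 0, na.rm = TRUE) || any(object@alt < 0, na.rm = TRUE))
    msg <- c(msg, "read counts must be non-negative")
  if (nrow(object@markerInfo) != ncol(object@ref))
    msg <- c(msg, "markerInfo must have one row per marker column")
  if (!all(c("marker", "chrom", "pos") %in% names(object@markerInfo)))
    msg <- c(msg, "markerInfo needs columns marker, chrom, pos")
  if (length(msg)) msg else TRUE
})

#' Allele-dosage matrix for a tetraploid panel
#'
#' The central genotype object: counts of the alternative allele (0--4) per
#' individual and biallelic marker, possibly with missing entries before
#' imputation. Mean imputation can introduce fractional values; all other
#' paths keep dosages integer. Per-marker alternative-allele frequencies are
#' carried along because every relationship-matrix construction needs them.
#'
#' @slot dosages numeric matrix (individuals x markers) with values in
#'   \[0, 4\] or `NA`.
#' @slot alleleFreq numeric vector, alternative-allele frequency per marker,
#'   computed from the non-missing dosages.
#' @slot markerInfo data.frame with `marker`, `chrom`, `pos`.
#'
#' @seealso [DosageMatrix()], [additiveKinship()], [imputeDosages()]
#' @export
setClass("DosageMatrix",
  slots = c(dosages = "matrix", alleleFreq = "numeric",
            markerInfo = "data.frame"))

setValidity("DosageMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (any(d < 0 | d > 4, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 4]")
  if (length(object@alleleFreq) != ncol(d))
    msg <- c(msg, "alleleFreq must have one entry per marker")
  if (any(object@alleleFreq < 0 | object@alleleFreq > 1, na.rm = TRUE))
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  if (nrow(object@markerInfo) != ncol(d))
    msg <- c(msg, "markerInfo must have one row per marker")
  if (length(msg)) msg else TRUE
})

#' Genomic relationship matrix
#'
#' Symmetric individual-by-individual relationship matrix, tagged with the
#' gene-action flavour it encodes. Gaussian kernels additionally carry the
#' bandwidth used.
#'
#' @slot values symmetric numeric matrix with individual ids as dimnames.
#' @slot flavor one of `"additive"`, `"dominance_digenic"`,
#'   `"epistatic_AxA"`, `"full_tetraploid"`, `"rkhs"`.
#' @slot theta Gaussian-kernel bandwidth (`NA` except for rkhs).
#' @slot nMarkers number of markers the matrix was built from.
#'
#' @export
setClass("KinshipMatrix",
  slots = c(values = "matrix", flavor = "character", theta = "numeric",
            nMarkers = "integer"))

.kinshipFlavors <- c("additive", "dominance_digenic", "epistatic_AxA",
                     "full_tetraploid", "rkhs")

setValidity("KinshipMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else if (max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "matrix must be symmetric within 1e-10")
  if (!object@flavor %in% .kinshipFlavors)
    msg <- c(msg, paste("flavor must be one of:",
                        paste(.kinshipFlavors, collapse = ", ")))
  if (object@flavor == "rkhs") {
    if (!is.finite(object@theta) || object@theta <= 0)
      msg <- c(msg, "rkhs kernel requires theta > 0")
    if (max(abs(diag(v) - 1)) > 1e-8)
      msg <- c(msg, "rkhs kernel diagonal must be exactly 1")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted genomic-prediction model
#'
#' Posterior (Gibbs) or REML/ML summaries of one of the eight prediction
#' models: overall mean, variance components, genotypic values per
#' individual, and -- for marker-effect models -- posterior means of marker
#' effects and any model-specific parameters (pi for BayesC-pi, lambda for
#' the Bayesian LASSO, theta for RKHS).
#'
#' @slot model tag: `"Add"`, `"A+D"`, `"A+D+Ep"`, `"FT"`, `"RKHS"`,
#'   `"BayesA"`, `"BayesCpi"`, `"BayesL"`.
#' @slot mu posterior mean (or GLS estimate) of the intercept.
#' @slot varComp named numeric vector of variance components.
#' @slot gebv named numeric vector of predicted genotypic values.
#' @slot gebvSD posterior SDs of the genotypic values (NA for ML fits).
#' @slot markerEffects posterior-mean marker effects (length 0 for kernel
#'   models).
#' @slot details list of extras: `pi`, `lambda`, `theta`, effective sample
#'   sizes, fitting engine, iteration counts.
#'
#' @export
setClass("GPFit",
  slots = c(model = "character", mu = "numeric", varComp = "numeric",
            gebv = "numeric", gebvSD = "numeric", markerEffects = "numeric",
            details = "list"))

setValidity("GPFit", function(object) {
  msg <- character()
  if (any(object@varComp < -1e-8, na.rm = TRUE))
    msg <- c(msg, "variance components must be non-negative")
  pi <- object@details$pi
  if (!is.null(pi) && (pi < 0 || pi > 1))
    msg <- c(msg, "pi must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Association-scan result under one gene-action coding
#'
#' Per-marker effect estimates, standard errors and -log10 p-values from a
#' mixed-model scan, together with the significance threshold used.
#'
#' @slot results data.frame: `marker`, `chrom`, `pos`, `beta`, `se`,
#'   `score` (-log10 p), `significant`.
#' @slot coding gene-action coding of the scan.
#' @slot threshold -log10 p significance threshold.
#' @slot meff effective number of tests behind the threshold.
#'
#' @export
setClass("GWASScan",
  slots = c(results = "data.frame", coding = "character",
            threshold = "numeric", meff = "numeric"))

setValidity("GWASScan", function(object) {
  msg <- character()
  r <- object@results
  need <- c("marker", "chrom", "pos", "beta", "se", "score", "significant")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("results needs columns:", paste(need, collapse = ", ")))
  else {
    if (any(r$score < 0, na.rm = TRUE))
      msg <- c(msg, "scores (-log10 p) must be non-negative")
    bad <- which(!is.na(r$score) & (r$score >= object@threshold) != r$significant)
    if (length(bad))
      msg <- c(msg, "significant flag inconsistent with score >= threshold")
  }
  if (length(msg)) msg else TRUE
})
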