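#' Accessors for tetragp data classes
#'
#' @param x a tetragp S4 object.
#' @param ... unused.
#' @return The requested component: `dosages()` the numeric dosage matrix,
#'   `alleleFreq()` per-marker alternative-allele frequencies, `markerInfo()`
#'   the marker map, `refCounts()`/`altCounts()` read-depth matrices,
#'   `kinship()` the relationship matrix values, `flavor()` its gene-action
#'   tag, `gebv()` predicted genotypic values, `varComp()` variance
#'   components, `scanResults()` the per-marker association table.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x, ...) standardGeneric("alleleFreq"))
#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x, ...) standardGeneric("markerInfo"))
#' @rdname accessors
#' @export
setGeneric("refCounts", function(x, ...) standardGeneric("refCounts"))
#' @rdname accessors
#' @export
setGeneric("altCounts", function(x, ...) standardGeneric("altCounts"))
#' @rdname accessors
#' @export
setGeneric("kinship", function(x, ...) standardGeneric("kinship"))
#' @rdname accessors
#' @export
setGeneric("flavor", function(x, ...) standardGeneric("flavor"))
#' @rdname accessors
#' @export
setGeneric("gebv", function(x, ...) standardGeneric("gebv"))
#' @rdname accessors
#' @export
setGeneric("varComp", function(x, ...) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setGeneric("scanResults", function(x, ...) standardGeneric("scanResults"))

#' @rdname accessors
#' @export
setMethod("dosages", "DosageMatrix", function(x, ...) x@dosages)
#' @rdname accessors
#' @export
setMethod("alleleFreq", "DosageMatrix", function(x, ...) x@alleleFreq)
#' @rdname accessors
#' @export
setMethod("markerInfo", "DosageMatrix", function(x, ...) x@markerInfo)
#' @rdname accessors
#' @export
setMethod("markerInfo", "ReadCountSet", function(x, ...) x@markerInfo)
#' @rdname accessors
#' @export
setMethod("refCounts", "ReadCountSet", function(x, ...) x@ref)
#' @rdname accessors
#' @export
setMethod("altCounts", "ReadCountSet", function(x, ...) x@alt)
#' @rdname accessors
#' @export
setMethod("kinship", "KinshipMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("flavor", "KinshipMatrix", function(x, ...) x@flavor)
#' @rdname accessors
#' @export
setMethod("gebv", "GPFit", function(x, ...) x@gebv)
#' @rdname accessors
#' @export
setMethod("varComp", "GPFit", function(x, ...) x@varComp)
#' @rdname accessors
#' @export
setMethod("scanResults", "GWASScan", function(x, ...) x@results)

#' @rdname accessors
#' @export
setMethod("dim", "DosageMatrix", function(x) dim(x@dosages))
#' @rdname accessors
#' @export
setMethod("dim", "ReadCountSet", function(x) dim(x@ref))

#' Coerce to an ordinary matrix
#'
#' @param x a `DosageMatrix` or `KinshipMatrix`.
#' @param ... unused.
#' @export
setMethod("as.matrix", "DosageMatrix", function(x, ...) x@dosages)
#' @rdname as.matrix-DosageMatrix-method
#' @export
setMethod("as.matrix", "KinshipMatrix", function(x, ...) x@values)

#' Subset individuals and markers
#'
#' `x[i, j]` subsets individuals (rows) and markers (columns). Allele
#' frequencies of a `DosageMatrix` are recomputed from the retained
#' individuals.
#'
#' @param x a `ReadCountSet` or `DosageMatrix`.
#' @param i,j individual and marker indices.
#' @param drop ignored; objects never drop dimensions.
#' @export
setMethod("[", "ReadCountSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@ref))
  if (missing(j)) j <- seq_len(ncol(x@ref))
  ReadCountSet(x@ref[i, j, drop = FALSE], x@alt[i, j, drop = FALSE],
               x@markerInfo[j, , drop = FALSE])
})

#' @rdname sub-ReadCountSet-ANY-ANY-ANY-method
#' @export
setMethod("[", "DosageMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  DosageMatrix(x@dosages[i, j, drop = FALSE], x@markerInfo[j, , drop = FALSE])
})

setMethod("show", "ReadCountSet", function(object) {
  cat("ReadCountSet:", nrow(object@ref), "individuals x",
      ncol(object@ref), "markers\n")
  dp <- object@ref + object@alt
  cat("  mean depth:", round(mean(dp), 1),
      " range:", paste(range(dp), collapse = "-"), "\n")
})

setMethod("show", "DosageMatrix", function(object) {
  d <- object@dosages
  nmiss <- sum(is.na(d))
  cat("DosageMatrix:", nrow(d), "individuals x", ncol(d), "markers\n")
  cat("  missing:", sprintf("%.2f%%", 100 * nmiss / length(d)),
      " mean alt-allele freq:", round(mean(object@alleleFreq, na.rm = TRUE), 3),
      "\n")
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix (", object@flavor, "): ",
      nrow(object@values), " x ", ncol(object@values),
      ", from ", object@nMarkers, " markers\n", sep = "")
  if (object@flavor == "rkhs") cat("  theta:", object@theta, "\n")
  cat("  mean diagonal:", round(mean(diag(object@values)), 3), "\n")
})

setMethod("show", "GPFit", function(object) {
  cat("GPFit [", object@model, "] fitted by ",
      object@details$engine %||% "gibbs", "\n", sep = "")
  cat("  mu:", signif(object@mu, 4), "\n  variance components:\n")
  print(signif(object@varComp, 4))
})

setMethod("show", "GWASScan", function(object) {
  cat("GWASScan (", object@coding, " coding): ", nrow(object@results),
      " markers\n", sep = "")
  cat("  threshold -log10 p:", round(object@threshold, 2),
      " (Meff =", round(object@meff, 1), ")\n")
  cat("  significant markers:", sum(object@results$significant, na.rm = TRUE),
      "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
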