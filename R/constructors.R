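.defaultMarkerInfo <- function(m, names = NULL) {
  if (is.null(names)) names <- sprintf("M%05d", seq_len(m))
  data.frame(marker = names, chrom = rep(1L, m), pos = seq_len(m),
             stringsAsFactors = FALSE)
}

.defaultIds <- function(n) sprintf("Ind%04d", seq_len(n))

#' Construct a ReadCountSet
#'
#' @param ref,alt integer matrices (individuals x markers) of reference- and
#'   alternative-allele read depths. Dimnames, when present, name individuals
#'   (rows) and markers (columns).
#' @param markerInfo optional data.frame with `marker`, `chrom`, `pos`;
#'   defaults to a single-chromosome map in column order.
#' @return A [ReadCountSet-class] object.
#' @examples
#' rc <- ReadCountSet(ref = matrix(10, 2, 3), alt = matrix(5, 2, 3))
#' dim(rc)
#' @export
ReadCountSet <- function(ref, alt, markerInfo = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(rownames(ref))) rownames(ref) <- .defaultIds(nrow(ref))
  if (is.null(markerInfo))
    markerInfo <- .defaultMarkerInfo(ncol(ref), colnames(ref))
  if (is.null(colnames(ref))) colnames(ref) <- markerInfo$marker
  dimnames(alt) <- dimnames(ref)
  new("ReadCountSet", ref = ref, alt = alt, markerInfo = markerInfo)
}

#' Construct a DosageMatrix
#'
#' Allele frequencies are recomputed from the non-missing dosages
#' (column mean / 4), so the object is always internally consistent.
#'
#' @param dosages numeric matrix (individuals x markers), entries in
#'   \[0, 4\] or `NA`.
#' @param markerInfo optional marker map (`marker`, `chrom`, `pos`).
#' @return A [DosageMatrix-class] object.
#' @examples
#' X <- DosageMatrix(matrix(c(0, 2, 4, 1, NA, 3), 3, 2))
#' alleleFreq(X)
#' @export
DosageMatrix <- function(dosages, markerInfo = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) rownames(dosages) <- .defaultIds(nrow(dosages))
  if (is.null(markerInfo))
    markerInfo <- .defaultMarkerInfo(ncol(dosages), colnames(dosages))
  if (is.null(colnames(dosages))) colnames(dosages) <- markerInfo$marker
  p <- colMeans(dosages, na.rm = TRUE) / 4
  p[!is.finite(p)] <- NA_real_
  new("DosageMatrix", dosages = dosages, alleleFreq = unname(p),
      markerInfo = markerInfo)
}

.newKinship <- function(values, flavor, nMarkers, theta = NA_real_,
                        ids = NULL) {
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  values <- (values + t(values)) / 2   # kill numerical asymmetry
  new("KinshipMatrix", values = values, flavor = flavor,
      theta = theta, nMarkers = as.integer(nMarkers))
}
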