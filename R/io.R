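#' Read allele depths from a VCF into a ReadCountSet
#'
#' Extracts the per-sample `AD` field (ref,alt depths) of biallelic sites.
#' Sites without an AD entry or with more than one alternative allele are
#' dropped with a message.
#'
#' @param file path to a VCF (plain or bgzipped).
#' @return A [ReadCountSet-class] (individuals = VCF samples).
#' @export
readVCFCounts <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  if (!all(biallelic)) {
    message("dropping ", sum(!biallelic), " non-biallelic site(s)")
    v <- v[biallelic, ]
    fix <- vcfR::getFIX(v)
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD (allele depth) field")
  refC <- vcfR::masplit(ad, record = 1, sort = FALSE)
  altC <- vcfR::masplit(ad, record = 2, sort = FALSE)
  refC[is.na(refC)] <- 0; altC[is.na(altC)] <- 0
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], "_", fix[noId, "POS"])
  mi <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  ReadCountSet(t(refC), t(altC), mi)
}

#' Write a ReadCountSet as a minimal VCF with AD field
#'
#' Plain-text VCFv4.2 with synthetic REF/ALT alleles and per-sample
#' `AD` values; ploidy-4 GT calls are deliberately omitted (dosage calling
#' is the job of [callDosages()]).
#'
#' @param counts a [ReadCountSet-class].
#' @param file output path.
#' @export
writeCountsVCF <- function(counts, file) {
  mi <- counts@markerInfo
  ids <- rownames(counts@ref)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tetragp",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(mi)), function(j) {
    ad <- paste(counts@ref[, j], counts@alt[, j], sep = ",")
    paste(c(mi$chrom[j], mi$pos[j], mi$marker[j], "A", "T", ".", "PASS",
            ".", "AD", ad), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), file)
}

#' Dosage matrix TSV round trip
#'
#' Individuals x markers table with row ids in the first column; missing
#' calls as NA.
#'
#' @param dosageMat a [DosageMatrix-class].
#' @param file path.
#' @export
writeDosageTSV <- function(dosageMat, file) {
  df <- data.frame(id = rownames(dosageMat@dosages),
                   dosageMat@dosages, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeDosageTSV
#' @export
readDosageTSV <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  DosageMatrix(M)
}

#' Kinship matrix TSV round trip
#'
#' @param K a [KinshipMatrix-class].
#' @param file path.
#' @export
writeKinshipTSV <- function(K, file) {
  df <- data.frame(id = rownames(K@values), K@values, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Tidy plot-level phenotype TSV round trip
#'
#' Columns: trial, location, year, block, row, col, genotype, trait, value.
#'
#' @param plots plot table as produced by [simulatePhenotypes()].
#' @param file path.
#' @export
writePhenoTSV <- function(plots, file) {
  write.table(plots, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writePhenoTSV
#' @export
readPhenoTSV <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulatePhenotypes()].
#' @param file path.
#' @export
writeTruthJSON <- function(truth, file) {
  jsonlite::write_json(truth, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
}
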