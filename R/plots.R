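#' Manhattan plot of an association scan
#'
#' @param scan a [GWASScan-class].
#' @param ... passed to `plot`.
#' @export
plotManhattan <- function(scan, ...) {
  r <- scan@results
  chrF <- factor(r$chrom)
  xpos <- seq_len(nrow(r))
  plot(xpos, r$score, pch = 20, cex = 0.6,
       col = c("grey30", "steelblue")[1 + as.integer(chrF) %% 2],
       xlab = "marker index (grouped by chromosome)",
       ylab = expression(-log[10](p)),
       main = paste("Scan under", scan@coding, "coding"), ...)
  abline(h = scan@threshold, col = "red")
  invisible(NULL)
}

#' QQ plot of scan p-values with genomic-control lambda
#'
#' @param scan a [GWASScan-class].
#' @export
plotQQ <- function(scan) {
  s <- sort(scan@results$score[!is.na(scan@results$score)],
            decreasing = TRUE)
  n <- length(s)
  expd <- -log10((seq_len(n) - 0.5) / n)
  lim <- range(c(s, expd))
  plot(expd, s, pch = 20, cex = 0.6, xlim = lim, ylim = lim,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = sprintf("QQ (%s), lambda_GC = %.2f", scan@coding,
                      attr(scan@results, "lambdaGC")))
  abline(0, 1, col = "red")
  invisible(NULL)
}
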