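#' Cross-validation scheme
#'
#' @param nTrain training-set size (default 105, against a 42-strong
#'   validation set in a 147-individual panel).
#' @param nReps number of repetitions (default 100).
#' @param selector `"cdmean"` (optimised training set) or `"random"`.
#' @param seed base RNG seed; repetition r uses `seed + r`.
#' @param lambdaRatio residual-to-genetic variance ratio used inside the CD
#'   computation; `NULL` means estimate it once from an additive GBLUP on
#'   all data as `(1 - h2) / h2`.
#' @return list of class `"CVScheme"`.
#' @export
cvScheme <- function(nTrain = 105, nReps = 100,
                     selector = c("cdmean", "random"), seed = 1,
                     lambdaRatio = NULL) {
  selector <- match.arg(selector)
  stopifnot(nTrain >= 2, nReps >= 1,
            is.null(lambdaRatio) || lambdaRatio > 0)
  structure(list(nTrain = as.integer(nTrain), nReps = as.integer(nReps),
                 selector = selector, seed = as.integer(seed),
                 lambdaRatio = lambdaRatio),
            class = "CVScheme")
}

#' Mean coefficient of determination of a candidate training set
#'
#' CD of the genotypic value (or of its contrast with the population mean)
#' of each non-training individual, predicted from the training phenotypes
#' under a one-kernel mixed model with variance ratio `lambda`:
#' the prediction error variance follows from the conditional distribution
#' of the validation genotypic values given training phenotypes.
#' @keywords internal
.cdMean <- function(G, trainIdx, lambda, contrasts = TRUE) {
  n <- nrow(G)
  valIdx <- setdiff(seq_len(n), trainIdx)
  Gtt <- G[trainIdx, trainIdx, drop = FALSE]
  A <- tryCatch(solve(Gtt + diag(lambda, length(trainIdx))),
                error = function(e) {
                  warning("singular training block; adding jitter")
                  solve(Gtt + diag(lambda + 1e-6, length(trainIdx)))
                })
  if (!contrasts) {
    B <- G[valIdx, trainIdx, drop = FALSE] %*% A
    cd <- rowSums(B * G[valIdx, trainIdx, drop = FALSE]) / diag(G)[valIdx]
    return(mean(cd))
  }
  # contrasts with the population mean: c_i = e_i - 1/n
  H <- G[, trainIdx, drop = FALSE] %*% A %*% G[trainIdx, , drop = FALSE]
  cG <- .contrastQuad(G, valIdx)
  cH <- .contrastQuad(H, valIdx)
  mean(cH / cG)
}

# c_i' M c_i for c_i = e_i - 1/n, all i in idx at once
.contrastQuad <- function(M, idx) {
  n <- nrow(M)
  rm_ <- rowMeans(M)
  mm <- mean(M)
  diag(M)[idx] - 2 * rm_[idx] + mm
}

#' CDmean training-set selection by exchange
#'
#' Starting from a random training set of size `nTrain`, repeatedly swaps
#' one member against one non-member while a swap increases the mean CD of
#' the validation individuals, until a full sweep over all swap pairs yields
#' no improvement (or `maxPasses` sweeps). Only improving swaps are
#' accepted, so the final criterion is never below the starting one. The
#' criterion landscape has non-global local optima on small panels, so the
#' exchange is restarted `nStarts` times from independent random sets and
#' the best result is kept.
#'
#' Two sweep strategies are available: `"steepest"` (default) evaluates all
#' swaps and takes the best improving one per sweep, which finds the global
#' optimum far more reliably; `"first"` accepts the first improving swap,
#' which is faster on large panels and is used inside repeated
#' cross-validation.
#'
#' @param G a [KinshipMatrix-class] (or plain PSD matrix) over all
#'   candidates.
#' @param nTrain training-set size.
#' @param lambdaRatio residual/genetic variance ratio inside the CD.
#' @param seed RNG seed for the random starts and sweep order.
#' @param contrasts optimise the CD of contrasts with the population mean
#'   (default) or of plain genotypic values.
#' @param maxPasses sweep cap per start (default 200).
#' @param nStarts independent random restarts (default 5).
#' @param method sweep strategy, `"steepest"` or `"first"`.
#' @return list: `train` (ids), `cdmean`, `cdmeanStart` (criterion of the
#'   winning start's initial set), `nPasses`.
#' @export
cdmeanSelect <- function(G, nTrain, lambdaRatio = 1, seed = 1,
                         contrasts = TRUE, maxPasses = 200, nStarts = 5,
                         method = c("steepest", "first")) {
  method <- match.arg(method)
  M <- if (is(G, "KinshipMatrix")) G@values else as.matrix(G)
  n <- nrow(M)
  stopifnot(nTrain >= 1, nTrain < n, lambdaRatio > 0, nStarts >= 1)
  ids <- rownames(M); if (is.null(ids)) ids <- as.character(seq_len(n))
  set.seed(seed)

  oneStart <- function() {
    train <- sort(sample.int(n, nTrain))
    cd <- .cdMean(M, train, lambdaRatio, contrasts)
    cdStart <- cd
    passes <- 0
    repeat {
      passes <- passes + 1
      improved <- FALSE
      if (method == "steepest") {
        bestCd <- cd; bestSet <- NULL
        for (i in train) for (j in setdiff(seq_len(n), train)) {
          cand <- sort(c(setdiff(train, i), j))
          cdNew <- .cdMean(M, cand, lambdaRatio, contrasts)
          if (cdNew > bestCd + 1e-12) { bestCd <- cdNew; bestSet <- cand }
        }
        if (!is.null(bestSet)) {
          train <- bestSet; cd <- bestCd; improved <- TRUE
        }
      } else {
        for (i in sample(train)) {
          for (j in sample(setdiff(seq_len(n), train))) {
            cand <- sort(c(setdiff(train, i), j))
            cdNew <- .cdMean(M, cand, lambdaRatio, contrasts)
            if (cdNew > cd + 1e-12) {
              train <- cand; cd <- cdNew; improved <- TRUE
              break
            }
          }
          if (improved) break
        }
      }
      if (!improved || passes >= maxPasses) break
    }
    list(train = train, cdmean = cd, cdmeanStart = cdStart,
         nPasses = passes)
  }

  best <- NULL
  for (s in seq_len(nStarts)) {
    res <- oneStart()
    if (is.null(best) || res$cdmean > best$cdmean) best <- res
  }
  list(train = ids[best$train], cdmean = best$cdmean,
       cdmeanStart = best$cdmeanStart, nPasses = best$nPasses)
}

#' Pearson prediction accuracy
#'
#' The Pearson correlation between observed adjusted means and predicted
#' genotypic values.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3 pairs).
#' @return correlation in \[-1, 1\].
#' @export
predictiveAccuracy <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(observed[ok]) == 0 || sd(predicted[ok]) == 0)
    stop("zero variance: accuracy undefined")
  cor(observed[ok], predicted[ok])
}

.fitModelForCV <- function(yMask, dosageMat, model, kernels, config, engine,
                           thetaGrid) {
  if (model %in% c("BayesA", "BayesCpi", "BayesL"))
    fitBayesMarker(yMask, dosageMat, model, config)
  else if (model == "RKHS")
    fitRKHS(yMask, dosageMat, thetaGrid)
  else
    fitGBLUP(yMask, kernels[[model]], config, engine = engine)
}

#' Repeated hold-out cross-validation of a prediction model
#'
#' Per repetition: choose a training set (CDmean-optimised or random), mask
#' the validation phenotypes, fit the model on the training phenotypes only
#' (relationship matrices and allele frequencies use all genotyped
#' individuals, which involves no phenotype information), predict the
#' validation individuals and score the Pearson accuracy. Failed repetitions
#' are recorded and excluded from the aggregate.
#'
#' @param y named phenotype vector (complete).
#' @param dosageMat complete [DosageMatrix-class] over the same individuals.
#' @param model one of `"Add"`, `"A+D"`, `"A+D+Ep"`, `"FT"`, `"RKHS"`,
#'   `"BayesA"`, `"BayesCpi"`, `"BayesL"`.
#' @param scheme a [cvScheme()].
#' @param config [gibbsConfig()] for the Bayesian fits.
#' @param engine engine for the kernel models (`"reml"` is the fast default
#'   inside CV; `"gibbs"` matches the full-data fitting configuration).
#' @param thetaGrid bandwidth grid for RKHS.
#' @return list of class `"CVResult"`: `accuracy` (per rep), `mean`, `se`
#'   (SD/sqrt(reps)), `trainIds`, `nFailed`, `model`, `scheme`.
#' @export
runCV <- function(y, dosageMat, model = "Add", scheme = cvScheme(),
                  config = gibbsConfig(), engine = c("reml", "gibbs"),
                  thetaGrid = c(0.1, 0.25, 0.5, 1, 2, 5)) {
  engine <- match.arg(engine)
  stopifnot(is(dosageMat, "DosageMatrix"), !anyNA(y))
  ids <- rownames(dosageMat@dosages)
  if (is.null(names(y))) names(y) <- ids
  stopifnot(all(names(y) %in% ids), scheme$nTrain < length(y))

  kernels <- list()
  GA <- additiveKinship(dosageMat)
  if (model %in% c("Add", "A+D", "A+D+Ep"))
    kernels$Add <- list(GA)
  if (model %in% c("A+D", "A+D+Ep")) {
    GD <- dominanceKinship(dosageMat)
    kernels$`A+D` <- list(GA, GD)
    if (model == "A+D+Ep")
      kernels$`A+D+Ep` <- list(GA, GD, epistasisKinship(GA))
  }
  if (model == "FT") kernels$FT <- list(fullTetraploidKinship(dosageMat))

  lambdaRatio <- scheme$lambdaRatio
  if (is.null(lambdaRatio) && scheme$selector == "cdmean") {
    f0 <- fitGBLUP(y, GA, engine = "reml")
    h2 <- f0@varComp[1] / sum(f0@varComp)
    h2 <- min(max(h2, 0.05), 0.95)
    lambdaRatio <- (1 - h2) / h2
  }

  acc <- rep(NA_real_, scheme$nReps)
  trainIds <- vector("list", scheme$nReps)
  nFailed <- 0
  for (r in seq_len(scheme$nReps)) {
    repSeed <- scheme$seed + r
    train <- if (scheme$selector == "cdmean")
      cdmeanSelect(GA, scheme$nTrain, lambdaRatio, seed = repSeed,
                   maxPasses = 30, nStarts = 1, method = "first")$train
    else {
      set.seed(repSeed)
      sample(names(y), scheme$nTrain)
    }
    trainIds[[r]] <- train
    val <- setdiff(names(y), train)
    yMask <- y
    yMask[val] <- NA
    cfg <- config; cfg$seed <- config$seed + r
    fit <- tryCatch(
      .fitModelForCV(yMask, dosageMat, model, kernels, cfg, engine,
                     thetaGrid),
      error = function(e) e)
    if (inherits(fit, "error")) { nFailed <- nFailed + 1; next }
    acc[r] <- tryCatch(predictiveAccuracy(y[val], gebv(fit)[val]),
                       error = function(e) { NA_real_ })
    if (is.na(acc[r])) nFailed <- nFailed + 1
  }
  ok <- !is.na(acc)
  structure(list(accuracy = acc, mean = mean(acc[ok]),
                 se = sd(acc[ok]) / sqrt(sum(ok)),
                 trainIds = trainIds, nFailed = nFailed,
                 model = model, scheme = scheme),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat("Cross-validation of", x$model, "model:",
      sum(!is.na(x$accuracy)), "of", length(x$accuracy), "repetitions\n")
  cat(sprintf("  mean accuracy %.3f (SE %.3f), selector = %s, nTrain = %d\n",
              x$mean, x$se, x$scheme$selector, x$scheme$nTrain))
  invisible(x)
}
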