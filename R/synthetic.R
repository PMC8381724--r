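#' Simulation configuration for a synthetic tetraploid panel
#'
#' Bundles everything the population generator needs. Defaults emulate a
#' diversity panel of 147 tetraploid cultivars with weak market-class
#' structure, GBS read depths spanning the accepted 10--100 band, and a
#' 12-chromosome genome.
#'
#' @param nIndividuals number of tetraploid individuals (default 147).
#' @param nMarkers number of biallelic markers.
#' @param nChromosomes chromosomes the markers are spread over (default 12).
#' @param alleleFreqRange range the ancestral alternative-allele frequency is
#'   drawn from, inside (0, 1).
#' @param nSubpops number of subpopulations (default 4, after the four major
#'   market classes).
#' @param structureStrength drift parameter F of the Balding-Nichols
#'   F-model; 0 means no structure. Default 0.01, giving pairwise
#'   differentiation of the order seen between potato market classes
#'   (F_ST around 0.01--0.03).
#' @param depthRange integer read-depth interval, within \[1, 10000\].
#' @param seqError per-read sequencing error probability, in \[0, 0.5).
#' @param seed integer RNG seed.
#' @return list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nIndividuals = 147, nMarkers = 2000,
                             nChromosomes = 12,
                             alleleFreqRange = c(0.05, 0.95),
                             nSubpops = 4, structureStrength = 0.01,
                             depthRange = c(10, 100), seqError = 0.002,
                             seed = 1) {
  stopifnot(nIndividuals >= 1, nMarkers >= 1, nChromosomes >= 1,
            length(alleleFreqRange) == 2,
            alleleFreqRange[1] > 0, alleleFreqRange[2] < 1,
            alleleFreqRange[1] <= alleleFreqRange[2],
            nSubpops >= 1, structureStrength >= 0,
            length(depthRange) == 2, depthRange[1] >= 1,
            depthRange[2] <= 10000, depthRange[1] <= depthRange[2],
            seqError >= 0, seqError < 0.5)
  if (nSubpops > nIndividuals)
    stop("invalid config: nSubpops exceeds nIndividuals")
  structure(list(nIndividuals = nIndividuals, nMarkers = nMarkers,
                 nChromosomes = nChromosomes,
                 alleleFreqRange = alleleFreqRange, nSubpops = nSubpops,
                 structureStrength = structureStrength,
                 depthRange = depthRange, seqError = seqError,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Genetic architecture of a simulated trait
#'
#' Variance components are targets for the realised variances of the
#' corresponding genetic-value components across the simulated panel, in
#' squared trait units. Dominance components use centred gene-action
#' codings (simplex: effect switched on by >= 1 copy of the alternative
#' allele; duplex: by >= 2 copies), so targets are directly interpretable.
#'
#' @param varAdditive,varDominance,varDuplexDominance,varEpistaticAxA target
#'   variances of the additive, simplex-dominance, duplex-dominance and
#'   additive-by-additive genetic components.
#' @param varGxL,varGxT genotype-by-location and genotype-by-year
#'   interaction variances.
#' @param varResidual plot-level residual variance.
#' @param nQtlAdditive,nQtlDominance numbers of causal loci per component.
#' @param architecture `"polygenic"` (many small effects; QTL counts used as
#'   given) or `"oligogenic"` (few loci; QTL counts capped at 10).
#' @return list of class `"TraitSpec"`.
#' @export
traitSpec <- function(varAdditive = 1, varDominance = 0,
                      varDuplexDominance = 0, varEpistaticAxA = 0,
                      varGxL = 0, varGxT = 0, varResidual = 1,
                      nQtlAdditive = 200, nQtlDominance = 50,
                      architecture = c("polygenic", "oligogenic")) {
  architecture <- match.arg(architecture)
  v <- c(varAdditive, varDominance, varDuplexDominance, varEpistaticAxA,
         varGxL, varGxT, varResidual)
  stopifnot(all(is.finite(v)), all(v >= 0))
  if (varAdditive + varDominance + varDuplexDominance + varEpistaticAxA <= 0)
    warning("no genetic variance: the trait is not heritable")
  if (architecture == "oligogenic") {
    nQtlAdditive <- min(nQtlAdditive, 10L)
    nQtlDominance <- min(nQtlDominance, 10L)
  }
  structure(list(varAdditive = varAdditive, varDominance = varDominance,
                 varDuplexDominance = varDuplexDominance,
                 varEpistaticAxA = varEpistaticAxA, varGxL = varGxL,
                 varGxT = varGxT, varResidual = varResidual,
                 nQtlAdditive = nQtlAdditive, nQtlDominance = nQtlDominance,
                 architecture = architecture),
            class = "TraitSpec")
}

#' Field-trial layout for the phenotype simulator
#'
#' A multi-environment series of row-column trials: one trial per
#' location-year combination, each with `nBlocks` complete blocks laid out
#' as a `rows` x `cols` grid, one plot per genotype per block. Defaults
#' mirror a two-block resolvable row-column design over three locations and
#' two years.
#'
#' @param nLocations,nYears numbers of locations and years.
#' @param nBlocks complete blocks per trial.
#' @param rows,cols grid dimensions of one block; `rows * cols` must be at
#'   least the number of genotypes.
#' @param varBlock,varRow,varCol,varPlot variances of block, row-in-block,
#'   column-in-block and plot-residual effects.
#' @return list of class `"FieldLayoutSpec"`.
#' @export
fieldLayoutSpec <- function(nLocations = 3, nYears = 2, nBlocks = 2,
                            rows = 15, cols = 10,
                            varBlock = 0.25, varRow = 0.25, varCol = 0.25,
                            varPlot = 1) {
  stopifnot(nLocations >= 1, nYears >= 1, nBlocks >= 1, rows >= 1, cols >= 1,
            varBlock >= 0, varRow >= 0, varCol >= 0, varPlot >= 0)
  structure(list(nLocations = nLocations, nYears = nYears, nBlocks = nBlocks,
                 rows = rows, cols = cols, varBlock = varBlock,
                 varRow = varRow, varCol = varCol, varPlot = varPlot),
            class = "FieldLayoutSpec")
}

#' Simulate tetraploid dosages under an F-model of population structure
#'
#' Draws ancestral allele frequencies uniformly over the configured range,
#' drifts them independently into each subpopulation with a Balding-Nichols
#' Beta distribution of strength `structureStrength`, and samples each
#' individual's dosage as Binomial(4, p) at its subpopulation frequency
#' (tetrasomic Hardy-Weinberg within subpopulation). Markers are grouped by
#' chromosome in map order.
#'
#' @param config a [simulationConfig()].
#' @return list with `dosages` (a complete [DosageMatrix-class]), `subpop`
#'   (factor of subpopulation labels) and `ancestralFreq`.
#' @examples
#' sim <- simulateDosages(simulationConfig(nIndividuals = 20, nMarkers = 50))
#' dim(sim$dosages)
#' @export
simulateDosages <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nIndividuals; m <- config$nMarkers
  Fst <- config$structureStrength
  pAnc <- runif(m, config$alleleFreqRange[1], config$alleleFreqRange[2])
  subpop <- factor(rep_len(seq_len(config$nSubpops), n))
  # subpopulation frequencies: Beta(p(1-F)/F, (1-p)(1-F)/F) around ancestral
  pSub <- matrix(pAnc, config$nSubpops, m, byrow = TRUE)
  if (Fst > 0) {
    a <- pAnc * (1 - Fst) / Fst
    b <- (1 - pAnc) * (1 - Fst) / Fst
    for (s in seq_len(config$nSubpops))
      pSub[s, ] <- rbeta(m, a, b)
  }
  D <- matrix(0L, n, m)
  for (s in seq_len(config$nSubpops)) {
    idx <- which(subpop == levels(subpop)[s])
    D[idx, ] <- rbinom(length(idx) * m, 4L,
                       rep(pSub[s, ], each = length(idx)))
  }
  chrom <- sort(rep_len(seq_len(config$nChromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), seq_along), use.names = FALSE)
  mi <- data.frame(marker = sprintf("chr%02d_%05d", chrom, pos),
                   chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  rownames(D) <- .defaultIds(n); colnames(D) <- mi$marker
  list(dosages = DosageMatrix(D, mi), subpop = subpop, ancestralFreq = pAnc)
}

#' Simulate GBS read counts from known dosages
#'
#' The exact inverse model of the dosage caller: per cell, total depth is
#' uniform over `depthRange` (a negative-binomial option mimics more
#' overdispersed libraries) and the alternative read count is
#' Binomial(depth, f(x)) with f(x) = (x/4)(1-e) + (1-x/4)e.
#'
#' @param dosageMat complete [DosageMatrix-class] of true dosages.
#' @param depthRange integer depth interval (uniform sampling).
#' @param seqError per-read error probability e.
#' @param seed RNG seed.
#' @param depthModel `"uniform"` (default) or `"nbinom"`; the
#'   negative-binomial uses the mid-range as mean with size 5.
#' @return a [ReadCountSet-class].
#' @export
simulateReadCounts <- function(dosageMat, depthRange = c(10, 100),
                               seqError = 0.002, seed = 1,
                               depthModel = c("uniform", "nbinom")) {
  stopifnot(is(dosageMat, "DosageMatrix"),
            !anyNA(dosageMat@dosages),
            depthRange[1] >= 1, depthRange[1] <= depthRange[2],
            seqError >= 0, seqError < 0.5)
  depthModel <- match.arg(depthModel)
  set.seed(seed)
  X <- dosageMat@dosages
  n <- nrow(X); m <- ncol(X)
  depth <- if (depthModel == "uniform") {
    depths <- seq(depthRange[1], depthRange[2])
    matrix(depths[sample.int(length(depths), n * m, replace = TRUE)], n, m)
  } else {
    matrix(pmax(depthRange[1],
                pmin(depthRange[2],
                     stats::rnbinom(n * m, size = 5,
                                    mu = mean(depthRange)))), n, m)
  }
  f <- (X / 4) * (1 - seqError) + (1 - X / 4) * seqError
  alt <- matrix(rbinom(n * m, as.vector(depth), as.vector(f)), n, m)
  ReadCountSet(depth - alt, alt, dosageMat@markerInfo)
}

# centred gene-action covariate matrices used as simulation truth
.centeredCoding <- function(X, type) {
  Z <- switch(type,
    additive = X,
    simplex = (X > 0) * 4,
    duplex = (X >= 2) * 4)
  sweep(Z, 2, colMeans(Z))
}

.scaleToVar <- function(x, target) {
  v <- var(x)
  if (target <= 0 || v <= 0) return(x * 0)
  x * sqrt(target / v)
}

#' Simulate plot-level phenotypes over a multi-environment trial series
#'
#' Builds per-individual genotypic values from sampled QTL with additive,
#' simplex-dominance, duplex-dominance and additive-by-additive components
#' (each rescaled so its realised variance across the panel hits the
#' `TraitSpec` target exactly), then scatters one plot per genotype per
#' block over the row-column layout and adds block, row, column,
#' genotype-by-location, genotype-by-year and plot-residual draws.
#'
#' @param dosageMat complete [DosageMatrix-class].
#' @param trait a [traitSpec()].
#' @param layout a [fieldLayoutSpec()]; `rows * cols` must hold all
#'   genotypes.
#' @param seed RNG seed.
#' @param traitName name used in the output table.
#' @return list with `plots` (data.frame: trial, location, year, block, row,
#'   col, genotype, trait, value) and `truth` (list: qtl positions, effects,
#'   per-component genetic values, total `geneticValue`, realised variance
#'   components).
#' @export
simulatePhenotypes <- function(dosageMat, trait = traitSpec(),
                               layout = fieldLayoutSpec(), seed = 1,
                               traitName = "trait1") {
  stopifnot(is(dosageMat, "DosageMatrix"), inherits(trait, "TraitSpec"),
            inherits(layout, "FieldLayoutSpec"), !anyNA(dosageMat@dosages))
  X <- dosageMat@dosages
  n <- nrow(X); m <- ncol(X)
  if (layout$rows * layout$cols < n)
    stop("layout too small: rows*cols = ", layout$rows * layout$cols,
         " < ", n, " genotypes")
  set.seed(seed)

  pickQtl <- function(k) sort(sample.int(m, min(k, m)))
  comp <- list()
  qtl <- list()
  eff <- list()

  Za <- .centeredCoding(X, "additive")
  qtl$additive <- pickQtl(trait$nQtlAdditive)
  eff$additive <- rnorm(length(qtl$additive))
  comp$additive <- .scaleToVar(
    drop(Za[, qtl$additive, drop = FALSE] %*% eff$additive),
    trait$varAdditive)

  Zs <- .centeredCoding(X, "simplex")
  qtl$dominance <- pickQtl(trait$nQtlDominance)
  eff$dominance <- rnorm(length(qtl$dominance))
  comp$dominance <- .scaleToVar(
    drop(Zs[, qtl$dominance, drop = FALSE] %*% eff$dominance),
    trait$varDominance)

  Zd <- .centeredCoding(X, "duplex")
  qtl$duplex <- pickQtl(trait$nQtlDominance)
  eff$duplex <- rnorm(length(qtl$duplex))
  comp$duplex <- .scaleToVar(
    drop(Zd[, qtl$duplex, drop = FALSE] %*% eff$duplex),
    trait$varDuplexDominance)

  # additive-by-additive: products of centred dosages at sampled locus pairs
  nPairs <- max(10L, trait$nQtlAdditive %/% 2L)
  pairIdx <- cbind(sample.int(m, nPairs, replace = TRUE),
                   sample.int(m, nPairs, replace = TRUE))
  pairIdx <- pairIdx[pairIdx[, 1] != pairIdx[, 2], , drop = FALSE]
  qtl$epistatic <- pairIdx
  eff$epistatic <- rnorm(nrow(pairIdx))
  W <- Za[, pairIdx[, 1], drop = FALSE] * Za[, pairIdx[, 2], drop = FALSE]
  W <- sweep(W, 2, colMeans(W))
  comp$epistatic <- .scaleToVar(drop(W %*% eff$epistatic),
                                trait$varEpistaticAxA)

  g <- comp$additive + comp$dominance + comp$duplex + comp$epistatic
  ids <- rownames(X)

  nL <- layout$nLocations; nT <- layout$nYears
  gL <- matrix(rnorm(n * nL, 0, sqrt(trait$varGxL)), n, nL)
  gT <- matrix(rnorm(n * nT, 0, sqrt(trait$varGxT)), n, nT)

  out <- vector("list", nL * nT)
  k <- 0
  for (loc in seq_len(nL)) for (yr in seq_len(nT)) {
    k <- k + 1
    trialId <- sprintf("L%d_Y%d", loc, yr)
    blockRows <- vector("list", layout$nBlocks)
    for (b in seq_len(layout$nBlocks)) {
      cells <- sample.int(layout$rows * layout$cols, n) # random row-column
      rw <- (cells - 1L) %/% layout$cols + 1L
      cl <- (cells - 1L) %% layout$cols + 1L
      bEff <- rnorm(1, 0, sqrt(layout$varBlock))
      rEff <- rnorm(layout$rows, 0, sqrt(layout$varRow))
      cEff <- rnorm(layout$cols, 0, sqrt(layout$varCol))
      val <- g + gL[, loc] + gT[, yr] + bEff + rEff[rw] + cEff[cl] +
        rnorm(n, 0, sqrt(trait$varResidual))
      blockRows[[b]] <- data.frame(trial = trialId, location = loc, year = yr,
                                   block = b, row = rw, col = cl,
                                   genotype = ids, trait = traitName,
                                   value = val, stringsAsFactors = FALSE)
    }
    out[[k]] <- do.call(rbind, blockRows)
  }
  plots <- do.call(rbind, out)
  rownames(plots) <- NULL
  truth <- list(qtl = qtl, effects = eff,
                components = comp,
                geneticValue = setNames(g, ids),
                realizedVarComp = c(
                  additive = var(comp$additive),
                  dominance = var(comp$dominance),
                  duplex = var(comp$duplex),
                  epistatic = var(comp$epistatic)))
  list(plots = plots, truth = truth)
}
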