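#' Fit a linear mixed model by REML and extract variance components
#'
#' Thin wrapper around `lme4::lmer` used by all field-trial analyses; pure
#' fixed-effect formulas fall back to `lm`. Non-convergence is flagged, not
#' raised.
#'
#' @param formula an `lmer`-style formula with `(1 | term)` random effects.
#' @param data data.frame holding the variables.
#' @return list with `varComp` (named vector of variance components,
#'   including `"residual"`), `fixef` (fixed-effect estimates), `logLik`
#'   (REML criterion), `converged` flag and the underlying `fit` object.
#' @examples
#' d <- data.frame(g = gl(10, 5), y = rnorm(50))
#' fitLmmReml(y ~ 1 + (1 | g), d)$varComp
#' @export
fitLmmReml <- function(formula, data) {
  hasRandom <- length(lme4::findbars(formula)) > 0
  if (!hasRandom) {
    fit <- lm(formula, data = data)
    return(list(varComp = c(residual = summary(fit)$sigma^2),
                fixef = coef(fit), logLik = as.numeric(stats::logLik(fit)),
                converged = TRUE, fit = fit))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comps <- setNames(vc$vcov, vc$grp)
  names(comps)[names(comps) == "Residual"] <- "residual"
  conv <- length(fit@optinfo$conv$lme4) == 0
  list(varComp = comps, fixef = lme4::fixef(fit),
       logLik = as.numeric(stats::logLik(fit)), converged = conv, fit = fit)
}

.checkPlotTable <- function(plots) {
  need <- c("trial", "block", "row", "col", "genotype", "value")
  miss <- setdiff(need, names(plots))
  if (length(miss))
    stop("plot table lacks columns: ", paste(miss, collapse = ", "))
  key <- interaction(plots$trial, plots$block, plots$row, plots$col)
  if (anyDuplicated(key))
    stop("duplicate (trial, block, row, col) plot positions")
  invisible(TRUE)
}

.blueFromFit <- function(fixef, vcovMat, prefix = "genotype") {
  gIdx <- grep(paste0("^", prefix), names(fixef))
  other <- fixef[-gIdx]
  # average over the reference-coded nuisance levels (reference level = 0)
  offset <- if (length(other)) mean(c(0, other)) else 0
  g <- fixef[gIdx] + offset
  names(g) <- sub(paste0("^", prefix), "", names(g))
  se <- sqrt(diag(vcovMat)[gIdx])
  data.frame(genotype = names(g), blue = unname(g), se = unname(se),
             stringsAsFactors = FALSE)
}

#' Within-trial adjusted genotype means (BLUEs)
#'
#' Fits, separately per trial, a row-column model with fixed complete-block
#' and genotype effects and random row-in-block and column-in-block effects,
#' and extracts each genotype's best linear unbiased estimate. Plots with
#' standardised conditional residuals beyond 3.5 in absolute value are
#' flagged as outliers and optionally removed (one refit).
#'
#' @param plots plot table (columns trial, block, row, col, genotype, value).
#' @param removeOutliers refit without flagged plots? (default FALSE; counts
#'   are always reported).
#' @param checks optional character vector of check-variety ids: they take
#'   part in the model fit but are excluded from the returned table.
#' @return data.frame (one row per trial x genotype): `trial`, `genotype`,
#'   `blue`, `se`, with attributes `level = "within_trial"` and
#'   `outliers` (flag counts per trial).
#' @export
bluesWithinTrial <- function(plots, removeOutliers = FALSE, checks = NULL) {
  .checkPlotTable(plots)
  out <- list(); nOut <- integer(0)
  for (tr in unique(plots$trial)) {
    d <- plots[plots$trial == tr, , drop = FALSE]
    d$genotype <- factor(d$genotype)
    d$blockf <- factor(d$block)
    d$rowf <- factor(paste(d$block, d$row))
    d$colf <- factor(paste(d$block, d$col))
    form <- if (nlevels(d$blockf) > 1)
      value ~ 0 + genotype + blockf + (1 | rowf) + (1 | colf)
    else value ~ 0 + genotype + (1 | rowf) + (1 | colf)
    f <- fitLmmReml(form, d)
    res <- residuals(f$fit)
    z <- if (sd(res) > 0) (res - mean(res)) / sd(res) else res * 0
    flag <- abs(z) > 3.5
    nOut[tr] <- sum(flag)
    if (removeOutliers && any(flag)) {
      d2 <- d[!flag, , drop = FALSE]
      lost <- setdiff(levels(d$genotype), unique(as.character(d2$genotype)))
      if (length(lost))
        warning("genotype(s) only present in removed plots, dropped: ",
                paste(lost, collapse = ", "))
      d2$genotype <- droplevels(d2$genotype)
      f <- fitLmmReml(form, d2)
    }
    vc <- as.matrix(suppressWarnings(stats::vcov(f$fit)))
    tab <- .blueFromFit(f$fixef, vc)
    tab <- cbind(trial = tr, tab, stringsAsFactors = FALSE)
    if (!is.null(checks)) tab <- tab[!tab$genotype %in% checks, ]
    out[[tr]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "level") <- "within_trial"
  attr(res, "outliers") <- nOut
  res
}

#' Across-trial adjusted genotype means
#'
#' Pools the within-trial BLUEs with a fixed trial + genotype model (the
#' residual absorbs genotype-by-trial interaction plus carried-over error)
#' and returns one adjusted mean per genotype -- the response variable for
#' genomic prediction.
#'
#' @param within data.frame from [bluesWithinTrial()].
#' @param warnSingle warn about genotypes observed in a single trial
#'   (retained, but with larger SE)?
#' @return data.frame `genotype`, `blue`, `se` with attribute
#'   `level = "across_trial"`.
#' @export
bluesAcrossTrials <- function(within, warnSingle = TRUE) {
  stopifnot(all(c("trial", "genotype", "blue") %in% names(within)))
  if (length(unique(within$trial)) < 2)
    stop("need BLUEs from at least two trials")
  tabG <- table(within$genotype)
  if (warnSingle && any(tabG == 1))
    warning(sum(tabG == 1), " genotype(s) present in a single trial; ",
            "retained with larger SE")
  d <- within
  d$genotype <- factor(d$genotype)
  d$trialf <- factor(d$trial)
  fit <- lm(blue ~ 0 + genotype + trialf, data = d)
  res <- .blueFromFit(coef(fit), as.matrix(suppressWarnings(stats::vcov(fit))))
  attr(res, "level") <- "across_trial"
  res
}

#' Single-step alternative to the two-step adjusted means
#'
#' Fits all trials jointly: fixed genotype and trial-by-block effects,
#' random rows and columns nested in trial and block. Used to check that the
#' two-step pipeline reproduces the joint analysis.
#'
#' @inheritParams bluesWithinTrial
#' @return data.frame `genotype`, `blue`, `se`.
#' @export
bluesSingleStep <- function(plots) {
  .checkPlotTable(plots)
  d <- plots
  d$genotype <- factor(d$genotype)
  d$tb <- factor(paste(d$trial, d$block))
  d$rowf <- factor(paste(d$trial, d$block, d$row))
  d$colf <- factor(paste(d$trial, d$block, d$col))
  f <- fitLmmReml(value ~ 0 + genotype + tb + (1 | rowf) + (1 | colf), d)
  res <- .blueFromFit(f$fixef, as.matrix(suppressWarnings(stats::vcov(f$fit))))
  attr(res, "level") <- "across_trial"
  res
}

#' Multi-environment variance components for heritability
#'
#' Takes within-trial BLUEs over a location x year trial series and fits
#' fixed location, year and location:year effects with random genotype,
#' genotype:location and genotype:year terms. The residual captures the
#' three-way interaction (plus carried-over within-trial error).
#'
#' @param within data.frame from [bluesWithinTrial()] with additional
#'   columns `location` and `year` (or trial ids of the form `"L?_Y?"`,
#'   which are parsed).
#' @return list with `varComp` (named: g, gL, gT, residual), `l`, `t`, and
#'   the fitted model.
#' @export
varCompH2 <- function(within) {
  d <- within
  if (!all(c("location", "year") %in% names(d))) {
    if (!all(grepl("^L.+_Y.+$", d$trial)))
      stop("need location/year columns or trial ids like 'L1_Y2'")
    parts <- strsplit(sub("^L", "", d$trial), "_Y")
    d$location <- vapply(parts, `[`, "", 1)
    d$year <- vapply(parts, `[`, "", 2)
  }
  d$L <- factor(d$location); d$Tm <- factor(d$year)
  d$G <- factor(d$genotype)
  f <- fitLmmReml(blue ~ L * Tm + (1 | G) + (1 | G:L) + (1 | G:Tm), d)
  vc <- f$varComp
  out <- c(g = unname(vc["G"]), gL = unname(vc["G:L"]),
           gT = unname(vc["G:Tm"]), residual = unname(vc["residual"]))
  out[is.na(out)] <- 0
  list(varComp = out, l = nlevels(d$L), t = nlevels(d$Tm), fit = f)
}

#' Broad-sense heritability across locations and years
#'
#' `H2 = s2_g / (s2_g + s2_gL / l + s2_gT / t + s2_eps / (l t))` on
#' genotype-mean basis, where `l` and `t` are the numbers of locations and
#' years. With trial means as input this is closer to a repeatability than a
#' narrow-sense heritability.
#'
#' @param vc named numeric vector with components `g`, `gL`, `gT`,
#'   `residual` (interaction components may be omitted and default to 0), or
#'   the list returned by [varCompH2()].
#' @param l,t numbers of locations and years (taken from `vc` when it is a
#'   [varCompH2()] result).
#' @return heritability in \[0, 1\].
#' @examples
#' heritability(c(g = 1, residual = 1), l = 3, t = 2)  # 6/7
#' @export
heritability <- function(vc, l, t) {
  if (is.list(vc) && !is.null(vc$varComp)) {
    if (missing(l)) l <- vc$l
    if (missing(t)) t <- vc$t
    vc <- vc$varComp
  }
  stopifnot(l >= 1, t >= 1)
  g <- vc["g"]; gL <- vc["gL"]; gT <- vc["gT"]; e <- vc["residual"]
  gL <- if (is.na(gL)) 0 else gL
  gT <- if (is.na(gT)) 0 else gT
  if (any(c(g, gL, gT, e) < 0, na.rm = TRUE))
    stop("variance components must be non-negative")
  denom <- g + gL / l + gT / t + e / (l * t)
  if (!is.finite(denom) || denom <= 0)
    stop("all variance components are zero: heritability undefined")
  unname(g / denom)
}
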