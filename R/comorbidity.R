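#' @importFrom stats glm binomial coef pnorm pchisq pt qnorm qlogis rbinom
#'   rnorm rpois runif var sd cor cor.test phyper complete.cases as.formula
#'   setNames plogis quantile median rexp
NULL

utils::globalVariables(c(
  "zSite", "nShared", "outcome", "predictor", "pair", "phecodeA", "phecodeB",
  "site", "beta", "se", "z", "converged", "..keep"))

.defaultComorbidityCovariates <-
  c("currentAge", "ehrAge", "sex", "race", "logUniquePhecodes")

# Logistic fit with separation / non-convergence detection. Returns the
# coefficient row for `term` plus a convergence verdict. Aliased covariates
# (NA coefficients, e.g. under extreme age collinearity) are tolerated as
# long as the term of interest is estimable and stable.
.safeLogistic <- function(formula, data, term) {
  fit <- tryCatch(
    suppressWarnings(glm(formula, data = data, family = binomial(),
                         control = stats::glm.control(epsilon = 1e-12,
                                                      maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                reason = "fit_error", fit = NULL))
  sm <- summary(fit)$coefficients
  if (!(term %in% rownames(sm)))
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                reason = "term_aliased", fit = fit))
  b <- sm[term, "Estimate"]; s <- sm[term, "Std. Error"]
  ok <- fit$converged && is.finite(b) && is.finite(s) &&
    abs(b) < 15 && s < 100
  list(beta = b, se = s, converged = ok,
       reason = if (ok) "" else "separation_or_nonconvergence", fit = fit)
}

#' Pairwise logistic comorbidity fit (one direction)
#'
#' Fits case (1) vs control (0) status of \code{outcome} on the case
#' indicator of \code{predictor} plus demographic covariates, on the patients
#' with non-missing status for both phecodes. The Wald Z for the predictor
#' term is the directional comorbidity statistic.
#'
#' @param pe a \linkS4class{PhecodeExperiment}.
#' @param outcome,predictor phecode strings.
#' @param covariates colData column names entering the model (default: both
#'   ages, sex, race, log unique-phecode burden).
#' @param minCases minimum case count for both phecodes in the analyzable
#'   subset; below it the fit is skipped with a reason code.
#' @return one-row data.frame: outcome, predictor, beta, se, z, p, nCase,
#'   nControl, converged, reason.
#' @export
fitPairwiseLogistic <- function(pe, outcome, predictor,
                                covariates = .defaultComorbidityCovariates,
                                minCases = 20L) {
  st <- statusMatrix(pe)
  y <- st[outcome, ]
  x <- st[predictor, ]
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  skip <- function(reason) data.frame(
    outcome = outcome, predictor = predictor, beta = NA_real_, se = NA_real_,
    z = NA_real_, p = NA_real_, nCase = sum(y == 1L), nControl = sum(y == 0L),
    converged = FALSE, reason = reason, stringsAsFactors = FALSE)
  if (sum(y == 1L) < minCases || sum(x == 1L) < minCases)
    return(skip("too_few_cases"))
  if (length(unique(y)) < 2L) return(skip("constant_outcome"))
  if (length(unique(x)) < 2L) return(skip("constant_predictor"))
  dat <- as.data.frame(colData(pe))[keep, covariates, drop = FALSE]
  dat$.y <- y
  dat$.x <- x
  # drop single-level factors (e.g. all one sex in a subset)
  for (cv in covariates)
    if (is.factor(dat[[cv]]) && length(unique(dat[[cv]])) < 2L)
      dat[[cv]] <- NULL
  keptCov <- intersect(covariates, names(dat))
  form <- as.formula(paste(c(".y ~ .x", keptCov), collapse = " + "))
  res <- .safeLogistic(form, dat, ".x")
  zv <- if (res$converged) res$beta / res$se else NA_real_
  data.frame(outcome = outcome, predictor = predictor,
             beta = if (res$converged) res$beta else NA_real_,
             se = if (res$converged) res$se else NA_real_,
             z = zv, p = if (is.finite(zv)) zToP(zv) else NA_real_,
             nCase = sum(y == 1L), nControl = sum(y == 0L),
             converged = res$converged, reason = res$reason,
             stringsAsFactors = FALSE)
}

#' Combine the two directional Zs of a phecode pair into one site Z
#'
#' @param forward,reverse one-row data.frames from
#'   \code{\link{fitPairwiseLogistic}} (forward: outcome = other phecode,
#'   predictor = index; reverse: the converse).
#' @param rule \code{"mean"} (default; arithmetic mean of converged Zs),
#'   \code{"outcome_direction_only"} (forward Z only), or \code{"stouffer"}
#'   (sum of converged Zs over sqrt of their number).
#' @return the combined site Z, or NA if neither direction converged.
#' @export
combineDirections <- function(forward, reverse,
                              rule = c("mean", "outcome_direction_only",
                                       "stouffer")) {
  rule <- match.arg(rule)
  zs <- c(if (isTRUE(forward$converged)) forward$z,
          if (isTRUE(reverse$converged)) reverse$z)
  zs <- zs[is.finite(zs)]
  if (!length(zs)) return(NA_real_)
  switch(rule,
    mean = mean(zs),
    outcome_direction_only =
      if (isTRUE(forward$converged) && is.finite(forward$z)) forward$z
      else zs[1],
    stouffer = sum(zs) / sqrt(length(zs)))
}

#' Count patients who are cases for both phecodes
#'
#' The shared-patient weight N_{A,B} of the cross-site combiner. With
#' \code{analyzable = TRUE} it instead counts patients with non-missing
#' status for both phecodes.
#'
#' @param pe a \linkS4class{PhecodeExperiment}.
#' @param a,b phecode strings.
#' @param analyzable count jointly analyzable instead of jointly case.
#' @return integer count.
#' @export
countSharedCases <- function(pe, a, b, analyzable = FALSE) {
  st <- statusMatrix(pe)
  if (analyzable) sum(!is.na(st[a, ]) & !is.na(st[b, ]))
  else sum(st[a, ] == 1L & st[b, ] == 1L, na.rm = TRUE)
}

#' Enumerate the directional regressions a phenome scan schedules
#'
#' In index mode (default) each non-index phecode of the universe yields two
#' directional fits against the index phecode. In full-grid mode every
#' ordered (outcome, predictor) pair over the universe is scheduled,
#' including the diagonal, matching a complete phenome-by-phenome grid of
#' size \code{length(universe)^2}.
#'
#' @param universe character vector of phecodes.
#' @param indexPhecode index phecode (ignored in full-grid mode).
#' @param fullGrid schedule the complete grid.
#' @return data.table (outcome, predictor), deterministically ordered by
#'   phecode string.
#' @export
enumerateScanPairs <- function(universe, indexPhecode = NULL,
                               fullGrid = FALSE) {
  universe <- sort(unique(universe))
  if (fullGrid)
    return(CJ(outcome = universe, predictor = universe)[, .(outcome, predictor)])
  if (is.null(indexPhecode)) stop("indexPhecode required in index mode")
  others <- setdiff(universe, indexPhecode)
  if (!length(others)) stop("empty phecode universe")
  rbindlist(list(
    data.table(outcome = others, predictor = indexPhecode),
    data.table(outcome = indexPhecode, predictor = others)))[
      order(outcome, predictor)]
}

#' Phenome-wide comorbidity scan against an index phecode (one site)
#'
#' For every phecode of the universe (default: phecodes occurring on at least
#' one distinct date in at least one index-phecode case), both directional
#' logistic fits against the index phecode are run and combined into one site
#' Z; the joint-case count provides the cross-site weight.
#'
#' @param pe a \linkS4class{PhecodeExperiment}.
#' @param indexPhecode the index phecode (e.g. \code{"295.1"}).
#' @param universe optional explicit phecode universe.
#' @param site site label carried into the output.
#' @param rule direction-combination rule, see
#'   \code{\link{combineDirections}}.
#' @param minCases,covariates passed to \code{\link{fitPairwiseLogistic}}.
#' @param sharedCases count shared patients as joint cases (default) or
#'   joint-analyzable (\code{FALSE} -> analyzable).
#' @return data.table: one row per (index, other) pair with directional Zs,
#'   the combined site Z, shared-case weight, case/control counts and
#'   convergence flags; ordered by phecode string.
#' @export
runPhenomeScan <- function(pe, indexPhecode, universe = NULL, site = "site1",
                           rule = "mean", minCases = 20L,
                           covariates = .defaultComorbidityCovariates,
                           sharedCases = c("cases", "analyzable")) {
  sharedCases <- match.arg(sharedCases)
  st <- statusMatrix(pe)
  if (!indexPhecode %in% rownames(st))
    stop("index phecode not present: ", indexPhecode)
  if (is.null(universe)) {
    idx <- caseIds(pe, indexPhecode)
    if (!length(idx)) stop("no cases for the index phecode")
    occ <- occurrenceCounts(pe)[, idx, drop = FALSE]
    universe <- rownames(occ)[Matrix::rowSums(occ >= 1) > 0]
  }
  others <- sort(setdiff(universe, indexPhecode))
  if (!length(others)) stop("empty phecode universe")
  rows <- lapply(others, function(ph) {
    fwd <- fitPairwiseLogistic(pe, outcome = ph, predictor = indexPhecode,
                               covariates = covariates, minCases = minCases)
    rev <- fitPairwiseLogistic(pe, outcome = indexPhecode, predictor = ph,
                               covariates = covariates, minCases = minCases)
    data.table(
      phecodeA = indexPhecode, phecodeB = ph, site = site,
      zForward = fwd$z, zReverse = rev$z,
      zSite = combineDirections(fwd, rev, rule = rule),
      nShared = countSharedCases(pe, indexPhecode, ph,
                                 analyzable = sharedCases == "analyzable"),
      nCase = fwd$nCase, nControl = fwd$nControl,
      convergedForward = fwd$converged, convergedReverse = rev$converged)
  })
  rbindlist(rows)[order(phecodeB)]
}
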