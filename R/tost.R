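#' Two one-sided tests (TOST) of equivalence from group summaries
#'
#' Tests whether the standardized mean difference between two groups (e.g.
#' polygenic scores of phecode cases vs controls) lies inside symmetric
#' Cohen's d equivalence bounds. Bounds are converted to the raw scale via
#' \code{sPool = sqrt((sd1^2 + sd2^2)/2)} (the root-mean-square convention;
#' switchable to the df-pooled form). One-sided t tests use the Welch
#' unequal-variance statistic with Satterthwaite degrees of freedom by
#' default; a pooled-variance variant is available. Each one-sided test
#' rejects toward the interior of the bounds and \code{pTost} is the larger
#' of the two one-sided p-values. All arguments are vectorized.
#'
#' @param n1,mean1,sd1 case-group size, mean, standard deviation.
#' @param n2,mean2,sd2 control-group size, mean, standard deviation.
#' @param bounds length-2 numeric, lower and upper equivalence bounds in
#'   Cohen's d units (default \code{c(-0.2, 0.2)}).
#' @param variant \code{"welch"} (default) or \code{"pooled"}.
#' @param boundScale \code{"rms"} (default, \code{sqrt((sd1^2+sd2^2)/2)}) or
#'   \code{"pooled_df"} (df-weighted pooled SD).
#' @return data.frame: tLower and pLower (test against the upper bound),
#'   tUpper and pUpper (test against the lower bound), df, pTost,
#'   deltaLower, deltaUpper (raw-scale bounds).
#' @examples
#' tostEquivalence(1e4, 0, 1, 1e4, 0, 1)$pTost   # overwhelming equivalence
#' @export
tostEquivalence <- function(n1, mean1, sd1, n2, mean2, sd2,
                            bounds = c(-0.2, 0.2),
                            variant = c("welch", "pooled"),
                            boundScale = c("rms", "pooled_df")) {
  variant <- match.arg(variant)
  boundScale <- match.arg(boundScale)
  if (length(bounds) != 2L || !(bounds[1] < 0 && 0 < bounds[2]))
    stop("bounds must straddle zero: d_low < 0 < d_high")
  if (any(n1 < 2L | n2 < 2L)) stop("both groups need n >= 2")
  if (any(sd1 <= 0 | sd2 <= 0)) stop("both groups need positive variance")
  sPool <- switch(boundScale,
    rms = sqrt((sd1^2 + sd2^2) / 2),
    pooled_df = sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)))
  dLow <- bounds[1] * sPool
  dHigh <- bounds[2] * sPool
  diff <- mean1 - mean2
  if (variant == "welch") {
    sem <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    sem <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tUpper <- (diff - dLow) / sem   # H0: diff <= dLow, reject upward
  tLower <- (diff - dHigh) / sem  # H0: diff >= dHigh, reject downward
  pUpper <- pt(tUpper, df, lower.tail = FALSE)
  pLower <- pt(tLower, df, lower.tail = TRUE)
  data.frame(tLower = tLower, tUpper = tUpper,
             pLower = pLower, pUpper = pUpper,
             df = df, pTost = pmax(pLower, pUpper),
             deltaLower = dLow, deltaUpper = dHigh)
}

#' Fisher's method for combining independent p-values
#'
#' \code{chi2 = -2 * sum(log(p))}, referred to a chi-square with \code{2k}
#' degrees of freedom (upper tail). With a single p-value the method is the
#' identity. Zero p-values are clamped to the smallest positive
#' representable double and flagged.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return list(chi2, df, p, k, clamped).
#' @export
fisherCombine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  clamped <- any(p == 0)
  p[p == 0] <- .Machine$double.xmin
  chi2 <- -2 * sum(log(p))
  k <- length(p)
  list(chi2 = chi2, df = 2L * k,
       p = pchisq(chi2, df = 2 * k, lower.tail = FALSE),
       k = k, clamped = clamped)
}

#' Bonferroni flags for meta-analyzed equivalence p-values
#'
#' Equivalence is declared when \code{pMeta < alpha/nTests} (strict
#' inequality at the boundary). \code{nTests} defaults to the number of
#' phecodes entering the meta-analysis.
#'
#' @param pMeta numeric vector of Fisher-combined equivalence p-values.
#' @param alpha family-wise error rate.
#' @param nTests Bonferroni denominator.
#' @return logical vector with attributes \code{threshold} and \code{nTests}.
#' @export
flagEquivalent <- function(pMeta, alpha = 0.05, nTests = sum(!is.na(pMeta))) {
  bonferroniFlag(pMeta, alpha = alpha, nTests = nTests)
}

#' Cross-site TOST meta-analysis table
#'
#' Runs \code{\link{tostEquivalence}} per (phecode, site) from the summary
#' columns of the per-site PRS association tables, combines the per-site
#' TOST p-values with Fisher's method, and applies the Bonferroni flag over
#' the phecodes tested.
#'
#' @param siteResults rbind of per-site \code{\link{prsPhewas}} outputs
#'   restricted to the phecodes of interest (must carry the case/control
#'   summary columns and be converged at each contributing site).
#' @param bounds,variant,boundScale passed to \code{\link{tostEquivalence}}.
#' @param alpha family-wise error rate.
#' @param nTests Bonferroni denominator; default = number of phecodes.
#' @return list with \code{perSite} (phecode, site, pTost, tLower, tUpper,
#'   df) and \code{meta} (phecode, chi2, df, pMeta, equivalent) data.tables;
#'   the meta table carries attributes \code{threshold} and \code{nTests}.
#' @export
tostMeta <- function(siteResults, bounds = c(-0.2, 0.2), variant = "welch",
                     boundScale = "rms", alpha = 0.05, nTests = NULL) {
  dt <- as.data.table(siteResults)
  dt <- dt[converged & caseN >= 2 & controlN >= 2 &
             is.finite(caseSd) & caseSd > 0 & controlSd > 0]
  if (!nrow(dt)) stop("no usable site results for equivalence testing")
  ts <- tostEquivalence(dt$caseN, dt$caseMean, dt$caseSd,
                        dt$controlN, dt$controlMean, dt$controlSd,
                        bounds = bounds, variant = variant,
                        boundScale = boundScale)
  perSite <- data.table(phecode = dt$phecode, site = dt$site,
                        pTost = ts$pTost, tLower = ts$tLower,
                        tUpper = ts$tUpper, df = ts$df)
  meta <- perSite[, {
    fc <- fisherCombine(pTost)
    list(chi2 = fc$chi2, df = fc$df, pMeta = fc$p, nSites = fc$k)
  }, by = phecode][order(phecode)]
  if (is.null(nTests)) nTests <- nrow(meta)
  flags <- flagEquivalent(meta$pMeta, alpha = alpha, nTests = nTests)
  meta[, equivalent := as.logical(flags)]
  data.table::setattr(meta, "threshold", attr(flags, "threshold"))
  data.table::setattr(meta, "nTests", attr(flags, "nTests"))
  list(perSite = perSite, meta = meta)
}

utils::globalVariables(c("caseN", "controlN", "caseSd", "controlSd",
                         "caseMean", "controlMean", "pTost", "equivalent",
                         "pMeta", "chi2"))
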