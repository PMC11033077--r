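utils::globalVariables(c("zCombined", "p", "significant", "singleSite",
                         "zForward", "zReverse"))

#' Convert a Z score to a two-sided normal p-value
#'
#' \code{p = 2 * pnorm(-abs(z))}; non-finite Z yields NA.
#'
#' @param z numeric vector of Z scores.
#' @return numeric vector of p-values in (0, 1].
#' @export
zToP <- function(z) {
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- NA_real_
  # report underflow as the smallest positive representable value
  p[is.finite(z) & p == 0] <- .Machine$double.xmin
  p
}

#' Bonferroni threshold and significance flags
#'
#' The denominator is the number of tests actually performed (non-missing
#' p-values) unless overridden.
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @param nTests Bonferroni denominator; default \code{sum(!is.na(p))}.
#' @return logical flag vector (strict \code{p < alpha/nTests}) with
#'   attributes \code{threshold} and \code{nTests}.
#' @export
bonferroniFlag <- function(p, alpha = 0.05, nTests = sum(!is.na(p))) {
  if (!length(p)) stop("empty p-value vector")
  if (nTests < 1) stop("nTests must be >= 1")
  thr <- alpha / nTests
  flags <- !is.na(p) & p < thr
  attr(flags, "threshold") <- thr
  attr(flags, "nTests") <- nTests
  flags
}

#' Combine per-site comorbidity Zs by shared-patient weighting
#'
#' The combined comorbidity Z for a phecode pair is the shared-case-weighted
#' average of the site Zs:
#' \deqn{Z_C = \frac{\sum_s Z_s N_s}{\sum_s N_s}}
#' over sites with a non-missing Z. If all usable weights are zero the
#' unweighted mean is used and flagged. Pairs testable at only one site are
#' retained with that site's Z and flagged \code{singleSite}. Two-sided
#' normal p-values and Bonferroni flags (denominator = pairs with a combined
#' Z) are attached.
#'
#' @param siteResults data.table/data.frame rbind of per-site
#'   \code{\link{runPhenomeScan}} outputs (columns phecodeA, phecodeB, site,
#'   zSite, nShared).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data.table: one row per pair with zCombined, p, significant,
#'   singleSite, unweighted, per-site columns; attributes \code{threshold}
#'   and \code{nTests}.
#' @export
combineSites <- function(siteResults, alpha = 0.05) {
  dt <- as.data.table(siteResults)
  need <- c("phecodeA", "phecodeB", "site", "zSite", "nShared")
  if (!all(need %in% names(dt)))
    stop("siteResults must have columns: ", paste(need, collapse = ", "))
  comb <- dt[, {
    ok <- is.finite(zSite)
    zs <- zSite[ok]; ns <- nShared[ok]
    if (!length(zs)) {
      list(zCombined = NA_real_, nSites = 0L, totalShared = sum(nShared),
           singleSite = FALSE, unweighted = FALSE)
    } else if (sum(ns) > 0) {
      list(zCombined = sum(zs * ns) / sum(ns), nSites = length(zs),
           totalShared = sum(ns), singleSite = length(zs) == 1L,
           unweighted = FALSE)
    } else {
      list(zCombined = mean(zs), nSites = length(zs), totalShared = 0L,
           singleSite = length(zs) == 1L, unweighted = TRUE)
    }
  }, by = .(phecodeA, phecodeB)]
  comb[, p := zToP(zCombined)]
  comb <- comb[order(phecodeA, phecodeB)]
  if (any(!is.na(comb$p))) {
    flags <- bonferroniFlag(comb$p, alpha = alpha)
    comb[, significant := as.logical(flags)]
    data.table::setattr(comb, "threshold", attr(flags, "threshold"))
    data.table::setattr(comb, "nTests", attr(flags, "nTests"))
  } else {
    comb[, significant := FALSE]
    data.table::setattr(comb, "threshold", NA_real_)
    data.table::setattr(comb, "nTests", 0L)
  }
  comb[]
}

#' Pearson correlation of two aligned Z-score profiles
#'
#' Pairwise-drops missing entries; p-value from the t transform.
#'
#' @param vecA,vecB numeric vectors aligned on shared pairs.
#' @return list(r, p, n).
#' @export
profileCorrelation <- function(vecA, vecB) {
  if (length(vecA) != length(vecB)) stop("vectors must be aligned")
  keep <- is.finite(vecA) & is.finite(vecB)
  if (sum(keep) < 3L) stop("need at least 3 shared finite entries")
  ct <- cor.test(vecA[keep], vecB[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
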