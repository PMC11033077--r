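utils::globalVariables(c("tier", "comorbidP", "comorbidSignificant",
                         "prsMetaP", "prsSignificantCorrected", "prsNominal",
                         "missingData", "direction"))

.tierLevels <- c("EQUIVALENT_PRS_NONSIG_NOMINAL",
                 "EQUIVALENT_PRS_NONSIG_CORRECTED",
                 "EQUIVALENT_COMORBID",
                 "PRS_ASSOC_NOT_COMORBID",
                 "OTHER")

# Pure tier rule on the boolean fields (vectorized). The first three tiers
# are nested as sets: NOMINAL implies CORRECTED implies COMORBID membership;
# the assigned tier is the most specific.
.assignTier <- function(comorbidSig, equivalent, prsSigCorrected, prsNominalNonsig,
                        comorbidNominalNonsig) {
  ifelse(comorbidSig & equivalent & !prsSigCorrected & prsNominalNonsig,
         "EQUIVALENT_PRS_NONSIG_NOMINAL",
  ifelse(comorbidSig & equivalent & !prsSigCorrected,
         "EQUIVALENT_PRS_NONSIG_CORRECTED",
  ifelse(comorbidSig & equivalent,
         "EQUIVALENT_COMORBID",
  ifelse(prsSigCorrected & comorbidNominalNonsig,
         "PRS_ASSOC_NOT_COMORBID",
         "OTHER"))))
}

#' Classify phenotypes into genetically-unrelated-comorbidity tiers
#'
#' Intersects the combined comorbidity results, the meta-analyzed PRS
#' associations, and the equivalence meta-results into one verdict per
#' phecode:
#' \itemize{
#'   \item \code{EQUIVALENT_COMORBID}: significantly comorbid and
#'     significantly equivalent PRS distributions (the PRS association may
#'     still be significant with a small effect size);
#'   \item \code{EQUIVALENT_PRS_NONSIG_CORRECTED}: additionally, the PRS
#'     meta-association is not significant after Bonferroni correction;
#'   \item \code{EQUIVALENT_PRS_NONSIG_NOMINAL}: additionally, the PRS
#'     meta p-value exceeds 0.05 — comorbid phenotypes with no discernible
#'     PRS difference despite power to detect one;
#'   \item \code{PRS_ASSOC_NOT_COMORBID}: corrected-significant PRS
#'     association but nominally non-significant comorbidity (p > 0.05);
#'   \item \code{OTHER}: everything else, including phecodes missing from
#'     any input (flagged \code{missingData}).
#' }
#' The first three tiers are nested as phecode sets; the assigned label is
#' the most specific. Assignment is a pure, order-independent function of
#' the inputs.
#'
#' @param combined combined comorbidity table from \code{\link{combineSites}}
#'   for the index phecode's pairs (columns phecodeB, p, significant,
#'   zCombined).
#' @param prs meta table from \code{\link{ivwMeta}} (columns phecode,
#'   metaP).
#' @param equiv meta table from \code{\link{tostMeta}$meta} (columns phecode,
#'   equivalent, pMeta).
#' @param alpha nominal significance level for the p > alpha conditions.
#' @param prsAlpha,prsNTests Bonferroni control for the PRS meta
#'   associations; denominator defaults to the number of PRS meta p-values.
#' @return data.table: one row per phecode in the union of the inputs with
#'   the boolean fields, the tier, and a \code{missingData} flag; attribute
#'   \code{tierCounts} holds the tier tally.
#' @export
assignTiers <- function(combined, prs, equiv, alpha = 0.05,
                        prsAlpha = 0.05, prsNTests = NULL) {
  cmb <- as.data.table(combined)
  keyCol <- if ("phecodeB" %in% names(cmb)) "phecodeB" else "phecode"
  cmb <- cmb[, .(phecode = get(keyCol), comorbidP = p,
                 comorbidSignificant = significant,
                 direction = sign(zCombined))]
  prs <- as.data.table(prs)
  if (is.null(prsNTests)) prsNTests <- sum(!is.na(prs$metaP))
  prsFlags <- bonferroniFlag(prs$metaP, alpha = prsAlpha, nTests = prsNTests)
  prs <- prs[, .(phecode, prsMetaP = metaP,
                 prsSignificantCorrected = as.logical(prsFlags),
                 prsNominal = !is.na(metaP) & metaP < alpha)]
  eqv <- as.data.table(equiv)[, .(phecode, pTostMeta = pMeta, equivalent)]
  all <- sort(unique(c(cmb$phecode, prs$phecode, eqv$phecode)))
  out <- data.table(phecode = all)
  out <- cmb[out, on = "phecode"]
  out <- prs[out, on = "phecode"]
  out <- eqv[out, on = "phecode"]
  out[, missingData := is.na(comorbidP) | is.na(prsMetaP) | is.na(equivalent)]
  out[, tier := ifelse(missingData, "OTHER", .assignTier(
    comorbidSig = comorbidSignificant,
    equivalent = equivalent,
    prsSigCorrected = prsSignificantCorrected,
    prsNominalNonsig = !is.na(prsMetaP) & prsMetaP > alpha,
    comorbidNominalNonsig = !is.na(comorbidP) & comorbidP > alpha))]
  out[, tier := factor(tier, levels = .tierLevels)]
  out <- out[order(phecode)]
  data.table::setattr(out, "tierCounts", table(out$tier))
  out
}

#' Literature-reported comorbidity phecodes
#'
#' Loads the editable TSV shipped at
#' \code{inst/extdata/literature_comorbidities.tsv}: phecodes of
#' comorbidities of the index disorder reported in at least two prior
#' publications, mapped to their closest specific phecode. This is
#' transcribed literature metadata — data, not code — intended as the
#' reference set for \code{\link{hypergeometricOverlap}} against an
#' EHR-derived comorbidity set.
#'
#' @param path optional alternative TSV (columns phecode, phenotype,
#'   category).
#' @return data.table (phecode, phenotype, category).
#' @export
literatureComorbidities <- function(path = system.file(
    "extdata", "literature_comorbidities.tsv", package = "equicomorb")) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          showProgress = FALSE)
  stopifnot(all(c("phecode", "phenotype", "category") %in% names(dt)))
  dt
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap of at least \code{overlapK} between
#' two sets of sizes \code{setAN} and \code{setBN} drawn from a universe of
#' \code{universeN}, i.e. P(X >= k) with X hypergeometric. Used to ask
#' whether literature-reported comorbidities overlap the EHR-derived ones
#' more than chance expects.
#'
#' @param universeN universe size.
#' @param setAN,setBN set sizes.
#' @param overlapK observed overlap.
#' @return upper-tail p-value.
#' @examples
#' hypergeometricOverlap(10, 5, 5, 5)  # = 1/choose(10, 5)
#' @export
hypergeometricOverlap <- function(universeN, setAN, setBN, overlapK) {
  if (overlapK < 0 || setAN > universeN || setBN > universeN ||
      overlapK > min(setAN, setBN))
    stop("inconsistent hypergeometric margins")
  phyper(overlapK - 1, m = setAN, n = universeN - setAN, k = setBN,
         lower.tail = FALSE)
}
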