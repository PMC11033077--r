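utils::globalVariables(c("N", "class"))

#' Run the labeled synthetic benchmark end-to-end
#'
#' Generates the two-site synthetic study, runs the full analysis, and
#' scores tier recovery against the generator's ground truth. The quantity
#' of interest is how well the most stringent tier
#' (\code{EQUIVALENT_PRS_NONSIG_NOMINAL}: significantly comorbid,
#' significantly equivalent PRS distributions, PRS meta p > 0.05) recovers
#' the truly consequence-driven (zero genetic loading) comorbidities.
#'
#' @param config a \code{simConfig}; default
#'   \code{\link{defaultSimConfig}()}.
#' @return list: \code{analysis} (full \code{\link{runStudyAnalysis}}
#'   output), \code{truth}, \code{metrics} (sensitivity, specificity,
#'   crossSiteR, nSignificantComorbid, nEquivalent, per-class comorbidity
#'   and PRS detection rates).
#' @export
runBenchmark <- function(config = defaultSimConfig()) {
  study <- simulateStudy(config)
  analysis <- runStudyAnalysis(study$sites, study$map,
                               indexPhecode = config$indexPhecode)
  metrics <- benchmarkMetrics(analysis, study$truth)
  list(analysis = analysis, truth = study$truth, metrics = metrics)
}

#' Score an analysis against generator ground truth
#'
#' @param analysis \code{\link{runStudyAnalysis}} output.
#' @param truth ground-truth table (phecode, g, c, b, class).
#' @return list of recovery metrics (see \code{\link{runBenchmark}}).
#' @export
benchmarkMetrics <- function(analysis, truth) {
  truth <- as.data.table(truth)[class != "background"]
  v <- as.data.table(analysis$verdicts)[truth, on = "phecode"]
  isConsequence <- v$class == "consequence"
  inTier <- !is.na(v$tier) & v$tier == "EQUIVALENT_PRS_NONSIG_NOMINAL"
  sens <- mean(inTier[isConsequence])
  spec <- mean(!inTier[!isConsequence])
  scan <- as.data.table(analysis$scan)
  wide <- data.table::dcast(scan, phecodeB ~ site, value.var = "zSite")
  siteCols <- setdiff(names(wide), "phecodeB")
  crossSiteR <- if (length(siteCols) >= 2L)
    profileCorrelation(wide[[siteCols[1]]], wide[[siteCols[2]]])$r
  else NA_real_
  comorbidByClass <- v[, .(rate = mean(comorbidSignificant %in% TRUE)),
                       by = class]
  prsByClass <- v[, .(rate = mean(!is.na(prsMetaP) & prsMetaP < 0.05)),
                  by = class]
  list(sensitivity = sens, specificity = spec, crossSiteR = crossSiteR,
       nSignificantComorbid = sum(v$comorbidSignificant %in% TRUE),
       nEquivalent = sum(v$equivalent %in% TRUE),
       comorbidRateByClass = setNames(comorbidByClass$rate,
                                      comorbidByClass$class),
       prsNominalRateByClass = setNames(prsByClass$rate, prsByClass$class))
}
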