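#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Phecode map with exclusion ranges
#'
#' Maps (vocabulary, code) pairs to phecodes and records, for every phecode,
#' the set of phecodes whose presence disqualifies a patient from serving as a
#' control for it ("exclusion ranges" in the phecode 1.2 dialect). Mapping is
#' many-codes-to-one-phecode and strictly within vocabulary: ICD-9 and ICD-10
#' entries are independent and no cross-mapping is ever performed.
#'
#' @slot table data.frame with columns \code{vocabulary} (\code{"ICD9"} or
#'   \code{"ICD10"}), \code{code}, \code{phecode}.
#' @slot exclusions named list: phecode -> character vector of phecodes whose
#'   occurrence (count >= 1) removes a would-be control.
#' @slot universe character vector of all phecodes the map defines.
#' @exportClass PhecodeMap
setClass("PhecodeMap",
  slots = c(table = "data.frame", exclusions = "list", universe = "character"))

setValidity("PhecodeMap", function(object) {
  msg <- character()
  tab <- object@table
  if (!all(c("vocabulary", "code", "phecode") %in% names(tab)))
    msg <- c(msg, "table must have columns vocabulary, code, phecode")
  else {
    if (!all(tab$vocabulary %in% c("ICD9", "ICD10")))
      msg <- c(msg, "vocabulary must be 'ICD9' or 'ICD10'")
    if (any(!nzchar(tab$code)))
      msg <- c(msg, "codes must be non-empty")
    if (!all(tab$phecode %in% object@universe))
      msg <- c(msg, "every mapped phecode must be in the universe")
  }
  if (length(object@exclusions) &&
      (is.null(names(object@exclusions)) ||
       !all(names(object@exclusions) %in% object@universe)))
    msg <- c(msg, "exclusion list names must be phecodes in the universe")
  if (length(msg)) msg else TRUE
})

#' Patient-by-phecode experiment container
#'
#' A \linkS4class{SummarizedExperiment} with phecodes as rows and patients as
#' columns. Assay \code{"counts"} holds the number of distinct calendar dates
#' on which any billing code mapping to the phecode was recorded; assay
#' \code{"status"} holds the derived case/control/missing coding
#' (\code{1} = case, \code{0} = control, \code{NA} = missing). Demographic
#' covariates (ages, sex, race, record length, log unique-phecode burden)
#' live in \code{colData}. The \linkS4class{PhecodeMap} used to build the
#' object is stored in \code{metadata(x)$map}.
#'
#' @exportClass PhecodeExperiment
setClass("PhecodeExperiment", contains = "SummarizedExperiment")

setValidity("PhecodeExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "status") %in% an))
    return("assays 'counts' and 'status' are required")
  st <- assay(object, "status")
  if (!all(st %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "status values must be 0 (control), 1 (case) or NA (missing)")
  cn <- assay(object, "counts")
  if (any(cn < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(st == 1L & cn < 2L, na.rm = TRUE))
    msg <- c(msg, "cases require >= 2 distinct-date occurrences")
  need <- c("currentAge", "ehrAge", "sex", "race",
            "recordLength", "uniquePhecodeCount", "logUniquePhecodes")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn PhecodeMap-class Number of (vocabulary, code) entries.
#' @param x,object a \code{PhecodeMap}.
#' @export
setMethod("length", "PhecodeMap", function(x) nrow(x@table))

setMethod("show", "PhecodeMap", function(object) {
  cat("PhecodeMap:", nrow(object@table), "code entries ->",
      length(object@universe), "phecodes;",
      sum(lengths(object@exclusions) > 0), "with exclusion sets\n")
})

setMethod("show", "PhecodeExperiment", function(object) {
  callNextMethod()
  st <- assay(object, "status")
  cat(sprintf("status cells: %d case, %d control, %d missing\n",
              sum(st == 1L, na.rm = TRUE), sum(st == 0L, na.rm = TRUE),
              sum(is.na(st))))
})
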