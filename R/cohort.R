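#' @importFrom data.table data.table as.data.table setkey setkeyv fread fwrite
#'   := .N CJ setnames rbindlist copy
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "patientId", "vocabulary", "code", "date", "phecode", "n", ".N",
  "currentAge", "ehrAge", "sex", "race", "J"))

#' Read a code-event TSV
#'
#' Expected header: \code{patient_id  vocabulary  code  date} with ISO-8601
#' dates. Rows are deduplicated on (patient, vocabulary, code, date).
#'
#' @param path TSV path.
#' @return data.table with columns patientId, vocabulary, code, date (IDate).
#' @export
readCodeEvents <- function(path) {
  ev <- data.table::fread(path, sep = "\t", colClasses = list(character = 1:3),
                          showProgress = FALSE)
  need <- c("patient_id", "vocabulary", "code", "date")
  if (!all(need %in% names(ev)))
    stop("code-event file must have columns: ", paste(need, collapse = ", "))
  ev <- ev[, need, with = FALSE]
  setnames(ev, "patient_id", "patientId")
  if (!inherits(ev$date, "Date")) {
    d <- data.table::as.IDate(as.character(ev$date), format = "%Y-%m-%d")
    if (anyNA(d)) {
      bad <- which(is.na(d))[1]
      stop("unparseable ISO-8601 date at data row ", bad, ": '",
           ev$date[bad], "'")
    }
    ev[, date := d]
  } else ev[, date := data.table::as.IDate(date)]
  validateCodeEvents(ev)
  unique(ev)
}

validateCodeEvents <- function(ev) {
  if (anyNA(ev$date)) stop("code events contain missing dates")
  if (any(!nzchar(ev$code))) stop("code events contain empty codes")
  bad <- setdiff(unique(ev$vocabulary), c("ICD9", "ICD10"))
  if (length(bad))
    stop("unknown vocabulary value(s): ", paste(bad, collapse = ", "))
  invisible(ev)
}

#' Read a demographics TSV
#'
#' Expected header: \code{patient_id  current_age  ehr_age  sex  race}.
#' Missing sex/race become \code{"unknown"}; \code{ehr_age > current_age} is
#' rejected.
#'
#' @param path TSV path.
#' @return data.table with columns patientId, currentAge, ehrAge, sex, race.
#' @export
readDemographics <- function(path) {
  dm <- data.table::fread(path, sep = "\t", showProgress = FALSE)
  need <- c("patient_id", "current_age", "ehr_age", "sex", "race")
  if (!all(need %in% names(dm)))
    stop("demographics file must have columns: ", paste(need, collapse = ", "))
  dm <- dm[, need, with = FALSE]
  setnames(dm, c("patientId", "currentAge", "ehrAge", "sex", "race"))
  dm[, patientId := as.character(patientId)]
  if (anyDuplicated(dm$patientId)) stop("duplicate patient ids in demographics")
  for (col in c("sex", "race")) {
    v <- as.character(dm[[col]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    data.table::set(dm, j = col, value = v)
  }
  if (any(is.na(dm$currentAge) | dm$currentAge < 0))
    stop("current_age must be >= 0 and non-missing")
  if (any(is.na(dm$ehrAge) | dm$ehrAge < 0))
    stop("ehr_age must be >= 0 and non-missing")
  if (any(dm$ehrAge > dm$currentAge))
    stop("ehr_age may not exceed current_age")
  dm
}

#' Consolidate ICD code events into per-patient phecode occurrence counts
#'
#' Each mapped code event contributes through its own vocabulary's map entries
#' only. The count for a (patient, phecode) cell is the number of *distinct
#' calendar dates* on which any code mapping to the phecode occurred: two
#' different codes hitting the same phecode on the same day count once.
#' Unmapped codes are dropped; their tally is attached as attribute
#' \code{"unmapped"}.
#'
#' @param events data.table from \code{\link{readCodeEvents}} (or equivalent).
#' @param map a \linkS4class{PhecodeMap}.
#' @return data.table (patientId, phecode, n) with attribute \code{unmapped}.
#' @export
consolidatePhecodes <- function(events, map) {
  stopifnot(is(map, "PhecodeMap"))
  ev <- unique(as.data.table(events)[, .(patientId = as.character(patientId),
                                         vocabulary, code, date)])
  validateCodeEvents(ev)
  mp <- as.data.table(map@table)
  hit <- mp[ev, on = c("vocabulary", "code"), allow.cartesian = TRUE]
  unmapped <- sum(is.na(hit$phecode))
  hit <- hit[!is.na(phecode)]
  counts <- unique(hit[, .(patientId, phecode, date)])[
    , .(n = .N), by = .(patientId, phecode)]
  setkey(counts, patientId, phecode)
  attr(counts, "unmapped") <- unmapped
  counts
}

#' Assign case/control/missing status from occurrence counts
#'
#' A patient is a case for a phecode with >= 2 distinct-date occurrences,
#' missing with exactly 1, and otherwise a control unless any phecode in the
#' phecode's exclusion set occurred at least once, in which case the would-be
#' control is removed (missing). Exclusion removal never demotes a case.
#'
#' @param counts sparse or dense phecode-by-patient count matrix, or the long
#'   counts table from \code{\link{consolidatePhecodes}}.
#' @param map a \linkS4class{PhecodeMap}; phecodes present in \code{counts}
#'   but absent from the map universe are kept with empty exclusion sets.
#' @param patients optional character vector fixing the patient (column)
#'   universe when \code{counts} is a long table.
#' @return integer matrix (phecode x patient): 1 case, 0 control, NA missing.
#' @export
assignStatus <- function(counts, map, patients = NULL) {
  cm <- if (is.matrix(counts) || is(counts, "Matrix")) counts
        else countsMatrix(counts, map, patients)
  extra <- setdiff(rownames(cm), map@universe)
  if (length(extra))
    message(length(extra), " phecode(s) absent from the map universe kept ",
            "with empty exclusion sets")
  dn <- dimnames(cm)
  cm <- as.matrix(cm)
  status <- matrix(0L, nrow(cm), ncol(cm), dimnames = dn)
  status[cm == 1L] <- NA_integer_
  status[cm >= 2L] <- 1L
  present <- cm >= 1L
  for (p in intersect(names(map@exclusions), rownames(status))) {
    excl <- intersect(map@exclusions[[p]], rownames(present))
    if (!length(excl)) next
    hasExcl <- if (length(excl) == 1L) present[excl, ]
               else colSums(present[excl, , drop = FALSE]) > 0
    demote <- hasExcl & status[p, ] %in% 0L
    status[p, demote] <- NA_integer_
  }
  status
}

#' Build a phecode-by-patient count matrix from the long counts table
#'
#' @inheritParams assignStatus
#' @param counts long table (patientId, phecode, n).
#' @return sparse \code{dgCMatrix}, rows = union of map universe and observed
#'   phecodes, columns = patients.
#' @export
countsMatrix <- function(counts, map, patients = NULL) {
  counts <- as.data.table(counts)
  if (is.null(patients)) patients <- sort(unique(counts$patientId))
  phe <- sort(unique(c(map@universe, counts$phecode)))
  counts <- counts[patientId %in% patients]
  Matrix::sparseMatrix(
    i = match(counts$phecode, phe),
    j = match(counts$patientId, patients),
    x = counts$n,
    dims = c(length(phe), length(patients)),
    dimnames = list(phe, patients))
}

#' Derive per-patient analysis covariates
#'
#' \code{uniquePhecodeCount} counts phecodes with at least
#' \code{countThreshold} distinct-date occurrences (default 1, so
#' single-instance codes count toward burden); the log covariate is
#' \code{log(count + 1)} so zero-phecode patients are tolerated.
#' \code{recordLength} is last minus first code-event date in days (0 for a
#' single visit or no events).
#'
#' @param events code-event table (for record length).
#' @param demographics table from \code{\link{readDemographics}}.
#' @param counts phecode-by-patient count matrix.
#' @param countThreshold minimum occurrences for a phecode to count toward
#'   burden.
#' @return data.table keyed by patientId with all covariates; patients present
#'   in events but absent from demographics are excluded with a message.
#' @export
computeDemographicCovariates <- function(events, demographics, counts,
                                         countThreshold = 1L) {
  dm <- as.data.table(demographics)
  ev <- as.data.table(events)[, .(patientId = as.character(patientId), date)]
  orphan <- setdiff(unique(ev$patientId), dm$patientId)
  if (length(orphan))
    message(length(orphan),
            " patient(s) with events but no demographics excluded")
  span <- ev[patientId %in% dm$patientId,
             .(recordLength = as.integer(max(date) - min(date))),
             by = patientId]
  out <- span[dm, on = "patientId"]
  out[is.na(recordLength), recordLength := 0L]
  uc <- Matrix::colSums(counts >= countThreshold)
  out[, uniquePhecodeCount := as.integer(uc[patientId])]
  out[is.na(uniquePhecodeCount), uniquePhecodeCount := 0L]
  out[, logUniquePhecodes := log(uniquePhecodeCount + 1)]
  # modal reference level; "unknown" always retained as a level
  for (col in c("sex", "race")) {
    v <- as.character(out[[col]])
    lev <- names(sort(table(v), decreasing = TRUE))
    lev <- union(lev, "unknown")
    data.table::set(out, j = col, value = factor(v, levels = lev))
  }
  setkey(out, patientId)
  out[]
}

#' Build a PhecodeExperiment from raw inputs
#'
#' Runs consolidation, status assignment and covariate derivation, returning
#' the central container for all downstream fits. Patients are the columns
#' (everyone in \code{demographics}); phecodes the rows.
#'
#' @param events code-event table or TSV path.
#' @param demographics demographics table or TSV path.
#' @param map a \linkS4class{PhecodeMap} or path to its CSV.
#' @param countThreshold passed to
#'   \code{\link{computeDemographicCovariates}}.
#' @return a \linkS4class{PhecodeExperiment}.
#' @examples
#' map <- PhecodeMap(data.frame(vocabulary = "ICD9", code = c("295.00", "296.00"),
#'                              phecode = c("295.1", "296")))
#' ev <- data.frame(patient_id = "p1", vocabulary = "ICD9", code = "295.00",
#'                  date = as.Date(c("2001-01-01", "2001-02-01")))
#' names(ev)[1] <- "patient_id"
#' dm <- data.frame(patient_id = "p1", current_age = 40, ehr_age = 39,
#'                  sex = "female", race = "unknown")
#' pe <- phecodeExperiment(ev, dm, map)
#' statusMatrix(pe)["295.1", ]
#' @export
phecodeExperiment <- function(events, demographics, map, countThreshold = 1L) {
  if (is.character(map)) map <- readPhecodeMap(map)
  if (is.character(events)) events <- readCodeEvents(events)
  else {
    events <- as.data.table(events)
    if ("patient_id" %in% names(events)) setnames(events, "patient_id", "patientId")
    events[, patientId := as.character(patientId)]
    events[, date := data.table::as.IDate(date)]
    events <- unique(events[, .(patientId, vocabulary, code, date)])
    validateCodeEvents(events)
  }
  if (is.character(demographics)) demographics <- readDemographics(demographics)
  else {
    demographics <- as.data.table(demographics)
    if ("patient_id" %in% names(demographics))
      setnames(demographics,
               c("patient_id", "current_age", "ehr_age", "sex", "race"),
               c("patientId", "currentAge", "ehrAge", "sex", "race"))
    demographics[, patientId := as.character(patientId)]
  }
  patients <- demographics$patientId
  events <- events[patientId %in% patients]
  longCounts <- consolidatePhecodes(events, map)
  cm <- countsMatrix(longCounts, map, patients = patients)
  status <- assignStatus(cm, map)
  cov <- computeDemographicCovariates(events, demographics, cm,
                                      countThreshold = countThreshold)
  cov <- cov[J(patients), on = "patientId"]
  se <- SummarizedExperiment(
    assays = list(counts = as.matrix(cm), status = status),
    rowData = DataFrame(phecode = rownames(cm), row.names = rownames(cm)),
    colData = DataFrame(as.data.frame(cov), row.names = cov$patientId))
  metadata(se)$map <- map
  metadata(se)$unmapped <- attr(longCounts, "unmapped")
  new("PhecodeExperiment", se)
}

#' Accessors for PhecodeExperiment assays
#'
#' @param x a \linkS4class{PhecodeExperiment}.
#' @return \code{statusMatrix}: integer matrix (1 case / 0 control / NA
#'   missing); \code{occurrenceCounts}: distinct-date count matrix;
#'   \code{caseIds}: patient ids who are cases for \code{phecode}.
#' @export
statusMatrix <- function(x) assay(x, "status")

#' @rdname statusMatrix
#' @export
occurrenceCounts <- function(x) assay(x, "counts")

#' @rdname statusMatrix
#' @param phecode phecode string.
#' @export
caseIds <- function(x, phecode) {
  st <- statusMatrix(x)[phecode, ]
  names(st)[!is.na(st) & st == 1L]
}
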