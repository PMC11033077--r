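#' Construct a phecode map
#'
#' @param table data.frame with columns \code{vocabulary}, \code{code},
#'   \code{phecode}. Vocabulary must be \code{"ICD9"} or \code{"ICD10"}.
#' @param excludeRanges optional named character vector or list mapping a
#'   phecode to its exclusion range(s), each range written \code{"lo-hi"}
#'   (comma-separated for multiple ranges). Ranges are expanded against the
#'   numeric phecode universe of \code{table}.
#' @param exclusions optional named list of already-expanded exclusion sets
#'   (phecode -> character vector); overrides \code{excludeRanges}.
#' @return a \linkS4class{PhecodeMap}.
#' @examples
#' tab <- data.frame(vocabulary = "ICD9", code = "295.00", phecode = "295.1")
#' PhecodeMap(tab)
#' @export
PhecodeMap <- function(table, excludeRanges = NULL, exclusions = NULL) {
  stopifnot(is.data.frame(table))
  table <- as.data.frame(table)[, c("vocabulary", "code", "phecode")]
  table$vocabulary <- as.character(table$vocabulary)
  table$code <- as.character(table$code)
  table$phecode <- as.character(table$phecode)
  bad <- setdiff(unique(table$vocabulary), c("ICD9", "ICD10"))
  if (length(bad))
    stop("unknown vocabulary value(s): ", paste(bad, collapse = ", "))
  if (!nrow(table)) stop("empty phecode map")
  universe <- sort(unique(table$phecode))
  if (is.null(exclusions)) {
    exclusions <- expandExclusionRanges(excludeRanges, universe)
  } else {
    exclusions <- lapply(exclusions, as.character)
  }
  new("PhecodeMap", table = table, exclusions = exclusions, universe = universe)
}

#' Expand "lo-hi" exclusion ranges against a phecode universe
#'
#' A range covers every phecode in the universe whose numeric value lies in
#' \code{[lo, hi]}. The phecode itself is retained in its own expansion when
#' covered; this is harmless because a patient with any occurrence of the
#' phecode is never a would-be control for it.
#'
#' @param excludeRanges named character vector/list of range strings, possibly
#'   comma-separated; \code{NULL}, \code{NA} or empty entries yield empty sets.
#' @param universe character vector of phecodes.
#' @return named list phecode -> character vector of excluded phecodes.
#' @export
expandExclusionRanges <- function(excludeRanges, universe) {
  if (is.null(excludeRanges) || !length(excludeRanges)) return(list())
  num <- suppressWarnings(as.numeric(universe))
  out <- lapply(excludeRanges, function(r) {
    r <- as.character(r)
    if (!length(r) || all(is.na(r)) || !any(nzchar(trimws(r))))
      return(character())
    parts <- trimws(unlist(strsplit(r, ",", fixed = TRUE)))
    parts <- parts[nzchar(parts)]
    hit <- rep(FALSE, length(universe))
    for (p in parts) {
      lohi <- suppressWarnings(as.numeric(trimws(strsplit(p, "-", fixed = TRUE)[[1]])))
      if (length(lohi) == 1L) lohi <- c(lohi, lohi)
      if (length(lohi) != 2L || any(is.na(lohi)))
        stop("malformed exclusion range: '", p, "'")
      hit <- hit | (!is.na(num) & num >= lohi[1] & num <= lohi[2])
    }
    universe[hit]
  })
  names(out) <- names(excludeRanges)
  missing <- setdiff(names(out), universe)
  if (length(missing))
    warning("exclusion ranges given for phecodes outside the map universe: ",
            paste(missing, collapse = ", "))
  out[lengths(out) > 0]
}

#' Read a phecode map CSV (phecode 1.2 dialect)
#'
#' Columns are located by name, case-insensitively: the ICD code
#' (\code{code}/\code{icd*}), the vocabulary (\code{vocabulary}/
#' \code{vocabulary_id}/\code{flag}, where a flag of 9/10 means ICD-9/ICD-10),
#' the phecode (\code{phecode}), and optionally the exclusion range
#' (any column whose name contains \code{excl} and \code{range}, e.g.
#' \code{phecode_exclude_range}), written \code{"lo-hi"} with commas between
#' multiple ranges.
#'
#' @param path CSV file path.
#' @param vocabulary override vocabulary for single-vocabulary files that lack
#'   a vocabulary/flag column.
#' @return a \linkS4class{PhecodeMap}.
#' @export
readPhecodeMap <- function(path, vocabulary = NULL) {
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  nm <- tolower(names(dt))
  pick <- function(cands) {
    i <- which(nm %in% cands)
    if (length(i)) i[1] else NA_integer_
  }
  iCode <- pick(c("code", "icd", "icd9", "icd10", "icd_code"))
  iPhe <- pick(c("phecode", "phewas_code"))
  iVoc <- pick(c("vocabulary", "vocabulary_id", "flag"))
  iExc <- grep("excl", nm)
  iExc <- iExc[grepl("range|phecode", nm[iExc])]
  if (is.na(iCode) || is.na(iPhe))
    stop("could not locate code/phecode columns in ", path)
  voc <- if (!is.na(iVoc)) {
    v <- dt[[iVoc]]
    v <- ifelse(v %in% c("9", "ICD9", "ICD9CM", "icd9"), "ICD9",
         ifelse(v %in% c("10", "ICD10", "ICD10CM", "icd10"), "ICD10", v))
    v
  } else if (!is.null(vocabulary)) {
    rep(vocabulary, nrow(dt))
  } else stop("no vocabulary column found and no vocabulary override given")
  tab <- data.frame(vocabulary = voc, code = dt[[iCode]],
                    phecode = dt[[iPhe]], stringsAsFactors = FALSE)
  tab <- tab[nzchar(tab$phecode) & !is.na(tab$phecode), , drop = FALSE]
  ranges <- NULL
  if (length(iExc)) {
    r <- dt[[iExc[1]]][match(unique(tab$phecode), tab$phecode)]
    names(r) <- unique(tab$phecode)
    r <- r[!is.na(r) & nzchar(trimws(r))]
    if (length(r)) ranges <- r
  }
  PhecodeMap(tab, excludeRanges = ranges)
}

#' @rdname PhecodeMap
#' @param map a \code{PhecodeMap}.
#' @return \code{phecodeUniverse}: character vector of phecodes defined by the
#'   map.
#' @export
phecodeUniverse <- function(map) map@universe

#' @rdname PhecodeMap
#' @param phecode phecode string.
#' @return \code{phecodeExclusions}: character vector of phecodes excluded for
#'   \code{phecode} (empty if none).
#' @export
phecodeExclusions <- function(map, phecode) {
  e <- map@exclusions[[phecode]]
  if (is.null(e)) character() else e
}

#' Write a phecode map in the CSV dialect readPhecodeMap() accepts
#'
#' @param map a \linkS4class{PhecodeMap}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePhecodeMap <- function(map, path) {
  ranges <- vapply(map@universe, function(p) {
    e <- phecodeExclusions(map, p)
    if (!length(e)) return("")
    num <- suppressWarnings(as.numeric(e))
    if (any(is.na(num))) return("")
    paste0(min(num), "-", max(num))
  }, character(1))
  tab <- map@table
  tab$exclude_range <- ranges[tab$phecode]
  data.table::fwrite(tab, path, sep = ",")
  invisible(path)
}
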