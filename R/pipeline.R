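utils::globalVariables(c("pTostMeta"))

#' Validate pipeline input files
#'
#' Checks each file against its schema without running any analysis:
#' code events (column set, ISO dates), demographics (columns, age
#' invariants, no duplicates), score files (header, unique ids, finite
#' scores), PC tables and the phecode map. Diagnostics are capped at 100
#' messages.
#'
#' @param paths named list, per site: \code{events}, \code{demographics},
#'   \code{scores}, optionally \code{pcs}; plus top-level \code{map}.
#' @return data.frame (file, role, ok, message); attribute \code{ok} is the
#'   overall verdict.
#' @export
validateInputs <- function(paths) {
  res <- list()
  note <- function(file, role, ok, message = "") {
    res[[length(res) + 1L]] <<- data.frame(
      file = file, role = role, ok = ok,
      message = substr(message, 1, 500), stringsAsFactors = FALSE)
  }
  check <- function(file, role, reader) {
    if (is.null(file)) return()
    out <- tryCatch({ reader(file); NULL }, error = function(e) conditionMessage(e))
    note(file, role, is.null(out), if (is.null(out)) "" else out)
  }
  check(paths$map, "map", readPhecodeMap)
  for (s in setdiff(names(paths), c("map", "truth"))) {
    p <- paths[[s]]
    check(p$events, paste0(s, ":events"), readCodeEvents)
    check(p$demographics, paste0(s, ":demographics"), readDemographics)
    check(p$scores, paste0(s, ":scores"), readScoreFile)
    check(p$pcs, paste0(s, ":pcs"), readPcs)
  }
  out <- do.call(rbind, res)
  if (nrow(out) > 100L) out <- out[seq_len(100L), ]
  attr(out, "ok") <- all(out$ok)
  out
}

#' Run the full analysis on in-memory site bundles
#'
#' Sequences the stages: cohort construction, per-site phenome comorbidity
#' scan, cross-site combination with Bonferroni control, per-site PRS
#' PheWAS, inverse-variance-weighted meta-analysis, TOST equivalence with
#' Fisher combination over the significant comorbidities that have PRS
#' results at every site, and tier classification.
#'
#' @param sites named list; each element a list with \code{events},
#'   \code{demographics}, \code{scores}, optionally \code{pcs}
#'   (data.frames or file paths).
#' @param map a \linkS4class{PhecodeMap} or path.
#' @param indexPhecode index phecode string.
#' @param alpha family-wise error rate used throughout.
#' @param minCases minimum case count per fit.
#' @param rule direction-combination rule.
#' @param bounds TOST equivalence bounds in Cohen's d units.
#' @param excludeIndexCases drop index cases from the PRS analyses.
#' @param nPcs principal components used when PC tables are supplied.
#' @return list: \code{cohorts} (PhecodeExperiments), \code{scan} (per-site
#'   comorbidity), \code{combined}, \code{prsSite}, \code{prsMeta},
#'   \code{tost} (perSite + meta), \code{verdicts}, \code{thresholds}.
#' @export
runStudyAnalysis <- function(sites, map, indexPhecode = "295.1",
                             alpha = 0.05, minCases = 20L, rule = "mean",
                             bounds = c(-0.2, 0.2),
                             excludeIndexCases = TRUE, nPcs = 10L) {
  if (is.character(map)) map <- readPhecodeMap(map)
  cohorts <- lapply(sites, function(b)
    phecodeExperiment(b$events, b$demographics, map))
  scan <- rbindlist(lapply(names(cohorts), function(s)
    runPhenomeScan(cohorts[[s]], indexPhecode, site = s, rule = rule,
                   minCases = minCases)))
  combined <- combineSites(scan, alpha = alpha)
  prsSite <- do.call(rbind, lapply(names(cohorts), function(s) {
    b <- sites[[s]]
    scores <- if (is.character(b$scores)) readScoreFile(b$scores)
              else as.data.table(b$scores)
    if ("patient_id" %in% names(scores))
      setnames(scores, "patient_id", "patientId")
    pcs <- if (is.null(b$pcs)) NULL
           else if (is.character(b$pcs)) readPcs(b$pcs, nPcs)
           else {
             p <- as.data.table(b$pcs)
             if ("patient_id" %in% names(p)) setnames(p, "patient_id", "patientId")
             p
           }
    prsPhewas(cohorts[[s]], scores, pcs = pcs,
              indexPhecode = indexPhecode,
              excludeIndexCases = excludeIndexCases,
              nPcs = if (is.null(pcs)) 0L else nPcs,
              site = s, minCases = minCases)
  }))
  prsMeta <- ivwMeta(prsSite)
  # TOST universe: significant comorbidities with converged PRS results at
  # every site (the both-site requirement of the meta design)
  sigPhe <- combined[significant == TRUE, phecodeB]
  prsDT <- as.data.table(prsSite)
  bothSites <- prsDT[converged == TRUE, .N, by = phecode][
    N == length(cohorts), phecode]
  tostPhe <- intersect(sigPhe, bothSites)
  tost <- if (length(tostPhe))
    tostMeta(prsDT[phecode %in% tostPhe], bounds = bounds, alpha = alpha)
  else list(perSite = NULL,
            meta = data.table(phecode = character(), chi2 = numeric(),
                              df = integer(), pMeta = numeric(),
                              nSites = integer(), equivalent = logical()))
  verdicts <- assignTiers(combined, prsMeta, tost$meta, alpha = alpha)
  list(cohorts = cohorts, scan = scan, combined = combined,
       prsSite = prsSite, prsMeta = prsMeta, tost = tost,
       verdicts = verdicts,
       thresholds = list(
         comorbidity = attr(combined, "threshold"),
         comorbidityNTests = attr(combined, "nTests"),
         equivalence = attr(tost$meta, "threshold"),
         equivalenceNTests = attr(tost$meta, "nTests"),
         alpha = alpha, bounds = bounds))
}

.writeStage <- function(dt, path, provenance) {
  if (is.null(dt)) dt <- data.table()
  writeLines(paste0("# ", provenance), path)
  dt <- as.data.table(dt)
  if (ncol(dt))
    data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Run the pipeline from input files and write every stage table
#'
#' Reads and validates all inputs, runs \code{\link{runStudyAnalysis}} and
#' writes the stage outputs (site comorbidity, combined comorbidity,
#' per-site and meta PRS associations, per-site and meta equivalence,
#' verdicts) as TSVs whose first line is a provenance comment carrying the
#' package version, a config hash and the thresholds used, plus a JSON tier
#' summary. Reruns with identical inputs and config are byte-identical.
#'
#' @param config list: \code{sites} (named list of per-site paths:
#'   events/demographics/scores/pcs), \code{map} path, \code{indexPhecode},
#'   \code{outDir}, and optionally \code{alpha}, \code{minCases},
#'   \code{rule}, \code{bounds}, \code{excludeIndexCases}, \code{nPcs}.
#'   Unknown keys are rejected.
#' @return the \code{\link{runStudyAnalysis}} result, invisibly, with
#'   \code{files} listing the written outputs.
#' @export
runPipeline <- function(config) {
  known <- c("sites", "map", "indexPhecode", "outDir", "alpha", "minCases",
             "rule", "bounds", "excludeIndexCases", "nPcs")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  for (k in c("sites", "map", "outDir"))
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  paths <- config$sites
  paths$map <- config$map
  v <- validateInputs(paths)
  if (!attr(v, "ok")) {
    bad <- v[!v$ok, , drop = FALSE]
    stop("input validation failed:\n",
         paste0("  ", bad$role, ": ", bad$message, collapse = "\n"))
  }
  res <- runStudyAnalysis(
    config$sites, config$map,
    indexPhecode = config$indexPhecode %||% "295.1",
    alpha = config$alpha %||% 0.05,
    minCases = config$minCases %||% 20L,
    rule = config$rule %||% "mean",
    bounds = config$bounds %||% c(-0.2, 0.2),
    excludeIndexCases = config$excludeIndexCases %||% TRUE,
    nPcs = config$nPcs %||% 10L)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  cfgCopy <- config
  cfgCopy$outDir <- NULL
  hash <- .configHash(cfgCopy)
  prov <- sprintf(paste0(
    "equicomorb %s | config=%s | alpha=%s | comorbidity_threshold=%s ",
    "(n=%s) | equivalence_threshold=%s (n=%s) | bounds=%s"),
    as.character(utils::packageVersion("equicomorb")), hash,
    res$thresholds$alpha,
    signif(res$thresholds$comorbidity, 3), res$thresholds$comorbidityNTests,
    signif(res$thresholds$equivalence %||% NA_real_, 3),
    res$thresholds$equivalenceNTests %||% 0L,
    paste(res$thresholds$bounds, collapse = ","))
  od <- config$outDir
  files <- c(
    .writeStage(res$scan, file.path(od, "comorbidity_site.tsv"), prov),
    .writeStage(res$combined, file.path(od, "comorbidity_combined.tsv"), prov),
    .writeStage(res$prsSite, file.path(od, "prs_site.tsv"), prov),
    .writeStage(res$prsMeta, file.path(od, "prs_meta.tsv"), prov),
    .writeStage(res$tost$perSite, file.path(od, "tost_site.tsv"), prov),
    .writeStage(res$tost$meta, file.path(od, "tost_meta.tsv"), prov),
    .writeStage(res$verdicts, file.path(od, "verdicts.tsv"), prov))
  tiers <- as.list(attr(res$verdicts, "tierCounts"))
  jsonlite::write_json(
    list(provenance = prov, thresholds = res$thresholds,
         tierCounts = tiers),
    file.path(od, "tier_summary.json"), auto_unbox = TRUE, digits = NA)
  res$files <- c(files, file.path(od, "tier_summary.json"))
  res$configHash <- hash
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids extra digest dependencies
  h <- 0
  for (ch in utf8ToInt(as.character(s)))
    h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
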