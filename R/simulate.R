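#' @importFrom stats rlnorm
NULL

utils::globalVariables(c("liability", "uz", "k", "offset", "start",
                         "interval", "idx", "classLabel", "g", "b", "span",
                         "first"))

#' Default synthetic-study configuration
#'
#' Two health-system sites of 20,000 patients each, a standard-normal
#' polygenic score, a liability-threshold index disorder (coded prevalence
#' 2\%, 20\% of liability variance from the score), and 40 comorbid
#' phenotypes in four ground-truth classes of ten: \emph{genetic}
#' (score loading g = 0.15 on the phenotype logit), \emph{consequence}
#' (log-odds increment c = 1.0 per index-case status, no score loading),
#' \emph{mixed} (both), and \emph{null} (neither). Every phenotype carries a
#' utilization loading b = 0.2 so the log-unique-phecode covariate has a
#' real confounder to absorb, and site 2 gets a +0.1 intercept shift.
#' Phenotype prevalences cycle over \{0.05, 0.08, 0.12, 0.15\}. Four decoy
#' phecodes sit inside exclusion ranges of the first four phenotypes to
#' exercise control-removal.
#'
#' @param seed base seed; each site draws from its own stream derived from
#'   (seed, site index).
#' @param nPatients patients per site.
#' @param nPerClass phenotypes per ground-truth class.
#' @param indexPrevalence coded prevalence of the index disorder.
#' @param h2Score share of index liability variance carried by the score.
#' @param g,cCoupling,b genetic, consequence and utilization loadings.
#' @param siteShift site-2 intercept shift (log-odds).
#' @param singleInstanceRate probability that a non-case emits exactly one
#'   code event (exercising the missing rule).
#' @param nBackground utilization-driven background phecodes. A real phenome
#'   holds on the order of a thousand codes, so any single pair contributes
#'   negligibly to a patient's total unique-phecode burden; without a
#'   background phenome the burden covariate would condition on a sum
#'   dominated by the tested pair itself (a collider). Background codes
#'   (class \code{"background"}: g = 0, c = 0, strong utilization loading)
#'   restore that regime and give the burden covariate its real confounder
#'   to absorb.
#' @param backgroundPrevalence,backgroundUtilLoading prevalence and
#'   utilization log-odds loading of the background codes.
#' @return a config list (class \code{simConfig}).
#' @export
defaultSimConfig <- function(seed = 1L, nPatients = 20000L, nPerClass = 10L,
                             indexPrevalence = 0.02, h2Score = 0.2,
                             g = 0.15, cCoupling = 1.0, b = 0.2,
                             siteShift = 0.1, singleInstanceRate = 0.03,
                             nBackground = 100L, backgroundPrevalence = 0.08,
                             backgroundUtilLoading = 1.2) {
  nPhen <- 4L * nPerClass
  classes <- rep(c("genetic", "consequence", "mixed", "null"),
                 each = nPerClass)
  phen <- data.frame(
    phecode = sprintf("%03d.1", 100L + seq_len(nPhen)),
    prevalence = rep(c(0.05, 0.08, 0.12, 0.15), length.out = nPhen),
    g = ifelse(classes %in% c("genetic", "mixed"), g, 0),
    c = ifelse(classes %in% c("consequence", "mixed"), cCoupling, 0),
    b = b,
    class = classes,
    stringsAsFactors = FALSE)
  if (nBackground > 0L) {
    bg <- data.frame(
      phecode = sprintf("%03d.9", 500L + seq_len(nBackground)),
      prevalence = backgroundPrevalence,
      g = 0, c = 0, b = backgroundUtilLoading,
      class = "background", stringsAsFactors = FALSE)
    phen <- rbind(phen, bg)
  }
  structure(list(
    seed = as.integer(seed), nPatients = as.integer(nPatients),
    nSites = 2L, indexPhecode = "295.1",
    indexPrevalence = indexPrevalence, h2Score = h2Score,
    phenotypes = phen, siteShift = siteShift,
    singleInstanceRate = singleInstanceRate,
    ageEffect = 0.01, meanVisitYears = 8,
    decoyPhecodes = sprintf("%05.1f", 900 + seq_len(4) / 10),
    decoyRate = 0.05, nPcs = 10L), class = "simConfig")
}

#' Ground-truth table of a configuration
#'
#' @param config a \code{simConfig}.
#' @return data.frame phecode, g, c, b, class; the class label is derivable
#'   from (g, c): genetic iff g != 0 & c == 0, consequence iff g == 0 &
#'   c != 0, mixed iff both, null iff neither.
#' @export
groundTruth <- function(config) {
  config$phenotypes[, c("phecode", "g", "c", "b", "class")]
}

#' Toy ICD-to-phecode map matching the generator's vocabulary
#'
#' Every phecode (index, phenotypes, decoys) gets two ICD-9 and two ICD-10
#' codes. Each of the first four phenotypes carries an exclusion range
#' covering its decoy phecode; the decoys are numerically adjacent
#' (phenotype k excludes 900.k via a range).
#'
#' @param config a \code{simConfig}.
#' @return a \linkS4class{PhecodeMap}.
#' @export
simPhecodeMap <- function(config) {
  phe <- c(config$indexPhecode, config$phenotypes$phecode,
           config$decoyPhecodes)
  tab <- do.call(rbind, lapply(phe, function(p) data.frame(
    vocabulary = c("ICD9", "ICD9", "ICD10", "ICD10"),
    code = paste0(c("9A-", "9B-", "10A-", "10B-"), p),
    phecode = p, stringsAsFactors = FALSE)))
  nDecoy <- length(config$decoyPhecodes)
  ranges <- setNames(
    vapply(seq_len(nDecoy), function(k) {
      d <- as.numeric(config$decoyPhecodes[k])
      paste0(d - 0.05, "-", d + 0.05)
    }, character(1)),
    config$phenotypes$phecode[seq_len(nDecoy)])
  PhecodeMap(tab, excludeRanges = ranges)
}

# Distinct-date event emitter: k dates per (patient, phecode) cell, spaced by
# random positive intervals so distinctness is guaranteed by construction.
.emitEvents <- function(patientId, phecode, k, firstDate, spanDays) {
  if (!length(patientId)) return(NULL)
  cell <- data.table(patientId = rep(patientId, k),
                     phecode = rep(phecode, sum(k)),
                     first = rep(firstDate, k),
                     span = rep(spanDays, k),
                     idx = unlist(lapply(k, seq_len)))
  cell[, start := floor(runif(.N) * pmax(1, span / 2))]
  cell[, interval := 1L + rpois(.N, 45)]
  # cumulative spacing within each cell via the per-event index
  cell[, offset := start + (idx - 1L) * interval]
  vocab <- sample(c("ICD9", "ICD10"), nrow(cell), replace = TRUE)
  ab <- sample(c("A", "B"), nrow(cell), replace = TRUE)
  data.table(
    patientId = cell$patientId,
    vocabulary = vocab,
    code = paste0(ifelse(vocab == "ICD9", "9", "10"), ab, "-", cell$phecode),
    date = cell$first + cell$offset)
}

#' Generate one synthetic site
#'
#' Scores are N(0,1); index liability is
#' \code{sqrt(h2) * score + sqrt(1 - h2) * noise} with the threshold set by
#' the target prevalence. Each phenotype's logit is
#' \code{intercept + g*score + c*1(index case) + b*utilization +
#' ageEffect*(age-50)/10 + siteShift*1(site 2)}. Cases emit >= 2 code events
#' on distinct dates; non-cases emit exactly one event at the
#' single-instance rate; decoy phecodes are sprinkled independently.
#'
#' @param config a \code{simConfig}.
#' @param site site index (1-based); the site's random stream is derived
#'   from \code{(seed, site)}.
#' @return list(events, demographics, scores, pcs) of data.tables in the
#'   pipeline's input schemas (ground truth is *not* included; see
#'   \code{\link{groundTruth}}).
#' @export
simulateSite <- function(config, site = 1L) {
  set.seed((as.numeric(config$seed) * 1000 + site) %% 2147483647)
  n <- config$nPatients
  id <- sprintf("S%d_%06d", site, seq_len(n))
  score <- rnorm(n)
  pcs <- matrix(rnorm(n * config$nPcs), n, config$nPcs,
                dimnames = list(NULL, paste0("PC", seq_len(config$nPcs))))
  currentAge <- round(runif(n, 18, 90))
  ehrAge <- pmax(18, currentAge - round(rexp(n, rate = 0.5)))
  sex <- sample(c("female", "male", "unknown"), n, TRUE,
                prob = c(0.49, 0.48, 0.03))
  race <- sample(c("White", "Black", "Asian", "Native American/Alaskan",
                   "Pacific Islander", "Other", "unknown"), n, TRUE,
                 prob = c(0.62, 0.16, 0.05, 0.01, 0.01, 0.05, 0.10))
  util <- rlnorm(n, meanlog = 0, sdlog = 0.6)
  uz <- as.numeric(scale(log(util)))
  firstDate <- data.table::as.IDate("2000-01-01") + sample.int(3000L, n, TRUE)
  spanDays <- pmax(30L, as.integer(round(
    config$meanVisitYears * 365 * util / mean(util))))

  h2 <- config$h2Score
  liability <- sqrt(h2) * score + sqrt(1 - h2) * rnorm(n)
  thr <- qnorm(1 - config$indexPrevalence)
  indexCase <- liability > thr

  phen <- config$phenotypes
  siteEff <- if (site >= 2L) config$siteShift else 0
  yMat <- matrix(FALSE, n, nrow(phen))
  for (j in seq_len(nrow(phen))) {
    eta <- qlogis(phen$prevalence[j]) + phen$g[j] * score +
      phen$c[j] * indexCase + phen$b[j] * uz +
      config$ageEffect * (currentAge - 50) / 10 + siteEff
    yMat[, j] <- runif(n) < plogis(eta)
  }

  events <- list()
  emitFor <- function(mask, phecode) {
    if (!any(mask)) return(NULL)
    kk <- 2L + rpois(sum(mask), 1)
    .emitEvents(id[mask], phecode, kk, firstDate[mask], spanDays[mask])
  }
  singleFor <- function(mask, phecode) {
    one <- mask & (runif(n) < config$singleInstanceRate)
    if (!any(one)) return(NULL)
    .emitEvents(id[one], phecode, rep(1L, sum(one)), firstDate[one],
                spanDays[one])
  }
  events[[length(events) + 1L]] <- emitFor(indexCase, config$indexPhecode)
  events[[length(events) + 1L]] <- singleFor(!indexCase, config$indexPhecode)
  for (j in seq_len(nrow(phen))) {
    events[[length(events) + 1L]] <- emitFor(yMat[, j], phen$phecode[j])
    events[[length(events) + 1L]] <- singleFor(!yMat[, j], phen$phecode[j])
  }
  for (d in config$decoyPhecodes) {
    hit <- runif(n) < config$decoyRate
    if (any(hit)) {
      kk <- 1L + rpois(sum(hit), 0.5)
      events[[length(events) + 1L]] <-
        .emitEvents(id[hit], d, kk, firstDate[hit], spanDays[hit])
    }
  }
  ev <- rbindlist(events)
  setkey(ev, patientId, code, date)
  ev <- unique(ev)

  list(
    events = ev[, .(patient_id = patientId, vocabulary, code,
                    date = as.character(date))],
    demographics = data.table(patient_id = id, current_age = currentAge,
                              ehr_age = ehrAge, sex = sex, race = race),
    scores = data.table(patient_id = id, score = score),
    pcs = data.table(patient_id = id, as.data.table(pcs)))
}

#' Generate the full multi-site synthetic study
#'
#' @param config a \code{simConfig} from \code{\link{defaultSimConfig}}.
#' @return list: \code{sites} (named list of per-site input bundles),
#'   \code{map} (the toy \linkS4class{PhecodeMap}), \code{truth} (ground
#'   truth; never written into any pipeline input), \code{config}.
#' @export
simulateStudy <- function(config = defaultSimConfig()) {
  sites <- lapply(seq_len(config$nSites), function(s) simulateSite(config, s))
  names(sites) <- paste0("site", seq_len(config$nSites))
  list(sites = sites, map = simPhecodeMap(config),
       truth = groundTruth(config), config = config)
}

#' Write a generated study to disk as pipeline input files
#'
#' Emits, per site, \code{events.tsv}, \code{demographics.tsv},
#' \code{scores.tsv} and \code{pcs.tsv}, plus \code{phecode_map.csv} and
#' \code{ground_truth.tsv} at the top level. All files are the exact formats
#' the package's readers accept; ground truth never appears in any input
#' file.
#'
#' @param study output of \code{\link{simulateStudy}} (or a \code{simConfig},
#'   which is generated first).
#' @param dir output directory (created if needed).
#' @return named list of per-site input paths plus \code{map} and
#'   \code{truth} paths, invisibly.
#' @export
makeBenchmark <- function(study = defaultSimConfig(), dir) {
  if (inherits(study, "simConfig")) study <- simulateStudy(study)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in names(study$sites)) {
    sd <- file.path(dir, s)
    dir.create(sd, showWarnings = FALSE)
    b <- study$sites[[s]]
    fwrite(b$events, file.path(sd, "events.tsv"), sep = "\t")
    fwrite(b$demographics, file.path(sd, "demographics.tsv"), sep = "\t")
    fwrite(b$scores, file.path(sd, "scores.tsv"), sep = "\t")
    fwrite(b$pcs, file.path(sd, "pcs.tsv"), sep = "\t")
    paths[[s]] <- list(events = file.path(sd, "events.tsv"),
                       demographics = file.path(sd, "demographics.tsv"),
                       scores = file.path(sd, "scores.tsv"),
                       pcs = file.path(sd, "pcs.tsv"))
  }
  paths$map <- file.path(dir, "phecode_map.csv")
  writePhecodeMap(study$map, paths$map)
  paths$truth <- file.path(dir, "ground_truth.tsv")
  fwrite(study$truth, paths$truth, sep = "\t")
  invisible(paths)
}
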