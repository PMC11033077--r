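utils::globalVariables(c("score", "metaBeta", "metaSe", "metaP", "w",
                         "nCase", "nControl", "vePct"))

#' Read a per-individual polygenic score file
#'
#' Accepts a plain TSV \code{patient_id  score} or a PLINK-style score output
#' (whitespace-delimited with columns such as \code{FID IID ... SCORESUM} or
#' \code{SCORE}); columns are detected by header. Scores are taken as-is and
#' standardized later, within each analysis sample.
#'
#' @param path file path.
#' @return data.table (patientId, score).
#' @export
readScoreFile <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  nm <- toupper(names(dt))
  if (all(c("PATIENT_ID", "SCORE") %in% nm)) {
    out <- data.table(patientId = as.character(dt[[which(nm == "PATIENT_ID")]]),
                      score = as.numeric(dt[[which(nm == "SCORE")]]))
  } else if ("IID" %in% nm) {
    sc <- intersect(c("SCORESUM", "SCORE1_SUM", "SCORE", "SCORE1_AVG"), nm)
    if (!length(sc)) stop("no score column found in PLINK-style file ", path)
    out <- data.table(patientId = as.character(dt[[which(nm == "IID")]]),
                      score = as.numeric(dt[[which(nm == sc[1])]]))
  } else stop("unrecognized score file header in ", path)
  if (anyDuplicated(out$patientId)) stop("duplicate patient ids in score file")
  if (any(!is.finite(out$score))) stop("non-finite scores in ", path)
  out
}

#' Read an ancestry principal-components TSV
#'
#' Header \code{patient_id PC1 ... PCk}.
#'
#' @param path file path.
#' @param nPcs number of PCs required (default 10).
#' @return data.table (patientId, PC1..PCk).
#' @export
readPcs <- function(path, nPcs = 10L) {
  dt <- data.table::fread(path, showProgress = FALSE)
  pcs <- paste0("PC", seq_len(nPcs))
  if (!all(c("patient_id", pcs) %in% names(dt)))
    stop("PC file must have columns patient_id, ", paste(pcs, collapse = ", "))
  out <- dt[, c("patient_id", pcs), with = FALSE]
  setnames(out, "patient_id", "patientId")
  out[, patientId := as.character(patientId)]
  out
}

# Nagelkerke pseudo-R2 of a glm fit relative to an intercept-only model.
.nagelkerke <- function(fit) {
  n <- length(fit$y)
  cs <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  mx <- 1 - exp(-fit$null.deviance / n)
  if (mx <= 0) return(0)
  cs / mx
}

#' Logistic PRS association for one phecode (one site)
#'
#' Fits case vs control status on the polygenic score (standardized to mean
#' 0, SD 1 within the analysis sample) plus covariates: sex, current age, the
#' first \code{nPcs} ancestry principal components and record length. Index-
#' disorder cases are removed from both cases and controls by default, so
#' associations reflect genetic effects independent of the index diagnosis.
#' Exclusion-range handling is inherited from the status matrix. Variance
#' explained is the Nagelkerke pseudo-R2 difference between the full and the
#' covariate-only model, in percent.
#'
#' @param pe a \linkS4class{PhecodeExperiment}.
#' @param prs data.table (patientId, score) as from
#'   \code{\link{readScoreFile}}.
#' @param phecode phecode to test.
#' @param pcs optional data.table (patientId, PC1..PCk).
#' @param indexPhecode index phecode whose cases are removed when
#'   \code{excludeIndexCases}.
#' @param excludeIndexCases remove index cases (default TRUE).
#' @param covariates colData columns used alongside the PCs.
#' @param nPcs number of PCs used (0 if \code{pcs} is NULL).
#' @param site site label.
#' @param minCases minimum case count; below it the fit is skipped.
#' @return one-row data.frame: phecode, site, beta (log-odds per SD of
#'   score), se, z, p, nCase, nControl, vePct, converged, reason, the
#'   case/control score summaries (caseN, caseMean, caseSd, controlN,
#'   controlMean, controlSd) for downstream equivalence testing, and the
#'   standardization parameters (scoreCenter, scoreScale).
#' @export
fitPrsAssociation <- function(pe, prs, phecode, pcs = NULL,
                              indexPhecode = NULL, excludeIndexCases = TRUE,
                              covariates = c("sex", "currentAge",
                                             "recordLength"),
                              nPcs = if (is.null(pcs)) 0L else 10L,
                              site = "site1", minCases = 20L) {
  st <- statusMatrix(pe)
  y <- st[phecode, ]
  if (excludeIndexCases) {
    if (is.null(indexPhecode))
      stop("indexPhecode required when excludeIndexCases = TRUE")
    idx <- st[indexPhecode, ]
    y[!is.na(idx) & idx == 1L] <- NA_integer_
  }
  prs <- as.data.table(prs)
  dat <- data.frame(as.data.frame(colData(pe))[, covariates, drop = FALSE],
                    .y = y)
  dat$score <- prs$score[match(rownames(dat), prs$patientId)]
  if (nPcs > 0L) {
    pcs <- as.data.table(pcs)
    pcCols <- paste0("PC", seq_len(nPcs))
    dat[pcCols] <- as.data.frame(pcs[match(rownames(dat), pcs$patientId),
                                     pcCols, with = FALSE])
  } else pcCols <- character()
  dat <- dat[!is.na(dat$.y) & is.finite(dat$score) &
               complete.cases(dat), , drop = FALSE]
  n1 <- sum(dat$.y == 1L); n0 <- sum(dat$.y == 0L)
  base <- data.frame(phecode = phecode, site = site, beta = NA_real_,
                     se = NA_real_, z = NA_real_, p = NA_real_,
                     nCase = n1, nControl = n0, vePct = NA_real_,
                     converged = FALSE, reason = "",
                     caseN = n1, caseMean = NA_real_, caseSd = NA_real_,
                     controlN = n0, controlMean = NA_real_,
                     controlSd = NA_real_,
                     scoreCenter = NA_real_, scoreScale = NA_real_,
                     stringsAsFactors = FALSE)
  if (n1 < minCases || n0 < minCases) {
    base$reason <- "too_few_cases"; return(base)
  }
  if (sd(dat$score) == 0) {
    base$reason <- "constant_score"; return(base)
  }
  ctr <- mean(dat$score); scl <- sd(dat$score)
  dat$score <- (dat$score - ctr) / scl
  base$scoreCenter <- ctr; base$scoreScale <- scl
  base$caseMean <- mean(dat$score[dat$.y == 1L])
  base$caseSd <- sd(dat$score[dat$.y == 1L])
  base$controlMean <- mean(dat$score[dat$.y == 0L])
  base$controlSd <- sd(dat$score[dat$.y == 0L])
  for (cv in covariates)
    if (is.factor(dat[[cv]]) && length(unique(dat[[cv]])) < 2L)
      dat[[cv]] <- NULL
  rhs <- c("score", intersect(covariates, names(dat)), pcCols)
  form <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  res <- .safeLogistic(form, dat, "score")
  if (!res$converged) {
    base$reason <- res$reason; return(base)
  }
  nullForm <- as.formula(paste(".y ~",
    paste(c(intersect(covariates, names(dat)), pcCols, "1"), collapse = " + ")))
  nullFit <- suppressWarnings(glm(nullForm, data = dat, family = binomial()))
  base$beta <- res$beta; base$se <- res$se
  base$z <- res$beta / res$se
  base$p <- zToP(base$z)
  base$vePct <- 100 * max(0, .nagelkerke(res$fit) - .nagelkerke(nullFit))
  base$converged <- TRUE
  base
}

#' PRS PheWAS across a set of phecodes (one site)
#'
#' @inheritParams fitPrsAssociation
#' @param phecodes phecodes to test; default: all phecodes with at least
#'   \code{minCases} cases in the (index-excluded) sample.
#' @return data.frame, one row per phecode, as in
#'   \code{\link{fitPrsAssociation}}.
#' @export
prsPhewas <- function(pe, prs, pcs = NULL, phecodes = NULL,
                      indexPhecode = NULL, excludeIndexCases = TRUE,
                      covariates = c("sex", "currentAge", "recordLength"),
                      nPcs = if (is.null(pcs)) 0L else 10L,
                      site = "site1", minCases = 20L) {
  if (is.null(phecodes)) {
    st <- statusMatrix(pe)
    if (excludeIndexCases && !is.null(indexPhecode)) {
      idx <- st[indexPhecode, ]
      st[, !is.na(idx) & idx == 1L] <- NA_integer_
    }
    nc <- rowSums(st == 1L, na.rm = TRUE)
    phecodes <- rownames(st)[nc >= minCases]
    phecodes <- setdiff(phecodes, indexPhecode)
  }
  out <- lapply(sort(phecodes), function(ph)
    fitPrsAssociation(pe, prs, ph, pcs = pcs, indexPhecode = indexPhecode,
                      excludeIndexCases = excludeIndexCases,
                      covariates = covariates, nPcs = nPcs, site = site,
                      minCases = minCases))
  do.call(rbind, out)
}

#' Fixed-effect inverse-variance-weighted meta-analysis of PRS associations
#'
#' Per phecode, over converged site results:
#' \code{metaBeta = sum(beta_i/se_i^2) / sum(1/se_i^2)},
#' \code{metaSe = (sum(1/se_i^2))^(-1/2)}, with a Wald p from the normal.
#' Single-site phecodes pass through flagged; phecodes with no converged site
#' are reported untestable (all meta fields NA).
#'
#' @param siteResults rbind of per-site \code{\link{prsPhewas}} outputs.
#' @return data.table, one row per phecode: metaBeta, metaSe, metaZ, metaP,
#'   nSites, singleSite, plus total case/control counts and the
#'   sample-size-weighted mean vePct.
#' @export
ivwMeta <- function(siteResults) {
  dt <- as.data.table(siteResults)
  dt[, {
    ok <- converged & is.finite(beta) & is.finite(se) & se > 0
    if (!any(ok)) {
      list(metaBeta = NA_real_, metaSe = NA_real_, metaZ = NA_real_,
           metaP = NA_real_, nSites = 0L, singleSite = FALSE,
           nCaseTotal = sum(nCase), nControlTotal = sum(nControl),
           vePct = NA_real_)
    } else {
      w <- 1 / se[ok]^2
      mb <- sum(beta[ok] * w) / sum(w)
      ms <- sqrt(1 / sum(w))
      nTot <- nCase[ok] + nControl[ok]
      list(metaBeta = mb, metaSe = ms, metaZ = mb / ms,
           metaP = zToP(mb / ms), nSites = sum(ok),
           singleSite = sum(ok) == 1L,
           nCaseTotal = sum(nCase[ok]), nControlTotal = sum(nControl[ok]),
           vePct = sum(vePct[ok] * nTot) / sum(nTot))
    }
  }, by = phecode][order(phecode)]
}
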