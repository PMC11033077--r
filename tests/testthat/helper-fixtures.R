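suppressPackageStartupMessages({
  library(data.table)
})

# Tiny map: three ordinary phecodes, one with an exclusion range covering a
# neighbour, built fresh per call.
tinyMap <- function() {
  tab <- data.frame(
    vocabulary = c("ICD9", "ICD9", "ICD9", "ICD10", "ICD9", "ICD9"),
    code = c("295.00", "295.01", "296.00", "F30.1", "297.00", "298.00"),
    phecode = c("295.1", "295.1", "296", "296", "297", "298"),
    stringsAsFactors = FALSE)
  PhecodeMap(tab, excludeRanges = c("296" = "297-298"))
}

tinyEvents <- function() {
  data.table(
    patientId = c("p1", "p1", "p1", "p2", "p2", "p3", "p4"),
    vocabulary = c("ICD9", "ICD9", "ICD9", "ICD9", "ICD10", "ICD9", "ICD9"),
    code = c("295.00", "295.01", "295.00", "296.00", "F30.1",
             "297.00", "295.00"),
    date = data.table::as.IDate(c("2001-01-01", "2001-01-01", "2001-02-01",
                      "2002-01-01", "2002-03-01", "2003-01-01",
                      "2004-01-01")))
}

tinyDemographics <- function(ids = c("p1", "p2", "p3", "p4")) {
  data.table(patient_id = ids,
             current_age = c(40, 55, 33, 60)[seq_along(ids)],
             ehr_age = c(39, 50, 33, 58)[seq_along(ids)],
             sex = c("female", "male", "male", "female")[seq_along(ids)],
             race = c("White", "unknown", "Black", "White")[seq_along(ids)])
}

# Random cohort where every phenotype is an independent Bernoulli; statuses
# are injected straight into a PhecodeExperiment-shaped object so logistic
# machinery can be exercised without event plumbing.
statusExperiment <- function(status, demographics = NULL) {
  n <- ncol(status)
  ids <- colnames(status)
  if (is.null(ids)) ids <- sprintf("p%04d", seq_len(n))
  dimnames(status) <- list(rownames(status), ids)
  counts <- status * 2L
  counts[is.na(counts)] <- 1L
  if (is.null(demographics)) {
    demographics <- data.frame(
      patientId = ids,
      currentAge = round(runif(n, 20, 80)),
      ehrAge = round(runif(n, 20, 80)))
    demographics$ehrAge <- pmin(demographics$ehrAge, demographics$currentAge)
    demographics$sex <- factor(sample(c("female", "male"), n, TRUE),
                               levels = c("female", "male", "unknown"))
    demographics$race <- factor(sample(c("White", "Black", "unknown"),
                                       n, TRUE),
                                levels = c("White", "Black", "unknown"))
    demographics$recordLength <- round(runif(n, 0, 7000))
    demographics$uniquePhecodeCount <- colSums(status == 1L, na.rm = TRUE)
    demographics$logUniquePhecodes <-
      log(demographics$uniquePhecodeCount + 1)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, status = status),
    rowData = S4Vectors::DataFrame(phecode = rownames(status),
                                   row.names = rownames(status)),
    colData = S4Vectors::DataFrame(demographics, row.names = ids))
  mp <- PhecodeMap(data.frame(vocabulary = "ICD9",
                              code = paste0("X", rownames(status)),
                              phecode = rownames(status)))
  S4Vectors::metadata(se)$map <- mp
  new("PhecodeExperiment", se)
}

# --- independent oracles -----------------------------------------------

# Welch TOST oracle: reconstruct samples with exact moments, then lean on
# stats::t.test for each one-sided test.
tostOracle <- function(n1, m1, s1, n2, m2, s2, bounds = c(-0.2, 0.2)) {
  exactSample <- function(n, m, s) {
    z <- seq_len(n)
    z <- (z - mean(z)) / sd(z)
    m + s * z
  }
  x <- exactSample(n1, m1, s1)
  y <- exactSample(n2, m2, s2)
  sPool <- sqrt((s1^2 + s2^2) / 2)
  pUpper <- t.test(x, y, mu = bounds[1] * sPool,
                   alternative = "greater")$p.value
  pLower <- t.test(x, y, mu = bounds[2] * sPool,
                   alternative = "less")$p.value
  max(pLower, pUpper)
}

# Fisher's-method oracle through the gamma survival function.
fisherOracle <- function(p) {
  chi2 <- -2 * sum(log(p))
  pgamma(chi2 / 2, shape = length(p), lower.tail = FALSE)
}

# Closed-form 2x2 logistic: cells (both, outcomeOnly, predictorOnly, neither).
logOddsOracle <- function(a, b, c, d) {
  list(beta = log(a * d / (b * c)), se = sqrt(1/a + 1/b + 1/c + 1/d))
}

# Expand a 2x2 table into a patient-level status matrix for two phecodes.
tableToStatus <- function(a, b, c, d) {
  y <- c(rep(1L, a + b), rep(0L, c + d))
  x <- c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d))
  st <- rbind(y, x)
  rownames(st) <- c("Y", "X")
  colnames(st) <- sprintf("p%05d", seq_along(y))
  st
}
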