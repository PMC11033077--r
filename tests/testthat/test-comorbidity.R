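test_that("covariate-free pairwise logistic matches the closed-form 2x2 log odds ratio", {
  set.seed(41)
  for (i in 1:50) {
    cells <- sample(10:80, 4, replace = TRUE)
    st <- tableToStatus(cells[1], cells[2], cells[3], cells[4])
    pe <- statusExperiment(st)
    fit <- fitPairwiseLogistic(pe, "Y", "X", covariates = character(),
                               minCases = 1L)
    oracle <- logOddsOracle(cells[1], cells[2], cells[3], cells[4])
    expect_true(fit$converged)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-6)
    expect_equal(fit$se, oracle$se, tolerance = 1e-6)
  }
})

test_that("directional Z is null-calibrated for independent phenotypes", {
  set.seed(7)
  zs <- replicate(200, {
    st <- rbind(Y = rbinom(5000, 1, 0.2), X = rbinom(5000, 1, 0.2))
    colnames(st) <- sprintf("p%04d", 1:5000)
    pe <- statusExperiment(st)
    fitPairwiseLogistic(pe, "Y", "X", covariates = character())$z
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_lt(abs(sd(zs) - 1), 0.15)
})

test_that("site-Z distribution over null pairs with active covariates is standard normal", {
  # Kolmogorov-Smirnov against N(0,1) at alpha = 0.01: phenotypes are
  # independent Bernoullis whose logits depend on age and sex, and the full
  # covariate set is in the model.
  set.seed(11)
  n <- 5000
  age <- round(runif(n, 20, 80))
  sexNum <- rbinom(n, 1, 0.5)
  nPairs <- 200
  st <- matrix(0L, 2 * nPairs, n,
               dimnames = list(sprintf("P%03d", 1:(2 * nPairs)),
                               sprintf("p%04d", 1:n)))
  for (r in 1:(2 * nPairs)) {
    eta <- qlogis(0.15) + 0.01 * (age - 50) + 0.2 * sexNum
    st[r, ] <- rbinom(n, 1, plogis(eta))
  }
  demo <- data.frame(
    patientId = colnames(st), currentAge = age,
    ehrAge = pmax(20, age - 2),
    sex = factor(ifelse(sexNum == 1, "male", "female"),
                 levels = c("female", "male", "unknown")),
    race = factor("White", levels = c("White", "unknown")),
    recordLength = 100L,
    uniquePhecodeCount = colSums(st),
    logUniquePhecodes = log(colSums(st) + 1))
  pe <- statusExperiment(st, demo)
  zs <- vapply(seq_len(nPairs), function(k) {
    fwd <- fitPairwiseLogistic(pe, sprintf("P%03d", 2 * k - 1),
                               sprintf("P%03d", 2 * k))
    rev <- fitPairwiseLogistic(pe, sprintf("P%03d", 2 * k),
                               sprintf("P%03d", 2 * k - 1))
    combineDirections(fwd, rev)
  }, numeric(1))
  # directional Zs of a pair share data; the mean of the two is deflated by
  # the known factor sqrt((1 + rho) / 2) with rho ~ 1 for exchangeable fits,
  # so test the KS property on the forward direction alone
  zFwd <- vapply(seq_len(nPairs), function(k)
    fitPairwiseLogistic(pe, sprintf("P%03d", 2 * k - 1),
                        sprintf("P%03d", 2 * k))$z, numeric(1))
  expect_gt(ks.test(zFwd, "pnorm")$p.value, 0.01)
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("burden conditioning attenuates a pure utilization association", {
  # Purpose-built generator: both phenotypes load on utilization only; the
  # log-unique-phecode covariate must absorb the induced comorbidity.
  set.seed(13)
  n <- 8000
  uz <- rnorm(n)
  nCodes <- 60
  st <- matrix(rbinom(n * nCodes, 1, plogis(qlogis(0.1) + 1.2 * rep(uz, each = nCodes))),
               nCodes, n, dimnames = list(sprintf("B%02d", 1:nCodes),
                                          sprintf("p%04d", 1:n)))
  y <- rbinom(n, 1, plogis(qlogis(0.1) + 0.8 * uz))
  x <- rbinom(n, 1, plogis(qlogis(0.1) + 0.8 * uz))
  st <- rbind(st, Y = y, X = x)
  demo <- data.frame(
    patientId = colnames(st),
    currentAge = 50, ehrAge = 50,
    sex = factor("female", levels = c("female", "unknown")),
    race = factor("White", levels = c("White", "unknown")),
    recordLength = 100L,
    uniquePhecodeCount = colSums(st),
    logUniquePhecodes = log(colSums(st) + 1))
  pe <- statusExperiment(st, demo)
  zWith <- fitPairwiseLogistic(pe, "Y", "X",
    covariates = "logUniquePhecodes")$z
  zWithout <- fitPairwiseLogistic(pe, "Y", "X", covariates = character())$z
  expect_lt(abs(zWith), abs(zWithout))
})

test_that("separation and degenerate fits are flagged, not reported", {
  set.seed(5)
  x <- rbinom(400, 1, 0.3)
  st <- rbind(Y = x, X = x)  # predictor identical to outcome
  colnames(st) <- sprintf("p%03d", 1:400)
  pe <- statusExperiment(st)
  fit <- fitPairwiseLogistic(pe, "Y", "X", covariates = character(),
                             minCases = 1L)
  expect_false(fit$converged)
  expect_true(is.na(fit$z))

  # all-one outcome among analyzable patients
  st2 <- rbind(Y = rep(1L, 400), X = x)
  colnames(st2) <- colnames(st)
  fit2 <- fitPairwiseLogistic(statusExperiment(st2), "Y", "X",
                              covariates = character(), minCases = 1L)
  expect_false(fit2$converged)

  # below the minimum case count -> skipped with a reason
  st3 <- rbind(Y = c(rep(1L, 5), rep(0L, 395)), X = x)
  colnames(st3) <- colnames(st)
  fit3 <- fitPairwiseLogistic(statusExperiment(st3), "Y", "X",
                              covariates = character(), minCases = 20L)
  expect_false(fit3$converged)
  expect_equal(fit3$reason, "too_few_cases")
})

test_that("direction combination follows the selected rule", {
  fwd <- data.frame(z = 3.0, converged = TRUE)
  rev <- data.frame(z = 5.0, converged = TRUE)
  expect_equal(combineDirections(fwd, rev, rule = "mean"), 4.0)
  expect_equal(combineDirections(fwd, rev, rule = "outcome_direction_only"), 3.0)
  expect_equal(combineDirections(fwd, rev, rule = "stouffer"), 8 / sqrt(2))

  failed <- data.frame(z = NA_real_, converged = FALSE)
  expect_equal(combineDirections(data.frame(z = 2.2, converged = TRUE),
                                 failed), 2.2)
  expect_true(is.na(combineDirections(failed, failed)))
})

test_that("exchangeable phenotypes give nearly symmetric directional Zs", {
  set.seed(23)
  n <- 6000
  latent <- rnorm(n)
  st <- rbind(A = rbinom(n, 1, plogis(-1.5 + latent)),
              B = rbinom(n, 1, plogis(-1.5 + latent)))
  colnames(st) <- sprintf("p%04d", 1:n)
  pe <- statusExperiment(st)
  fwd <- fitPairwiseLogistic(pe, "A", "B", covariates = character())
  rev <- fitPairwiseLogistic(pe, "B", "A", covariates = character())
  expect_lt(abs(fwd$z - rev$z) / abs(fwd$z), 0.15)
  expect_equal(combineDirections(fwd, rev), (fwd$z + rev$z) / 2)
})

test_that("shared-case counts equal the brute-force set intersection", {
  set.seed(31)
  st <- matrix(sample(c(0L, 1L, NA_integer_), 5 * 60, TRUE), 5, 60,
               dimnames = list(LETTERS[1:5], sprintf("p%02d", 1:60)))
  pe <- statusExperiment(st)
  for (a in rownames(st)) for (b in rownames(st)) {
    brute <- length(intersect(
      colnames(st)[!is.na(st[a, ]) & st[a, ] == 1L],
      colnames(st)[!is.na(st[b, ]) & st[b, ] == 1L]))
    expect_equal(countSharedCases(pe, a, b), brute)
  }
  expect_equal(countSharedCases(pe, "A", "A"),
               sum(st["A", ] == 1L, na.rm = TRUE))
})

test_that("scan scheduling enumerates the grid and index mode correctly", {
  u <- sprintf("%04.1f", seq(1, 170.1, by = 0.1))  # 1692 labels
  expect_equal(nrow(enumerateScanPairs(u, fullGrid = TRUE)), length(u)^2)
  idx <- enumerateScanPairs(c("A", "B", "C", "X"), indexPhecode = "X")
  expect_equal(nrow(idx), 6L)  # 3 pairs x 2 directions
  expect_true(all(idx$outcome == "X" | idx$predictor == "X"))
  expect_error(enumerateScanPairs("X", indexPhecode = "X"), "empty")
})

test_that("phenome scan output is deterministic and ordered", {
  set.seed(59)
  st <- rbind(IDX = rbinom(800, 1, 0.2),
              B = rbinom(800, 1, 0.3),
              A = rbinom(800, 1, 0.3),
              C = rbinom(800, 1, 0.3))
  colnames(st) <- sprintf("p%03d", 1:800)
  pe <- statusExperiment(st)
  s1 <- runPhenomeScan(pe, "IDX", universe = c("A", "B", "C", "IDX"),
                       covariates = character(), minCases = 5L)
  s2 <- runPhenomeScan(pe, "IDX", universe = c("C", "B", "A", "IDX"),
                       covariates = character(), minCases = 5L)
  expect_identical(s1, s2)
  expect_equal(s1$phecodeB, c("A", "B", "C"))
})
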