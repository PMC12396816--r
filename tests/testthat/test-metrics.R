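test_that("AUROC reproduces worked examples and the tie convention", {
  expect_equal(aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(aurocScore(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(aurocScore(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(aurocScore(c(0.1, 0.2), c(1, 1)), "positive")
})

test_that("AUROC equals brute-force all-pairs counting on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))[sample.int(n)]
    expect_equal(aurocScore(scores, labels), bruteForceAuroc(scores, labels))
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(102)
  for (rep in 1:10) {
    scores <- runif(80)
    labels <- rbinom(80, 1, 0.3)
    if (sum(labels) %in% c(0, 80)) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aurocScore(scores, labels), ref)
  }
})

test_that("average precision reproduces worked examples", {
  expect_equal(auprcScore(c(0.2, 0.5, 0.9), c(1, 1, 1)), 1)
  expect_equal(auprcScore(c(0.9, 0.8, 0.7), c(1, 0, 1)), (1 + 2 / 3) / 2)
  expect_error(auprcScore(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("random classifiers hit the prevalence baselines", {
  set.seed(103)
  n <- 2000
  rho <- 0.15
  npos <- as.integer(n * rho)
  apReps <- numeric(100)
  for (r in seq_len(100)) {
    labels <- rep(FALSE, n)
    labels[sample.int(n, npos)] <- TRUE
    apReps[r] <- auprcScore(runif(n), labels)
  }
  se <- function(x) sd(x) / sqrt(length(x))
  # the exact random-ranking expectation sits just above rho at finite n
  target <- exactRandomAP(n, npos)
  expect_lt(abs(target - rho), 0.005)
  expect_lt(abs(mean(apReps) - target), 2 * se(apReps))

  # R-precision: pairs with a fixed mutation count R have expectation R/n
  rpReps <- numeric(200)
  for (r in seq_len(200)) {
    sByPair <- lapply(1:10, function(i) runif(40))
    lByPair <- lapply(1:10, function(i) {
      lab <- rep(FALSE, 40); lab[sample.int(40, 6)] <- TRUE; lab
    })
    rpReps[r] <- rPrecisionScore(sByPair, lByPair)
  }
  expect_lt(abs(mean(rpReps) - 6 / 40), 2 * se(rpReps))
})

test_that("R-precision follows the micro-average convention", {
  # one pair, R = 2, one hit in the top 2
  expect_equal(rPrecisionScore(list(c(0.9, 0.8, 0.1)),
                               list(c(TRUE, FALSE, TRUE))), 0.5)
  # pair A (R=1, hit) + pair B (R=3, 1 hit in its top 3): (1+1)/(1+3)
  expect_equal(rPrecisionScore(
    list(c(0.9, 0.1), c(0.9, 0.8, 0.7, 0.1, 0.1)),
    list(c(TRUE, FALSE), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  ), 0.5)
  expect_error(rPrecisionScore(list(c(0.5)), list(FALSE)), "zero mutations")
})

test_that("substitution accuracy counts argmax hits with alphabetical ties", {
  rows <- rbind(
    c(0, 1, 0, 0), # C, correct
    c(0, 0.2, 0.7, 0.1), # G, correct
    c(0, 0.2, 0.7, 0.1), # G, child is T: wrong
    c(0.5, 0, 0, 0.5) # tie A/T -> A, child is A: correct
  )
  expect_equal(substitutionAccuracyScore(rows, c("C", "G", "T", "A")), 0.75)
  expect_error(substitutionAccuracyScore(rows[0, , drop = FALSE], character(0)),
               "no mutated")
})

test_that("binned fit and overlap reproduce the hand example and invariants", {
  expect_equal(overlapStatistic(c(2, 0), c(1, 1)), 0.5)
  expect_equal(overlapStatistic(c(3, 4), c(3, 4)), 1)
  expect_equal(overlapStatistic(c(2, 0), c(0, 2)), 0)
  # scale invariance
  expect_equal(overlapStatistic(c(2, 0) * 7, c(1, 1) * 7),
               overlapStatistic(c(2, 0), c(1, 1)))
  set.seed(104)
  scores <- runif(500, 0.001, 0.5)
  labels <- rbinom(500, 1, scores)
  bf <- binnedFit(scores, labels, nBins = 10)
  expect_equal(sum(bf$expected), sum(scores))
  expect_identical(sum(bf$observed), sum(labels))
  expect_true(bf$overlap >= 0 && bf$overlap <= 1)
  expect_error(binnedFit(scores, labels, nBins = 0), "nBins")
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(105)
  scores <- runif(120)
  labels <- rbinom(120, 1, 0.25)
  labels[1:2] <- c(1, 0)
  mono <- function(s) log(s + 1) * 3 + 2
  expect_equal(aurocScore(mono(scores), labels), aurocScore(scores, labels))
  expect_equal(auprcScore(mono(scores), labels), auprcScore(scores, labels))
  sp <- split(scores, rep(1:4, each = 30))
  lp <- split(as.logical(labels), rep(1:4, each = 30))
  expect_equal(rPrecisionScore(lapply(sp, mono), lp), rPrecisionScore(sp, lp))
})

test_that("the evaluation window is 0-based inclusive", {
  tm <- randomTrueModel(3, seed = 106)
  parent <- randomParent(400, seed = 107)
  ch <- strsplit(parent, "")[[1]]
  ch[81] <- setdiff(NUC, ch[81])[1] # 0-based site 80 mutated
  mask <- rep(FALSE, 400)
  mask[c(80, 81, 320, 321)] <- TRUE # 0-based sites 79, 80, 319, 320
  pcps <- PcpSet(parent, paste0(ch, collapse = ""), lossMask = list(mask))
  rep <- evaluateModel(tm, pcps, siteWindow = c(80, 319))
  expect_identical(rep@nSites, 2L) # only 0-based 80 and 319 fall inside
  expect_identical(rep@nMutated, 1L)
})

test_that("evaluation is invariant to pair order and prediction-identical models", {
  tm <- randomTrueModel(3, seed = 108)
  sim <- simulateDataset(simConfig(10, 120, "loguniform", seed = 109), tm)
  r1 <- evaluateModel(tm, sim, siteWindow = c(0, 9999))
  r2 <- evaluateModel(tm, sim[length(sim):1], siteWindow = c(0, 9999))
  for (s in c("auroc", "auprc", "rPrecision", "substitutionAccuracy",
              "overlap", "prevalence", "meanLogLik")) {
    expect_equal(slot(r1, s), slot(r2, s), label = s)
  }
  expect_lte(r1@meanLogLik, 0)
  expect_gte(r1@auprc, r1@prevalence * 0.8) # better than random ordering
})

test_that("the true generative model is well calibrated on its own simulation", {
  tm <- randomTrueModel(3, seed = 110)
  sim <- simulateDataset(simConfig(60, 200, 0.25, seed = 111), tm)
  rep <- evaluateModel(tm, sim, siteWindow = c(0, 9999))
  expect_gt(rep@overlap, 0.95)
})

test_that("metric reports are written as delimited text and key-value pairs", {
  tm <- randomTrueModel(3, seed = 112)
  sim <- simulateDataset(simConfig(5, 80, 0.2, seed = 113), tm)
  rep <- evaluateModel(tm, sim, siteWindow = c(0, 9999))
  dir <- withr::local_tempdir()
  paths <- writeMetricReport(rep, file.path(dir, "run"))
  expect_true(all(file.exists(paths)))
  kv <- readRunConfig(file.path(dir, "run_metrics.txt"))
  expect_equal(as.numeric(kv[["auroc"]]), rep@auroc)
  expect_identical(length(kv), 9L)
})
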