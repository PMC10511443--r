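# A synthetic session table: 18 subjects x 17 sessions, mirroring the
# study's cohort shape, without any signal payload.
sessionTable18 <- function() {
  data.frame(
    session_id = as.vector(outer(sprintf("S%02d", 1:18), 1:17,
                                 function(s, k) paste0(s, "_", k))),
    subject_id = rep(sprintf("S%02d", 1:18), times = 17),
    stringsAsFactors = FALSE)
}

test_that("LOSO folds hold out each subject exactly once", {
  tab <- sessionTable18()
  plan <- losoFolds(tab, seed = 4)
  expect_length(plan$folds, 18)
  for (fold in plan$folds) {
    testSubjects <- unique(sub("_.*", "", fold$test))
    expect_identical(testSubjects, fold$subject)
    expect_length(fold$test, 17)
    expect_length(intersect(fold$test, c(fold$train, fold$val)), 0)
    expect_length(intersect(fold$train, fold$val), 0)
    # 15% of the remaining 289 sessions -> 43 or 44 validation sessions
    expect_true(length(fold$val) %in% c(43, 44))
    expect_equal(length(fold$train) + length(fold$val), 289)
  }
})

test_that("LOSO on a single subject is an error", {
  tab <- data.frame(session_id = c("A_1", "A_2"), subject_id = c("A", "A"))
  expect_error(losoFolds(tab), "2 subjects")
})

test_that("pooled split cuts 70/15/15 and is deterministic per seed", {
  tab <- data.frame(session_id = sprintf("X_%03d", 1:100),
                    subject_id = rep(sprintf("S%02d", 1:10), 10))
  p1 <- pooledSplit(tab, seed = 9)
  fold <- p1$folds[[1]]
  expect_length(fold$train, 70)
  expect_length(fold$val, 15)
  expect_length(fold$test, 15)
  expect_setequal(c(fold$train, fold$val, fold$test), tab$session_id)
  expect_length(intersect(fold$train, fold$val), 0)
  expect_length(intersect(fold$val, fold$test), 0)
  p2 <- pooledSplit(tab, seed = 9)
  expect_identical(p1$folds, p2$folds)
  expect_error(pooledSplit(tab[1:5, ]), "7 sessions")
})

test_that("error statistics use the sample SD of differences", {
  s0 <- errorStats(c(120, 80), c(120, 80))
  expect_equal(s0$me, 0)
  expect_equal(s0$sd, 0)

  s1 <- errorStats(c(99, 101), c(100, 100))
  expect_equal(s1$me, 0)
  expect_equal(s1$sd, sqrt(2))

  est <- withSeed(33, 100 + rnorm(1e5, 0.44, 6.00))
  s2 <- errorStats(est, rep(100, 1e5))
  expect_lt(abs(s2$me - 0.44), 0.06)
  expect_lt(abs(s2$sd - 6.00), 0.05)

  expect_error(errorStats(1:3, 1:4), "length")
})

test_that("Bland-Altman limits are exact linear identities", {
  ba <- blandAltmanLimits(0.44, 6.00)
  expect_equal(ba$loaLower, 0.44 - 1.96 * 6.00)
  expect_equal(round(ba$loaLower, 2), -11.32)

  ba2 <- blandAltmanLimits(-0.50, 6.20)
  expect_equal(round(ba2$loaUpper, 2), 11.65)

  ba3 <- blandAltmanLimits(0, 3)
  expect_equal(ba3$loaLower, -ba3$loaUpper)
  expect_equal(ba3$loaUpper - ba3$loaLower, 2 * 1.96 * 3)

  expect_error(blandAltmanLimits(0, -1), "non-negative")
})

test_that("the LOA interval covers 95% of normal errors", {
  e <- withSeed(14, rnorm(1e5, 1.2, 5))
  st <- errorStats(e + 100, rep(100, 1e5))
  ba <- blandAltmanLimits(st$me, st$sd)
  inside <- mean(e >= ba$loaLower & e <= ba$loaUpper)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("AAMI pass/fail uses strict inequalities", {
  pass <- function(me, sd) aamiCheck(structure(list(me = me, sd = sd, n = 100),
                                               class = "errorStats"))
  expect_true(pass(0.44, 6.00))
  expect_false(pass(5.0, 6.0))
  expect_false(pass(0.0, 8.0))
  expect_true(pass(-4.99, 7.99))
})

test_that("BHS grading matches brute-force counts", {
  allZero <- bhsGrade(rep(0, 10))
  expect_equal(allZero$grade, "A")
  expect_equal(allZero$pctLe5, 100)

  e <- c(4, 4, 4, 4, 4, 12, 12, 12, 12, 16)
  g <- bhsGrade(e)
  expect_equal(g$pctLe5, 50)
  expect_equal(g$pctLe10, 50)
  expect_equal(g$pctLe15, 90)
  expect_equal(g$grade, "D")

  expect_true(g$pctLe5 <= g$pctLe10 && g$pctLe10 <= g$pctLe15)
})

test_that("folded-normal errors reproduce the closed-form BHS percentages", {
  sigma <- 6.0
  e <- withSeed(15, rnorm(1e5, 0, sigma))
  g <- bhsGrade(e)
  cdf <- function(x) 100 * (2 * pnorm(x / sigma) - 1)
  expect_lt(abs(g$pctLe5 - cdf(5)), 0.5)
  expect_lt(abs(g$pctLe10 - cdf(10)), 0.5)
  expect_lt(abs(g$pctLe15 - cdf(15)), 0.5)
  expect_equal(g$grade, "B")
})

test_that("the mean-predictor harness reproduces plain error statistics", {
  f <- smallFeatures()
  plan <- losoFolds(f, seed = 5)
  st <- meanPredictorStats(f, "SBP", plan = plan)
  # recompute by hand from the same plan
  est <- numeric(); ref <- numeric()
  for (fold in plan$folds) {
    iTr <- f$session_id %in% c(fold$train, fold$val) & f$valid
    iTe <- f$session_id %in% fold$test & f$valid
    est <- c(est, rep(mean(f$ref_sbp[iTr]), sum(iTe)))
    ref <- c(ref, f$ref_sbp[iTe])
  }
  manual <- errorStats(est, ref)
  expect_equal(st$me, manual$me)
  expect_equal(st$sd, manual$sd)
  expect_equal(st$n, manual$n)
})

test_that("the held-out subject's references never influence its estimates", {
  f <- smallFeatures()
  cfg <- mlpConfig(maxEpochs = 40, earlyStopPatience = 10, batchSize = 64)
  r1 <- runLosoExperiment(f, "SBP", cfg, seed = 6)
  f2 <- f
  pert <- f2$subject_id == "S01"
  f2$ref_sbp[pert] <- f2$ref_sbp[pert] + 50
  r2 <- runLosoExperiment(f2, "SBP", cfg, seed = 6)
  expect_equal(r1$estimates[r1$subjects == "S01"],
               r2$estimates[r2$subjects == "S01"], tolerance = 1e-9)
})

test_that("evaluation reports expose consistent statistics", {
  f <- smallFeatures()
  cfg <- mlpConfig(maxEpochs = 40, earlyStopPatience = 10, batchSize = 64)
  rep <- runLosoExperiment(f, "SBP", cfg, seed = 7)
  expect_s3_class(rep, "bpEvaluation")
  expect_equal(rep$blandAltman$loaUpper - rep$blandAltman$loaLower,
               2 * 1.96 * rep$stats$sd, tolerance = 1e-9)
  expect_equal(rep$stats$n, length(rep$estimates))
  expect_equal(sum(rep$perSubject$n), rep$stats$n)
  expect_true(rep$bhs$pctLe5 <= rep$bhs$pctLe10)
  tmp <- tempfile(fileext = ".json")
  writeEvaluationReport(rep, tmp)
  j <- jsonlite::fromJSON(tmp)
  expect_equal(j$sd, rep$stats$sd, tolerance = 1e-8)
  unlink(tmp)
})
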