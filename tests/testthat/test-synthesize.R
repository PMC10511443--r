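test_that("subject sampling is deterministic under a fixed seed", {
  p1 <- withSeed(7, sampleSubject("A"))
  p2 <- withSeed(7, sampleSubject("A"))
  for (sl in slotNames(p1)) expect_identical(slot(p1, sl), slot(p2, sl))
})

test_that("sampled subjects match the cohort model and its invariants", {
  profiles <- withSeed(123, replicate(1000, sampleSubject(), simplify = FALSE))
  bmi <- vapply(profiles, function(p) p@bmi, numeric(1))
  expect_lt(abs(mean(bmi) - 21.1), 0.5)
  for (p in profiles[1:50]) {
    expect_gt(p@age, 0)
    expect_gt(p@height, 0)
    expect_gt(p@weight, 0)
    expect_lt(abs(p@bmi - p@weight / (p@height / 100)^2), 0.1)
    expect_true(p@sex %in% c(0, 1))
  }
})

test_that("beat template morphology responds to peripheral resistance", {
  lat <- function(r) list(r = r)
  ampRatio <- function(r) {
    tpl <- synthesizeBeatTemplate(lat(r), 0.8, fs = 1000)
    w <- tpl$waveform
    fs <- 1000
    iN <- round(tpl$fiducials$dicroticNotch * fs) + 1
    max(w[iN:length(w)]) / max(w[1:iN])
  }
  rs <- c(0.6, 1.2, 2.4)
  ratios <- vapply(rs, ampRatio, numeric(1))
  expect_true(all(diff(ratios) > 0))

  # dicrotic delay (systolic peak -> dicrotic peak) also grows with R
  delay <- function(r) {
    tpl <- synthesizeBeatTemplate(lat(r), 0.8, fs = 1000)
    w <- tpl$waveform
    iN <- round(tpl$fiducials$dicroticNotch * 1000) + 1
    (iN + which.max(w[iN:length(w)]) - 1) / 1000 - tpl$fiducials$systolicPeak
  }
  expect_true(all(diff(vapply(rs, delay, numeric(1))) > 0))
})

test_that("beat template is nonnegative with its maximum at the systolic peak", {
  tpl <- synthesizeBeatTemplate(list(r = 1.1), 0.9, fs = 500)
  expect_gte(min(tpl$waveform), 0)
  expect_equal(which.max(tpl$waveform),
               round(tpl$fiducials$systolicPeak * 500) + 1)
})

test_that("reported notch is a local minimum of the sampled waveform", {
  tpl <- synthesizeBeatTemplate(list(r = 1.4), 0.8, fs = 500)
  w <- tpl$waveform
  n <- length(w)
  locMax <- which(c(FALSE, w[2:(n - 1)] > w[1:(n - 2)] &
                      w[2:(n - 1)] >= w[3:n], FALSE))
  modes <- sort(locMax[order(w[locMax], decreasing = TRUE)][1:2])
  iMin <- modes[1] + which.min(w[modes[1]:modes[2]]) - 1   # brute-force scan
  expect_lt(abs((iMin - 1) / 500 - tpl$fiducials$dicroticNotch), 1.5 / 500)
})

test_that("beat period outside [0.3, 2] s is a domain error", {
  expect_error(synthesizeBeatTemplate(list(r = 1), 0.2), "range")
  expect_error(synthesizeBeatTemplate(list(r = 1), 2.5), "range")
})

test_that("noise-free DC difference equals the forward model exactly", {
  out <- cleanSession(sv = 80, r = 1.2)
  gt <- out$groundTruth
  cfg <- gt$config
  expected <- (cfg$svGainDorsal - cfg$svGainPalmar) * 80 +
    cfg$pressureGain * (2400 - 2000)
  expect_equal(gt$windows$dcDiff[1], expected, tolerance = 1e-12)
})

test_that("a 60-s session at 60 bpm contains exactly 60 true beats", {
  out <- cleanSession(hr = 60, duration = 60)
  expect_equal(nrow(out$groundTruth$beats), 60)
})

test_that("subject optical offset does not enter the true DC difference", {
  mk <- function(alpha) {
    cfg <- simulationConfig(noiseSdPpg = 0, driftAmplitude = 0, bpNoiseSd = 0)
    profile <- SubjectProfile("SX", 25, 170, 65, 1, heartRate = 70)
    latent <- list(sv = 70, r = 1.2, heartRate = 70, pressurePalmar = 2000,
                   pressureDorsal = 2400, tempPalmar = 33.4, tempDorsal = 33.6,
                   alphaSubj = alpha, gainSubj = 1, bpOffsetSbp = 0,
                   bpOffsetDbp = 0, driftPhase = 0)
    withSeed(3, synthesizeSession(profile, latent, cfg, "X"))$groundTruth
  }
  expect_identical(mk(4000)$windows$dcDiff, mk(12000)$windows$dcDiff)
})

test_that("cohort size is subjects x sessions and generation is reproducible", {
  cfg <- simulationConfig(nSubjects = 18, sessionsPerSubject = 17,
                          sessionDuration = 5, seed = 31)
  co <- generateCohort(cfg)
  expect_equal(length(co$dataset), 306)
  expect_equal(anyDuplicated(sessionIds(co$dataset)), 0)

  cfg2 <- simulationConfig(nSubjects = 2, sessionsPerSubject = 2,
                           sessionDuration = 10, seed = 55)
  a <- generateCohort(cfg2)
  b <- generateCohort(cfg2)
  expect_identical(lapply(sessions(a$dataset), function(s) tsValues(s@ppgDorsal)),
                   lapply(sessions(b$dataset), function(s) tsValues(s@ppgDorsal)))
  expect_identical(a$groundTruths[[3]]$windows, b$groundTruths[[3]]$windows)
})

test_that("true DC difference tracks stroke volume while single channels do not", {
  co <- generateCohort(simulationConfig(nSubjects = 18, sessionsPerSubject = 2,
                                        sessionDuration = 10, seed = 13))
  gts <- co$groundTruths
  sv <- vapply(gts, function(g) g$latent$sv, numeric(1))
  dcDiff <- vapply(gts, function(g) g$windows$dcDiff[1], numeric(1))
  dcDorsal <- vapply(gts, function(g) g$windows$dcDorsal[1], numeric(1))
  expect_gt(cor(dcDiff, sv), 0.95)
  expect_lt(abs(cor(dcDorsal, sv)), 0.5)
})

test_that("cohort ground-truth SBP spans a usable pressure range", {
  co <- generateCohort(simulationConfig(sessionDuration = 10, seed = 2))
  sbp <- vapply(co$groundTruths, function(g) g$windows$sbpDeterministic[1],
                numeric(1))
  expect_gte(diff(range(sbp)), 30)
})

test_that("forward model: SBP rises with stroke volume, falls with temperature", {
  base <- cleanSession(sv = 70, duration = 15)$groundTruth
  up <- cleanSession(sv = 90, duration = 15)$groundTruth
  expect_gt(up$windows$sbpDeterministic[1], base$windows$sbpDeterministic[1])

  warm <- cleanSession(sv = 70, duration = 15)
  lat <- warm$groundTruth$latent
  lat$tempPalmar <- lat$tempPalmar + 2
  lat$tempDorsal <- lat$tempDorsal + 2
  cfg <- warm$groundTruth$config
  profile <- SubjectProfile("SX", 25, 170, 65, 1, heartRate = 72)
  hot <- withSeed(1, synthesizeSession(profile, lat, cfg, "H"))$groundTruth
  expect_lt(hot$windows$sbpDeterministic[1],
            base$windows$sbpDeterministic[1])
})
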