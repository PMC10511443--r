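test_that("beat segmentation recovers the true onsets on synthetic sessions", {
  out <- cleanSession(hr = 60, duration = 14)
  cond <- conditionChannel(out$session@ppgDorsal)
  puls <- downsampleSeries(cond$pulsatile, 500)
  b <- segmentBeats(puls)
  tr <- out$groundTruth$beats$onset
  tr <- tr[tr > 2.5 & tr < 11.5]
  err <- vapply(tr, function(o) min(abs(b$onset - o)), numeric(1))
  expect_true(all(err <= 0.020))
})

test_that("flat signals yield no beats", {
  flat <- TimeSeries(rep(0, 5000), 500)
  expect_equal(nrow(segmentBeats(flat)), 0)
})

test_that("inter-onset intervals at 120 bpm stay within 5% of 0.5 s", {
  out <- cleanSession(hr = 120, duration = 14)
  cond <- conditionChannel(out$session@ppgDorsal)
  b <- segmentBeats(downsampleSeries(cond$pulsatile, 500))
  ibis <- diff(b$onset)
  mid <- b$onset[-nrow(b)] > 2.5 & b$onset[-nrow(b)] < 11
  expect_true(all(abs(ibis[mid] - 0.5) <= 0.025))
})

test_that("fiducial delineation finds the template notch", {
  tpl <- synthesizeBeatTemplate(list(r = 1.2), 0.8, fs = 500)
  ts <- TimeSeries(tpl$waveform, 500)
  fid <- locateFiducials(ts, 0, 0.8)
  expect_equal(fid$notchMethod, "minimum")
  expect_lt(abs(fid$dicroticNotch - tpl$fiducials$dicroticNotch), 0.020)
  expect_lt(abs(fid$systolicPeak - tpl$fiducials$systolicPeak), 0.010)
  expect_true(fid$onset < fid$systolicPeak &&
              fid$systolicPeak < fid$dicroticNotch &&
              fid$dicroticNotch < fid$end)
})

test_that("a dicrotic-free beat falls back or is flagged missing", {
  u <- (0:399) / 400
  w <- dualppg:::.beatWave(u, 0.35, 0)     # dicrotic amplitude zero
  fid <- locateFiducials(TimeSeries(w, 500), 0, 0.8)
  expect_true(fid$notchMethod %in% c("d2", "missing"))

  flat <- TimeSeries(rep(0, 400), 500)
  fidFlat <- locateFiducials(flat, 0, 0.8)
  expect_true(is.na(fidFlat$dicroticNotch) || fidFlat$notchMethod != "minimum")
})

test_that("K value matches closed forms for canonical pulses", {
  fs <- 1000
  # symmetric triangle 0 -> 1 -> 0: mean 1/2
  tri <- c(seq(0, 1, length.out = 501), seq(1, 0, length.out = 501)[-1])
  fid <- list(onset = 0, systolicPeak = 0.5, dicroticNotch = 0.6, end = 1)
  base <- TimeSeries(rep(100, length(tri)), fs)
  f <- computeBeatFeatures(TimeSeries(tri, fs), fid, base)
  expect_equal(f$kValue, 0.5, tolerance = 1e-3)

  # half sine 0 -> 1 -> 0: mean 2/pi
  hs <- sin(pi * seq(0, 1, length.out = 1001))
  f2 <- computeBeatFeatures(TimeSeries(hs, fs), fid, base)
  expect_equal(f2$kValue, 2 / pi, tolerance = 1e-3)
})

test_that("ST + DT equals CP identically and the notch splits times correctly", {
  # template with notch at 30% of CP: fn = 0.22 + 0.09 R = 0.30 at R = 8/9
  r <- (0.30 - 0.22) / 0.09
  tpl <- synthesizeBeatTemplate(list(r = r), 1.0, fs = 1000)
  ts <- TimeSeries(tpl$waveform, 1000)
  fid <- locateFiducials(ts, 0, 1.0)
  base <- TimeSeries(rep(8000, 1000), 1000)
  f <- computeBeatFeatures(ts, fid, base)
  expect_equal(f$st + f$dt, f$cp, tolerance = 1e-9)
  expect_equal(f$stDtRatio, 3 / 7, tolerance = 0.02 * 3 / 7 + 0.004)
  expect_gt(f$kValue, 0)
  expect_lt(f$kValue, 1)
})

test_that("beat features on segmented synthetic beats satisfy the invariants", {
  fx <- tinyConditioned()
  bt <- dualppg:::.sessionBeatTable(fx$pulsatile, fx$baseline)
  ok <- !is.na(bt$cp)
  expect_gt(mean(ok), 0.8)
  expect_equal(bt$st[ok] + bt$dt[ok], bt$cp[ok], tolerance = 1e-9)
  expect_true(all(bt$kValue[ok] > 0 & bt$kValue[ok] < 1))
  expect_true(all(bt$cp[ok] > 0))
})

test_that("degenerate beats raise degenerate-beat errors", {
  fid <- list(onset = 0, systolicPeak = 0.3, dicroticNotch = 0.5, end = 1)
  flat <- TimeSeries(rep(1, 1000), 1000)
  base <- TimeSeries(rep(100, 1000), 1000)
  expect_error(computeBeatFeatures(flat, fid, base), "degenerate")
  tri <- TimeSeries(c(seq(0, 1, length.out = 500),
                      seq(1, 0, length.out = 500)), 1000)
  negBase <- TimeSeries(rep(-5, 1000), 1000)
  expect_error(computeBeatFeatures(tri, fid, negBase), "baseline")
  fidNoNotch <- list(onset = 0, systolicPeak = 0.3, dicroticNotch = NA_real_,
                     end = 1)
  expect_error(computeBeatFeatures(tri, fidNoNotch, base), "notch")
})

test_that("baseline difference cancels common additive offsets exactly", {
  set.seed(21)
  bp <- TimeSeries(8000 + rnorm(1250), 125)
  bd <- TimeSeries(8300 + rnorm(1250), 125)
  ref <- baselineDifference(bp, bd, 1, 8)
  for (i in 1:20) {
    c0 <- runif(1, -5000, 5000)
    shifted <- baselineDifference(TimeSeries(tsValues(bp) + c0, 125),
                                  TimeSeries(tsValues(bd) + c0, 125), 1, 8)
    expect_equal(shifted, ref, tolerance = 1e-9)
  }
  expect_equal(baselineDifference(bp, bp, 1, 8), 0)
  expect_error(baselineDifference(bp, bd, 8, 8), "cover")
})

test_that("measured DC difference increases with stroke volume", {
  dc <- vapply(c(55, 70, 85, 100), function(sv) {
    out <- cleanSession(sv = sv, duration = 15)
    cp <- conditionChannel(out$session@ppgPalmar)
    cd <- conditionChannel(out$session@ppgDorsal)
    baselineDifference(cp$baseline, cd$baseline, 4, 10)
  }, numeric(1))
  expect_true(all(diff(dc) > 0))
})

test_that("pressure calibration is exact at anchors and invertible", {
  curve <- defaultCalibrationCurve()
  expect_equal(calibratePressure(curve$voltage[4], curve), curve$pressure[4],
               tolerance = 1)
  vMid <- (curve$voltage[3] + curve$voltage[4]) / 2
  pMid <- calibratePressure(vMid, curve)
  expect_gt(pMid, curve$pressure[3])
  expect_lt(pMid, curve$pressure[4])

  v2000 <- 1 - exp(-2000 / 1000)
  curve2 <- calibrationCurve(1 - exp(-seq(0, 4000, by = 500) / 1000),
                             seq(0, 4000, by = 500))
  expect_equal(calibratePressure(v2000, curve2), 2000, tolerance = 20)

  expect_error(calibrationCurve(c(0.1, 0.3, 0.2), c(1, 2, 3)), "increasing")
  expect_warning(calibratePressure(2, curve), "clamping")
})

test_that("interface window features recover the latent contact state", {
  out <- cleanSession(duration = 15)
  f <- interfaceWindowFeatures(out$session, 4, 10)
  lat <- out$groundTruth$latent
  expect_lt(abs(f$pressurePalmar - lat$pressurePalmar) / lat$pressurePalmar,
            0.05)
  expect_lt(abs(f$pressureDorsal - lat$pressureDorsal) / lat$pressureDorsal,
            0.05)
  expect_lt(abs(f$tempPalmar - lat$tempPalmar), 0.1)
  expect_error(interfaceWindowFeatures(out$session, 10, 10), "cover")
})

test_that("window aggregation counts whole beats and flags sparse windows", {
  out <- cleanSession(hr = 72, duration = 30)
  condP <- conditionChannel(out$session@ppgPalmar)
  condD <- conditionChannel(out$session@ppgDorsal)
  pulsD <- downsampleSeries(condD$pulsatile, 500)
  baseD <- downsampleSeries(condD$baseline, 500)
  bt <- dualppg:::.sessionBeatTable(pulsD, baseD)
  # a 10-s window aligned at a beat onset holds floor(10 / (60/72)) = 12 beats
  start <- bt$onset[6]
  wf <- aggregateWindowFeatures(bt, condP, condD, out$session, start, 10)
  expect_equal(wf$n_beats, 12)
  expect_true(wf$valid)
  expect_equal(wf$heart_rate, 72, tolerance = 0.5)

  empty <- bt[0, , drop = FALSE]
  wf2 <- aggregateWindowFeatures(empty, condP, condD, out$session, 4, 10)
  expect_false(wf2$valid)
  expect_true(is.na(wf2$cp))
})

test_that("feature vectors have the documented widths and order", {
  f <- smallFeatures()
  row <- f[f$valid, ][1, ]
  profile <- SubjectProfile(row$subject_id, row$age, row$height, row$weight,
                            row$sex, bmi = row$bmi, heartRate = 70)
  vSbp <- assembleFeatureVector(row, profile, "SBP")
  vDbp <- assembleFeatureVector(row, profile, "DBP")
  expect_length(vSbp, 11)
  expect_length(vDbp, 18)
  expect_identical(names(vSbp), featureNames("SBP"))
  expect_identical(names(vDbp), featureNames("DBP"))
  expect_identical(unname(vDbp[1:11]), unname(vSbp))
  expect_true(all(is.finite(vDbp)))
})

test_that("feature assembly refuses invalid windows and incomplete profiles", {
  f <- smallFeatures()
  row <- f[f$valid, ][1, ]
  profile <- SubjectProfile(row$subject_id, row$age, row$height, row$weight,
                            row$sex, bmi = row$bmi)
  bad <- row; bad$valid <- FALSE
  expect_error(assembleFeatureVector(bad, profile, "SBP"), "invalid")
  noWeight <- SubjectProfile(row$subject_id, row$age, row$height, NA_real_,
                             row$sex, bmi = row$bmi)
  expect_error(assembleFeatureVector(row, noWeight, "DBP"), "weight")
})

test_that("session feature tables align windows with cuff references", {
  s <- tinySession()
  f <- sessionFeatures(s)
  expect_true(all(f$valid))
  refs <- sessionReferences(s)
  centers <- f$window_start + 5
  for (i in seq_len(nrow(f))) {
    j <- which.min(abs(refs$time - centers[i]))
    expect_equal(f$ref_sbp[i], refs$sbp[j])
  }
})
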