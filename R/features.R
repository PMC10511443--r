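#' Segment a pulsatile PPG channel into beats
#'
#' Detects systolic peaks (local maxima above an adaptive amplitude
#' threshold, separated by at least `minPeakDistance`), then places each
#' beat onset at the waveform foot — the minimum of the signal in a short
#' interval preceding each systolic upstroke. Beats are the intervals
#' between successive feet, so each contains exactly one dominant peak.
#'
#' @param pulsatile a pulsatile (AC) [TimeSeries-class], at least 2 s at
#'   100 Hz or better.
#' @param minPeakDistance minimum systolic peak separation, seconds.
#' @return data.frame with columns `onset`, `end` (seconds); zero rows when
#'   no beats are found.
#' @export
segmentBeats <- function(pulsatile, minPeakDistance = 0.3) {
  x <- tsValues(pulsatile)
  fs <- tsRate(pulsatile)
  t0 <- tsStart(pulsatile)
  n <- length(x)
  if (n < 3) return(data.frame(onset = numeric(), end = numeric()))
  isMax <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  # amplitude threshold from the interior of the channel, so conditioning
  # edge transients cannot inflate it
  trim <- round(fs)
  xi <- if (n > 4 * trim) x[(trim + 1):(n - trim)] else x
  thr <- 0.45 * quantile(xi, 0.98, names = FALSE)
  if (!is.finite(thr) || thr <= 0)
    return(data.frame(onset = numeric(), end = numeric()))
  cand <- which(isMax & x > thr)
  if (!length(cand)) return(data.frame(onset = numeric(), end = numeric()))
  # greedy peak pruning: keep the higher peak within minPeakDistance
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  gap <- round(minPeakDistance * fs)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    blocked[max(1, i - gap):min(n, i + gap)] <- TRUE
  }
  peaks <- which(keep)
  if (length(peaks) < 2) return(data.frame(onset = numeric(), end = numeric()))
  ibi <- median(diff(peaks))
  back <- round(0.35 * ibi)
  # foot of each upstroke: the pre-peak minimum refined by the intersecting
  # tangent (tangent at the max-slope point, intersected with the level of
  # the minimum); less biased than the raw argmin when low-pass smoothing
  # flattens the foot
  onsets <- vapply(peaks, function(p) {
    lo <- max(1L, p - back)
    m <- lo + which.min(x[lo:p]) - 1L
    level <- x[m]
    if (p - m >= 2L) {
      d1 <- diff(x[m:p])
      i <- which.max(d1)
      slope <- d1[i] * fs
      tSlope <- (m + i - 1.5) / fs          # midpoint of the steepest rise
      vSlope <- (x[m + i - 1L] + x[m + i]) / 2
      foot <- tSlope - (vSlope - level) / slope
      foot <- min(max(foot, (m - 1) / fs), (p - 1) / fs)
    } else {
      foot <- (m - 1) / fs
    }
    t0 + foot
  }, numeric(1))
  onsets <- sort(unique(onsets))
  if (length(onsets) < 2) return(data.frame(onset = numeric(), end = numeric()))
  data.frame(onset = head(onsets, -1), end = tail(onsets, -1))
}

#' Locate fiducial landmarks within one beat
#'
#' The systolic peak is the global maximum of the beat. The dicrotic notch is
#' the most prominent local minimum between the peak and 80% of the cardiac
#' period; when no local minimum exists (degenerate, e.g. vanishing dicrotic
#' wave), the maximum of the second derivative in (peak + 0.1 CP,
#' peak + 0.5 CP) is used as a fallback, and if that fails too the notch is
#' reported missing (`NA`) so the beat is excluded from the notch-dependent
#' features.
#'
#' @param pulsatile pulsatile [TimeSeries-class] covering the beat.
#' @param onset,end beat boundaries, seconds (from [segmentBeats()]).
#' @return list with `onset`, `systolicPeak`, `dicroticNotch` (possibly
#'   `NA`), `end` (seconds) and `notchMethod`
#'   (`"minimum"`, `"d2"` or `"missing"`).
#' @export
locateFiducials <- function(pulsatile, onset, end) {
  fs <- tsRate(pulsatile)
  t0 <- tsStart(pulsatile)
  i1 <- max(1L, round((onset - t0) * fs) + 1L)
  i2 <- min(length(pulsatile), round((end - t0) * fs) + 1L)
  seg <- tsValues(pulsatile)[i1:i2]
  m <- length(seg)
  cp <- end - onset
  pk <- which.max(seg)
  peakTime <- onset + (pk - 1) / fs
  lim <- min(m, round(0.8 * cp * fs) + 1L)
  notch <- NA_real_
  method <- "missing"
  if (lim - pk >= 3) {
    reg <- seg[pk:lim]
    k <- length(reg)
    isMin <- which(c(FALSE, reg[2:(k - 1)] < reg[1:(k - 2)] &
                       reg[2:(k - 1)] <= reg[3:k], FALSE))
    if (length(isMin)) {
      prom <- vapply(isMin, function(i) {
        min(max(reg[1:i]) - reg[i], max(reg[i:k]) - reg[i])
      }, numeric(1))
      best <- isMin[which.max(prom)]
      if (max(prom) > 1e-6 * diff(range(seg))) {
        notch <- peakTime + (best - 1) / fs
        method <- "minimum"
      }
    }
  }
  if (is.na(notch)) {
    j1 <- pk + max(1L, round(0.1 * cp * fs))
    j2 <- min(m, pk + round(0.5 * cp * fs))
    if (j2 - j1 >= 4) {
      d2 <- diff(seg[j1:j2], differences = 2)
      if (length(d2) && any(is.finite(d2)) && diff(range(seg)) > 0) {
        notch <- onset + (j1 + which.max(d2)) / fs  # centre of the 2nd diff
        method <- "d2"
      }
    }
  }
  list(onset = onset, systolicPeak = peakTime, dicroticNotch = notch,
       end = end, notchMethod = method)
}

#' Per-beat pulse-waveform features
#'
#' Computes the per-cycle features: cardiac period `CP = end - onset`,
#' systolic time `ST = notch - onset`, diastolic time `DT = end - notch`
#' (so `ST + DT = CP` identically), their ratio, the systolic/diastolic area
#' ratio (areas above the beat minimum, trapezoid rule, split at the notch),
#' the waveform K value `(mean - min) / (max - min)`, and the AC/DC ratio
#' (peak-to-peak pulsatile amplitude over the mean baseline level across the
#' beat). K and the areas are computed on the pulsatile component; both are
#' invariant to the constant shift the (per-beat essentially constant)
#' baseline would add.
#'
#' @param pulsatile pulsatile [TimeSeries-class] covering the beat.
#' @param fiducials output of [locateFiducials()]; the notch must be present.
#' @param baseline baseline [TimeSeries-class] covering the beat (for the
#'   DC level of the AC/DC ratio).
#' @return named list: `cp`, `st`, `dt`, `stDtRatio`, `areaRatio`, `kValue`,
#'   `acDcRatio`.
#' @export
computeBeatFeatures <- function(pulsatile, fiducials, baseline) {
  if (is.na(fiducials$dicroticNotch))
    stopf("beat has no dicrotic notch; notch-dependent features undefined")
  fs <- tsRate(pulsatile)
  t0 <- tsStart(pulsatile)
  idx <- function(tt) min(max(1L, round((tt - t0) * fs) + 1L), length(pulsatile))
  i1 <- idx(fiducials$onset); i2 <- idx(fiducials$end)
  iN <- idx(fiducials$dicroticNotch)
  seg <- tsValues(pulsatile)[i1:i2]
  mn <- min(seg); mx <- max(seg)
  if (mx - mn <= 1e-12)
    stopf("degenerate beat: zero peak-to-peak amplitude")
  cp <- fiducials$end - fiducials$onset
  st <- fiducials$dicroticNotch - fiducials$onset
  dt <- cp - st
  trapz <- function(y) if (length(y) < 2) 0 else
    sum((y[-1] + y[-length(y)]) / 2) / fs
  aSys <- trapz(tsValues(pulsatile)[i1:iN] - mn)
  aDia <- trapz(tsValues(pulsatile)[iN:i2] - mn)
  bfs <- tsRate(baseline)
  b1 <- min(max(1L, round((fiducials$onset - tsStart(baseline)) * bfs) + 1L),
            length(baseline))
  b2 <- min(max(1L, round((fiducials$end - tsStart(baseline)) * bfs) + 1L),
            length(baseline))
  dc <- mean(tsValues(baseline)[b1:b2])
  if (!is.finite(dc) || dc <= 0)
    stopf("degenerate beat: nonpositive mean baseline (DC) level")
  list(cp = cp, st = st, dt = dt, stDtRatio = st / dt,
       areaRatio = if (aDia > 0) aSys / aDia else NA_real_,
       kValue = (mean(seg) - mn) / (mx - mn),
       acDcRatio = (mx - mn) / dc)
}

#' Dual-channel DC baseline difference
#'
#' The window-mean difference between the dorsal and palmar PPG baselines,
#' in absolute ADC counts. Subject- and wear-specific optical offsets are
#' common to both channels and cancel in the difference, which is what makes
#' this quantity a cross-subject surrogate for stroke volume.
#'
#' @param baselinePalmar,baselineDorsal baseline [TimeSeries-class] objects.
#' @param windowStart,windowLength window, seconds; both baselines must
#'   cover it.
#' @return the mean of `dorsal - palmar` over the window (ADC counts).
#' @export
baselineDifference <- function(baselinePalmar, baselineDorsal,
                               windowStart, windowLength) {
  winMean <- function(ts) {
    fs <- tsRate(ts)
    i1 <- round((windowStart - tsStart(ts)) * fs) + 1L
    i2 <- round((windowStart + windowLength - tsStart(ts)) * fs)
    if (i1 < 1L || i2 > length(ts))
      stopf("baseline channel does not cover the window [%g, %g] s",
            windowStart, windowStart + windowLength)
    mean(tsValues(ts)[i1:i2])
  }
  winMean(baselineDorsal) - winMean(baselinePalmar)
}

#' Interface-sensor calibration curve
#'
#' Maps interface-sensor output voltage to contact pressure via anchor
#' points from a (monotone, saturating) sensor response. Interpolation is
#' monotone piecewise-cubic Hermite, so calibrated pressure is monotone in
#' voltage and exact at the anchors.
#'
#' @param voltage,pressure anchor coordinates (volts, Pa); both must be
#'   strictly increasing.
#' @return a `calibrationCurve` object.
#' @export
calibrationCurve <- function(voltage, pressure) {
  if (length(voltage) != length(pressure) || length(voltage) < 2)
    stopf("calibration needs >= 2 matched (voltage, pressure) anchors")
  if (any(diff(voltage) <= 0) || any(diff(pressure) <= 0))
    stopf("calibration anchors must be strictly increasing in both coordinates")
  structure(list(voltage = voltage, pressure = pressure,
                 fn = stats::splinefun(voltage, pressure, method = "monoH.FC")),
            class = "calibrationCurve")
}

#' @rdname calibrationCurve
#' @param vSat,p0 parameters of the synthetic sensor response
#'   `V = vSat (1 - exp(-P / p0))` from which the default anchors
#'   (P = 0, 500, ..., 4000 Pa) are taken.
#' @export
defaultCalibrationCurve <- function(vSat = 1, p0 = 2000) {
  p <- seq(0, 4000, by = 500)
  calibrationCurve(vSat * (1 - exp(-p / p0)), p)
}

#' Convert interface voltage to contact pressure
#'
#' @param voltage volts; values outside the anchor range are clamped with a
#'   warning.
#' @param curve a [calibrationCurve()].
#' @return pressure in Pa.
#' @export
calibratePressure <- function(voltage, curve) {
  rng <- range(curve$voltage)
  if (any(voltage < rng[1] | voltage > rng[2])) {
    warning("voltage outside calibration range; clamping to anchor range")
    voltage <- pmin(pmax(voltage, rng[1]), rng[2])
  }
  curve$fn(voltage)
}

#' Window means of the interface-sensor features
#'
#' Per-channel window means of the interface voltages (calibrated to Pa) and
#' skin temperatures.
#'
#' @param session a [SensorSession-class].
#' @param windowStart,windowLength window, seconds.
#' @param curve a [calibrationCurve()].
#' @return named list: `pressurePalmar`, `pressureDorsal` (Pa),
#'   `tempPalmar`, `tempDorsal` (deg C).
#' @export
interfaceWindowFeatures <- function(session, windowStart, windowLength,
                                    curve = defaultCalibrationCurve()) {
  winMean <- function(ts) {
    fs <- tsRate(ts)
    i1 <- round((windowStart - tsStart(ts)) * fs) + 1L
    i2 <- round((windowStart + windowLength - tsStart(ts)) * fs)
    if (i1 < 1L || i2 > length(ts))
      stopf("interface channel does not cover the window [%g, %g] s",
            windowStart, windowStart + windowLength)
    mean(tsValues(ts)[i1:i2])
  }
  ch <- sessionChannels(session)
  list(pressurePalmar = calibratePressure(winMean(ch$iface_palmar_v), curve),
       pressureDorsal = calibratePressure(winMean(ch$iface_dorsal_v), curve),
       tempPalmar = winMean(ch$temp_palmar),
       tempDorsal = winMean(ch$temp_dorsal))
}

# Beat table for one conditioned dorsal channel: fiducials + per-beat
# features for every segmented beat (notchless beats keep NA features).
.sessionBeatTable <- function(pulsatile, baseline) {
  beats <- segmentBeats(pulsatile)
  if (!nrow(beats))
    return(data.frame(onset = numeric(), end = numeric(),
                      systolicPeak = numeric(), dicroticNotch = numeric(),
                      cp = numeric(), st = numeric(), dt = numeric(),
                      stDtRatio = numeric(), areaRatio = numeric(),
                      kValue = numeric(), acDcRatio = numeric()))
  rows <- lapply(seq_len(nrow(beats)), function(i) {
    fid <- locateFiducials(pulsatile, beats$onset[i], beats$end[i])
    feat <- if (!is.na(fid$dicroticNotch))
      tryCatch(computeBeatFeatures(pulsatile, fid, baseline),
               error = function(e) NULL)
    else NULL
    if (is.null(feat))
      feat <- list(cp = NA_real_, st = NA_real_, dt = NA_real_,
                   stDtRatio = NA_real_, areaRatio = NA_real_,
                   kValue = NA_real_, acDcRatio = NA_real_)
    data.frame(onset = fid$onset, end = fid$end,
               systolicPeak = fid$systolicPeak,
               dicroticNotch = fid$dicroticNotch %||% NA_real_,
               cp = feat$cp, st = feat$st, dt = feat$dt,
               stDtRatio = feat$stDtRatio, areaRatio = feat$areaRatio,
               kValue = feat$kValue, acDcRatio = feat$acDcRatio)
  })
  do.call(rbind, rows)
}

#' Aggregate beat and interface features over one analysis window
#'
#' Waveform features are averaged over the valid (notch-bearing) beats fully
#' inside the window, the heart-rate feature is `60 / mean(CP)`, the
#' dual-channel DC difference comes from the window means of the two
#' baselines, and the interface features are calibrated window means. A
#' window with fewer than `minBeats` valid beats is flagged invalid.
#'
#' @param beatTable per-beat features for the dorsal channel (internal table
#'   built by [sessionFeatures()]).
#' @param condPalmar,condDorsal conditioned channels from
#'   [conditionChannel()].
#' @param session the [SensorSession-class].
#' @param windowStart,windowLength window, seconds.
#' @param curve a [calibrationCurve()].
#' @param minBeats minimum valid beats for a usable window.
#' @return one-row data.frame of window features plus `nBeats` and `valid`.
#' @export
aggregateWindowFeatures <- function(beatTable, condPalmar, condDorsal, session,
                                    windowStart, windowLength,
                                    curve = defaultCalibrationCurve(),
                                    minBeats = 5) {
  inWin <- beatTable$onset >= windowStart - 1e-9 &
    beatTable$end <= windowStart + windowLength + 1e-9
  bt <- beatTable[inWin & !is.na(beatTable$cp), , drop = FALSE]
  nb <- nrow(bt)
  iface <- interfaceWindowFeatures(session, windowStart, windowLength, curve)
  dcDiff <- baselineDifference(condPalmar$baseline, condDorsal$baseline,
                               windowStart, windowLength)
  valid <- nb >= minBeats
  mn <- function(v) if (valid) mean(v) else NA_real_
  data.frame(window_start = windowStart, dc_diff = dcDiff,
             pressure_palmar = iface$pressurePalmar,
             pressure_dorsal = iface$pressureDorsal,
             temp_palmar = iface$tempPalmar, temp_dorsal = iface$tempDorsal,
             heart_rate = if (valid) 60 / mean(bt$cp) else NA_real_,
             cp = mn(bt$cp), st = mn(bt$st), dt = mn(bt$dt),
             st_dt_ratio = mn(bt$stDtRatio), area_ratio = mn(bt$areaRatio),
             k_value = mn(bt$kValue), ac_dc_ratio = mn(bt$acDcRatio),
             n_beats = nb, valid = valid)
}

#' Extract the full window-feature table of a session
#'
#' Runs the conditioning chain on both PPG channels, segments and delineates
#' beats on the dorsal channel (the higher-SNR side) at the feature rate,
#' aggregates the 8 pulse features, the dual-channel DC difference and the
#' interface features over every 10-s/2-s analysis window, and aligns each
#' window with the nearest-in-time cuff reference reading. Windows
#' overlapping the first or last baseline period of the session (filter
#' edge region) are excluded.
#'
#' @param session a [SensorSession-class].
#' @param cfg a [preprocConfig()].
#' @param curve a [calibrationCurve()].
#' @param minBeats minimum valid beats per window.
#' @return data.frame, one row per window: identifiers, the 18 model
#'   features, `n_beats`, `valid`, and the matched `ref_sbp`, `ref_dbp`.
#' @export
sessionFeatures <- function(session, cfg = preprocConfig(),
                            curve = defaultCalibrationCurve(), minBeats = 5) {
  condP <- conditionChannel(session@ppgPalmar, cfg)
  condD <- conditionChannel(session@ppgDorsal, cfg)
  pulsD <- downsampleSeries(condD$pulsatile, cfg$featureRate)
  baseD <- downsampleSeries(condD$baseline, cfg$featureRate)
  beatTable <- .sessionBeatTable(pulsD, baseD)
  dur <- sessionDuration(session)
  win <- makeWindows(dur, cfg)
  edge <- 1 / cfg$baselineBandEdge
  keep <- win$start >= edge - 1e-9 & win$start + win$length <= dur - edge + 1e-9
  win <- win[keep, , drop = FALSE]
  if (!nrow(win)) return(NULL)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    aggregateWindowFeatures(beatTable, condP, condD, session,
                            win$start[i], win$length[i], curve, minBeats)
  })
  wf <- do.call(rbind, rows)
  p <- sessionProfile(session)
  refs <- sessionReferences(session)
  center <- wf$window_start + cfg$windowLength / 2
  if (nrow(refs)) {
    nearest <- vapply(center, function(tc) which.min(abs(refs$time - tc)),
                      integer(1))
    wf$ref_sbp <- refs$sbp[nearest]
    wf$ref_dbp <- refs$dbp[nearest]
  } else {
    wf$ref_sbp <- NA_real_
    wf$ref_dbp <- NA_real_
  }
  cbind(data.frame(session_id = sessionId(session),
                   subject_id = p@subjectId, stringsAsFactors = FALSE),
        wf,
        data.frame(age = p@age, height = p@height, weight = p@weight,
                   bmi = p@bmi, sex = p@sex))
}

#' Window-feature table for a whole dataset
#'
#' @param dataset a [SensorDataset-class].
#' @param ... passed to [sessionFeatures()].
#' @return row-bound feature table over all sessions.
#' @export
datasetFeatures <- function(dataset, ...) {
  out <- lapply(sessions(dataset), sessionFeatures, ...)
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Feature names of the two model inputs
#'
#' The SBP model uses the DC baseline difference, the interface features and
#' the subject's physical characteristics (11 inputs); the DBP model adds
#' the 7 pulse-waveform features (18 inputs).
#'
#' @param target `"SBP"` or `"DBP"`.
#' @return character vector of ordered feature names.
#' @export
featureNames <- function(target = c("SBP", "DBP")) {
  target <- match.arg(target)
  base <- c("dc_diff", "pressure_palmar", "pressure_dorsal",
            "temp_palmar", "temp_dorsal", "heart_rate",
            "age", "height", "weight", "bmi", "sex")
  wave <- c("cp", "st", "dt", "st_dt_ratio", "area_ratio", "k_value",
            "ac_dc_ratio")
  if (target == "SBP") base else c(base, wave)
}

#' Assemble a model input vector for one window
#'
#' @param windowFeatures one row of a [sessionFeatures()] table (or the
#'   output of [aggregateWindowFeatures()]); must be a valid window.
#' @param profile a [SubjectProfile-class]; every field must be present.
#' @param target `"SBP"` (11 features) or `"DBP"` (18 features).
#' @return named numeric vector in the model's feature order.
#' @export
assembleFeatureVector <- function(windowFeatures, profile,
                                  target = c("SBP", "DBP")) {
  target <- match.arg(target)
  wf <- as.list(windowFeatures)
  if (!isTRUE(as.logical(wf$valid)))
    stopf("cannot assemble features for an invalid window")
  for (f in c("age", "height", "weight", "bmi", "sex"))
    wf[[f]] <- slot(profile, c(age = "age", height = "height",
                               weight = "weight", bmi = "bmi",
                               sex = "sex")[[f]])
  nms <- featureNames(target)
  vals <- vapply(nms, function(nm) {
    v <- wf[[nm]]
    if (is.null(v) || is.na(v))
      stopf("missing feature value for %s", nm)
    as.numeric(v)
  }, numeric(1))
  setNames(vals, nms)
}
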