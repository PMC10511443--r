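#' Simulation configuration for synthetic sensor sessions
#'
#' Defines the statistical structure of a synthetic cohort: cohort size,
#' session length, the forward model tying the latent hemodynamics (stroke
#' volume SV, peripheral resistance R, heart rate, skin temperature, contact
#' pressure) to ground-truth SBP/DBP, the optical model mapping the latents
#' to PPG channels, and the noise/drift levels. Defaults encode the
#' qualitative physiology the measurement principle relies on — SBP rises
#' with stroke volume and falls with skin temperature, DBP tracks peripheral
#' resistance — with recoverable linear structure.
#'
#' @param nSubjects,sessionsPerSubject cohort shape (a "dataset" is one
#'   wearing session; subjects own several).
#' @param sessionDuration seconds per session.
#' @param bpCoefficients named list of forward-model coefficients; see
#'   Details.
#' @param noiseSdPpg white-noise SD on the PPG channels, ADC counts (the
#'   default of 3 gives roughly 20 dB SNR against the pulsatile component).
#' @param driftAmplitude,driftFreq respiratory baseline drift: a sinusoid
#'   common to both PPG channels (one respiration source), ADC counts / Hz.
#' @param bpNoiseSd per-window SD of the blood-pressure noise, mmHg.
#' @param subjectBpSd SD of an optional per-subject blood-pressure intercept
#'   (mmHg) not explained by any feature, for stress-testing cross-subject
#'   generalization. The default of 0 keeps the forward model fully
#'   recoverable from the features; leave-one-subject-out error still
#'   exceeds pooled-split error because unseen subjects sit at the edges of
#'   the training feature distribution.
#' @param gainModel `"additive_offset"` (subject optical variation is an
#'   additive offset common to both channels, so the dual-channel difference
#'   cancels it exactly) or `"multiplicative"` (a per-subject gain, for
#'   stress-testing robustness).
#' @param subjectOffsetMean,subjectOffsetSd distribution of the subject
#'   optical offset alpha, ADC counts.
#' @param svGainPalmar,svGainDorsal DC gain of stroke volume into each PPG
#'   channel, ADC counts per mL.
#' @param pressureGain DC gain of contact pressure into the PPG channels,
#'   ADC counts per Pa.
#' @param pulseAmpPalmar,pulseAmpDorsal pulsatile amplitude per mL of stroke
#'   volume, ADC counts.
#' @param vSat,p0 interface-sensor response `V = vSat (1 - exp(-P / p0))`
#'   (volts, Pa): a monotone saturating curve over the 0-4 kPa wear range.
#' @param ifaceNoiseSd,tempNoiseSd sensor noise SDs (volts, Celsius).
#' @param ppgRate,ifaceRate channel sampling rates, Hz.
#' @param windowLength,windowShift cadence at which ground-truth BP and cuff
#'   references are emitted, seconds.
#' @param seed master seed; every draw in the cohort is a pure function of
#'   (config, seed).
#'
#' @details The forward model with default coefficients is
#' \deqn{SBP = 40 + 0.8 SV + 0.2 HR - 1.5 (T - 33) + 0.002 (P_p + P_d) + b_s + \epsilon}
#' \deqn{DBP = 20 + 40 R + 0.15 HR - 1.0 (T - 33) + b_s + \epsilon}
#' with \eqn{T} the mean skin temperature (deg C), \eqn{P_p, P_d} the contact
#' pressures (Pa), \eqn{b_s \sim N(0, subjectBpSd)} per subject (0 by
#' default) and \eqn{\epsilon \sim N(0, bpNoiseSd)} per window. All
#' coefficients are simulator choices, exposed here, not measured values.
#' @return a `simulationConfig` list.
#' @export
simulationConfig <- function(nSubjects = 18, sessionsPerSubject = 4,
                             sessionDuration = 120,
                             bpCoefficients = list(
                               sbp_intercept = 40, sbp_sv = 0.8, sbp_hr = 0.2,
                               sbp_temp = -1.5, sbp_pressure = 0.002,
                               dbp_intercept = 20, dbp_r = 40, dbp_hr = 0.15,
                               dbp_temp = -1.0),
                             noiseSdPpg = 3, driftAmplitude = 30,
                             driftFreq = 0.25, bpNoiseSd = 2,
                             subjectBpSd = 0,
                             gainModel = c("additive_offset", "multiplicative"),
                             subjectOffsetMean = 8000, subjectOffsetSd = 1500,
                             svGainPalmar = 5, svGainDorsal = 8,
                             pressureGain = 0.01,
                             pulseAmpPalmar = 0.7, pulseAmpDorsal = 1.2,
                             vSat = 1, p0 = 2000,
                             ifaceNoiseSd = 0.005, tempNoiseSd = 0.02,
                             ppgRate = 1000, ifaceRate = 125,
                             windowLength = 10, windowShift = 2,
                             seed = 1) {
  gainModel <- match.arg(gainModel)
  cfg <- as.list(environment())
  if (nSubjects < 1 || sessionsPerSubject < 1)
    stopf("nSubjects and sessionsPerSubject must be >= 1")
  if (noiseSdPpg < 0 || bpNoiseSd < 0 || subjectBpSd < 0)
    stopf("noise standard deviations must be >= 0")
  if (driftFreq <= 0 || driftFreq >= 1)
    stopf("driftFreq must lie in (0, 1) Hz")
  class(cfg) <- "simulationConfig"
  cfg
}

#' Draw a synthetic subject profile
#'
#' Samples a profile from the cohort model (age ~ N(25, 3) clipped to
#' 18-60 years, height ~ N(170, 8) cm, BMI ~ N(21.1, 2.6) kg/m^2 with
#' weight derived from height and BMI, sex ~ Bernoulli(0.7) male, resting
#' heart rate ~ N(70, 7) bpm). Uses the current RNG stream; seed it for
#' reproducibility.
#'
#' @param subjectId identifier for the new subject.
#' @return a [SubjectProfile-class].
#' @export
sampleSubject <- function(subjectId = "S1") {
  age <- min(max(rnorm(1, 25, 3), 18), 60)
  height <- min(max(rnorm(1, 170, 8), 145), 200)
  bmi <- min(max(rnorm(1, 21.1, 2.6), 15), 35)
  weight <- bmi * (height / 100)^2
  sex <- rbinom(1, 1, 0.7)
  hr <- min(max(rnorm(1, 70, 7), 50), 100)
  SubjectProfile(subjectId, age, height, weight, sex, heartRate = hr)
}

# Subject-level latent parameters (the session latents jitter around these).
.sampleSubjectLatents <- function(cfg) {
  list(svSubj = min(max(rnorm(1, 70, 10), 40), 110),
       rSubj = max(rnorm(1, 1.2, 0.12), 0.5),
       tempSubj = rnorm(1, 33.5, 0.6),
       alphaSubj = max(rnorm(1, cfg$subjectOffsetMean, cfg$subjectOffsetSd), 2000),
       gainSubj = exp(rnorm(1, 0, 0.2)),
       bpOffsetSbp = rnorm(1, 0, cfg$subjectBpSd),
       bpOffsetDbp = rnorm(1, 0, cfg$subjectBpSd))
}

#' Sample the latent hemodynamic state for one session
#'
#' @param profile a [SubjectProfile-class].
#' @param subjectLatents subject-level latents (internal; drawn by
#'   [generateCohort()]).
#' @param cfg a [simulationConfig()].
#' @return a named list: stroke volume `sv` (mL), peripheral resistance `r`
#'   (dimensionless), `heartRate` (bpm), contact pressures (Pa), skin
#'   temperatures (deg C), the subject optical offset/gain, subject BP
#'   intercepts and the respiratory drift phase.
#' @export
sampleLatentState <- function(profile, subjectLatents = NULL,
                              cfg = simulationConfig()) {
  sl <- subjectLatents %||% .sampleSubjectLatents(cfg)
  list(sv = min(max(sl$svSubj + rnorm(1, 0, 5), 35), 120),
       r = max(sl$rSubj + rnorm(1, 0, 0.06), 0.4),
       heartRate = min(max(profile@heartRate + rnorm(1, 0, 3), 45), 130),
       pressurePalmar = min(max(rnorm(1, 2000, 400), 200), 3900),
       pressureDorsal = min(max(rnorm(1, 2400, 400), 200), 3900),
       tempPalmar = sl$tempSubj + rnorm(1, -0.1, 0.1),
       tempDorsal = sl$tempSubj + rnorm(1, 0.1, 0.1),
       alphaSubj = sl$alphaSubj, gainSubj = sl$gainSubj,
       bpOffsetSbp = sl$bpOffsetSbp, bpOffsetDbp = sl$bpOffsetDbp,
       driftPhase = runif(1, 0, 2 * pi))
}

# Notch fraction and dicrotic/systolic amplitude ratio as functions of
# peripheral resistance: the reflected wave arrives later and larger when the
# peripheral bed is stiffer.
.notchFraction <- function(r) min(max(0.22 + 0.09 * r, 0.25), 0.45)
.dicroticRatio <- function(r) 0.6 * r / (1 + r)

#' Synthesize one pulse-beat template
#'
#' Builds a single cardiac cycle as the sum of two positive compact-support
#' lobes: a percussion (systolic) lobe — a quadratic bump on
#' `[0, fn * period]` peaking at its midpoint — and a dicrotic (reflected)
#' lobe — a beta-shaped bump on `[fn * period, period]` peaking at 35% of its
#' support. The notch fraction `fn` and the dicrotic/percussion amplitude
#' ratio both increase with peripheral resistance. The waveform is zero at
#' onset, notch and end, so the exact landmark times are known analytically.
#'
#' @param latent latent state (only `r`, the peripheral resistance, is used);
#'   see [sampleLatentState()].
#' @param beatPeriod cardiac period in seconds, within 0.3 to 2.
#' @param fs sampling rate, Hz.
#' @return list with `waveform` (unit-amplitude samples over one period) and
#'   `fiducials` (onset, systolicPeak, dicroticNotch, end; seconds from beat
#'   onset).
#' @export
synthesizeBeatTemplate <- function(latent, beatPeriod, fs = 500) {
  if (beatPeriod < 0.3 || beatPeriod > 2)
    stopf("beat period %.3f s outside the supported range [0.3, 2] s", beatPeriod)
  fn <- .notchFraction(latent$r)
  amp2 <- .dicroticRatio(latent$r)
  n <- round(beatPeriod * fs)
  u <- (seq_len(n) - 1) / n            # phase in [0, 1)
  w <- .beatWave(u, fn, amp2)
  list(waveform = w,
       fiducials = list(onset = 0,
                        systolicPeak = 0.5 * fn * beatPeriod,
                        dicroticNotch = fn * beatPeriod,
                        end = beatPeriod))
}

# Unit-amplitude beat waveform at phases u in [0, 1).
.beatWave <- function(u, fn, amp2) {
  w <- numeric(length(u))
  sys <- u < fn
  v <- u[sys] / fn
  w[sys] <- 4 * v * (1 - v)
  v <- (u[!sys] - fn) / (1 - fn)
  a <- 1.4; b <- 2.6; vstar <- a / (a + b)
  w[!sys] <- amp2 * (v^a * (1 - v)^b) / (vstar^a * (1 - vstar)^b)
  w
}

# Deterministic part of the forward model (no window noise).
.forwardBp <- function(latent, co) {
  tbar <- (latent$tempPalmar + latent$tempDorsal) / 2
  sbp <- co$sbp_intercept + co$sbp_sv * latent$sv +
    co$sbp_hr * latent$heartRate + co$sbp_temp * (tbar - 33) +
    co$sbp_pressure * (latent$pressurePalmar + latent$pressureDorsal) +
    latent$bpOffsetSbp
  dbp <- co$dbp_intercept + co$dbp_r * latent$r +
    co$dbp_hr * latent$heartRate + co$dbp_temp * (tbar - 33) +
    latent$bpOffsetDbp
  list(sbp = sbp, dbp = dbp)
}

# True DC level of one PPG channel (excluding the drift term).
.trueDcLevel <- function(latent, cfg, side) {
  beta <- if (side == "palmar") cfg$svGainPalmar else cfg$svGainDorsal
  p <- if (side == "palmar") latent$pressurePalmar else latent$pressureDorsal
  dc <- latent$alphaSubj + beta * latent$sv + cfg$pressureGain * p
  if (cfg$gainModel == "multiplicative") dc <- latent$gainSubj * dc
  dc
}

#' Ground-truth baseline trajectory of a synthetic channel
#'
#' Recomputes the true DC trajectory (optical level plus respiratory drift)
#' of a synthetic PPG channel at arbitrary times, from the stored latent
#' state — the oracle against which baseline recovery is scored.
#'
#' @param groundTruth a ground truth object from [synthesizeSession()].
#' @param side `"palmar"` or `"dorsal"`.
#' @param times numeric vector of times, seconds.
#' @return numeric vector of true baseline values (ADC counts).
#' @export
groundTruthBaseline <- function(groundTruth, side, times) {
  lat <- groundTruth$latent
  cfg <- groundTruth$config
  drift <- cfg$driftAmplitude *
    sin(2 * pi * cfg$driftFreq * times + lat$driftPhase)
  if (cfg$gainModel == "multiplicative") drift <- lat$gainSubj * drift
  .trueDcLevel(lat, cfg, side) + drift
}

#' Synthesize one sensor session with known ground truth
#'
#' Generates the six channels of a wearing session from a latent hemodynamic
#' state: each PPG channel is the subject optical offset plus the
#' stroke-volume and contact-pressure DC terms, a pulse train of beat
#' templates scaled per channel, a common-mode respiratory drift sinusoid and
#' white noise; the interface voltage follows the saturating
#' pressure-response curve; the temperature channels are the latent skin
#' temperatures plus noise. Ground-truth per-window SBP/DBP come from the
#' forward model; cuff reference readings are emitted at window cadence.
#'
#' Uses the current RNG stream; [generateCohort()] seeds it per session.
#'
#' @param profile a [SubjectProfile-class].
#' @param latent a latent state from [sampleLatentState()].
#' @param cfg a [simulationConfig()].
#' @param sessionId identifier for the session.
#' @return list with `session` (a [SensorSession-class]) and `groundTruth`
#'   (beat fiducials, per-window true BP and DC levels, the latent state and
#'   the config).
#' @export
synthesizeSession <- function(profile, latent, cfg = simulationConfig(),
                              sessionId = "S1_1") {
  dur <- cfg$sessionDuration
  fs <- cfg$ppgRate
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / latent$heartRate
  nBeats <- floor(dur / period + 1e-9)
  fn <- .notchFraction(latent$r)
  amp2 <- .dicroticRatio(latent$r)
  phase <- (t %% period) / period
  pulse <- .beatWave(phase, fn, amp2)

  drift <- cfg$driftAmplitude * sin(2 * pi * cfg$driftFreq * t + latent$driftPhase)
  mkPpg <- function(side) {
    ampl <- if (side == "palmar") cfg$pulseAmpPalmar else cfg$pulseAmpDorsal
    beta <- if (side == "palmar") cfg$svGainPalmar else cfg$svGainDorsal
    p <- if (side == "palmar") latent$pressurePalmar else latent$pressureDorsal
    clean <- latent$alphaSubj + beta * latent$sv + cfg$pressureGain * p +
      ampl * latent$sv * pulse + drift
    if (cfg$gainModel == "multiplicative") clean <- latent$gainSubj * clean
    TimeSeries(clean + rnorm(n, 0, cfg$noiseSdPpg), fs, 0, "adc_counts")
  }
  ppgP <- mkPpg("palmar")
  ppgD <- mkPpg("dorsal")

  ni <- round(dur * cfg$ifaceRate)
  mkIface <- function(p) TimeSeries(
    cfg$vSat * (1 - exp(-p / cfg$p0)) + rnorm(ni, 0, cfg$ifaceNoiseSd),
    cfg$ifaceRate, 0, "volts")
  mkTemp <- function(tc) TimeSeries(tc + rnorm(ni, 0, cfg$tempNoiseSd),
                                    cfg$ifaceRate, 0, "celsius")

  win <- makeWindows(dur, preprocConfig(windowLength = cfg$windowLength,
                                        windowShift = cfg$windowShift))
  det <- .forwardBp(latent, cfg$bpCoefficients)
  nw <- nrow(win)
  sbp <- det$sbp + rnorm(nw, 0, cfg$bpNoiseSd)
  dbp <- det$dbp + rnorm(nw, 0, cfg$bpNoiseSd)
  dbp <- pmin(dbp, sbp - 10)            # keep sbp > dbp even in noise tails
  center <- win$start + win$length / 2
  refs <- data.frame(time = center, sbp = sbp, dbp = dbp)

  onsets <- (seq_len(nBeats) - 1) * period
  beats <- data.frame(onset = onsets,
                      systolicPeak = onsets + 0.5 * fn * period,
                      dicroticNotch = onsets + fn * period,
                      end = onsets + period)
  windows <- data.frame(start = win$start, center = center,
                        sbp = sbp, dbp = dbp,
                        sbpDeterministic = rep(det$sbp, nw),
                        dbpDeterministic = rep(det$dbp, nw),
                        dcPalmar = rep(.trueDcLevel(latent, cfg, "palmar"), nw),
                        dcDorsal = rep(.trueDcLevel(latent, cfg, "dorsal"), nw))
  windows$dcDiff <- windows$dcDorsal - windows$dcPalmar

  session <- SensorSession(sessionId, profile, ppgP, ppgD,
                           mkIface(latent$pressurePalmar),
                           mkIface(latent$pressureDorsal),
                           mkTemp(latent$tempPalmar), mkTemp(latent$tempDorsal),
                           refs)
  gt <- structure(list(sessionId = sessionId, beats = beats, windows = windows,
                       latent = latent, config = cfg),
                  class = "bpGroundTruth")
  list(session = session, groundTruth = gt)
}

#' Generate a synthetic cohort
#'
#' Draws `nSubjects` profiles with subject-level latents, then
#' `sessionsPerSubject` sessions per subject, all reproducible from the
#' master seed: every subject and session uses an independent derived
#' substream, so the cohort is a pure function of `(config, seed)`.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `dataset` (a [SensorDataset-class]) and `groundTruths`
#'   (named list, one per session, aligned by session id).
#' @examples
#' cohort <- generateCohort(simulationConfig(nSubjects = 2,
#'   sessionsPerSubject = 1, sessionDuration = 15, seed = 7))
#' length(cohort$dataset)
#' @export
generateCohort <- function(cfg = simulationConfig()) {
  ses <- list()
  gts <- list()
  for (i in seq_len(cfg$nSubjects)) {
    sid <- sprintf("S%02d", i)
    sub <- withSeed(subSeed(cfg$seed, paste0("subject_", i)), {
      list(profile = sampleSubject(sid), latents = .sampleSubjectLatents(cfg))
    })
    for (j in seq_len(cfg$sessionsPerSubject)) {
      sessId <- sprintf("%s_%02d", sid, j)
      out <- withSeed(subSeed(cfg$seed, paste0("session_", i, "_", j)), {
        lat <- sampleLatentState(sub$profile, sub$latents, cfg)
        synthesizeSession(sub$profile, lat, cfg, sessId)
      })
      ses[[sessId]] <- out$session
      gts[[sessId]] <- out$groundTruth
    }
  }
  list(dataset = SensorDataset(unname(ses)), groundTruths = gts)
}
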