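# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Two-subject, 30-s cohort used by most signal-level tests.
tinyCohort <- function() memo("tinyCohort", {
  generateCohort(simulationConfig(nSubjects = 2, sessionsPerSubject = 1,
                                  sessionDuration = 30, seed = 42))
})

tinySession <- function() sessions(tinyCohort()$dataset)[[1]]
tinyTruth <- function() tinyCohort()$groundTruths[[1]]

# Conditioned dorsal channel of the tiny session, at the feature rate.
tinyConditioned <- function() memo("tinyConditioned", {
  cond <- conditionChannel(tinySession()@ppgDorsal)
  list(cond = cond,
       pulsatile = downsampleSeries(cond$pulsatile, 500),
       baseline = downsampleSeries(cond$baseline, 500))
})

# Feature table of a small multi-subject cohort (for model-level tests).
smallFeatures <- function() memo("smallFeatures", {
  co <- generateCohort(simulationConfig(nSubjects = 4, sessionsPerSubject = 2,
                                        sessionDuration = 60, seed = 77))
  datasetFeatures(co$dataset)
})

# Noiseless session synthesized from a fully specified latent state.
cleanSession <- function(sv = 70, r = 1.2, hr = 72, seed = 9,
                         duration = 30, ...) {
  cfg <- simulationConfig(nSubjects = 1, sessionsPerSubject = 1,
                          sessionDuration = duration, noiseSdPpg = 0,
                          driftAmplitude = 0, ifaceNoiseSd = 0,
                          tempNoiseSd = 0, bpNoiseSd = 0, seed = seed, ...)
  profile <- SubjectProfile("SX", 25, 170, 65, 1, heartRate = hr)
  latent <- list(sv = sv, r = r, heartRate = hr,
                 pressurePalmar = 2000, pressureDorsal = 2400,
                 tempPalmar = 33.4, tempDorsal = 33.6,
                 alphaSubj = 8000, gainSubj = 1,
                 bpOffsetSbp = 0, bpOffsetDbp = 0, driftPhase = 0)
  withSeed(seed, synthesizeSession(profile, latent, cfg, "SX_1"))
}
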