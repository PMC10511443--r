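#' Uniformly sampled sensor channel
#'
#' `TimeSeries` is the substrate of all signal processing in the package: a
#' numeric vector sampled at a fixed rate, with a start time (seconds from
#' session start) and a unit tag.
#'
#' @slot values numeric vector of samples, in the channel's units.
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot startTime time of the first sample, seconds from session start.
#' @slot units one of `"adc_counts"`, `"volts"`, `"celsius"`, `"pascal"`,
#'   `"dimensionless"`.
#'
#' @examples
#' ts <- TimeSeries(sin(2 * pi * 1.2 * seq(0, 5, by = 1e-3)), 1000)
#' tsDuration(ts)
#' @export
setClass("TimeSeries",
  representation(values = "numeric", samplingRate = "numeric",
                 startTime = "numeric", units = "character"),
  prototype(values = 0, samplingRate = 1, startTime = 0,
            units = "dimensionless"))

.tsUnits <- c("adc_counts", "volts", "celsius", "pascal", "dimensionless")

setValidity("TimeSeries", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive finite number")
  if (length(object@values) < 1)
    msg <- c(msg, "values must contain at least one sample")
  if (length(object@startTime) != 1 || !is.finite(object@startTime))
    msg <- c(msg, "startTime must be a single finite number")
  if (length(object@units) != 1 || !(object@units %in% .tsUnits))
    msg <- c(msg, sprintf("units must be one of: %s",
                          paste(.tsUnits, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname TimeSeries-class
#' @param values,samplingRate,startTime,units see slots.
#' @export
TimeSeries <- function(values, samplingRate, startTime = 0,
                       units = "dimensionless") {
  new("TimeSeries", values = as.numeric(values),
      samplingRate = as.numeric(samplingRate),
      startTime = as.numeric(startTime), units = units)
}

#' @describeIn TimeSeries-class sample values.
#' @param x a `TimeSeries`.
#' @export
tsValues <- function(x) x@values

#' @describeIn TimeSeries-class sampling rate in Hz.
#' @export
tsRate <- function(x) x@samplingRate

#' @describeIn TimeSeries-class start time in seconds.
#' @export
tsStart <- function(x) x@startTime

#' @describeIn TimeSeries-class unit tag.
#' @export
tsUnits <- function(x) x@units

#' @describeIn TimeSeries-class duration in seconds (length / rate).
#' @export
tsDuration <- function(x) length(x@values) / x@samplingRate

#' @describeIn TimeSeries-class sample times in seconds.
#' @export
tsTimes <- function(x) {
  x@startTime + (seq_along(x@values) - 1) / x@samplingRate
}

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples @ %g Hz (%.3f s), units=%s\n",
              length(object@values), object@samplingRate,
              tsDuration(object), object@units))
})

setMethod("length", "TimeSeries", function(x) length(x@values))

#' Subject physical characteristics
#'
#' Age, height, weight, BMI, sex and session-level resting heart rate; these
#' enter the blood-pressure model as features alongside the signal-derived
#' ones. Sex is coded 0 = female, 1 = male.
#'
#' @slot subjectId character identifier.
#' @slot age years.
#' @slot height cm.
#' @slot weight kg.
#' @slot sex 0 (female) or 1 (male).
#' @slot bmi kg/m^2; must be consistent with height and weight.
#' @slot heartRate resting heart rate, bpm.
#' @export
setClass("SubjectProfile",
  representation(subjectId = "character", age = "numeric", height = "numeric",
                 weight = "numeric", sex = "numeric", bmi = "numeric",
                 heartRate = "numeric"))

#' @rdname SubjectProfile-class
#' @param subjectId,age,height,weight,sex,bmi,heartRate see slots. `bmi` is
#'   computed from height and weight when omitted.
#' @export
SubjectProfile <- function(subjectId, age, height, weight, sex,
                           bmi = NULL, heartRate = NA_real_) {
  if (is.null(bmi)) bmi <- weight / (height / 100)^2
  new("SubjectProfile", subjectId = as.character(subjectId),
      age = as.numeric(age), height = as.numeric(height),
      weight = as.numeric(weight), sex = as.numeric(sex),
      bmi = as.numeric(bmi), heartRate = as.numeric(heartRate))
}

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf(
    "SubjectProfile %s: age %.0f y, %.0f cm, %.1f kg, BMI %.1f, sex %d, HR %.0f bpm\n",
    object@subjectId, object@age, object@height, object@weight, object@bmi,
    object@sex, object@heartRate))
})

#' One wearing session of the wearable device
#'
#' Holds the four sensor modalities of one session — palmar/dorsal PPG at
#' 1 kHz and palmar/dorsal interface-sensor voltage and skin temperature at
#' 125 Hz — the subject profile, and the cuff reference readings taken during
#' the session.
#'
#' @slot sessionId character identifier, unique within a dataset.
#' @slot profile a [SubjectProfile-class].
#' @slot ppgPalmar,ppgDorsal PPG channels (`adc_counts`, nominally 1000 Hz).
#' @slot ifacePalmarV,ifaceDorsalV interface-sensor voltages (`volts`, 125 Hz).
#' @slot tempPalmar,tempDorsal skin temperature (`celsius`, 125 Hz).
#' @slot references data.frame with columns `time` (s), `sbp`, `dbp` (mmHg).
#' @export
setClass("SensorSession",
  representation(sessionId = "character", profile = "SubjectProfile",
                 ppgPalmar = "TimeSeries", ppgDorsal = "TimeSeries",
                 ifacePalmarV = "TimeSeries", ifaceDorsalV = "TimeSeries",
                 tempPalmar = "TimeSeries", tempDorsal = "TimeSeries",
                 references = "data.frame"))

setValidity("SensorSession", function(object) {
  msg <- character()
  if (length(object@sessionId) != 1 || !nzchar(object@sessionId))
    msg <- c(msg, "sessionId must be a non-empty string")
  if (!all(c("time", "sbp", "dbp") %in% names(object@references)))
    msg <- c(msg, "references must have columns time, sbp, dbp")
  if (length(msg)) msg else TRUE
})

#' @rdname SensorSession-class
#' @param sessionId,profile,ppgPalmar,ppgDorsal,ifacePalmarV,ifaceDorsalV,tempPalmar,tempDorsal,references
#'   see slots.
#' @export
SensorSession <- function(sessionId, profile, ppgPalmar, ppgDorsal,
                          ifacePalmarV, ifaceDorsalV, tempPalmar, tempDorsal,
                          references) {
  new("SensorSession", sessionId = as.character(sessionId), profile = profile,
      ppgPalmar = ppgPalmar, ppgDorsal = ppgDorsal,
      ifacePalmarV = ifacePalmarV, ifaceDorsalV = ifaceDorsalV,
      tempPalmar = tempPalmar, tempDorsal = tempDorsal,
      references = as.data.frame(references))
}

#' @describeIn SensorSession-class session identifier.
#' @param x a `SensorSession`.
#' @export
sessionId <- function(x) x@sessionId

#' @describeIn SensorSession-class subject profile.
#' @export
sessionProfile <- function(x) x@profile

#' @describeIn SensorSession-class cuff reference readings.
#' @export
sessionReferences <- function(x) x@references

#' @describeIn SensorSession-class named list of the six channels.
#' @export
sessionChannels <- function(x) {
  list(ppg_palmar = x@ppgPalmar, ppg_dorsal = x@ppgDorsal,
       iface_palmar_v = x@ifacePalmarV, iface_dorsal_v = x@ifaceDorsalV,
       temp_palmar = x@tempPalmar, temp_dorsal = x@tempDorsal)
}

#' @describeIn SensorSession-class session duration in seconds (PPG span).
#' @export
sessionDuration <- function(x) tsDuration(x@ppgPalmar)

setMethod("show", "SensorSession", function(object) {
  cat(sprintf(
    "SensorSession %s (subject %s): %.1f s, %d cuff reference readings\n",
    object@sessionId, object@profile@subjectId, sessionDuration(object),
    nrow(object@references)))
})

#' A collection of sensor sessions
#'
#' One subject may own several sessions (the device is removed and re-worn
#' between measurements); session identifiers are unique across the dataset.
#'
#' @slot sessions list of [SensorSession-class] objects.
#' @export
setClass("SensorDataset", representation(sessions = "list"))

setValidity("SensorDataset", function(object) {
  if (!all(vapply(object@sessions, is, logical(1), "SensorSession")))
    return("all elements of sessions must be SensorSession objects")
  TRUE
})

#' @rdname SensorDataset-class
#' @param sessions list of sessions.
#' @export
SensorDataset <- function(sessions) new("SensorDataset", sessions = sessions)

#' @describeIn SensorDataset-class list of sessions.
#' @param x a `SensorDataset`.
#' @export
sessions <- function(x) x@sessions

#' @describeIn SensorDataset-class session identifiers.
#' @export
sessionIds <- function(x) vapply(x@sessions, sessionId, character(1))

#' @describeIn SensorDataset-class subject identifier per session.
#' @export
subjectIds <- function(x)
  vapply(x@sessions, function(s) s@profile@subjectId, character(1))

setMethod("length", "SensorDataset", function(x) length(x@sessions))

setMethod("show", "SensorDataset", function(object) {
  cat(sprintf("SensorDataset: %d sessions from %d subjects\n",
              length(object@sessions),
              length(unique(subjectIds(object)))))
})
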