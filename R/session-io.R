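#' Validate a sensor session against its domain invariants
#'
#' Checks every invariant of the session and its components — finite samples,
#' positive sampling rates, nominal channel rates, channel time alignment,
#' profile consistency (BMI vs height/weight), and reference-reading sanity
#' (`sbp > dbp > 0`). Reports violations instead of raising, so that corrupt
#' sessions can be triaged.
#'
#' @param session a [SensorSession-class].
#' @param ppgRate,ifaceRate nominal sampling rates (Hz) the channels are
#'   expected to carry; defaults are the device rates (1 kHz PPG, 125 Hz
#'   interface sensors).
#' @return character vector of human-readable violation descriptions; empty
#'   when the session is well formed.
#' @examples
#' cfg <- simulationConfig(nSubjects = 1, sessionsPerSubject = 1,
#'                         sessionDuration = 10)
#' ds <- generateCohort(cfg)$dataset
#' validateSession(sessions(ds)[[1]])
#' @export
validateSession <- function(session, ppgRate = 1000, ifaceRate = 125) {
  v <- character()
  chk <- function(cond, fmt, ...) if (isTRUE(cond)) v <<- c(v, sprintf(fmt, ...))
  ch <- sessionChannels(session)
  for (nm in names(ch)) {
    x <- ch[[nm]]
    chk(any(!is.finite(tsValues(x))), "channel %s contains non-finite values", nm)
    chk(tsRate(x) <= 0, "channel %s has non-positive sampling rate", nm)
  }
  for (nm in c("ppg_palmar", "ppg_dorsal"))
    chk(abs(tsRate(ch[[nm]]) - ppgRate) > 1e-9,
        "channel %s sampled at %g Hz, expected %g Hz", nm, tsRate(ch[[nm]]), ppgRate)
  for (nm in c("iface_palmar_v", "iface_dorsal_v", "temp_palmar", "temp_dorsal"))
    chk(abs(tsRate(ch[[nm]]) - ifaceRate) > 1e-9,
        "channel %s sampled at %g Hz, expected %g Hz", nm, tsRate(ch[[nm]]), ifaceRate)
  starts <- vapply(ch, tsStart, numeric(1))
  chk(diff(range(starts)) >= 1 / ifaceRate,
      "channel start-time skew %.4f s exceeds one interface-rate sample",
      diff(range(starts)))
  p <- sessionProfile(session)
  chk(p@age <= 0, "profile age must be positive (got %g)", p@age)
  chk(p@height <= 0, "profile height must be positive (got %g)", p@height)
  chk(p@weight <= 0, "profile weight must be positive (got %g)", p@weight)
  chk(!(p@sex %in% c(0, 1)), "profile sex must be coded 0 or 1 (got %g)", p@sex)
  trueBmi <- p@weight / (p@height / 100)^2
  chk(p@height > 0 && p@weight > 0 && abs(p@bmi - trueBmi) >= 0.1,
      "profile bmi %.2f inconsistent with height/weight (implies %.2f)",
      p@bmi, trueBmi)
  refs <- sessionReferences(session)
  if (nrow(refs)) {
    bad <- which(!(refs$sbp > refs$dbp & refs$dbp > 0))
    for (i in bad)
      chk(TRUE, "reference reading %d violates sbp > dbp > 0 (sbp=%g, dbp=%g)",
          i, refs$sbp[i], refs$dbp[i])
  }
  v
}

.channelNames <- c("ppg_palmar", "ppg_dorsal", "iface_palmar_v",
                   "iface_dorsal_v", "temp_palmar", "temp_dorsal")

#' Write a session to a directory
#'
#' Serializes a session as `metadata.json` (profile, channel manifest with
#' rates and units, reference readings) plus one CSV per channel with header
#' `time_s,value`. Values are written with 17 significant digits so the
#' write/read round trip is exact for 64-bit doubles.
#'
#' @param session a [SensorSession-class]; sessions containing non-finite
#'   samples are refused.
#' @param path directory to create/fill.
#' @return `invisible(path)`.
#' @seealso [readSession()]
#' @export
writeSession <- function(session, path) {
  ch <- sessionChannels(session)
  for (nm in names(ch))
    if (any(!is.finite(tsValues(ch[[nm]]))))
      stopf("refusing to write session %s: channel %s contains non-finite values",
            sessionId(session), nm)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stopf("cannot create session directory %s", path)
  p <- sessionProfile(session)
  meta <- list(
    session_id = sessionId(session),
    profile = list(subject_id = p@subjectId, age = p@age, height = p@height,
                   weight = p@weight, sex = p@sex, bmi = p@bmi,
                   heart_rate = p@heartRate),
    channels = lapply(ch, function(x) list(
      sampling_rate = tsRate(x), start_time = tsStart(x), units = tsUnits(x),
      n = length(tsValues(x)))),
    references = sessionReferences(session))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17)),
             file.path(path, "metadata.json"))
  for (nm in names(ch)) {
    x <- ch[[nm]]
    con <- file(file.path(path, paste0(nm, ".csv")), "w")
    writeLines("time_s,value", con)
    writeLines(sprintf("%.17g,%.17g", tsTimes(x), tsValues(x)), con)
    close(con)
  }
  invisible(path)
}

#' Read a session from a directory (or zip archive)
#'
#' Inverse of [writeSession()]. A `.zip` archive of a session directory is
#' accepted and unpacked to a temporary location first.
#'
#' @param path session directory (or `.zip` file) produced by [writeSession()].
#' @return a validated [SensorSession-class].
#' @export
readSession <- function(path) {
  if (grepl("\\.zip$", path) && file.exists(path) && !dir.exists(path)) {
    tmp <- tempfile("session_unzip_")
    utils::unzip(path, exdir = tmp)
    inner <- list.files(tmp, "metadata\\.json$", recursive = TRUE,
                        full.names = TRUE)
    if (!length(inner)) stopf("zip archive %s contains no metadata.json", path)
    path <- dirname(inner[[1]])
  }
  metaPath <- file.path(path, "metadata.json")
  if (!file.exists(metaPath)) stopf("missing metadata.json in %s", path)
  meta <- jsonlite::fromJSON(metaPath, simplifyVector = TRUE)
  chans <- list()
  for (nm in .channelNames) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stopf("missing channel file for %s in %s", nm, path)
    m <- meta$channels[[nm]]
    if (is.null(m)) stopf("metadata.json lists no channel %s", nm)
    d <- data.table::fread(f, colClasses = "numeric", showProgress = FALSE)
    if (!all(c("time_s", "value") %in% names(d)))
      stopf("channel file for %s lacks time_s,value header", nm)
    if (nrow(d) != m$n)
      stopf("channel %s: metadata says %d samples, file has %d", nm, m$n, nrow(d))
    if (nrow(d) >= 2) {
      impliedRate <- (nrow(d) - 1) / (d$time_s[nrow(d)] - d$time_s[1])
      if (abs(impliedRate - m$sampling_rate) > 0.01 * m$sampling_rate)
        stopf("channel %s: metadata rate %g Hz does not match timestamps (%.3g Hz)",
              nm, m$sampling_rate, impliedRate)
    }
    chans[[nm]] <- TimeSeries(d$value, m$sampling_rate, m$start_time, m$units)
  }
  pr <- meta$profile
  profile <- SubjectProfile(pr$subject_id, pr$age, pr$height, pr$weight,
                            pr$sex, bmi = pr$bmi, heartRate = pr$heart_rate)
  refs <- meta$references
  if (is.null(refs) || length(refs) == 0 || (is.data.frame(refs) && !nrow(refs)))
    refs <- data.frame(time = numeric(), sbp = numeric(), dbp = numeric())
  SensorSession(meta$session_id, profile,
                chans$ppg_palmar, chans$ppg_dorsal,
                chans$iface_palmar_v, chans$iface_dorsal_v,
                chans$temp_palmar, chans$temp_dorsal, refs)
}

#' Write / read a dataset manifest
#'
#' The manifest is a CSV with columns `session_id,subject_id,path`, one row
#' per session directory.
#'
#' @param dataset a [SensorDataset-class].
#' @param dir output directory; each session is written to `dir/<session_id>/`.
#' @return path of the manifest file.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(sessions(dataset), function(s) {
    p <- file.path(dir, sessionId(s))
    writeSession(s, p)
    data.frame(session_id = sessionId(s),
               subject_id = sessionProfile(s)@subjectId,
               path = sessionId(s), stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  manPath
}

#' @rdname writeDataset
#' @param manifest path to a `manifest.csv`; session paths are resolved
#'   relative to its directory.
#' @export
readDataset <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  ses <- lapply(man$path, function(p) {
    full <- if (dir.exists(p) || file.exists(p)) p else file.path(base, p)
    readSession(full)
  })
  SensorDataset(ses)
}
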