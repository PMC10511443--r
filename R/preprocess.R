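#' Signal-conditioning configuration
#'
#' Parameters of the conditioning chain applied to each PPG channel:
#' zero-phase Butterworth low-pass, wavelet denoising with the universal
#' soft threshold, baseline (DC) extraction, and the 10-s/2-s analysis
#' windowing used for estimation.
#'
#' @param lowpassCutoff low-pass corner frequency, Hz. Pulse energy lies
#'   below ~10 Hz, the default.
#' @param lowpassOrder Butterworth order (applied twice, forward/backward).
#' @param decompositionLevel wavelet decomposition depth (default 4 at 1 kHz).
#' @param baselineBandEdge Hz; content below this edge is the baseline (DC)
#'   component. Default 0.4 Hz, below the slowest plausible heart rate.
#' @param featureRate Hz; PPG channels are decimated to this rate before
#'   waveform feature extraction (default 500).
#' @param windowLength,windowShift analysis window length and shift, seconds
#'   (defaults 10 and 2: 8-s overlap, one estimate every 2 s).
#' @return a `preprocConfig` list.
#' @export
preprocConfig <- function(lowpassCutoff = 10, lowpassOrder = 4,
                          decompositionLevel = 4, baselineBandEdge = 0.4,
                          featureRate = 500, windowLength = 10,
                          windowShift = 2) {
  cfg <- list(lowpassCutoff = lowpassCutoff, lowpassOrder = lowpassOrder,
              decompositionLevel = decompositionLevel,
              baselineBandEdge = baselineBandEdge, featureRate = featureRate,
              windowLength = windowLength, windowShift = windowShift)
  if (baselineBandEdge <= 0 || baselineBandEdge >= lowpassCutoff)
    stopf("baselineBandEdge must lie in (0, lowpassCutoff)")
  if (lowpassCutoff >= featureRate / 2)
    stopf("lowpassCutoff must be below featureRate/2")
  if (windowShift <= 0 || windowShift > windowLength)
    stopf("windowShift must be positive and not exceed windowLength")
  class(cfg) <- "preprocConfig"
  cfg
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward Butterworth filtering with odd reflection padding, so the
#' output has zero phase lag, unchanged length, and unit passband gain.
#'
#' @param series a [TimeSeries-class].
#' @param cutoff corner frequency in Hz (must be below Nyquist).
#' @param order filter order per pass.
#' @return filtered [TimeSeries-class] at the same rate.
#' @export
lowpassFilter <- function(series, cutoff = 10, order = 4) {
  fs <- tsRate(series)
  if (cutoff >= fs / 2)
    stopf("low-pass cutoff %g Hz must be below the Nyquist rate %g Hz",
          cutoff, fs / 2)
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  TimeSeries(zeroPhaseFilter(bt$b, bt$a, tsValues(series)), fs,
             tsStart(series), tsUnits(series))
}

#' Wavelet denoising with the universal soft threshold
#'
#' Decomposes the signal with an 8-tap Daubechies filter bank, estimates the
#' noise scale from the median absolute deviation of the finest detail
#' coefficients (`sigma = MAD / 0.6745`), soft-thresholds every detail level
#' at `sigma * sqrt(2 log N)`, and reconstructs.
#'
#' @param series a [TimeSeries-class] with at least `2^level` samples.
#' @param level decomposition depth.
#' @return denoised [TimeSeries-class], same length and rate.
#' @export
waveletDenoise <- function(series, level = 4) {
  x <- tsValues(series)
  n <- length(x)
  if (n < 2^level)
    stopf("series of length %d too short for decomposition level %d", n, level)
  w <- dwt(x, level)
  sigma <- median(abs(w$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  w$details <- lapply(w$details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  TimeSeries(idwt(w), tsRate(series), tsStart(series), tsUnits(series))
}

#' Extract the baseline (DC) component of a channel
#'
#' Returns the slow trajectory of the signal: everything below
#' `bandEdge` Hz. For numerical robustness at very low normalized corner
#' frequencies, the signal is first decimated to roughly `50 * bandEdge` Hz
#' (after a zero-phase anti-alias pass), filtered there with a zero-phase
#' order-2 Butterworth low-pass, and linearly interpolated back onto the
#' original sample grid. The pulsatile (AC) component is the residual
#' `series - baseline`.
#'
#' @param series a [TimeSeries-class] covering at least two baseline periods
#'   (`2 / bandEdge` seconds).
#' @param bandEdge upper band edge of the baseline, Hz.
#' @return baseline [TimeSeries-class], same grid as the input.
#' @export
extractBaseline <- function(series, bandEdge = 0.4) {
  fs <- tsRate(series)
  x <- tsValues(series)
  if (length(x) < 2 / bandEdge * fs)
    stopf("series of %.2f s is shorter than two baseline periods (%.2f s)",
          length(x) / fs, 2 / bandEdge)
  m <- max(1L, floor(fs / (50 * bandEdge)))
  if (m > 1L) {
    aa <- signal::butter(4, min(0.8 / m, 0.99), type = "low")
    xa <- zeroPhaseFilter(aa$b, aa$a, x)
    xi <- xa[seq(1L, length(xa), by = m)]
    fsi <- fs / m
  } else {
    xi <- x
    fsi <- fs
  }
  bt <- signal::butter(2, bandEdge / (fsi / 2), type = "low")
  bi <- zeroPhaseFilter(bt$b, bt$a, xi)
  ti <- (seq_along(xi) - 1) / fsi
  t0 <- (seq_along(x) - 1) / fs
  b <- approx(ti, bi, xout = t0, rule = 2)$y
  TimeSeries(b, fs, tsStart(series), tsUnits(series))
}

#' Z-score standardization
#'
#' Shifts and scales a series to mean 0 and standard deviation 1
#' (population denominator).
#'
#' @param series a [TimeSeries-class] with at least 2 samples and nonzero
#'   variance.
#' @return standardized [TimeSeries-class] (`dimensionless`).
#' @export
standardizeSeries <- function(series) {
  x <- tsValues(series)
  if (length(x) < 2) stopf("standardization needs at least 2 samples")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s < 1e-12 * max(1, abs(mu)))
    stopf("standardization undefined for a zero-variance series")
  TimeSeries((x - mu) / s, tsRate(series), tsStart(series), "dimensionless")
}

#' Downsample by an integer factor with anti-alias filtering
#'
#' @param series a [TimeSeries-class].
#' @param targetRate Hz; must divide the sampling rate exactly.
#' @return decimated [TimeSeries-class] at `targetRate`.
#' @export
downsampleSeries <- function(series, targetRate) {
  fs <- tsRate(series)
  m <- fs / targetRate
  if (abs(m - round(m)) > 1e-9)
    stopf("downsampling factor %g Hz -> %g Hz is not an integer", fs, targetRate)
  m <- as.integer(round(m))
  if (m == 1L) return(series)
  aa <- signal::butter(6, 0.9 / m, type = "low")
  xa <- zeroPhaseFilter(aa$b, aa$a, tsValues(series))
  TimeSeries(xa[seq(1L, length(xa), by = m)], targetRate,
             tsStart(series), tsUnits(series))
}

#' Sliding analysis windows over a session
#'
#' Windows start at `0, shift, 2 shift, ...` and a window is emitted iff it
#' fits entirely in the session, so the count is
#' `floor((duration - length) / shift) + 1` when `duration >= length`, else 0.
#'
#' @param duration session duration, seconds.
#' @param cfg a [preprocConfig()].
#' @return data.frame with columns `start`, `length` (seconds).
#' @export
makeWindows <- function(duration, cfg = preprocConfig()) {
  L <- cfg$windowLength
  S <- cfg$windowShift
  if (duration + 1e-9 < L)
    return(data.frame(start = numeric(), length = numeric()))
  k <- floor((duration - L) / S + 1e-9)
  data.frame(start = (0:k) * S, length = L)
}

#' Condition one PPG channel
#'
#' Full conditioning chain: low-pass filter, wavelet denoise, split into
#' baseline (DC) and pulsatile (AC) components, and z-score standardize the
#' pulsatile path. The baseline is deliberately left in absolute units
#' (ADC counts): the dual-channel baseline difference is the key feature and
#' standardization would destroy it.
#'
#' @param series a PPG [TimeSeries-class].
#' @param cfg a [preprocConfig()].
#' @return a `conditionedChannel` list with `denoised`, `baseline`,
#'   `pulsatile`, `standardized` (all [TimeSeries-class]); the identity
#'   `denoised = baseline + pulsatile` holds pointwise.
#' @export
conditionChannel <- function(series, cfg = preprocConfig()) {
  den <- waveletDenoise(lowpassFilter(series, cfg$lowpassCutoff,
                                      cfg$lowpassOrder),
                        cfg$decompositionLevel)
  base <- extractBaseline(den, cfg$baselineBandEdge)
  puls <- TimeSeries(tsValues(den) - tsValues(base), tsRate(den),
                     tsStart(den), tsUnits(den))
  std <- tryCatch(standardizeSeries(puls), error = function(e) NULL)
  structure(list(denoised = den, baseline = base, pulsatile = puls,
                 standardized = std),
            class = "conditionedChannel")
}
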