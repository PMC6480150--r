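#' Z-score normalization of a BCG recording
#'
#' Removes the amplitude scale differences caused by body weight by
#' subtracting the signal mean and dividing by its standard deviation.
#' The population (1/N) standard deviation is used.
#'
#' @param recording a [BCGRecording-class].
#' @return A list with `recording` (the normalized [BCGRecording-class]) and
#'   `params` (list with `mu` and `sigma` of the input).
#' @examples
#' rec <- BCGRecording(c(1, 2, 3))
#' zscoreNormalize(rec)$recording
#' @export
zscoreNormalize <- function(recording) {
  x <- samples(recording)
  if (length(x) < 2L) stop("zscoreNormalize: need at least 2 samples")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("zscoreNormalize: degenerate constant signal (sigma = 0)")
  out <- BCGRecording((x - mu) / sigma, sampleRate(recording),
                      subjectLabel(recording), recording@subjectId)
  list(recording = out, params = list(mu = mu, sigma = sigma))
}

#' Elliptic bandpass filter specification
#'
#' The heartbeat band for 100 Hz mattress BCG: passband 5/6 to 13/6 Hz,
#' 0.2 dB passband ripple, 8 dB stopband attenuation, filter order 4.
#'
#' @param lowHz,highHz passband corner frequencies in Hz.
#' @param rippleDb passband ripple in dB.
#' @param attenDb stopband attenuation in dB.
#' @param order filter order.
#' @return A list of class `"filterSpec"`.
#' @export
filterSpec <- function(lowHz = 5 / 6, highHz = 13 / 6, rippleDb = 0.2,
                       attenDb = 8, order = 4L) {
  if (!(lowHz > 0 && lowHz < highHz))
    stop("filterSpec: need 0 < lowHz < highHz")
  structure(list(lowHz = lowHz, highHz = highHz, rippleDb = rippleDb,
                 attenDb = attenDb, order = as.integer(order)),
            class = "filterSpec")
}

#' Zero-phase elliptic bandpass filtering
#'
#' Applies the elliptic bandpass filter forward and backward
#' ([signal::filtfilt()]) so that beat peak timing is not shifted. The
#' signal is reflection-padded before filtering to suppress edge
#' transients.
#'
#' @param recording a [BCGRecording-class].
#' @param spec a [filterSpec()].
#' @param pad reflection padding length in samples.
#' @return The filtered [BCGRecording-class], same length as the input.
#' @export
bandpassFilter <- function(recording, spec = filterSpec(), pad = 512L) {
  fs <- sampleRate(recording)
  if (spec$highHz >= fs / 2)
    stop("bandpassFilter: passband corner above Nyquist frequency")
  flt <- signal::ellip(spec$order, spec$rippleDb, spec$attenDb,
                       c(spec$lowHz, spec$highHz) / (fs / 2), type = "pass")
  x <- samples(recording)
  p <- min(pad, length(x) - 1L)
  xp <- .reflect_pad(x, p)
  y <- as.numeric(signal::filtfilt(flt, xp))[(p + 1L):(p + length(x))]
  BCGRecording(y, fs, subjectLabel(recording), recording@subjectId)
}

#' Wavelet approximation layer of a BCG recording
#'
#' Reconstructs the signal from its low-frequency (approximation)
#' content at the requested decomposition level of a db6 wavelet filter
#' bank, with all detail content zeroed. The undecimated (shift-invariant,
#' zero-phase) transform is used, so peak positions are preserved. At
#' 100 Hz, level 5 retains content roughly below 100/2^6 = 1.56 Hz, which
#' isolates the heartbeat fundamental.
#'
#' @param recording a [BCGRecording-class].
#' @param level decomposition level (default 5).
#' @param what `"smooth"` for the approximation reconstruction (default) or
#'   `"detail"` for the detail reconstruction at `level`.
#' @return A [BCGRecording-class] of the same length.
#' @export
approximationLayer <- function(recording, level = 5L, what = "smooth") {
  x <- samples(recording)
  if (length(x) < 2L^level)
    stop("approximationLayer: signal too short for decomposition level ", level)
  y <- .modwt_mra(x, as.integer(level), what = what)
  BCGRecording(y, sampleRate(recording), subjectLabel(recording),
               recording@subjectId)
}

#' Peak detection specification
#'
#' @param windowSamples sliding window length (samples).
#' @param overlapSamples overlap between consecutive windows (samples).
#' @param minSeparationSamples candidates closer than this are merged,
#'   keeping the larger amplitude (0.4 s at 100 Hz, consistent with a
#'   maximum plausible heart rate of 150 bpm).
#' @param minAmplitudeFrac candidates below this fraction of the median
#'   candidate amplitude are discarded (suppresses residual ripple near
#'   the recording edges).
#' @param rrGate plausible RR interval range in seconds; intervals outside
#'   it are dropped.
#' @return A list of class `"peakSpec"`.
#' @export
peakSpec <- function(windowSamples = 100L, overlapSamples = 60L,
                     minSeparationSamples = 40L, minAmplitudeFrac = 0.2,
                     rrGate = c(0.4, 2.0)) {
  if (!(overlapSamples > 0 && overlapSamples < windowSamples))
    stop("peakSpec: need 0 < overlapSamples < windowSamples")
  structure(list(windowSamples = as.integer(windowSamples),
                 overlapSamples = as.integer(overlapSamples),
                 minSeparationSamples = as.integer(minSeparationSamples),
                 minAmplitudeFrac = minAmplitudeFrac, rrGate = rrGate),
            class = "peakSpec")
}

#' Detect heartbeats by overlapping sliding windows
#'
#' Slides a window of `windowSamples` samples advancing by
#' `windowSamples - overlapSamples`; the maximal sample in each window is a
#' peak candidate. Candidates are then validated as strict local maxima,
#' small candidates (below `minAmplitudeFrac` of the median candidate
#' amplitude) are dropped, near-duplicates within `minSeparationSamples`
#' are merged keeping the larger amplitude, and RR intervals outside the
#' plausibility gate are discarded.
#'
#' @param approx the approximation-layer [BCGRecording-class].
#' @param spec a [peakSpec()].
#' @param invert set `TRUE` to detect troughs instead of peaks.
#' @return An [RRSequence-class].
#' @export
detectBeats <- function(approx, spec = peakSpec(), invert = FALSE) {
  y <- samples(approx)
  if (invert) y <- -y
  N <- length(y)
  fs <- sampleRate(approx)
  step <- spec$windowSamples - spec$overlapSamples
  starts <- seq.int(1L, max(1L, N - 1L), by = step)
  cand <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- min(s + spec$windowSamples - 1L, N)
    cand[i] <- s - 1L + which.max(y[s:e])
  }
  cand <- sort(unique(cand))
  ok <- cand > 1L & cand < N
  ok[ok] <- y[cand[ok]] > y[cand[ok] - 1L] & y[cand[ok]] >= y[cand[ok] + 1L]
  cand <- cand[ok]
  if (length(cand) >= 2L)
    cand <- cand[y[cand] >= spec$minAmplitudeFrac * stats::median(y[cand])]
  keep <- integer(0)
  for (c_ in cand) {
    if (length(keep) && c_ - keep[length(keep)] < spec$minSeparationSamples) {
      if (y[c_] > y[keep[length(keep)]]) keep[length(keep)] <- c_
    } else keep <- c(keep, c_)
  }
  if (length(keep) < 2L)
    stop("detectBeats: fewer than 2 beats detected")
  rr <- diff(keep) / fs
  inGate <- rr >= spec$rrGate[1] & rr <= spec$rrGate[2]
  if (!any(inGate))
    stop("detectBeats: no plausible RR intervals after gating")
  new("RRSequence", intervals = rr[inGate], beatIndices = as.integer(keep),
      sampleRate = fs)
}

#' Extract the RR interval sequence from a raw BCG recording
#'
#' The full conditioning chain: z-score normalization, zero-phase elliptic
#' bandpass filtering, db6 approximation layer (level 5), and
#' overlapping-window beat detection.
#'
#' @param recording a raw [BCGRecording-class].
#' @param filtSpec a [filterSpec()].
#' @param level wavelet approximation level.
#' @param pkSpec a [peakSpec()].
#' @param invert detect troughs instead of peaks.
#' @return An [RRSequence-class].
#' @examples
#' sim <- simulateBCG(simConfig(duration_s = 30, noise_sd = 0, thorn_rate = 0))
#' rr <- extractRR(sim$recording)
#' mean(intervals(rr))
#' @export
extractRR <- function(recording, filtSpec = filterSpec(), level = 5L,
                      pkSpec = peakSpec(), invert = FALSE) {
  z <- zscoreNormalize(recording)$recording
  f <- bandpassFilter(z, filtSpec)
  a <- approximationLayer(f, level)
  detectBeats(a, pkSpec, invert = invert)
}
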