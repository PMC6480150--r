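# BCG fluctuation features: four noise-tolerant descriptors of how wildly
# the conditioned BCG trace fluctuates. All four are computed on the
# normalized, bandpass-filtered signal (the same trace the wavelet stage
# consumes): normalization is what makes the fixed ASTC amplitude
# threshold comparable across subjects.

.as_signal <- function(x) {
  if (is(x, "BCGRecording")) list(s = samples(x), T = duration(x))
  else stop("expected a BCGRecording")
}

#' Zero crossing rate
#'
#' `sum(|sgn(S_i) - sgn(S_{i-1})|) / (2 (N - 1))` over i = 2..N, with
#' `sgn(0) = 0`. A unit-free rate in `[0, 1]`; 1 for a strictly
#' alternating-sign series.
#'
#' @param recording a [BCGRecording-class].
#' @return The zero crossing rate.
#' @examples
#' zcr(BCGRecording(c(1, 0, -1), 100))  # 0.5
#' @export
zcr <- function(recording) {
  v <- .as_signal(recording)
  s <- sign(v$s)
  N <- length(s)
  if (N < 2L) stop("zcr: need at least 2 samples")
  sum(abs(diff(s))) / (2 * (N - 1L))
}

#' Average cumulative amplitude change
#'
#' Total variation of the trace divided by its duration T in seconds:
#' `sum(|S_i - S_{i-1}|) / T`. Amplitude units per second.
#'
#' @param recording a [BCGRecording-class].
#' @return The ACAC value.
#' @export
acac <- function(recording) {
  v <- .as_signal(recording)
  if (length(v$s) < 2L) stop("acac: need at least 2 samples")
  sum(abs(diff(v$s))) / v$T
}

#' Average number of extreme points
#'
#' Counts strict local extrema through the second-difference sign pattern
#' (entries of `diff(sign(diff(S)))` equal to +/-2), adds 1 as the
#' end-point compensation for the two samples lost to differencing, and
#' divides by the duration T. Plateau samples (zero first differences)
#' are not counted: a flat-topped peak contributes no +/-2 entry.
#'
#' @param recording a [BCGRecording-class].
#' @return Extreme points per second.
#' @examples
#' anep(BCGRecording(c(0, 1, 0), 100))  # (1 + 1) / 0.03
#' @export
anep <- function(recording) {
  v <- .as_signal(recording)
  if (length(v$s) < 3L) stop("anep: need at least 3 samples")
  d2 <- diff(sign(diff(v$s)))
  (sum(abs(d2) == 2) + 1) / v$T
}

#' Average signal turns count
#'
#' Counts interior samples that are both a signal turn (the first
#' differences on either side have opposite signs) and have an amplitude
#' gap of at least `threshold` to both neighbours, divided by the
#' duration T.
#'
#' @param recording a [BCGRecording-class].
#' @param threshold the minimum amplitude gap Th (on the normalized trace;
#'   default 0.01).
#' @return Qualified turns per second.
#' @examples
#' astc(BCGRecording(c(0, 1, 0), 100))  # 1 / 0.03
#' @export
astc <- function(recording, threshold = 0.01) {
  if (threshold <= 0) stop("astc: threshold must be positive")
  v <- .as_signal(recording)
  s <- v$s
  N <- length(s)
  if (N < 3L) stop("astc: need at least 3 samples")
  dl <- s[2:(N - 1L)] - s[1:(N - 2L)]
  dr <- s[3:N] - s[2:(N - 1L)]
  n <- sum(dl * dr < 0 & abs(dr) >= threshold & abs(dl) >= threshold)
  n / v$T
}

#' All four BCG fluctuation features
#'
#' Convenience wrapper computing [zcr()], [acac()], [anep()] and [astc()]
#' on a conditioned (normalized, bandpass-filtered) recording.
#'
#' @param recording a conditioned [BCGRecording-class].
#' @param threshold the ASTC amplitude threshold.
#' @return Named list with `ZCR`, `ACAC`, `ANEP`, `ASTC`.
#' @export
fluctuationFeatures <- function(recording, threshold = 0.01) {
  list(ZCR = zcr(recording), ACAC = acac(recording),
       ANEP = anep(recording), ASTC = astc(recording, threshold))
}

#' Extract the full fourteen-feature vector from a raw recording
#'
#' Runs the conditioning chain once: the HRV features are computed from
#' the RR sequence extracted via the level-5 approximation layer, and the
#' fluctuation features from the normalized, bandpass-filtered trace.
#' DFA needs more than `sMax` (default 240) beats, so recordings of
#' several minutes are required for the full vector.
#'
#' @param recording a raw [BCGRecording-class].
#' @param filtSpec,level,pkSpec passed to the conditioning chain.
#' @param astcThreshold ASTC amplitude threshold.
#' @param dfaRange DFA segment-length range (beats).
#' @return A one-row data.frame with `subjectId`, `label`, and the
#'   fourteen features of [featureNames()].
#' @export
extractFeatures <- function(recording, filtSpec = filterSpec(), level = 5L,
                            pkSpec = peakSpec(), astcThreshold = 0.01,
                            dfaRange = c(40L, 240L)) {
  z <- zscoreNormalize(recording)$recording
  f <- bandpassFilter(z, filtSpec)
  a <- approximationLayer(f, level)
  rr <- detectBeats(a, pkSpec)
  td <- hrvTimeDomain(rr)
  fd <- hrvFrequencyDomain(rr)
  nd <- list(SampEn = sampleEntropy(rr),
             DFA = dfaAlpha(rr, dfaRange[1], dfaRange[2]))
  bf <- fluctuationFeatures(f, astcThreshold)
  out <- data.frame(subjectId = recording@subjectId,
                    label = subjectLabel(recording),
                    stringsAsFactors = FALSE)
  vals <- c(td, fd, nd, bf)
  for (nm in featureNames()) out[[nm]] <- vals[[nm]]
  out
}
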