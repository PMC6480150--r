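#' Time-domain heart rate variability features
#'
#' MEAN and SDNN describe the distribution of RR intervals; RMSSD and
#' pNN50 describe beat-to-beat change. SDNN uses the sample (N-1)
#' denominator; RMSSD averages over the N-1 successive differences; pNN50
#' is the fraction of successive differences whose magnitude exceeds
#' 50 ms.
#'
#' @param rr an [RRSequence-class] or numeric vector of RR intervals (s).
#' @return Named list with `Mean`, `SDNN`, `RMSSD`, `PNN50`.
#' @examples
#' hrvTimeDomain(c(1.0, 1.06, 0.98, 1.0))
#' @export
hrvTimeDomain <- function(rr) {
  x <- if (is(rr, "RRSequence")) intervals(rr) else as.numeric(rr)
  if (length(x) < 3L) stop("hrvTimeDomain: need at least 3 intervals")
  d <- diff(x)
  list(Mean = mean(x),
       SDNN = stats::sd(x),
       RMSSD = sqrt(mean(d^2)),
       PNN50 = mean(abs(d) > 0.050))
}

# Welch power spectral density of a demeaned uniform series.
# Hann window, segLen-sample segments, 50% overlap; one-sided density.
.welch_psd <- function(x, fs, segLen = 256L, overlap = 0.5) {
  n <- length(x)
  segLen <- min(segLen, n)
  step <- max(1L, as.integer(segLen * (1 - overlap)))
  starts <- seq.int(1L, n - segLen + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segLen) - 1L) / (segLen - 1L))
  U <- sum(w^2)
  acc <- numeric(segLen %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + segLen - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(segLen %/% 2L + 1L)]
    acc <- acc + Mod(X)^2 / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided scaling: double all bins except DC (and Nyquist when present)
  dbl <- rep(2, length(psd)); dbl[1] <- 1
  if (segLen %% 2L == 0L) dbl[length(psd)] <- 1
  list(freq = (seq_along(psd) - 1L) * fs / segLen, psd = psd * dbl,
       df = fs / segLen)
}

#' Frequency-domain heart rate variability features
#'
#' The RR tachogram (interval value against cumulative beat time) is
#' resampled onto a uniform 4 Hz grid by cubic spline interpolation, the
#' mean is removed, and the power spectral density is estimated by Welch's
#' method (Hann window, 256-sample segments, 50% overlap). Band powers
#' are integrated over the very-low (0.0033-0.04 Hz), low (0.04-0.15 Hz)
#' and high (0.15-0.4 Hz) frequency bands.
#'
#' @param rr an [RRSequence-class] or numeric vector of RR intervals (s).
#' @param resampleHz uniform resampling rate (Hz).
#' @param minDuration_s minimum total RR duration; sequences shorter than
#'   this are rejected (the vLF band needs long records; 300 s or more is
#'   recommended).
#' @param normalize when `TRUE`, band powers are divided by their sum.
#' @return Named list with `vLF`, `LF`, `HF`, `LF_HF`.
#' @export
hrvFrequencyDomain <- function(rr, resampleHz = 4, minDuration_s = 60,
                               normalize = FALSE) {
  x <- if (is(rr, "RRSequence")) intervals(rr) else as.numeric(rr)
  tBeat <- cumsum(x)
  if (tBeat[length(tBeat)] < minDuration_s)
    stop("hrvFrequencyDomain: total RR duration below ", minDuration_s, " s")
  grid <- seq(tBeat[1], tBeat[length(tBeat)], by = 1 / resampleHz)
  yi <- stats::spline(tBeat, x, xout = grid, method = "fmm")$y
  yi <- yi - mean(yi)
  sp <- .welch_psd(yi, resampleHz)
  band <- function(lo, hi) {
    sel <- sp$freq > lo & sp$freq <= hi
    sum(sp$psd[sel]) * sp$df
  }
  vlf <- band(0.0033, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  if (hf == 0) stop("hrvFrequencyDomain: HF power is zero, LF/HF undefined")
  if (normalize) {
    tot <- vlf + lf + hf
    if (tot > 0) { vlf <- vlf / tot; lf <- lf / tot; hf <- hf / tot }
  }
  list(vLF = vlf, LF = lf, HF = hf, LF_HF = lf / hf)
}

#' Sample entropy
#'
#' SampEn(m, r) = -log(A / B), where B counts pairs of distinct length-m
#' templates within Chebyshev distance r of each other, A the same for
#' length m+1, and both counts run over the N-m templates starting at
#' positions 1..N-m (self-matches excluded). The tolerance is
#' `r_coeff * sd(x)`.
#'
#' @param x an [RRSequence-class] or numeric vector.
#' @param m embedding (template) length.
#' @param r_coeff tolerance coefficient; the tolerance is `r_coeff` times
#'   the standard deviation of the series.
#' @return The sample entropy (dimensionless); `Inf` when no length-m+1
#'   template pair matches.
#' @examples
#' sampleEntropy(sin(1:100))
#' @export
sampleEntropy <- function(x, m = 2L, r_coeff = 0.15) {
  x <- if (is(x, "RRSequence")) intervals(x) else as.numeric(x)
  N <- length(x)
  if (N < m + 2L) stop("sampleEntropy: need at least m + 2 points")
  sdev <- stats::sd(x)
  if (sdev == 0) stop("sampleEntropy: degenerate constant series")
  r <- r_coeff * sdev
  nt <- N - m   # templates of length m and m+1 both taken from 1..N-m
  # Chebyshev distances accumulated by shifting the absolute-difference matrix
  D <- abs(outer(x, x, "-"))
  within_m <- matrix(TRUE, nt, nt)
  for (k in 0:(m - 1L))
    within_m <- within_m & (D[(1:nt) + k, (1:nt) + k, drop = FALSE] <= r)
  within_m1 <- within_m & (D[(1:nt) + m, (1:nt) + m, drop = FALSE] <= r)
  B <- (sum(within_m) - nt) / 2     # exclude self-matches, count pairs once
  A <- (sum(within_m1) - nt) / 2
  if (B == 0) stop("sampleEntropy: no matching length-m templates")
  if (A == 0) return(Inf)
  -log(A / B)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' The series is mean-centered and integrated; for each segment length s
#' (log-spaced over `[sMin, sMax]`) the integrated profile is partitioned
#' into `floor(N/s)` non-overlapping segments, each segment is detrended
#' by a least-squares line, and the root-mean-square fluctuation F(s) is
#' computed. The exponent alpha is the slope of log F(s) against log s.
#' The default scale range 40-240 beats skips the respiratory periodicity
#' (about 3-6 beats per breath).
#'
#' @param x an [RRSequence-class] or numeric vector.
#' @param sMin,sMax minimum and maximum segment length (beats).
#' @param nScales number of log-spaced scales.
#' @return The scaling exponent alpha.
#' @export
dfaAlpha <- function(x, sMin = 40L, sMax = 240L, nScales = 15L) {
  x <- if (is(x, "RRSequence")) intervals(x) else as.numeric(x)
  N <- length(x)
  if (N <= sMax) stop("dfaAlpha: series must be longer than sMax = ", sMax)
  y <- cumsum(x - mean(x))
  scales <- unique(round(exp(seq(log(sMin), log(sMax), length.out = nScales))))
  Fs <- vapply(scales, function(s) {
    nseg <- N %/% s
    tt <- seq_len(s)
    sxx <- sum((tt - mean(tt))^2)
    rms2 <- vapply(seq_len(nseg), function(j) {
      seg <- y[((j - 1L) * s + 1L):(j * s)]
      beta <- sum((tt - mean(tt)) * (seg - mean(seg))) / sxx
      res <- seg - (mean(seg) + beta * (tt - mean(tt)))
      mean(res^2)
    }, numeric(1))
    sqrt(mean(rms2))
  }, numeric(1))
  stats::coef(stats::lm(log(Fs) ~ log(scales)))[[2]]
}
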