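# Synthetic mattress-BCG generator with known ground truth.
#
# The generator emulates the signal structure the downstream pipeline relies
# on: a quasi-periodic train of heartbeat pulses with RR variability, a slow
# respiratory baseline, wideband sensor noise, and "signal thorns" (isolated
# extreme points), which are denser in hypertensive recordings.

# run `expr` with a local RNG seeded at `seed`, restoring the caller's RNG
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration for synthetic BCG
#'
#' Defaults reflect a sleeping adult recorded on a 100 Hz mattress sensor:
#' mean RR 0.8 s (~75 bpm), 20 ms beat-to-beat jitter plus a 30 ms
#' sinusoidal RR modulation in the LF band, respiration at 0.25 Hz, and a
#' thorn (spike artifact) rate that is the main class-dependent control.
#'
#' @param sample_rate_hz sampling rate in Hz.
#' @param duration_s recording length in seconds; `duration_s *
#'   sample_rate_hz` must be a whole number of samples.
#' @param mean_rr_s mean RR interval (s).
#' @param rr_sd_s standard deviation of the Gaussian beat-to-beat jitter (s).
#' @param rr_modulation_amp_s amplitude of the sinusoidal RR modulation (s).
#' @param rr_modulation_freq_hz frequency of the RR modulation (Hz).
#' @param respiration_freq_hz respiratory baseline frequency (Hz).
#' @param respiration_amp respiratory amplitude relative to the unit pulse.
#' @param thorn_rate_per_s expected number of thorns (single-sample spikes of
#'   random sign, amplitude 2x the pulse) per second.
#' @param noise_sd additive white noise standard deviation relative to the
#'   unit pulse.
#' @param class_label `"hypertensive"`, `"normotensive"`, or `NA`.
#' @param seed integer RNG seed; the same configuration always yields a
#'   bit-identical recording.
#' @param pulse_carrier_hz,pulse_width_s shape of the heartbeat pulse: a
#'   Gaussian-windowed cosine, symmetric about the beat time.
#' @return A list of class `"simConfig"`.
#' @export
simConfig <- function(sample_rate_hz = 100, duration_s = 120,
                      mean_rr_s = 0.8, rr_sd_s = 0.02,
                      rr_modulation_amp_s = 0.03, rr_modulation_freq_hz = 0.1,
                      respiration_freq_hz = 0.25, respiration_amp = 0.3,
                      thorn_rate_per_s = 0.5, noise_sd = 0.1,
                      class_label = NA_character_, seed = 1L,
                      pulse_carrier_hz = 1.2, pulse_width_s = 0.12) {
  cfg <- list(sample_rate_hz = sample_rate_hz, duration_s = duration_s,
              mean_rr_s = mean_rr_s, rr_sd_s = rr_sd_s,
              rr_modulation_amp_s = rr_modulation_amp_s,
              rr_modulation_freq_hz = rr_modulation_freq_hz,
              respiration_freq_hz = respiration_freq_hz,
              respiration_amp = respiration_amp,
              thorn_rate_per_s = thorn_rate_per_s, noise_sd = noise_sd,
              class_label = class_label, seed = as.integer(seed),
              pulse_carrier_hz = pulse_carrier_hz,
              pulse_width_s = pulse_width_s)
  if (mean_rr_s - 3 * rr_sd_s <= 0)
    stop("simConfig: mean_rr_s - 3*rr_sd_s must be positive")
  if (thorn_rate_per_s < 0 || noise_sd < 0)
    stop("simConfig: rates and noise must be non-negative")
  n <- duration_s * sample_rate_hz
  if (abs(n - round(n)) > 1e-9)
    stop("simConfig: duration_s * sample_rate_hz must be an integer")
  if (!is.na(class_label) && !class_label %in% .CLASS_LEVELS)
    stop("simConfig: unknown class_label")
  structure(cfg, class = "simConfig")
}

#' Simulate a synthetic BCG recording with ground truth
#'
#' Each beat contributes a Gaussian-windowed cosine pulse centered at its
#' beat time; respiration is an additive slow sinusoid; thorns are
#' single-sample spikes of random sign and double pulse amplitude at a
#' Poisson rate; noise is additive white Gaussian. The beat train extends
#' about two seconds beyond both recording edges (those phantom beats are
#' not part of the ground truth) so that edge pulses see symmetric
#' neighbours, exactly as a recording window cut from an ongoing heartbeat
#' process would.
#'
#' @param config a [simConfig()].
#' @return A list with `recording` (a [BCGRecording-class]) and `truth`
#'   (list with `beat_times_s`, `true_rr_s` and the `config`). `true_rr_s`
#'   are the successive differences of `beat_times_s`.
#' @examples
#' sim <- simulateBCG(simConfig(duration_s = 10, rr_sd_s = 0, noise_sd = 0,
#'                              thorn_rate_per_s = 0, rr_modulation_amp_s = 0))
#' length(sim$truth$beat_times_s)
#' @export
simulateBCG <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  .with_seed(config$seed, {
    fs <- config$sample_rate_hz
    dur <- config$duration_s
    n <- as.integer(round(dur * fs))
    t <- (seq_len(n) - 1L) / fs
    next_rr <- function(tt) {
      config$mean_rr_s + stats::rnorm(1, 0, config$rr_sd_s) +
        config$rr_modulation_amp_s *
          sin(2 * pi * config$rr_modulation_freq_hz * tt)
    }
    # beat train across [0, dur), extended ~2 s outward for edge continuity
    bt <- c(); tt <- config$mean_rr_s / 2
    while (tt < dur) { bt <- c(bt, tt); tt <- tt + next_rr(tt) }
    pre <- c(); tt <- bt[1]
    while (tt > -2) { tt <- tt - next_rr(tt); pre <- c(pre, tt) }
    post <- c(); tt <- bt[length(bt)]
    while (tt < dur + 2) { tt <- tt + next_rr(tt); post <- c(post, tt) }
    bt_all <- sort(c(pre, bt, post))

    sig2 <- 2 * config$pulse_width_s^2
    x <- numeric(n)
    for (ct in bt_all) {
      lo <- max(1L, as.integer(floor((ct - 1) * fs)))
      hi <- min(n, as.integer(ceiling((ct + 1) * fs)))
      if (hi < lo) next
      idx <- lo:hi
      x[idx] <- x[idx] + exp(-(t[idx] - ct)^2 / sig2) *
        cos(2 * pi * config$pulse_carrier_hz * (t[idx] - ct))
    }
    x <- x + config$respiration_amp *
      sin(2 * pi * config$respiration_freq_hz * t)
    if (config$thorn_rate_per_s > 0) {
      nth <- stats::rpois(1, config$thorn_rate_per_s * dur)
      if (nth > 0) {
        idx <- sample.int(n, min(nth, n))
        x[idx] <- x[idx] + sample(c(-2, 2), length(idx), replace = TRUE)
      }
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)

    rec <- BCGRecording(x, fs, config$class_label)
    list(recording = rec,
         truth = list(beat_times_s = bt, true_rr_s = diff(bt),
                      config = config))
  })
}

#' Default class-conditional feature effect profile
#'
#' Per-class means and a pooled standard deviation for each of the fourteen
#' features, following the direction and magnitude of the group differences
#' observed on real mattress-BCG data: hypertensive subjects show lower
#' mean RR, vLF, ACAC and DFA but higher sample entropy, ZCR, ANEP and
#' ASTC.
#'
#' @param separation optional effect-size override: when not `NULL`, every
#'   feature's class means are moved to `+/- separation/2` standard
#'   deviations around their midpoint, giving `|mean_h - mean_n|/sd =
#'   separation` for all features (useful for constructing clearly
#'   separable synthetic cohorts).
#' @return data.frame with columns `feature`, `mean_h`, `mean_n`, `sd`.
#' @export
defaultEffectProfile <- function(separation = NULL) {
  prof <- data.frame(
    feature = featureNames(),
    mean_h = c(1.01, 0.11, 0.15, 0.25, 0.002, 0.010, 0.05, 591.6,
               0.68, 0.65, 0.05, 0.11, 8.74, 6.68),
    mean_n = c(1.04, 0.12, 0.15, 0.25, 0.006, 0.013, 0.04, 762.1,
               0.63, 0.70, 0.05, 0.14, 6.97, 4.88),
    sd     = c(0.10, 0.06, 0.095, 0.14, 0.003, 0.0115, 0.01, 1461,
               0.145, 0.215, 0.01, 0.045, 1.535, 1.955),
    stringsAsFactors = FALSE)
  if (!is.null(separation)) {
    mid <- (prof$mean_h + prof$mean_n) / 2
    dir <- ifelse(prof$mean_h >= prof$mean_n, 1, -1)
    dir[prof$mean_h == prof$mean_n] <- 1
    prof$mean_h <- mid + dir * separation / 2 * prof$sd
    prof$mean_n <- mid - dir * separation / 2 * prof$sd
  }
  prof
}

#' Simulate a labeled feature table
#'
#' Draws each feature independently from a class-conditional normal
#' distribution, `n_per_class` subjects per class.
#'
#' @param n_per_class subjects per class.
#' @param effect_profile data.frame as returned by [defaultEffectProfile()].
#' @param seed integer RNG seed.
#' @return data.frame with `subjectId`, `label`, and one column per feature.
#' @examples
#' head(simulateFeatureTable(5, seed = 1))
#' @export
simulateFeatureTable <- function(n_per_class,
                                 effect_profile = defaultEffectProfile(),
                                 seed = 1L) {
  stopifnot(all(c("feature", "mean_h", "mean_n", "sd") %in%
                  names(effect_profile)))
  if (any(effect_profile$sd <= 0))
    stop("simulateFeatureTable: every feature sd must be positive")
  feats <- effect_profile$feature
  if (n_per_class == 0) {
    out <- data.frame(subjectId = character(0), label = character(0))
    for (f in feats) out[[f]] <- numeric(0)
    return(out)
  }
  .with_seed(seed, {
    lab <- rep(.CLASS_LEVELS, each = n_per_class)
    out <- data.frame(
      subjectId = sprintf("S%03d", seq_len(2 * n_per_class)),
      label = lab, stringsAsFactors = FALSE)
    for (i in seq_along(feats)) {
      mu <- ifelse(lab == "hypertensive",
                   effect_profile$mean_h[i], effect_profile$mean_n[i])
      out[[feats[i]]] <- stats::rnorm(2 * n_per_class, mu,
                                      effect_profile$sd[i])
    }
    out
  })
}
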