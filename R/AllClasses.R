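#' @import methods
NULL

.CLASS_LEVELS <- c("hypertensive", "normotensive")

#' BCGRecording: a uniformly sampled ballistocardiogram
#'
#' Container for a single-channel BCG amplitude series recorded at a fixed
#' sample rate (100 Hz for the mattress sensor this package targets),
#' optionally carrying the subject's class label.
#'
#' @slot samples numeric vector of amplitudes.
#' @slot sampleRate sampling rate in Hz.
#' @slot label class label, one of `"hypertensive"`, `"normotensive"`, or
#'   `NA_character_` when unknown.
#' @slot subjectId subject identifier.
#' @export
setClass("BCGRecording",
  representation(samples = "numeric", sampleRate = "numeric",
                 label = "character", subjectId = "character"),
  prototype(sampleRate = 100, label = NA_character_, subjectId = NA_character_),
  validity = function(object) {
    msg <- character(0)
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (anyNA(object@samples))
      msg <- c(msg, "samples must not contain NA")
    if (!is.na(object@label) && !object@label %in% .CLASS_LEVELS)
      msg <- c(msg, sprintf("label must be one of %s",
                            paste(.CLASS_LEVELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a BCGRecording
#'
#' @param samples numeric amplitude series.
#' @param sampleRate sampling rate in Hz (default 100).
#' @param label optional class label (`"hypertensive"` / `"normotensive"`).
#' @param subjectId optional subject identifier.
#' @return A [BCGRecording-class] object.
#' @examples
#' rec <- BCGRecording(sin(2 * pi * (0:999) / 100), sampleRate = 100)
#' duration(rec)
#' @export
BCGRecording <- function(samples, sampleRate = 100, label = NA_character_,
                         subjectId = NA_character_) {
  new("BCGRecording", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate),
      label = as.character(label), subjectId = as.character(subjectId))
}

#' RRSequence: inter-beat intervals from detected heartbeats
#'
#' Ordered RR intervals (seconds) together with the sample indices of the
#' detected beats they derive from. Intervals are the successive differences
#' of `beatIndices / sampleRate`, except that intervals discarded by the
#' physiological plausibility gate are absent.
#'
#' @slot intervals numeric vector of RR intervals in seconds.
#' @slot beatIndices integer sample indices of detected beats.
#' @slot sampleRate sampling rate in Hz of the originating recording.
#' @export
setClass("RRSequence",
  representation(intervals = "numeric", beatIndices = "integer",
                 sampleRate = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@intervals <= 0)) msg <- c(msg, "intervals must be positive")
    if (is.unsorted(object@beatIndices, strictly = TRUE))
      msg <- c(msg, "beatIndices must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct an RRSequence
#'
#' @param intervals RR intervals in seconds.
#' @param beatIndices sample indices of the detected beats (optional; when
#'   omitted, indices are reconstructed from the cumulated intervals).
#' @param sampleRate sample rate in Hz.
#' @return An [RRSequence-class] object.
#' @export
RRSequence <- function(intervals, beatIndices = NULL, sampleRate = 100) {
  intervals <- as.numeric(intervals)
  if (is.null(beatIndices))
    beatIndices <- as.integer(round(c(0, cumsum(intervals)) * sampleRate) + 1L)
  new("RRSequence", intervals = intervals,
      beatIndices = as.integer(beatIndices), sampleRate = as.numeric(sampleRate))
}

#' CARClassifier: an ordered class-association-rule classifier
#'
#' The fitted model: marked rules in precedence order (each a row of the
#' rules table with a list-column antecedent), the default class used when no
#' rule matches, the equal-width discretization scheme fitted on training
#' data, and the mining thresholds.
#'
#' @slot rules data.frame of marked rules in precedence order with columns
#'   `antecedent` (list of named integer vectors, names are feature names,
#'   values bin codes 1-5), `class` (integer 1 = hypertensive,
#'   2 = normotensive), `support`, `confidence`, `nItems`.
#' @slot defaultClass integer class code (1 or 2).
#' @slot scheme list: the discretization scheme from [fitDiscretizer()].
#' @slot minSup,minConf numeric mining thresholds.
#' @export
setClass("CARClassifier",
  representation(rules = "data.frame", defaultClass = "integer",
                 scheme = "list", minSup = "numeric", minConf = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@defaultClass %in% c(1L, 2L))
      msg <- c(msg, "defaultClass must be 1 (hypertensive) or 2 (normotensive)")
    need <- c("antecedent", "class", "support", "confidence", "nItems")
    if (!all(need %in% names(object@rules)))
      msg <- c(msg, paste("rules must have columns:", paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

# ---- generics & accessors ---------------------------------------------------

#' @rdname BCGRecording-class
#' @param object,x a `BCGRecording` or `RRSequence`.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname BCGRecording-class
#' @export
setMethod("samples", "BCGRecording", function(x) x@samples)

#' @rdname BCGRecording-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname BCGRecording-class
#' @export
setMethod("sampleRate", "BCGRecording", function(x) x@sampleRate)
#' @rdname RRSequence-class
#' @export
setMethod("sampleRate", "RRSequence", function(x) x@sampleRate)

#' @rdname BCGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname BCGRecording-class
#' @export
setMethod("nSamples", "BCGRecording", function(x) length(x@samples))

#' @rdname BCGRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname BCGRecording-class
#' @export
setMethod("duration", "BCGRecording", function(x) length(x@samples) / x@sampleRate)

#' @rdname BCGRecording-class
#' @export
setGeneric("subjectLabel", function(x) standardGeneric("subjectLabel"))
#' @rdname BCGRecording-class
#' @export
setMethod("subjectLabel", "BCGRecording", function(x) x@label)

#' @rdname RRSequence-class
#' @param x an `RRSequence`.
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @rdname RRSequence-class
#' @export
setMethod("intervals", "RRSequence", function(x) x@intervals)

#' @rdname RRSequence-class
#' @export
setGeneric("beatIndices", function(x) standardGeneric("beatIndices"))
#' @rdname RRSequence-class
#' @export
setMethod("beatIndices", "RRSequence", function(x) x@beatIndices)

#' @rdname CARClassifier-class
#' @param x a `CARClassifier`.
#' @export
setGeneric("classifierRules", function(x) standardGeneric("classifierRules"))
#' @rdname CARClassifier-class
#' @export
setMethod("classifierRules", "CARClassifier", function(x) x@rules)

#' @rdname CARClassifier-class
#' @export
setGeneric("defaultClass", function(x) standardGeneric("defaultClass"))
#' @rdname CARClassifier-class
#' @export
setMethod("defaultClass", "CARClassifier", function(x) x@defaultClass)

setMethod("show", "BCGRecording", function(object) {
  cat(sprintf("BCGRecording: %d samples @ %g Hz (%.1f s), label=%s, subject=%s\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate,
              object@label, object@subjectId))
})

setMethod("show", "RRSequence", function(object) {
  cat(sprintf("RRSequence: %d intervals, mean RR %.3f s (%.1f bpm)\n",
              length(object@intervals), mean(object@intervals),
              60 / mean(object@intervals)))
})

setMethod("show", "CARClassifier", function(object) {
  cat(sprintf("CARClassifier: %d marked rules, default class %d (%s)\n",
              nrow(object@rules), object@defaultClass,
              .CLASS_LEVELS[object@defaultClass]))
  cat(sprintf("  minSup=%.2f minConf=%.2f, %d discretized features\n",
              object@minSup, object@minConf, length(object@scheme$breaks)))
})

#' Names and groups of the fourteen subject-level features
#'
#' `featureNames()` returns the canonical feature names in table order;
#' `featureGroups()` maps the four group labels to their member features:
#' `TD` (time domain), `FD` (frequency domain), `ND` (non-linear domain)
#' and `BF` (BCG fluctuation).
#'
#' @return Character vector, or named list of character vectors.
#' @export
featureNames <- function() {
  c("Mean", "SDNN", "RMSSD", "PNN50", "vLF", "LF", "HF", "LF_HF",
    "SampEn", "DFA", "ZCR", "ACAC", "ANEP", "ASTC")
}

#' @rdname featureNames
#' @export
featureGroups <- function() {
  list(TD = c("Mean", "SDNN", "RMSSD", "PNN50"),
       FD = c("vLF", "LF", "HF", "LF_HF"),
       ND = c("SampEn", "DFA"),
       BF = c("ZCR", "ACAC", "ANEP", "ASTC"))
}

#' Class labels and their integer codes
#'
#' Hypertensive subjects are coded 1 and normotensive subjects 2 throughout
#' the rule miner and classifier.
#'
#' @return Named integer vector.
#' @export
classCodes <- function() c(hypertensive = 1L, normotensive = 2L)
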