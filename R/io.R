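# Plain-text I/O: recordings as two-column CSV, ground truth as a JSON
# sidecar, RR sequences as single-column CSV.

#' Read and write BCG recordings as CSV
#'
#' Recordings are stored as two-column CSV (`time_s`, `amplitude`); a
#' single-column amplitude file is also accepted when `rate` is supplied.
#'
#' @param recording a [BCGRecording-class].
#' @param path CSV file path.
#' @param truth optional ground-truth list (from [simulateBCG()]) written
#'   as a JSON sidecar next to `path` (same name, `.truth.json` suffix).
#' @return `path`, invisibly (writer); a [BCGRecording-class] (reader).
#' @export
writeBCGRecording <- function(recording, path, truth = NULL) {
  t <- (seq_len(nSamples(recording)) - 1L) / sampleRate(recording)
  utils::write.csv(data.frame(time_s = t, amplitude = samples(recording)),
                   path, row.names = FALSE)
  if (!is.null(truth)) {
    side <- sub("\\.csv$", "", path)
    jsonlite::write_json(
      list(beat_times_s = truth$beat_times_s, true_rr_s = truth$true_rr_s,
           config = unclass(truth$config)),
      paste0(side, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeBCGRecording
#' @param rate sample rate in Hz, required for single-column files;
#'   otherwise inferred from the time column.
#' @param label,subjectId attached to the returned recording.
#' @export
readBCGRecording <- function(path, rate = NULL, label = NA_character_,
                             subjectId = NA_character_) {
  df <- utils::read.csv(path)
  if (ncol(df) >= 2L) {
    fs <- 1 / stats::median(diff(df[[1]]))
    BCGRecording(df[[2]], round(fs, 6), label, subjectId)
  } else {
    if (is.null(rate))
      stop("readBCGRecording: single-column file needs an explicit rate")
    BCGRecording(df[[1]], rate, label, subjectId)
  }
}

#' Read and write RR sequences as single-column CSV of seconds
#'
#' @param rr an [RRSequence-class].
#' @param path CSV file path.
#' @return `path` invisibly (writer); an [RRSequence-class] (reader).
#' @export
writeRRSequence <- function(rr, path) {
  utils::write.csv(data.frame(rr_s = intervals(rr)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRRSequence
#' @param sampleRate sample rate recorded in the restored object.
#' @export
readRRSequence <- function(path, sampleRate = 100) {
  df <- utils::read.csv(path)
  RRSequence(df[[1]], sampleRate = sampleRate)
}
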