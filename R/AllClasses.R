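#' @import methods
NULL

#' EpochSet: multichannel epoched EEG
#'
#' Container for epoched multichannel data: a trials x channels x time array
#' in microvolts, a sampling rate, epoch time stamps (ms relative to the ping
#' trigger), ordered channel names (scalp channels, earlobe references,
#' VEOG/HEOG), per-trial metadata (the trial table), and per-trial keep/drop
#' flags so that every dropped trial is accounted for with a reason.
#'
#' @slot data numeric array, trials x channels x time (microvolts).
#' @slot srate sampling rate in Hz.
#' @slot times numeric vector of time stamps in ms.
#' @slot channels character vector of channel names (dim 2 of \code{data}).
#' @slot trials data.frame of per-trial metadata, one row per epoch.
#' @slot flags data.frame with columns \code{keep} (logical) and
#'   \code{reason} (character, \code{""} for kept trials).
#' @slot log list of processing records (filters applied, interpolations,
#'   rejection details).
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", srate = "numeric", times = "numeric",
                 channels = "character", trials = "data.frame",
                 flags = "data.frame", log = "list"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a trials x channels x time array")
  if (d[2] != length(object@channels)) return("channel count mismatch")
  if (d[3] != length(object@times)) return("time axis mismatch")
  if (nrow(object@trials) != d[1]) return("trial metadata mismatch")
  if (nrow(object@flags) != d[1]) return("flags must cover every trial")
  if (!all(c("keep", "reason") %in% names(object@flags)))
    return("flags needs keep/reason columns")
  if (any(!object@flags$keep & object@flags$reason == ""))
    return("every dropped trial needs a reason")
  if (any(!is.finite(object@data))) return("data must be finite")
  TRUE
})

#' ContinuousEEG: continuous multichannel recording
#'
#' A continuous recording (samples x channels, microvolts) with an event
#' table (sample index, event code, trial index) used to epoch it.
#'
#' @slot data numeric matrix, samples x channels.
#' @slot srate sampling rate in Hz.
#' @slot channels character vector of channel names.
#' @slot events data.frame with columns \code{sample}, \code{code},
#'   \code{trial}.
#' @slot trials data.frame of per-trial metadata matching \code{events$trial}.
#' @exportClass ContinuousEEG
setClass("ContinuousEEG",
  representation(data = "matrix", srate = "numeric", channels = "character",
                 events = "data.frame", trials = "data.frame"))

setValidity("ContinuousEEG", function(object) {
  if (ncol(object@data) != length(object@channels))
    return("channel count mismatch")
  if (!all(c("sample", "code", "trial") %in% names(object@events)))
    return("events needs sample/code/trial columns")
  if (nrow(object@events) &&
      (min(object@events$sample) < 1 ||
       max(object@events$sample) > nrow(object@data)))
    return("events outside recording")
  TRUE
})

#' GazeEpochSet: epoched two-channel gaze traces
#'
#' Fixation-centered gaze epochs (trials x \{x, y\} x time, pixels; x
#' rightward, y upward), blink-interpolated, with per-trial metadata.
#'
#' @slot data numeric array, trials x 2 x time (px).
#' @slot srate sampling rate in Hz.
#' @slot times numeric time stamps in ms.
#' @slot baselined logical; TRUE once the pre-ping baseline was subtracted.
#' @slot trials data.frame of per-trial metadata.
#' @slot flags data.frame with \code{keep}/\code{reason} per trial.
#' @exportClass GazeEpochSet
setClass("GazeEpochSet",
  representation(data = "array", srate = "numeric", times = "numeric",
                 baselined = "logical", trials = "data.frame",
                 flags = "data.frame"))

setValidity("GazeEpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3 || d[2] != 2)
    return("data must be trials x {x,y} x time")
  if (d[3] != length(object@times)) return("time axis mismatch")
  if (nrow(object@trials) != d[1]) return("trial metadata mismatch")
  TRUE
})

#' GazeRecording: continuous gaze log
#'
#' Raw gaze samples in screen pixels (top-left origin, y downward, as emitted
#' by a video eye tracker), with blink windows, per-trial ping-trigger times
#' and a ground-truth log of injected deviations.
#'
#' @slot samples data.frame with \code{time_ms}, \code{x}, \code{y}.
#' @slot blinks data.frame with \code{start_ms}, \code{end_ms}.
#' @slot events data.frame with \code{trial}, \code{onset_ms} (ping trigger).
#' @slot srate sampling rate in Hz.
#' @slot screen numeric length-2, screen centre (px).
#' @slot log list of ground-truth annotations (e.g. deviant trials).
#' @exportClass GazeRecording
setClass("GazeRecording",
  representation(samples = "data.frame", blinks = "data.frame",
                 events = "data.frame", srate = "numeric",
                 screen = "numeric", log = "list"))

#' AUCTimecourse: time-resolved decoding scores
#'
#' Per-subject, per-timepoint area-under-the-ROC-curve decoding scores.
#' Chance is 0.5 regardless of the number of classes (AUC, not accuracy).
#'
#' @slot auc numeric matrix, subjects x timepoints, values in [0, 1].
#' @slot times numeric time stamps in ms.
#' @slot chance numeric chance level (0.5).
#' @slot variant character label of the decoding variant.
#' @exportClass AUCTimecourse
setClass("AUCTimecourse",
  representation(auc = "matrix", times = "numeric", chance = "numeric",
                 variant = "character"))

setValidity("AUCTimecourse", function(object) {
  if (ncol(object@auc) != length(object@times)) return("time axis mismatch")
  if (any(!is.finite(object@auc))) return("AUC values must be finite")
  if (any(object@auc < 0 | object@auc > 1)) return("AUC must lie in [0, 1]")
  if (!identical(object@chance, 0.5)) return("chance level is fixed at 0.5")
  TRUE
})

#' ClusterResult: cluster-based permutation test outcome
#'
#' Maximal contiguous runs (1-D) or connected components (2-D) of
#' supra-threshold test statistics, each with its mass (sum of t) and
#' permutation p-value from a max-statistic sign-flip null.
#'
#' @slot clusters data.frame; for time courses columns \code{start},
#'   \code{end} (ms), \code{mass}, \code{p}; for grids \code{mass}, \code{p}
#'   plus a \code{cells} list-column of cell indices.
#' @slot nPermutations integer number of sign-flip iterations.
#' @slot alpha cluster significance level.
#' @slot type "onesample" or "paired".
#' @slot tCrit cluster-forming threshold on |t|.
#' @slot stat observed t statistic (vector over time, or matrix over grid).
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(clusters = "data.frame", nPermutations = "numeric",
                 alpha = "numeric", type = "character", tCrit = "numeric",
                 stat = "ANY"))

setValidity("ClusterResult", function(object) {
  if (nrow(object@clusters)) {
    pmin <- 1 / (object@nPermutations + 1)
    if (any(object@clusters$p < pmin - 1e-12 | object@clusters$p > 1))
      return("cluster p-values outside [1/(n_perm+1), 1]")
  }
  TRUE
})
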