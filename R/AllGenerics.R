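#' @include AllClasses.R
NULL

#' Accessors for pingmap containers
#'
#' Accessor generics for the package's S4 containers; prefer these over
#' direct slot access.
#'
#' @param object a pingmap S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("keepFlags", function(object) standardGeneric("keepFlags"))
#' @rdname accessors
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))
#' @rdname accessors
#' @export
setGeneric("aucValues", function(object) standardGeneric("aucValues"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("epochData", "GazeEpochSet", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("sampleRate", "EpochSet", function(object) object@srate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "ContinuousEEG", function(object) object@srate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "GazeEpochSet", function(object) object@srate)
#' @rdname accessors
#' @export
setMethod("timePoints", "EpochSet", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("timePoints", "GazeEpochSet", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("timePoints", "AUCTimecourse", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "ContinuousEEG", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("trialInfo", "EpochSet", function(object) object@trials)
#' @rdname accessors
#' @export
setMethod("trialInfo", "ContinuousEEG", function(object) object@trials)
#' @rdname accessors
#' @export
setMethod("trialInfo", "GazeEpochSet", function(object) object@trials)
#' @rdname accessors
#' @export
setMethod("keepFlags", "EpochSet", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("keepFlags", "GazeEpochSet", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("processingLog", "EpochSet", function(object) object@log)
#' @rdname accessors
#' @export
setMethod("aucValues", "AUCTimecourse", function(object) object@auc)
#' @rdname accessors
#' @export
setMethod("clusterTable", "ClusterResult", function(object) object@clusters)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@srate))
  cat(sprintf("  time span %.1f..%.1f ms; %d trials kept, %d dropped\n",
              min(object@times), max(object@times),
              sum(object@flags$keep), sum(!object@flags$keep)))
})

setMethod("show", "ContinuousEEG", function(object) {
  cat(sprintf("ContinuousEEG: %d samples x %d channels @ %g Hz; %d events\n",
              nrow(object@data), ncol(object@data), object@srate,
              nrow(object@events)))
})

setMethod("show", "GazeEpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("GazeEpochSet: %d trials x {x,y} x %d samples @ %g Hz (%s)\n",
              d[1], d[3], object@srate,
              if (object@baselined) "baselined" else "raw"))
})

setMethod("show", "GazeRecording", function(object) {
  cat(sprintf("GazeRecording: %d samples @ %g Hz; %d blinks; %d trials\n",
              nrow(object@samples), object@srate, nrow(object@blinks),
              nrow(object@events)))
})

setMethod("show", "AUCTimecourse", function(object) {
  cat(sprintf("AUCTimecourse [%s]: %d subjects x %d timepoints, mean AUC %.3f\n",
              object@variant, nrow(object@auc), ncol(object@auc),
              mean(object@auc)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s, %d permutations, alpha %.3g): %d cluster(s)\n",
              object@type, object@nPermutations, object@alpha,
              nrow(object@clusters)))
  if (nrow(object@clusters)) print(object@clusters[
    , setdiff(names(object@clusters), "cells"), drop = FALSE])
})
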