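#' Lateralized ERP waveforms (N2pc-style)
#'
#' Computes contralateral and ipsilateral average waveforms at a posterior
#' electrode pair, after 30 Hz zero-phase low-pass filtering and baseline
#' correction on the 200 ms pre-onset window. Trial selection:
#' \describe{
#'   \item{search}{targets on the left or right hemifield, with the
#'     distractor absent or on the vertical meridian.}
#'   \item{ping}{HP location left or right (the lateral factor is the HP
#'     location).}
#' }
#' With the default pair, PO7 is contralateral to right-hemifield stimuli
#' and PO8 to left-hemifield stimuli; the difference wave is contra minus
#' ipsi.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} time-locked to the
#'   relevant display (kept trials are used).
#' @param selection "search" or "ping".
#' @param pair electrode pair, left then right (c("PO7", "PO8")).
#' @param lowpass_hz low-pass cutoff (30).
#' @param baseline baseline window in ms (c(-200, 0)).
#' @return list of class \code{ERPWaveforms}: \code{times}, \code{contra},
#'   \code{ipsi}, \code{difference} (microvolts), \code{n_trials},
#'   \code{selection}.
#' @export
lateralizedErp <- function(epochs, selection = c("search", "ping"),
                           pair = c("PO7", "PO8"), lowpass_hz = 30,
                           baseline = c(-200, 0)) {
  selection <- match.arg(selection)
  tr <- epochs@trials
  keep <- epochs@flags$keep
  leftLocs <- c(3, 4, 5)      # left hemifield (0 = right, CCW)
  rightLocs <- c(7, 0, 1)
  vertical <- c(2, 6)
  if (selection == "search") {
    lateral <- keep & tr$target_location %in% c(leftLocs, rightLocs) &
      (is.na(tr$distractor_location) | tr$distractor_location %in% vertical)
    side <- ifelse(tr$target_location %in% leftLocs, "L", "R")
  } else {
    lateral <- keep & !is.na(tr$hp_location) &
      tr$hp_location %in% c(leftLocs, rightLocs)
    side <- ifelse(!is.na(tr$hp_location) & tr$hp_location %in% leftLocs,
                   "L", "R")
  }
  if (!any(lateral)) stop("no trials match the selection", call. = FALSE)

  ci <- match(pair, epochs@channels)
  if (anyNA(ci)) stop("electrode pair not found", call. = FALSE)
  h <- firLowpass(epochs@srate, lowpass_hz)
  bi <- timeIndex(epochs@times, baseline)
  wave <- function(chan, rows) {
    if (!length(rows)) return(rep(NA_real_, length(epochs@times)))
    w <- colMeans(matrix(epochs@data[rows, chan, ], nrow = length(rows)))
    w <- firApply(w, h)
    w - mean(w[bi])
  }
  li <- which(lateral & side == "L")
  ri <- which(lateral & side == "R")
  # contra: PO7 (left electrode) for right-hemifield, PO8 for left-hemifield
  contra <- (wave(ci[1], ri) * length(ri) + wave(ci[2], li) * length(li)) /
    (length(ri) + length(li))
  ipsi <- (wave(ci[1], li) * length(li) + wave(ci[2], ri) * length(ri)) /
    (length(ri) + length(li))
  structure(list(times = epochs@times, contra = contra, ipsi = ipsi,
                 difference = contra - ipsi,
                 n_trials = length(li) + length(ri),
                 selection = selection, pair = pair),
            class = "ERPWaveforms")
}
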