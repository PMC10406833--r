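#' Gaze bias parameters for the synthetic eye tracker
#'
#' Controls the simulated gaze stream: fixational jitter is a mean-reverting
#' random walk around the fixation point; an optional constant offset pulls
#' gaze toward the current HP location on biased blocks; an optional slow
#' drift wanders over the experiment; blinks appear as logged dropout
#' windows with extreme samples; a configurable fraction of trials receives
#' a large sustained deviation (for exercising gaze-based trial exclusion).
#'
#' @param toward_px constant offset toward the HP location (px; 0 = none).
#' @param jitter_sd_px stationary SD of fixational jitter.
#' @param mean_revert per-sample mean-reversion rate of the jitter walk.
#' @param slow_drift_px amplitude of a slow sinusoidal drift across the
#'   experiment (0 = none).
#' @param blink_rate_hz blink rate.
#' @param blink_dur_ms blink duration.
#' @param deviant_fraction fraction of trials given a sustained deviation.
#' @param deviant_px deviation amplitude in px (58 px is about 1.5 degrees
#'   at the default screen geometry).
#' @param srate tracker sampling rate (500, 1000 or 2000 Hz).
#' @param screen_center_px screen centre (fixation) in native pixels.
#' @return list of class \code{GazeBias}.
#' @export
gazeBias <- function(toward_px = 0, jitter_sd_px = 4, mean_revert = 0.02,
                     slow_drift_px = 0, blink_rate_hz = 0.05,
                     blink_dur_ms = 120, deviant_fraction = 0,
                     deviant_px = 58, srate = 1000,
                     screen_center_px = c(960, 540)) {
  if (!srate %in% c(500, 1000, 2000))
    stop("parameter error: srate must be 500, 1000 or 2000 Hz",
         call. = FALSE)
  b <- as.list(environment())
  class(b) <- "GazeBias"
  b
}

# Unit vector pointing at location index i (0 = right, counter-clockwise),
# in a y-up frame.
locationVector <- function(i) {
  a <- i * pi / 4
  c(cos(a), sin(a))
}

#' Generate a synthetic gaze recording
#'
#' Simulates one continuous gaze log covering every trial of a schedule.
#' Native tracker coordinates are emitted: screen pixels with the origin at
#' the top-left corner and y increasing downward; fixation sits at
#' \code{screen_center_px}. Each trial occupies a fixed slot on the
#' timeline, with the ping trigger at the scheduled jitter after trial
#' onset. Blink windows are logged and filled with off-screen extreme
#' samples, as video trackers report.
#'
#' @param schedule trial table from \code{\link{generateSchedule}}.
#' @param bias a \code{\link{gazeBias}}.
#' @param seed integer seed.
#' @param trial_span_ms time simulated around each ping trigger
#'   (default c(-800, 1200)).
#' @return A \code{\linkS4class{GazeRecording}}; \code{log$deviant_trials}
#'   holds the ground-truth trials given a sustained deviation.
#' @export
generateGaze <- function(schedule, bias = gazeBias(), seed = 1L,
                         trial_span_ms = c(-800, 1200)) {
  srate <- bias$srate
  step <- 1000 / srate
  nper <- length(seq(trial_span_ms[1], trial_span_ms[2], by = step))
  ntrial <- nrow(schedule)
  span <- trial_span_ms[2] - trial_span_ms[1]

  withSeed(seed, {
    devTrials <- integer(0)
    if (bias$deviant_fraction > 0)
      devTrials <- sort(sample(ntrial, round(bias$deviant_fraction * ntrial)))

    total <- ntrial * nper
    tglobal <- (seq_len(total) - 1) * step
    # mean-reverting fixational walk, simulated over the whole recording
    sdstep <- bias$jitter_sd_px * sqrt(2 * bias$mean_revert)
    ex <- stats::rnorm(total, 0, sdstep)
    ey <- stats::rnorm(total, 0, sdstep)
    a <- 1 - bias$mean_revert
    x <- stats::filter(ex, a, method = "recursive")
    y <- stats::filter(ey, a, method = "recursive")
    x <- as.numeric(x); y <- as.numeric(y)
    if (bias$slow_drift_px > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      x <- x + bias$slow_drift_px * sin(2 * pi * tglobal / (tglobal[total]) +
                                        ph[1])
      y <- y + bias$slow_drift_px * sin(4 * pi * tglobal / (tglobal[total]) +
                                        ph[2])
    }

    events <- data.frame(trial = seq_len(ntrial),
                         onset_ms = (seq_len(ntrial) - 1) * nper * step -
                           trial_span_ms[1])
    for (tr in seq_len(ntrial)) {
      idx <- (tr - 1) * nper + seq_len(nper)
      hp <- schedule$hp_location[tr]
      if (!is.na(hp) && bias$toward_px != 0) {
        v <- bias$toward_px * locationVector(hp)
        x[idx] <- x[idx] + v[1]
        y[idx] <- y[idx] + v[2]
      }
      if (tr %in% devTrials) {
        # sustained deviation in a random direction, starting post-trigger
        ang <- stats::runif(1, 0, 2 * pi)
        on <- which(tglobal[idx] - tglobal[idx[1]] + trial_span_ms[1] > 50)
        x[idx[on]] <- x[idx[on]] + bias$deviant_px * cos(ang)
        y[idx[on]] <- y[idx[on]] + bias$deviant_px * sin(ang)
      }
    }

    # native screen coordinates: y grows downward
    xs <- bias$screen_center_px[1] + x
    ys <- bias$screen_center_px[2] - y

    blinks <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
    if (bias$blink_rate_hz > 0) {
      nb <- stats::rpois(1, bias$blink_rate_hz * total / srate)
      if (nb > 0) {
        st <- sort(stats::runif(nb, 0, tglobal[total] - bias$blink_dur_ms))
        en <- st + bias$blink_dur_ms
        keep <- c(TRUE, st[-1] > en[-nb] + 50)
        blinks <- data.frame(start_ms = st[keep], end_ms = en[keep])
        for (b in seq_len(nrow(blinks))) {
          bi <- which(tglobal >= blinks$start_ms[b] &
                      tglobal <= blinks$end_ms[b])
          xs[bi] <- 1e7
          ys[bi] <- 1e7
        }
      }
    }

    new("GazeRecording",
        samples = data.frame(time_ms = tglobal, x = xs, y = ys),
        blinks = blinks, events = events, srate = srate,
        screen = bias$screen_center_px,
        log = list(deviant_trials = devTrials,
                   trial_span_ms = trial_span_ms))
  })
}
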