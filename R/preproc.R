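#' Artifact-rejection configuration
#'
#' Parameters of the EMG scan and trial-exclusion stages. The EMG scan
#' band-passes 110-140 Hz, takes the analytic-signal envelope smoothed over
#' 200 ms, z-scores it across trials per channel, and marks epochs whose
#' accumulated (channel-summed) z exceeds a subject-adaptive threshold
#' median + \code{z_mad_mult} * MAD of the per-trial accumulated z.
#'
#' @param band_lo,band_hi EMG detection band edges in Hz (110/140).
#' @param z_mad_mult MAD multiplier of the adaptive threshold (default 3).
#' @param z_threshold fixed accumulated-z threshold; overrides the adaptive
#'   rule when non-NULL.
#' @param inspect_window ms window inspected for artifacts (-200..600).
#' @param max_interp_electrodes electrodes interpolated per marked epoch
#'   before the epoch is dropped (5).
#' @param envelope_smooth_ms boxcar width for envelope smoothing (200).
#' @param gaze_limit_deg gaze-deviation exclusion limit in degrees (1).
#' @param px_per_deg pixel pitch conversion; the default 38.5 px/degree
#'   corresponds to a 1920-px, 52.7-cm-wide monitor viewed at 60 cm.
#' @param gaze_segment_ms segment length for the drift statistic (40).
#' @param heog_window_ms,heog_step_ms,heog_threshold_uv step-detector
#'   parameters for the HEOG fallback (200 ms / 10 ms / 20 uV).
#' @param max_gaze_drop_fraction fraction of dropped trials above which a
#'   low-quality-gaze subject is switched to the HEOG detector (0.3).
#' @return list of class \code{RejectionConfig}.
#' @export
rejectionConfig <- function(band_lo = 110, band_hi = 140, z_mad_mult = 3,
                            z_threshold = NULL,
                            inspect_window = c(-200, 600),
                            max_interp_electrodes = 5,
                            envelope_smooth_ms = 200,
                            gaze_limit_deg = 1, px_per_deg = 38.5,
                            gaze_segment_ms = 40,
                            heog_window_ms = 200, heog_step_ms = 10,
                            heog_threshold_uv = 20,
                            max_gaze_drop_fraction = 0.3) {
  cfg <- as.list(environment())
  class(cfg) <- "RejectionConfig"
  if (cfg$band_lo >= cfg$band_hi)
    stop("band_lo must be below band_hi", call. = FALSE)
  cfg
}

#' Re-reference epochs to the earlobe average
#'
#' Subtracts the mean of the two earlobe reference channels (EXG1/EXG2)
#' from every channel.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @return the re-referenced \code{EpochSet}.
#' @export
rereference <- function(epochs) {
  refs <- match(refChannels(), epochs@channels)
  if (anyNA(refs)) stop("missing reference channels", call. = FALSE)
  ref <- (epochs@data[, refs[1], , drop = FALSE] +
            epochs@data[, refs[2], , drop = FALSE]) / 2
  d <- dim(epochs@data)
  epochs@data <- epochs@data - ref[, rep(1, d[2]), , drop = FALSE]
  epochs@log <- c(epochs@log, list(reference = "earlobe average"))
  epochs
}

#' Preprocess a continuous recording into epochs
#'
#' Re-references to the earlobe average, applies a zero-phase
#' Hamming-windowed FIR high-pass at \code{highpass} Hz (filter length
#' capped at a third of the recording), and epochs around the ping triggers
#' in the event table, joining trial metadata.
#'
#' @param raw a \code{\linkS4class{ContinuousEEG}}.
#' @param cfg a \code{\link{rejectionConfig}} (carried into the log).
#' @param window epoch window in ms (default c(-700, 1100)).
#' @param highpass high-pass cutoff in Hz (0.01).
#' @return an \code{\linkS4class{EpochSet}} with one epoch per event.
#' @export
preprocessRaw <- function(raw, cfg = rejectionConfig(),
                          window = c(-700, 1100), highpass = 0.01) {
  refs <- match(refChannels(), raw@channels)
  if (anyNA(refs)) stop("missing reference channels", call. = FALSE)
  x <- raw@data
  x <- x - rowMeans(x[, refs, drop = FALSE])

  n <- nrow(x)
  h <- designHighpass(raw@srate, highpass, n)
  x <- firApply(x, h)

  srate <- raw@srate
  pre <- round(-window[1] / 1000 * srate)
  post <- round(window[2] / 1000 * srate)
  times <- (seq_len(pre + post + 1) - pre - 1) * 1000 / srate
  ev <- raw@events
  if (any(ev$sample - pre < 1 | ev$sample + post > n))
    stop("events outside recording", call. = FALSE)
  ntrial <- nrow(ev)
  dat <- array(0, c(ntrial, ncol(x), length(times)))
  for (i in seq_len(ntrial))
    dat[i, , ] <- t(x[(ev$sample[i] - pre):(ev$sample[i] + post), ])
  trials <- raw@trials[ev$trial, , drop = FALSE]
  rownames(trials) <- NULL
  flags <- data.frame(keep = rep(TRUE, ntrial), reason = rep("", ntrial),
                      stringsAsFactors = FALSE)
  new("EpochSet", data = dat, srate = srate, times = times,
      channels = raw@channels, trials = trials, flags = flags,
      log = list(reference = "earlobe average",
                 highpass_hz = highpass, highpass_taps = length(h),
                 config = cfg))
}

# High-pass design with data-length cap; returns the impulse response.
designHighpass <- function(srate, cutoff, n_samples) {
  # Hamming transition ~ 3.3 / (order / srate); a literal 0.01 Hz band needs
  # more taps than desk-scale recordings hold, so the order is capped.
  order <- ceiling(3.3 * srate / cutoff)
  order <- min(order, floor((n_samples - 1) / 3))
  if (order %% 2 == 1) order <- order - 1
  order <- max(order, 2)
  firHighpass(srate, cutoff, order)
}

#' Designed frequency response of the preprocessing high-pass
#'
#' Gain of the Hamming FIR high-pass actually used for a recording of
#' \code{n_samples} samples, evaluated at \code{freq} Hz. Used to verify the
#' measured attenuation of slow components against the designed response.
#'
#' @param srate sampling rate (Hz).
#' @param n_samples recording length in samples (determines the tap cap).
#' @param freq frequencies (Hz) at which to evaluate the gain.
#' @param highpass cutoff (Hz).
#' @return numeric vector of gains.
#' @export
highpassGain <- function(srate, n_samples, freq, highpass = 0.01) {
  h <- designHighpass(srate, highpass, n_samples)
  k <- seq_along(h) - 1
  vapply(freq, function(f)
    Mod(sum(h * exp(-2i * pi * f * k / srate))), numeric(1))
}

# Per-trial accumulated z statistic of the EMG envelope, plus per-channel
# contributions. env: trials x channels x window-time z-scored envelope.
emgAccumulatedZ <- function(z) {
  chanSum <- apply(z, c(1, 3), sum)       # trials x time
  acc <- apply(chanSum, 1, max)           # max over the inspected window
  peak <- apply(chanSum, 1, which.max)
  list(acc = acc, peak = peak)
}

emgEnvelope <- function(dat, h, smooth) {
  # dat: channels x time for one trial -> smoothed band envelope
  y <- firApply(t(dat), h)                # time x channels
  env <- hilbertEnvelope(y)
  boxcarSmooth(env, smooth)
}

#' EMG artifact scan with iterative spline repair
#'
#' Detects muscle-contaminated epochs: the scalp channels are band-pass
#' filtered (110-140 Hz), the analytic-signal envelope is smoothed and
#' z-scored per channel across trials within the inspection window, and
#' per-trial accumulated z is the maximum over time of the channel-summed z.
#' Epochs above the subject-adaptive threshold (median + k * MAD) are
#' marked; for each marked epoch the five electrodes contributing most to
#' the accumulated z around its peak are spherically spline-interpolated one
#' at a time, re-testing after each; epochs still above threshold are
#' dropped. Every interpolation and drop is logged.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} at native sampling rate.
#' @param cfg a \code{\link{rejectionConfig}}.
#' @return the \code{EpochSet} with repaired data, updated flags and a
#'   \code{rejection} entry in the log (threshold, marked trials,
#'   interpolations, drops).
#' @export
emgScanRepair <- function(epochs, cfg = rejectionConfig()) {
  scalp <- match(scalpChannels(), epochs@channels)
  win <- timeIndex(epochs@times, cfg$inspect_window)
  h <- firBandpass(epochs@srate, cfg$band_lo, cfg$band_hi, order = 128)
  smooth <- max(1, round(cfg$envelope_smooth_ms / 1000 * epochs@srate))
  ntrial <- dim(epochs@data)[1]

  env <- array(0, c(ntrial, length(scalp), length(win)))
  for (tr in seq_len(ntrial))
    env[tr, , ] <- t(emgEnvelope(epochs@data[tr, scalp, ], h, smooth)[win, ])

  # robust normalization so that artifact trials cannot mask themselves by
  # inflating the per-channel scale
  mu <- apply(env, 2, function(e) stats::median(as.numeric(e)))
  sdv <- apply(env, 2, function(e) stats::mad(as.numeric(e)))
  sdv[sdv == 0] <- apply(env, 2, function(e) stats::sd(as.numeric(e)))[
    sdv == 0]
  zOf <- function(e) sweep(sweep(e, 1, mu), 1, sdv, "/")  # channels x time
  z <- env
  for (tr in seq_len(ntrial)) z[tr, , ] <- zOf(env[tr, , ])

  st <- emgAccumulatedZ(z)
  thr <- if (!is.null(cfg$z_threshold)) cfg$z_threshold
  else stats::median(st$acc) + cfg$z_mad_mult * stats::mad(st$acc)
  marked <- which(st$acc > thr)
  if (length(marked) > 0.5 * ntrial)
    stop("data-quality error: more than half of the epochs exceed the EMG ",
         "threshold", call. = FALSE)

  interpLog <- list()
  dropped <- integer(0)
  montage <- standardMontage()
  for (tr in marked) {
    ztr <- z[tr, , ]
    acc <- st$acc[tr]
    # contribution: channel z summed around the accumulated-z peak
    peak <- st$peak[tr]
    nb <- max(1, round(100 / 1000 * epochs@srate / 2))
    seg <- max(1, peak - nb):min(length(win), peak + nb)
    contrib <- rowSums(ztr[, seg, drop = FALSE])
    worst <- order(contrib, decreasing = TRUE)[
      seq_len(cfg$max_interp_electrodes)]
    done <- integer(0)
    for (w in worst) {
      if (acc <= thr) break
      done <- c(done, w)
      good <- setdiff(seq_along(scalp), done)
      interp <- splineInterpolateMatrix(
        epochs@data[tr, scalp[good], ], montage$channel[good],
        montage$channel[done], montage)
      epochs@data[tr, scalp[done], ] <- interp
      e <- emgEnvelope(epochs@data[tr, scalp, ], h, smooth)[win, ]
      ztr <- zOf(t(e))
      acc <- max(colSums(ztr))
    }
    interpLog[[as.character(tr)]] <-
      list(channels = montage$channel[done], final_z = acc)
    if (acc > thr) {
      dropped <- c(dropped, tr)
      epochs@flags$keep[tr] <- FALSE
      epochs@flags$reason[tr] <- "EMG artifact"
    }
  }
  epochs@log <- c(epochs@log, list(rejection = list(
    threshold = thr, accumulated_z = st$acc, marked = marked,
    interpolations = interpLog, dropped = dropped)))
  validObject(epochs)
  epochs
}

#' Exclude trials by gaze deviation (with HEOG fallback)
#'
#' For each trial the gaze trace is baselined on the 300 ms pre-ping window
#' and averaged in consecutive 40 ms segments; if the maximum Euclidean
#' deviation of any segment mean exceeds \code{gaze_limit_deg}, the trial is
#' dropped. If more than \code{max_gaze_drop_fraction} of a subject's trials
#' would drop and the gaze stream is flagged low-quality, the subject falls
#' back to an HEOG step detector (200 ms window sliding in 10 ms steps,
#' flagged when the two half-window means differ by more than 20 uV).
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @param gaze a trial-matched \code{\linkS4class{GazeEpochSet}} (raw,
#'   fixation-centered px), or NULL to force the HEOG fallback.
#' @param cfg a \code{\link{rejectionConfig}}.
#' @param gaze_low_quality logical: operator flag that the gaze stream is
#'   unreliable.
#' @return the \code{EpochSet} with updated flags and a \code{gaze_exclusion}
#'   log entry (method used and per-trial decisions).
#' @export
excludeByGaze <- function(epochs, gaze, cfg = rejectionConfig(),
                          gaze_low_quality = FALSE) {
  useHeog <- is.null(gaze)
  drops <- NULL
  if (!useHeog) {
    drops <- gazeDeviationDrops(gaze, epochs, cfg)
    if (mean(drops) > cfg$max_gaze_drop_fraction && gaze_low_quality)
      useHeog <- TRUE
  }
  if (useHeog) {
    heog <- match("HEOG", epochs@channels)
    if (is.na(heog))
      stop("no gaze and no HEOG channel available", call. = FALSE)
    drops <- heogStepDrops(epochs, heog, cfg)
    method <- "heog_step"
    reason <- "HEOG step"
  } else {
    method <- "gaze_deviation"
    reason <- "gaze deviation > limit"
  }
  newly <- which(drops & epochs@flags$keep)
  epochs@flags$keep[newly] <- FALSE
  epochs@flags$reason[newly] <- reason
  epochs@log <- c(epochs@log, list(gaze_exclusion = list(
    method = method, dropped = which(drops))))
  epochs
}

gazeDeviationDrops <- function(gaze, epochs, cfg) {
  tm <- gaze@times
  base <- timeIndex(tm, c(-300, 0))
  post <- which(tm >= -300)
  segLen <- max(1, round(cfg$gaze_segment_ms / 1000 * gaze@srate))
  limit <- cfg$gaze_limit_deg * cfg$px_per_deg
  ntrial <- dim(gaze@data)[1]
  vapply(seq_len(ntrial), function(tr) {
    x <- gaze@data[tr, 1, ] - mean(gaze@data[tr, 1, base])
    y <- gaze@data[tr, 2, ] - mean(gaze@data[tr, 2, base])
    nseg <- floor(length(post) / segLen)
    if (nseg == 0) return(FALSE)
    idx <- post[seq_len(nseg * segLen)]
    mx <- colMeans(matrix(x[idx], segLen, nseg))
    my <- colMeans(matrix(y[idx], segLen, nseg))
    max(sqrt(mx^2 + my^2)) > limit
  }, logical(1))
}

heogStepDrops <- function(epochs, heog, cfg) {
  srate <- epochs@srate
  half <- max(1, round(cfg$heog_window_ms / 2 / 1000 * srate))
  step <- max(1, round(cfg$heog_step_ms / 1000 * srate))
  win <- timeIndex(epochs@times, cfg$inspect_window)
  ntrial <- dim(epochs@data)[1]
  vapply(seq_len(ntrial), function(tr) {
    x <- epochs@data[tr, heog, win]
    starts <- seq(1, length(x) - 2 * half + 1, by = step)
    any(vapply(starts, function(s) {
      abs(mean(x[s:(s + half - 1)]) - mean(x[(s + half):(s + 2 * half - 1)]))
    }, numeric(1)) > cfg$heog_threshold_uv)
  }, logical(1))
}

#' Drop flagged trials
#'
#' Returns a copy of an epoch container restricted to kept trials; the log
#' records the removed trials so that every input trial remains accounted
#' for.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @return the reduced \code{EpochSet}.
#' @export
dropFlagged <- function(epochs) {
  keep <- epochs@flags$keep
  removed <- data.frame(trial = which(!keep),
                        reason = epochs@flags$reason[!keep])
  epochs@data <- epochs@data[keep, , , drop = FALSE]
  epochs@trials <- epochs@trials[keep, , drop = FALSE]
  rownames(epochs@trials) <- NULL
  epochs@flags <- epochs@flags[keep, , drop = FALSE]
  rownames(epochs@flags) <- NULL
  epochs@log <- c(epochs@log, list(removed = removed))
  epochs
}
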