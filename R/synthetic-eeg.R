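#' EEG signal model for the synthetic generator
#'
#' Describes how synthetic epochs are composed: spatially correlated 1/f
#' background noise everywhere; on ping trials only, a class-independent
#' evoked response (the ping ERP) plus a class-specific spatial pattern --
#' one unit-norm channel vector per HP location -- modulated by a Gaussian
#' temporal kernel; optionally a pattern tied to the previous trial's target
#' location (8 classes), a slow cross-experiment drift of the evoked
#' response (the temporal confound probed by dummy decoding), band-limited
#' EMG bursts on a fraction of trials, and blinks on VEOG/frontal channels.
#' With \code{class_gain = 0}, \code{prev_target_gain = 0} and
#' \code{drift_gain = 0}, epochs are exchangeable across HP labels.
#'
#' Amplitudes are in microvolts. The defaults place a few-microvolt evoked
#' pattern on top of ~10 microvolt RMS background activity, the typical
#' ratio for scalp EEG evoked responses.
#'
#' @param class_gain peak amplitude of the HP-class-specific pattern.
#' @param kernel_peak_ms,kernel_width_ms Gaussian temporal kernel of the
#'   class-specific response (peak 350 ms, width 50 ms, so the injected
#'   information spans the 300-400 ms window).
#' @param ping_erp_gain amplitude of the class-independent ping ERP.
#' @param erp_peak_ms,erp_width_ms temporal kernel of the ping ERP.
#' @param noise_sd per-channel background noise SD.
#' @param noise_exponent 1/f spectral slope of the spatially correlated
#'   background component.
#' @param sensor_noise_frac fraction of the noise variance contributed by
#'   channel-independent broadband sensor noise (the 1/f brain background
#'   is spatially mixed, but amplifier/thermal noise is not).
#' @param drift_gain amplitude of the slow cross-experiment drift pattern
#'   (0 disables it).
#' @param prev_target_gain amplitude of the previous-trial target pattern.
#' @param emg_trial_fraction fraction of trials receiving an EMG burst.
#' @param emg_gain burst SD in the 110-140 Hz band.
#' @param blink_rate_hz blink rate; blinks load on VEOG and frontal sites.
#' @param blink_gain blink peak amplitude on VEOG.
#' @param common_gain amplitude of the recording-reference signal shared by
#'   all channels (removed by earlobe re-referencing).
#' @param srate sampling rate in Hz.
#' @return list of class \code{SignalModel}.
#' @export
signalModel <- function(class_gain = 8, kernel_peak_ms = 350,
                        kernel_width_ms = 50, ping_erp_gain = 12,
                        erp_peak_ms = 150, erp_width_ms = 60,
                        noise_sd = 10, noise_exponent = 1,
                        sensor_noise_frac = 0.3,
                        drift_gain = 0, prev_target_gain = 0,
                        emg_trial_fraction = 0, emg_gain = 40,
                        blink_rate_hz = 0, blink_gain = 150,
                        common_gain = 15, srate = 512) {
  m <- as.list(environment())
  class(m) <- "SignalModel"
  m
}

# Unit-norm random channel pattern.
unitPattern <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

# Background noise: spatially mixed 1/f component plus channel-independent
# broadband sensor noise; time x nchan x batch, total per-channel SD = sd.
# Generated at a composite FFT length (highly factorizable) and truncated,
# and for a whole batch of trials in one mvfft call.
pinkNoise <- function(ntime, nchan, sd, exponent, mix, sensor_frac = 0.3,
                      batch = 1) {
  nfft <- stats::nextn(ntime)
  ncol <- nchan * batch
  w <- matrix(stats::rnorm(nfft * ncol), nfft, ncol)
  f <- c(0, seq_len(nfft - 1))
  f <- pmin(f, nfft - f)             # two-sided frequency index
  g <- ifelse(f == 0, 0, f^(-exponent / 2))
  W <- stats::mvfft(w) * g
  x <- Re(stats::mvfft(W, inverse = TRUE))[seq_len(ntime), , drop = FALSE] /
    nfft
  # mix channels within each trial of the batch
  dim(x) <- c(ntime, nchan, batch)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(ntime * batch, nchan)
  x <- x %*% mix
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  x <- x * rep(1 / sds, each = ntime * batch)
  s <- matrix(stats::rnorm(ntime * batch * nchan), ntime * batch, nchan)
  x <- sd * (sqrt(1 - sensor_frac) * x + sqrt(sensor_frac) * s)
  dim(x) <- c(ntime, batch, nchan)
  aperm(x, c(1, 3, 2))               # time x channels x batch
}

#' Generate synthetic multichannel EEG epochs
#'
#' Creates raw (unreferenced) epochs for every trial of a schedule, following
#' a \code{\link{signalModel}}: 64 scalp channels plus two earlobe reference
#' channels (EXG1/EXG2) and bipolar VEOG/HEOG, sampled at 512 Hz over
#' -700..1100 ms around the ping trigger. Class-specific patterns are evoked
#' on ping trials only; injected EMG bursts and blinks are logged as ground
#' truth. With \code{mode = "continuous"} the same epochs are laid out on a
#' continuous timeline with an event table, for exercising
#' \code{\link{preprocessRaw}}.
#'
#' @param schedule trial table from \code{\link{generateSchedule}}.
#' @param model a \code{\link{signalModel}}.
#' @param seed integer seed.
#' @param mode "epochs" (default) or "continuous".
#' @param window epoch window in ms (default c(-700, 1100)).
#' @return An \code{\linkS4class{EpochSet}}, or a
#'   \code{\linkS4class{ContinuousEEG}} for \code{mode = "continuous"}. The
#'   processing log carries \code{emg_trials}, \code{emg_channels} and
#'   \code{blink_trials} ground truth, and the class patterns used.
#' @export
generateEEG <- function(schedule, model = signalModel(), seed = 1L,
                        mode = c("epochs", "continuous"),
                        window = c(-700, 1100)) {
  mode <- match.arg(mode)
  srate <- model$srate
  step <- 1000 / srate
  times <- seq(window[1], window[2], by = step)
  ntime <- length(times)
  chans <- allChannels()
  nscalp <- length(scalpChannels())
  nchan <- length(chans)
  ntrial <- nrow(schedule)

  withSeed(seed, {
    # Fixed per-run spatial structure.
    mix <- {
      A <- matrix(stats::rnorm(nchan * nchan), nchan) / sqrt(nchan)
      R <- chol(crossprod(A) + diag(0.5, nchan))
      R / sqrt(mean(diag(crossprod(R))))
    }
    classPat <- vapply(1:8, function(i) unitPattern(nscalp),
                       numeric(nscalp))   # one per location; HP uses 0..7
    prevPat <- vapply(1:8, function(i) unitPattern(nscalp), numeric(nscalp))
    erpPat <- unitPattern(nscalp)
    driftPat <- unitPattern(nscalp)
    kClass <- gaussKernel(times, model$kernel_peak_ms, model$kernel_width_ms)
    kErp <- gaussKernel(times, model$erp_peak_ms, model$erp_width_ms)

    emgTrials <- integer(0)
    if (model$emg_trial_fraction > 0)
      emgTrials <- sort(sample(ntrial,
                               round(model$emg_trial_fraction * ntrial)))
    emgChan <- list()
    blinkTrials <- integer(0)
    emgH <- if (length(emgTrials))
      firBandpass(srate, 110, 140, order = 128) else NULL

    dat <- array(0, dim = c(ntrial, nchan, ntime))
    driftEnv <- 2 * (seq_len(ntrial) - 1) / max(ntrial - 1, 1) - 1
    inspect <- timeIndex(times, c(-200, 600))

    batchSize <- 16L
    noiseBatch <- NULL
    for (tr in seq_len(ntrial)) {
      j <- (tr - 1L) %% batchSize
      if (j == 0L)
        noiseBatch <- pinkNoise(ntime, nchan, model$noise_sd,
                                model$noise_exponent, mix,
                                model$sensor_noise_frac,
                                batch = min(batchSize, ntrial - tr + 1L))
      x <- noiseBatch[, , j + 1L]
      # common recording-reference signal, removed by re-referencing
      if (model$common_gain > 0) {
        cm <- model$common_gain *
          sin(2 * pi * (times / 1000) * stats::runif(1, 0.5, 2) +
              stats::runif(1, 0, 2 * pi))
        x <- x + cm
      }
      if (schedule$ping[tr]) {
        ev <- model$ping_erp_gain * outer(kErp, erpPat)
        hp <- schedule$hp_location[tr]
        if (!is.na(hp) && model$class_gain > 0)
          ev <- ev + model$class_gain * outer(kClass, classPat[, hp + 1])
        pv <- schedule$prev_target_location[tr]
        if (!is.na(pv) && model$prev_target_gain > 0)
          ev <- ev + model$prev_target_gain * outer(kClass, prevPat[, pv + 1])
        if (model$drift_gain > 0)
          ev <- ev + model$drift_gain * driftEnv[tr] * outer(kErp, driftPat)
        x[, seq_len(nscalp)] <- x[, seq_len(nscalp)] + ev
      }
      if (tr %in% emgTrials) {
        nch <- sample(1:3, 1)
        ch <- sample(nscalp, nch)
        emgChan[[as.character(tr)]] <- ch
        w0 <- sample(inspect[seq_len(length(inspect) - 80)], 1)
        wlen <- sample(80:200, 1)  # 150-400 ms at 512 Hz
        wi <- w0:min(w0 + wlen, ntime)
        burst <- firApply(matrix(stats::rnorm(length(wi) * nch), ncol = nch),
                          emgH)
        burst <- matrix(burst, ncol = nch)
        burst <- burst * rep(model$emg_gain / apply(burst, 2, stats::sd),
                             each = nrow(burst))
        x[wi, ch] <- x[wi, ch] + burst
      }
      if (model$blink_rate_hz > 0) {
        nb <- stats::rpois(1, model$blink_rate_hz * (ntime / srate))
        if (nb > 0) {
          blinkTrials <- c(blinkTrials, tr)
          front <- match(c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8"),
                         chans)
          for (b in seq_len(nb)) {
            ctr <- stats::runif(1, times[1] + 100, times[ntime] - 100)
            bump <- model$blink_gain * gaussKernel(times, ctr, 50)
            x[, nchan - 1] <- x[, nchan - 1] + bump          # VEOG
            x[, front] <- x[, front] + outer(bump, rep(0.35, length(front)))
          }
        }
      }
      dat[tr, , ] <- t(x)
    }

    log <- list(emg_trials = emgTrials, emg_channels = emgChan,
                blink_trials = unique(blinkTrials),
                class_patterns = classPat, prev_patterns = prevPat,
                erp_pattern = erpPat, drift_pattern = driftPat)

    if (mode == "epochs") {
      flags <- data.frame(keep = rep(TRUE, ntrial),
                          reason = rep("", ntrial),
                          stringsAsFactors = FALSE)
      return(new("EpochSet", data = dat, srate = srate, times = times,
                 channels = chans, trials = schedule, flags = flags,
                 log = log))
    }
    # Continuous layout: epochs end-to-end; trigger at the t = 0 sample.
    zero <- which.min(abs(times))
    cont <- matrix(0, ntrial * ntime, nchan)
    for (tr in seq_len(ntrial))
      cont[(tr - 1) * ntime + seq_len(ntime), ] <- t(dat[tr, , ])
    events <- data.frame(sample = (seq_len(ntrial) - 1) * ntime + zero,
                         code = ifelse(schedule$ping, 1L, 2L),
                         trial = seq_len(ntrial))
    new("ContinuousEEG", data = cont, srate = srate, channels = chans,
        events = events, trials = schedule)
  })
}
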