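# Builds a small continuous recording by hand: known offsets per channel,
# the same offset on the earlobe references, plus a slow sinusoid.
makeContinuous <- function(n = 20000, srate = 512, slow_hz = NULL,
                           offset = 50) {
  chans <- allChannels()
  dat <- matrix(0, n, length(chans))
  dat <- dat + offset                        # common DC offset everywhere
  if (!is.null(slow_hz))
    dat <- dat + 20 * sin(2 * pi * slow_hz * seq_len(n) / srate)
  ev <- data.frame(sample = seq(2000, n - 2000, length.out = 5),
                   code = 1L, trial = 1:5)
  ev$sample <- round(ev$sample)
  trials <- data.frame(trial_index = 1:5)
  new("ContinuousEEG", data = dat, srate = srate, channels = chans,
      events = ev, trials = trials)
}

test_that("constant offsets vanish after re-referencing and high-pass", {
  raw <- makeContinuous()
  ep <- preprocessRaw(raw, window = c(-100, 100))
  expect_lt(max(abs(epochData(ep))), 1e-6)
  expect_equal(dim(epochData(ep))[1], nrow(raw@events))
})

test_that("slow sinusoids are attenuated per the designed FIR response", {
  srate <- 512
  n <- 60000
  f <- 0.005
  raw <- makeContinuous(n = n, srate = srate, slow_hz = f, offset = 0)
  x <- raw@data[, 1]
  h <- pingmap:::designHighpass(srate, 0.01, n)
  y <- pingmap:::firApply(x, h)
  core <- seq(round(n * 0.3), round(n * 0.7))     # avoid edge transients
  measured <- stats::sd(y[core]) / stats::sd(x[core])
  designed <- highpassGain(srate, n, f)
  expect_equal(measured, designed, tolerance = 0.05)
  # and a fast component passes essentially unchanged
  expect_gt(highpassGain(srate, n, 10), 0.99)
})

test_that("preprocessRaw validates reference channels and event bounds", {
  raw <- makeContinuous()
  bad <- raw
  bad@channels[match("EXG1", bad@channels)] <- "nope"
  expect_error(preprocessRaw(bad), "reference")
  raw2 <- makeContinuous()
  raw2@events$sample[1] <- 10   # too close to the edge for the epoch
  expect_error(preprocessRaw(raw2, window = c(-700, 1100)), "events")
})

test_that("EMG scan marks injected bursts, repairs, and logs everything", {
  sched <- smallSchedule()[1:100, ]
  ep <- generateEEG(sched, signalModel(emg_trial_fraction = 0.1),
                    seed = 4, window = c(-250, 650))
  truth <- processingLog(ep)$emg_trials
  ep2 <- emgScanRepair(ep)
  rej <- processingLog(ep2)$rejection
  expect_gte(mean(truth %in% rej$marked), 0.9)
  expect_lte(mean(setdiff(seq_len(100), truth) %in% rej$marked), 0.05)
  # every marked epoch was either repaired below threshold or dropped
  expect_true(all(rej$dropped %in% rej$marked))
  expect_true(all(!keepFlags(ep2)$keep[rej$dropped]))
  expect_true(all(keepFlags(ep2)$reason[rej$dropped] == "EMG artifact"))
  # single-electrode bursts are repaired by interpolation, not dropped
  chans <- processingLog(ep)$emg_channels
  one <- truth[vapply(as.character(truth), function(t)
    length(chans[[t]]) == 1, logical(1))]
  expect_true(all(!one %in% rej$dropped))
})

test_that("clean epochs survive the EMG scan untouched", {
  sched <- smallSchedule()[1:80, ]
  ep <- generateEEG(sched, signalModel(), seed = 6, window = c(-250, 650))
  ep2 <- emgScanRepair(ep)
  expect_length(processingLog(ep2)$rejection$dropped, 0)
  expect_true(all(keepFlags(ep2)$keep))
})

test_that("repair never increases the accumulated z (monotone interpolation)", {
  sched <- smallSchedule()[1:60, ]
  ep <- generateEEG(sched, signalModel(emg_trial_fraction = 0.15),
                    seed = 8, window = c(-250, 650))
  ep2 <- emgScanRepair(ep)
  rej <- processingLog(ep2)$rejection
  marked <- rej$marked
  for (tr in marked) {
    entry <- rej$interpolations[[as.character(tr)]]
    expect_lte(entry$final_z, rej$accumulated_z[tr] + 1e-6)
  }
})

test_that("mass contamination aborts with a data-quality error", {
  # with a fixed (non-adaptive) threshold, majority contamination trips the
  # safety valve instead of silently shifting the adaptive threshold
  sched <- smallSchedule()[1:40, ]
  ep <- generateEEG(sched, signalModel(emg_trial_fraction = 0.6,
                                       emg_gain = 120),
                    seed = 10, window = c(-250, 650))
  expect_error(emgScanRepair(ep, rejectionConfig(z_threshold = 30)),
               "data-quality")
})

test_that("gaze exclusion drops exactly the trials with injected deviations", {
  sched <- smallSchedule()[1:150, ]
  rec <- generateGaze(sched, gazeBias(deviant_fraction = 0.08), seed = 5)
  g <- preprocessGaze(rec, trials = sched, window = c(-400, 700),
                      baseline = NULL)
  ep <- stubEpochs(sched)
  ex <- excludeByGaze(ep, g)
  truth <- rec@log$deviant_trials
  expect_setequal(processingLog(ex)$gaze_exclusion$dropped, truth)
  expect_true(all(!keepFlags(ex)$keep[truth]))
  # fixation-only gaze drops nothing
  rec0 <- generateGaze(sched, gazeBias(), seed = 6)
  g0 <- preprocessGaze(rec0, trials = sched, window = c(-400, 700),
                       baseline = NULL)
  ex0 <- excludeByGaze(stubEpochs(sched), g0)
  expect_length(processingLog(ex0)$gaze_exclusion$dropped, 0)
})

test_that("HEOG step detector flags square steps above 20 microvolts", {
  sched <- smallSchedule()[1:10, ]
  ep <- generateEEG(sched, signalModel(noise_sd = 1), seed = 2,
                    window = c(-250, 650))
  heog <- match("HEOG", channelNames(ep))
  tms <- timePoints(ep)
  d <- epochData(ep)
  d[3, heog, tms > 200] <- d[3, heog, tms > 200] + 40
  ep@data <- d
  ex <- excludeByGaze(ep, NULL)
  expect_true(3 %in% processingLog(ex)$gaze_exclusion$dropped)
  expect_identical(processingLog(ex)$gaze_exclusion$method, "heog_step")
  # absent both gaze and HEOG: error
  ep2 <- stubEpochs(sched)
  expect_error(excludeByGaze(ep2, NULL), "HEOG")
})

test_that("every input trial is accounted for as kept or dropped-with-reason", {
  sched <- smallSchedule()[1:100, ]
  ep <- generateEEG(sched, signalModel(emg_trial_fraction = 0.1),
                    seed = 4, window = c(-250, 650))
  rec <- generateGaze(sched, gazeBias(deviant_fraction = 0.1), seed = 5)
  g <- preprocessGaze(rec, trials = sched, window = c(-400, 700),
                      baseline = NULL)
  ep2 <- excludeByGaze(emgScanRepair(ep), g)
  fl <- keepFlags(ep2)
  expect_equal(nrow(fl), 100)
  expect_true(all(fl$reason[!fl$keep] != ""))
  kept <- dropFlagged(ep2)
  expect_equal(dim(epochData(kept))[1] +
                 nrow(processingLog(kept)$removed), 100)
})
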