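test_that("constant gaze becomes all-zero epochs after baselining", {
  sched <- smallSchedule()[1:20, ]
  rec <- generateGaze(sched, gazeBias(jitter_sd_px = 0, blink_rate_hz = 0),
                      seed = 1)
  # add a constant offset: (10, -4) px in y-up terms
  rec@samples$x <- rec@samples$x + 10
  rec@samples$y <- rec@samples$y + 4
  g <- preprocessGaze(rec, trials = sched)
  expect_lt(max(abs(epochData(g))), 1e-9)
  expect_true(g@baselined)
})

test_that("2000 Hz input comes out at 500 Hz with identical duration", {
  sched <- smallSchedule()[1:10, ]
  rec <- generateGaze(sched, gazeBias(srate = 2000), seed = 2)
  g <- preprocessGaze(rec, trials = sched, window = c(-700, 600))
  expect_equal(sampleRate(g), 500)
  expect_equal(diff(range(timePoints(g))), 1300, tolerance = 5)
  # 500 Hz input is left untouched
  rec5 <- generateGaze(sched, gazeBias(srate = 500), seed = 2)
  g5 <- preprocessGaze(rec5, trials = sched, window = c(-700, 600))
  expect_equal(sampleRate(g5), 500)
})

test_that("blink windows are replaced by linear interpolation, pads included", {
  sched <- smallSchedule()[1:3, ]
  rec <- generateGaze(sched, gazeBias(jitter_sd_px = 0, blink_rate_hz = 0,
                                      srate = 500), seed = 1)
  # ramp signal so interpolation is exact and detectable
  rec@samples$x <- rec@samples$x + rec@samples$time_ms * 0.01
  on2 <- rec@events$onset_ms[2]
  # blink spanning 100..200 ms post-ping on trial 2
  rec@blinks <- data.frame(start_ms = on2 + 100, end_ms = on2 + 200)
  bi <- which(rec@samples$time_ms >= on2 + 100 &
                rec@samples$time_ms <= on2 + 200)
  rec@samples$x[bi] <- 1e7
  g <- preprocessGaze(rec, trials = sched, baseline = NULL,
                      window = c(-700, 600))
  x2 <- epochData(g)[2, 1, ]
  tms <- timePoints(g)
  # a linear signal is reproduced exactly by linear blink interpolation,
  # across -100..400 ms (the padded window) and everywhere else
  expect_lt(max(abs(diff(x2) - diff(x2)[1])), 1e-6)
  expect_false(any(abs(x2) > 1e5))
})

test_that("trial matching mirrors the EEG kept set", {
  sched <- smallSchedule()[1:30, ]
  rec <- generateGaze(sched, gazeBias(), seed = 3)
  g <- preprocessGaze(rec, trials = sched)
  ep <- stubEpochs(sched)
  ep@flags$keep[c(4, 9)] <- FALSE
  ep@flags$reason[c(4, 9)] <- "test"
  gm <- matchTrials(g, ep)
  expect_equal(dim(epochData(gm))[1], 28)
  expect_identical(trialInfo(gm)$trial_index,
                   sched$trial_index[-c(4, 9)])
})

test_that("occupancy grids are normalized and differences sum to zero", {
  sched <- smallSchedule()
  rec <- generateGaze(sched, gazeBias(toward_px = 5), seed = 4)
  g <- preprocessGaze(rec, trials = sched)
  dm <- densityMaps(g, cell_px = 1, extent_px = 30)
  for (o in dm$occupancy) expect_equal(sum(o), 1, tolerance = 1e-12)
  for (d in dm$difference) expect_lt(abs(sum(d)), 1e-12)
  expect_length(dm$occupancy, 4)
})

test_that("identical gaze across conditions gives all-zero differences", {
  full <- smallSchedule()
  sched <- full[full$block_index %in% c(1, 4, 7, 10) &
                  full$trial_in_block <= 10, ]
  rec <- generateGaze(sched, gazeBias(jitter_sd_px = 0, blink_rate_hz = 0),
                      seed = 1)
  g <- preprocessGaze(rec, trials = sched)
  dm <- densityMaps(g, cell_px = 1, extent_px = 10)
  for (d in dm$difference) expect_lt(max(abs(d)), 1e-12)
})

test_that("a condition-specific rightward bias lands right of center", {
  # 5 px rightward shift only when HP = right (0)
  sched <- smallSchedule()
  rec <- generateGaze(sched, gazeBias(jitter_sd_px = 2, blink_rate_hz = 0),
                      seed = 5)
  hp <- sched$hp_location
  right <- which(!is.na(hp) & hp == 0)
  nper <- nrow(rec@samples) / nrow(sched)
  for (tr in right) {
    idx <- (tr - 1) * nper + seq_len(nper)
    rec@samples$x[idx] <- rec@samples$x[idx] + 5
  }
  g <- preprocessGaze(rec, trials = sched, baseline = NULL)
  dm <- densityMaps(g, cell_px = 1, extent_px = 20)
  d0 <- dm$difference[["0"]]
  xc <- dm$centers
  mass <- rowSums(d0)
  expect_gt(sum(mass[xc > 0]), 0)   # net positive mass right of center
  expect_gt(which.max(mass), which(xc == 0))
})

test_that("towardness recovers injected bias with slope one and sign", {
  sched <- smallSchedule()
  for (px in c(9.25, -9.25)) {
    rec <- generateGaze(sched, gazeBias(toward_px = px, jitter_sd_px = 2,
                                        blink_rate_hz = 0), seed = 6)
    g <- preprocessGaze(rec, trials = sched, baseline = NULL)
    tw <- towardness(g)
    expect_equal(mean(tw$towardness["ping", ]), px / 185 * 100,
                 tolerance = 0.12)
    expect_equal(mean(tw$towardness["noping", ]), px / 185 * 100,
                 tolerance = 0.12)
  }
  # unbiased gaze: about zero
  rec0 <- generateGaze(sched, gazeBias(jitter_sd_px = 2,
                                       blink_rate_hz = 0), seed = 7)
  tw0 <- towardness(preprocessGaze(rec0, trials = sched, baseline = NULL))
  expect_lt(abs(mean(tw0$towardness)), 0.4)
})

test_that("towardness demands both opposing conditions", {
  sched <- smallSchedule()
  keep <- is.na(sched$hp_location) | sched$hp_location != 4
  sub <- sched[keep, ]
  rec <- generateGaze(sub, gazeBias(), seed = 8)
  g <- preprocessGaze(rec, trials = sub, baseline = NULL)
  expect_error(towardness(g), "opposing")
})
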