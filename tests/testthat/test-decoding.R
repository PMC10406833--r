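test_that("pseudo-trial averaging has exact counts and variance reduction", {
  set.seed(1)
  dat <- array(rnorm(40 * 3 * 2), c(40, 3, 2))
  lab <- rep(c("a", "b"), c(10, 30))
  ps <- makePseudotrials(dat, lab, avg_k = 3, seed = 2)
  expect_equal(sum(ps$labels == "a"), 3)      # floor(10 / 3)
  expect_equal(sum(ps$labels == "b"), 10)
  # avg_k = 1 is the identity
  ps1 <- makePseudotrials(dat, lab, avg_k = 1)
  expect_identical(ps1$data, dat)
  # noise variance shrinks by ~ 1/3 (ratio cancels the draw's variance)
  big <- array(rnorm(3000), c(3000, 1, 1))
  pb <- makePseudotrials(big, rep("a", 3000), avg_k = 3, seed = 1)
  expect_equal(var(as.numeric(pb$data)) / var(as.numeric(big)), 1 / 3,
               tolerance = 0.1)
  expect_error(makePseudotrials(dat, rep(c("a", "b"), c(2, 38)), 3),
               "fewer than avg_k")
})

test_that("fold assignment is stratified with equal class counts per fold", {
  set.seed(2)
  lab <- rep(c("a", "b", "c"), c(33, 47, 52))
  fold <- suppressWarnings(withr::with_seed(1, pingmap:::foldAssign(lab, 10)))
  used <- !is.na(fold)
  tab <- table(fold[used], lab[used])
  expect_true(all(tab == tab[1, 1]))
  expect_equal(nrow(tab), 10)
  expect_warning(withr::with_seed(1, pingmap:::foldAssign(lab, 10)),
                 "imbalance")
  expect_error(pingmap:::foldAssign(rep(c("a", "b"), c(5, 50)), 10),
               "fewer pseudo-trials than folds")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  score <- rnorm(200)
  pos <- runif(200) < 0.4
  mine <- pingmap:::rankAUC(score, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("decoding AUC matches the Gaussian closed form", {
  # 1 feature, 2 classes at N(+/- d/2, 1): AUC = Phi(d / sqrt(2))
  set.seed(4)
  n <- 800
  for (d in c(1, 2)) {
    x <- c(rnorm(n, -d / 2), rnorm(n, d / 2))
    dat <- array(x, c(2 * n, 1, 1))
    lab <- rep(c("l", "r"), each = n)
    res <- decodeTimecourse(dat, lab,
                            decodeConfig(avg_k = 1, n_folds = 10,
                                         baseline_window = c(-2, -1),
                                         decode_window = c(0, 1),
                                         downsample_to = 1, seed = 5),
                            times = 0.5, srate = 1)
    expect_equal(as.numeric(aucValues(res)), pnorm(d / sqrt(2)),
                 tolerance = 0.02)
  }
})

test_that("shuffled labels decode at chance", {
  set.seed(5)
  # strong 2-class signal, then labels permuted: exchangeability
  n <- 120
  dat <- array(rnorm(n * 4 * 3), c(n, 4, 3))
  lab <- sample(rep(c("a", "b"), each = n / 2))
  dat[lab == "a", 1, ] <- dat[lab == "a", 1, ] + 2
  shuffled <- sample(lab)
  res <- decodeTimecourse(dat, shuffled,
                          decodeConfig(avg_k = 1, n_folds = 6,
                                       baseline_window = c(-2, -1),
                                       decode_window = c(0, 10),
                                       downsample_to = 1, seed = 6),
                          times = c(1, 2, 3), srate = 1)
  expect_lt(abs(mean(aucValues(res)) - 0.5), 0.08)
})

test_that("decoding is deterministic under a fixed seed", {
  dat <- withr::with_seed(7, array(rnorm(80 * 4 * 2), c(80, 4, 2)))
  lab <- rep(c("a", "b"), 40)
  cfg <- decodeConfig(avg_k = 2, n_folds = 5,
                      baseline_window = c(-2, -1), decode_window = c(0, 10),
                      downsample_to = 1, seed = 11)
  r1 <- decodeTimecourse(dat, lab, cfg, times = c(1, 2), srate = 1)
  r2 <- decodeTimecourse(dat, lab, cfg, times = c(1, 2), srate = 1)
  expect_identical(aucValues(r1), aucValues(r2))
})

test_that("ping-gated class patterns are recovered at 300-400 ms only", {
  ep <- signalEpochs()
  cfg <- decodeConfig(seed = 21)
  ping <- runVariant(ep, "hp_ping", cfg)
  noping <- runVariant(ep, "hp_noping", cfg)
  tms <- timePoints(ping)
  w <- tms >= 300 & tms <= 400
  pre <- tms < 100
  expect_gt(mean(aucValues(ping)[, w]), 0.62)
  expect_lt(abs(mean(aucValues(ping)[, pre]) - 0.5), 0.07)
  expect_lt(abs(mean(aucValues(noping)[, w]) - 0.5), 0.07)
  expect_equal(ping@chance, 0.5)
})

test_that("variant selections implement their trial rules", {
  sched <- generateSchedule(designConfig(seed = 31))
  ep <- stubEpochs(sched)
  # dummy phases: 224 trials each, with the documented block spans
  ph <- pingmap:::dummyPhase(sched)
  expect_equal(as.numeric(table(ph[ph > 0])), rep(224, 3))
  expect_setequal(unique(sched$block_index[ph == 1]), 4:7)
  expect_setequal(unique(sched$block_index[ph == 2]), 9:12)
  expect_setequal(unique(sched$block_index[ph == 3]), 14:17)
  # hp_exclusion removes trials whose previous target was at the current HP
  # (37.5% in expectation; averaged over schedules)
  fracs <- vapply(41:46, function(s) {
    sc <- generateSchedule(designConfig(seed = s))
    biasedPing <- !sc$practice & sc$block_type == "biased" & sc$ping
    prevAtHP <- !is.na(sc$prev_target_location) &
      sc$prev_target_location == sc$hp_location
    sum(biasedPing & prevAtHP) / sum(biasedPing)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.375), 0.03)
  expect_error(runVariant(ep, "nonsense"), "unknown variant")
  # dummy construction fails without enough neutral blocks
  short <- generateSchedule(designConfig(hp_cycle = c(0L, 4L),
                                         practice = FALSE, seed = 1))
  expect_error(pingmap:::dummyPhase(short), "neutral")
})

test_that("gaze coordinates can serve as decoding features", {
  sched <- smallSchedule()
  rec <- generateGaze(sched, gazeBias(toward_px = 12, jitter_sd_px = 3,
                                      blink_rate_hz = 0), seed = 9)
  g <- preprocessGaze(rec, trials = sched, baseline = NULL)
  ep <- stubEpochs(sched)
  # the injected offset is sustained through the whole trial, so decode the
  # un-baselined positions (a pre-ping baseline would remove it)
  res <- runVariant(ep, "gaze_features",
                    decodeConfig(seed = 13, downsample_to = 125,
                                 baseline_window = c(-2000, -1500)),
                    gaze = g)
  # a 12 px toward-HP offset separates the four conditions in gaze space
  expect_gt(mean(aucValues(res)), 0.8)
})
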