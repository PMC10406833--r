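makeNullSubjects <- function(n_subj = 10, n_trials = 400, seed = 1,
                             rt_sd = 50) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_subj), function(s)
    data.frame(subject_id = s, practice = FALSE, block_index = 1,
               block_type = "biased", trial_in_block = seq_len(n_trials),
               hp_location = 0, target_location = 1,
               distractor_location = NA, ping = FALSE,
               target_repeat = FALSE,
               rt_ms = rnorm(n_trials, 600, rt_sd),
               correct = runif(n_trials) > 0.1))))
}

test_that("per-subject RT trimming removes the Gaussian tail fraction", {
  trs <- makeNullSubjects(n_subj = 12, n_trials = 1500)
  cl <- cleanBehavior(trs)
  # 2 * pnorm(-2.5) = 1.24% expected outside +/- 2.5 SD
  expect_equal(mean(cl$report$trimmed_fraction), 2 * pnorm(-2.5),
               tolerance = 0.25)
  expect_true(all(!cl$report$excluded))
  expect_true(all(cl$trials$correct))
})

test_that("a low-accuracy subject is flagged and removed", {
  trs <- makeNullSubjects(n_subj = 12)
  bad <- trs$subject_id == 3
  trs$correct[bad] <- withr::with_seed(4, runif(sum(bad)) > 0.55)
  cl <- cleanBehavior(trs)
  expect_true(cl$report$excluded[cl$report$subject_id == 3])
  expect_match(cl$report$reason[cl$report$subject_id == 3], "accuracy")
  expect_false(3 %in% cl$trials$subject_id)
})

test_that("trimming is idempotent given the retained set", {
  trs <- makeNullSubjects(n_subj = 6)
  cl1 <- cleanBehavior(trs)
  cl2 <- cleanBehavior(cl1$trials)
  # a second pass at the same bounds removes (almost) nothing: the trimmed
  # fraction shrinks by an order of magnitude
  expect_lt(mean(cl2$report$trimmed_fraction),
            mean(cl1$report$trimmed_fraction) / 2)
})

test_that("paired contrasts report d_z = t / sqrt(n) exactly and recover
           injected effects", {
  trs <- do.call(rbind, lapply(1:10, function(s) {
    d <- smallDesign(seed = 300 + s)
    generateBehavior(generateSchedule(d, subject_id = s),
                     seed = 400 + s)
  }))
  cl <- cleanBehavior(trs)
  ct <- behaviorContrasts(cl)
  for (nm in names(ct)) {
    if (ct[[nm]]$degenerate) next
    expect_equal(ct[[nm]]$d_z, ct[[nm]]$t / sqrt(ct[[nm]]$n))
    expect_true(ct[[nm]]$ci95[1] <= ct[[nm]]$mean_diff &&
                  ct[[nm]]$mean_diff <= ct[[nm]]$ci95[2])
  }
  # repetition-controlled HP contrast recovers the injected 45 ms benefit
  expect_equal(ct$hp_vs_lp_norep$mean_diff, 45, tolerance = 0.25)
  expect_lt(ct$hp_vs_lp_norep$p, 0.05)
  # repetition benefit: the raw contrast carries a known HP confound
  # (repeats are concentrated at the HP location), so the design-derived
  # expectation is rep_benefit + hp_benefit * (P(HP|repeat) - P(HP|switch))
  kept <- cl$trials
  atHP <- !is.na(kept$hp_location) &
    kept$target_location == kept$hp_location
  sw <- !kept$target_repeat & kept$trial_in_block > 1
  expected <- 55 + 45 * (mean(atHP[kept$target_repeat]) - mean(atHP[sw]))
  expect_equal(ct$repeat_vs_switch$mean_diff, expected, tolerance = 0.15)
  # distractor-at-HP cost present and positive
  expect_gt(ct$distractor_at_hp$mean_diff, 0)
  # neutral-block extinction check: no true effect injected there
  expect_lt(abs(ct$neutral_prev_hp$mean_diff), 30)
})

test_that("degenerate zero-variance contrasts are flagged, not fabricated", {
  trs <- makeNullSubjects(n_subj = 5, n_trials = 40, rt_sd = 0)
  trs$correct <- TRUE
  cl <- cleanBehavior(trs)
  ct <- suppressWarnings(behaviorContrasts(cl))
  expect_true(ct$distractor_present$degenerate ||
                is.na(ct$distractor_present$t))
})

test_that("phase ANOVA finds a constant HP benefit with a flat interaction", {
  trs <- do.call(rbind, lapply(1:10, function(s) {
    d <- smallDesign(seed = 500 + s)
    generateBehavior(generateSchedule(d, subject_id = s),
                     behaviorEffects(rep_benefit_ms = 0), seed = 600 + s)
  }))
  an <- phaseAnova(cleanBehavior(trs))
  expect_identical(an$effect, c("loc", "phase", "loc:phase"))
  expect_lt(an$p[an$effect == "loc"], 0.001)
  expect_gt(an$p[an$effect == "loc:phase"], 0.05)
  expect_true(all(an$F >= 0))
  expect_equal(an$df1, c(1, 3, 3))
  expect_true(all(an$eta_sq_g >= 0 & an$eta_sq_g <= 1))
})

test_that("phase ANOVA detects a phase-varying benefit", {
  trs <- do.call(rbind, lapply(1:10, function(s) {
    d <- smallDesign(seed = 700 + s)
    sc <- generateSchedule(d, subject_id = s)
    sc <- generateBehavior(sc, behaviorEffects(hp_benefit_ms = 0,
                                               rep_benefit_ms = 0,
                                               sigma_ms = 40, tau_ms = 0),
                           seed = 800 + s)
    # benefit grows over phases: 0/20/40/60 ms
    phase <- match(sc$hp_location, unique(sc$hp_location[!is.na(
      sc$hp_location)]))
    atHP <- !is.na(sc$hp_location) &
      sc$target_location == sc$hp_location
    sc$rt_ms <- sc$rt_ms - ifelse(atHP, (phase - 1) * 20, 0)
    sc
  }))
  an <- phaseAnova(cleanBehavior(trs))
  expect_lt(an$p[an$effect == "loc:phase"], 0.05)
})
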