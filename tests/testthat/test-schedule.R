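test_that("default schedule has the full block structure and exact counts", {
  sched <- generateSchedule(designConfig(seed = 11))
  exp <- sched[!sched$practice, ]
  blocks <- split(exp, exp$block_index)
  expect_length(blocks, 19)
  expect_true(all(vapply(blocks, nrow, numeric(1)) == 56))
  # 4 biased + 1 neutral per HP location, no trailing neutral
  types <- vapply(blocks, function(b) b$block_type[1], character(1))
  expect_identical(unname(types),
                   c(rep(c(rep("biased", 4), "neutral"), 3),
                     rep("biased", 4)))
  for (b in blocks) {
    counts <- table(factor(b$target_location, 0:7))
    if (b$block_type[1] == "biased") {
      expect_equal(unname(counts[as.character(b$hp_location[1])]), 21,
                   ignore_attr = TRUE)
      expect_true(all(counts[setdiff(names(counts),
                                     as.character(b$hp_location[1]))] == 5))
    } else {
      expect_true(all(counts == 7))
      expect_true(all(is.na(b$hp_location)))
    }
    expect_equal(sum(b$ping), 28)
    dcounts <- table(factor(b$distractor_location, 0:7))
    expect_true(all(dcounts == 5))
    expect_equal(sum(!is.na(b$distractor_location)), 40)
    expect_false(any(b$distractor_location == b$target_location,
                     na.rm = TRUE))
  }
  # HP cycle order: up, down, left, right by default
  hpseq <- vapply(blocks[types == "biased"], function(b) b$hp_location[1],
                  numeric(1))
  expect_identical(unname(hpseq), rep(c(2, 6, 4, 0), each = 4))
})

test_that("practice block is generated, flagged and unbiased", {
  sched <- generateSchedule(designConfig(seed = 2))
  pr <- sched[sched$practice, ]
  expect_equal(nrow(pr), 56)
  expect_true(all(pr$block_index == 0))
  expect_true(all(table(pr$target_location) == 7))
})

test_that("degenerate single-location cycle gives all-biased blocks", {
  sched <- generateSchedule(designConfig(hp_cycle = 0L, practice = FALSE,
                                         seed = 1))
  expect_equal(length(unique(sched$block_index)), 4)
  expect_true(all(sched$block_type == "biased"))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(designConfig(hp_probability = 0.4), "hp_probability")
  expect_error(designConfig(trials_per_block = 50), "trials_per_block")
  expect_error(designConfig(distractor_trials_per_block = 39),
               "distractor_trials_per_block")
  expect_error(designConfig(ping_fraction = 0.51), "ping_fraction")
})

test_that("schedules are bit-identical under a fixed seed", {
  a <- generateSchedule(designConfig(seed = 123))
  b <- generateSchedule(designConfig(seed = 123))
  expect_identical(a, b)
  c <- generateSchedule(designConfig(seed = 124))
  expect_false(identical(a$target_location, c$target_location))
})

test_that("repeat fraction matches the exact-count permutation expectation", {
  # Oracle: expected adjacent equal pairs in a random permutation of a
  # multiset with counts c_i is sum c_i (c_i - 1) / n; per biased block
  # (21*20 + 7*5*4)/56 = 10, per neutral block 8*7*6/56 = 6.
  perBiased <- (21 * 20 + 7 * 5 * 4) / 56
  perNeutral <- (8 * 7 * 6) / 56
  expected <- (16 * perBiased + 3 * perNeutral) / (19 * 56)
  reps <- vapply(1:25, function(s) {
    sc <- generateSchedule(designConfig(seed = s))
    mean(sc$target_repeat[!sc$practice])
  }, numeric(1))
  expect_equal(mean(reps), expected, tolerance = 0.04)
  # and within biased blocks the fraction is 10/56
  sched <- do.call(rbind, lapply(26:30, function(s)
    generateSchedule(designConfig(seed = s))))
  bb <- sched[sched$block_type == "biased" & !sched$practice, ]
  expect_equal(mean(bb$target_repeat), perBiased / 56, tolerance = 0.05)
})

test_that("behavior generator reproduces its declared expectations", {
  sched <- smallSchedule()
  # zero effects, zero noise: every RT equals baseline
  eff0 <- behaviorEffects(hp_benefit_ms = 0, rep_benefit_ms = 0,
                          distractor_cost_ms = 0, hp_distractor_cost_ms = 0,
                          sigma_ms = 0, tau_ms = 0, error_rate = 0)
  beh0 <- generateBehavior(sched, eff0, seed = 1)
  expect_true(all(beh0$rt_ms == eff0$baseline_ms))
  expect_true(all(beh0$correct))

  # HP benefit recovery on a large table (no competing effects)
  big <- do.call(rbind, lapply(1:17, function(s) {
    d <- smallDesign(seed = 1000 + s)
    generateBehavior(generateSchedule(d, subject_id = s),
                     behaviorEffects(rep_benefit_ms = 0,
                                     distractor_cost_ms = 0,
                                     hp_distractor_cost_ms = 0),
                     seed = 2000 + s)
  }))
  atHP <- big$target_location == big$hp_location & !is.na(big$hp_location)
  lp <- big$block_type == "biased" & !atHP
  expect_equal(mean(big$rt_ms[lp]) - mean(big$rt_ms[atHP]), 45,
               tolerance = 0.15)
  # error rate binomial check
  expect_equal(mean(!big$correct), 0.11, tolerance = 0.02)
  # negative expected RT errors out
  expect_error(generateBehavior(sched,
                                behaviorEffects(baseline_ms = 40,
                                                hp_benefit_ms = 45)),
               "parameter error")
})
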