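#' Experiment design configuration
#'
#' Parameters of the visual-search statistical-learning design: blocks of
#' search trials in which one high-probability (HP) location holds the target
#' on a fixed fraction of trials, the HP location cycling over the four
#' cardinal positions every \code{neutral_after} blocks with an interleaved
#' neutral (unbiased) block, task-irrelevant visual pings on a fraction of
#' trials, and exactly location-balanced color-singleton distractors.
#'
#' Locations are indexed 0-7 with 0 = right, counting counter-clockwise, so
#' the cardinals are right/up/left/down = 0/2/4/6. Defaults give 19
#' experiment blocks of 56 trials (4 biased + 1 neutral per HP location,
#' no trailing neutral), 21 HP trials per biased block (37.5\%) against 5 per
#' low-probability location, 28 ping trials per block, and 40 distractor
#' trials per block (5 per location) -- the only location-balanced count near
#' the nominal 70\% distractor rate.
#'
#' @param trials_per_block trials per block (56).
#' @param hp_probability fraction of biased-block trials at the HP location
#'   (0.375).
#' @param hp_cycle ordered HP locations, one per biased-block sequence;
#'   cardinal indices (default up, down, left, right = 2, 6, 4, 0).
#' @param neutral_after number of biased blocks before each neutral block (4).
#' @param ping_fraction fraction of trials carrying a ping (0.5).
#' @param distractor_trials_per_block trials per block with a distractor (40).
#' @param n_locations number of display locations (8).
#' @param stimulus_eccentricity_px radius of the stimulus circle in pixels
#'   (185).
#' @param practice generate a practice block (flagged, excluded from
#'   analysis)?
#' @param seed integer seed for schedule randomization.
#' @return A validated list of class \code{DesignConfig}.
#' @export
designConfig <- function(trials_per_block = 56,
                         hp_probability = 0.375,
                         hp_cycle = c(2L, 6L, 4L, 0L),
                         neutral_after = 4,
                         ping_fraction = 0.5,
                         distractor_trials_per_block = 40,
                         n_locations = 8,
                         stimulus_eccentricity_px = 185,
                         practice = TRUE,
                         seed = 1L) {
  cfg <- list(trials_per_block = as.integer(trials_per_block),
              hp_probability = hp_probability,
              hp_cycle = as.integer(hp_cycle),
              neutral_after = as.integer(neutral_after),
              ping_fraction = ping_fraction,
              distractor_trials_per_block =
                as.integer(distractor_trials_per_block),
              n_locations = as.integer(n_locations),
              stimulus_eccentricity_px = stimulus_eccentricity_px,
              practice = isTRUE(practice),
              seed = as.integer(seed))
  class(cfg) <- "DesignConfig"
  validateDesign(cfg)
  cfg
}

intish <- function(x) abs(x - round(x)) < 1e-9

validateDesign <- function(cfg) {
  tpb <- cfg$trials_per_block
  nl <- cfg$n_locations
  nHP <- cfg$hp_probability * tpb
  if (!intish(nHP))
    stop("configuration error: hp_probability * trials_per_block ",
         "is not an integer (field hp_probability)", call. = FALSE)
  if (!intish((tpb - nHP) / (nl - 1)))
    stop("configuration error: low-probability trials not divisible across ",
         "the other locations (field hp_probability)", call. = FALSE)
  if (!intish(tpb / nl))
    stop("configuration error: trials_per_block not divisible by ",
         "n_locations (field trials_per_block)", call. = FALSE)
  if (!intish(cfg$distractor_trials_per_block / nl))
    stop("configuration error: distractor_trials_per_block not divisible ",
         "by n_locations (field distractor_trials_per_block)", call. = FALSE)
  if (!intish(cfg$ping_fraction * tpb))
    stop("configuration error: ping_fraction * trials_per_block is not an ",
         "integer (field ping_fraction)", call. = FALSE)
  if (any(cfg$hp_cycle < 0 | cfg$hp_cycle >= nl))
    stop("configuration error: hp_cycle indices out of range ",
         "(field hp_cycle)", call. = FALSE)
  invisible(TRUE)
}

# Balanced distractor assignment for one block: each location appears the same
# number of times among distractor trials, never colocated with the target.
assignDistractors <- function(target, n_distr, n_locations) {
  n <- length(target)
  dloc <- rep(seq_len(n_locations) - 1L, each = n_distr / n_locations)
  dloc <- sample(dloc)
  idx <- sample(n, n_distr)
  bad <- which(dloc == target[idx])
  guard <- 0
  while (length(bad)) {
    i <- bad[1]
    ok <- which(dloc != target[idx[bad[1]]] & dloc[bad[1]] != target[idx])
    ok <- setdiff(ok, bad[1])
    if (!length(ok)) { # re-deal, essentially never reached at design counts
      dloc <- sample(dloc)
    } else {
      j <- sample(ok, 1)
      tmp <- dloc[i]; dloc[i] <- dloc[j]; dloc[j] <- tmp
    }
    bad <- which(dloc == target[idx])
    guard <- guard + 1
    if (guard > 1000) stop("distractor balancing failed")
  }
  out <- rep(NA_integer_, n)
  out[idx] <- dloc
  out
}

makeBlock <- function(cfg, block_index, block_type, hp_location, subject_id,
                      practice = FALSE) {
  tpb <- cfg$trials_per_block
  nl <- cfg$n_locations
  if (block_type == "biased") {
    nHP <- as.integer(round(cfg$hp_probability * tpb))
    nLP <- as.integer((tpb - nHP) / (nl - 1))
    target <- c(rep(hp_location, nHP),
                rep(setdiff(seq_len(nl) - 1L, hp_location), each = nLP))
  } else {
    target <- rep(seq_len(nl) - 1L, each = tpb / nl)
  }
  target <- sample(target)
  dloc <- assignDistractors(target, cfg$distractor_trials_per_block, nl)
  ping <- logical(tpb)
  ping[sample(tpb, round(cfg$ping_fraction * tpb))] <- TRUE
  data.frame(subject_id = subject_id,
             block_index = block_index,
             block_type = block_type,
             practice = practice,
             trial_in_block = seq_len(tpb),
             hp_location = if (block_type == "biased") hp_location
                           else NA_integer_,
             target_location = target,
             distractor_location = dloc,
             ping = ping,
             ping_onset_jitter_ms = round(stats::runif(tpb, 700, 900), 1),
             rt_ms = NA_real_,
             correct = NA,
             stringsAsFactors = FALSE)
}

#' Generate a full experiment schedule
#'
#' Builds the trial-by-trial schedule: for each HP location in
#' \code{hp_cycle}, \code{neutral_after} biased blocks followed by one
#' neutral block, with the trailing neutral block omitted, preceded by an
#' optional practice block (flagged, target locations unbiased). Within each
#' block the per-location target counts, ping count and per-location
#' distractor counts are exact; only the ordering is randomized.
#'
#' @param cfg a \code{\link{designConfig}}.
#' @param subject_id subject identifier stored in the table.
#' @return A data.frame with one row per trial (design fields plus empty
#'   \code{rt_ms}/\code{correct} columns and a global \code{trial_index}).
#' @examples
#' sched <- generateSchedule(designConfig(seed = 7))
#' table(sched$block_type[!sched$practice & sched$trial_in_block == 1])
#' @export
generateSchedule <- function(cfg = designConfig(), subject_id = 1L) {
  validateDesign(cfg)
  withSeed(subSeed(cfg$seed, subject_id), {
    blocks <- list()
    bi <- 0L
    if (cfg$practice) {
      blocks[[length(blocks) + 1L]] <-
        makeBlock(cfg, 0L, "neutral", NA_integer_, subject_id,
                  practice = TRUE)
    }
    for (s in seq_along(cfg$hp_cycle)) {
      hp <- cfg$hp_cycle[s]
      for (b in seq_len(cfg$neutral_after)) {
        bi <- bi + 1L
        blocks[[length(blocks) + 1L]] <-
          makeBlock(cfg, bi, "biased", hp, subject_id)
      }
      if (s < length(cfg$hp_cycle)) {
        bi <- bi + 1L
        blocks[[length(blocks) + 1L]] <-
          makeBlock(cfg, bi, "neutral", NA_integer_, subject_id)
      }
    }
    out <- do.call(rbind, blocks)
    out$trial_index <- seq_len(nrow(out))
    # Intertrial repetition: same target location on consecutive trials
    # within a block (block breaks reset the comparison).
    prev <- c(NA_integer_, out$target_location[-nrow(out)])
    prev[out$trial_in_block == 1] <- NA_integer_
    out$prev_target_location <- prev
    out$target_repeat <- !is.na(prev) & prev == out$target_location
    out
  })
}

#' Behavioral effect parameters for the RT generator
#'
#' Expected RT is \code{baseline_ms} minus the HP benefit when the target is
#' at the HP location, minus the repetition benefit when the target location
#' repeats, plus the distractor-present cost, plus an extra cost when the
#' distractor sits at the HP location; ex-Gaussian noise (normal sigma plus
#' exponential tau) is added on top. Defaults follow the condition
#' differences typical of this paradigm (tens of ms) and an 11\% error rate.
#'
#' @param baseline_ms grand baseline RT.
#' @param hp_benefit_ms speed-up for targets at the HP location.
#' @param rep_benefit_ms speed-up for exact target-location repeats.
#' @param distractor_cost_ms slowing when any distractor is present.
#' @param hp_distractor_cost_ms extra slowing when the distractor occupies
#'   the HP location.
#' @param error_rate Bernoulli probability of an incorrect response.
#' @param sigma_ms Gaussian RT noise SD.
#' @param tau_ms exponential (slow-tail) RT noise mean.
#' @return list of class \code{BehaviorEffects}.
#' @export
behaviorEffects <- function(baseline_ms = 650, hp_benefit_ms = 45,
                            rep_benefit_ms = 55, distractor_cost_ms = 25,
                            hp_distractor_cost_ms = 26, error_rate = 0.11,
                            sigma_ms = 60, tau_ms = 100) {
  eff <- as.list(environment())
  class(eff) <- "BehaviorEffects"
  eff
}

#' Fill a schedule with simulated behavior
#'
#' @param schedule a schedule from \code{\link{generateSchedule}}.
#' @param effects a \code{\link{behaviorEffects}} list.
#' @param seed integer seed.
#' @return The schedule with \code{rt_ms} and \code{correct} filled.
#' @export
generateBehavior <- function(schedule, effects = behaviorEffects(),
                             seed = 1L) {
  atHP <- !is.na(schedule$hp_location) &
    schedule$target_location == schedule$hp_location
  distr <- !is.na(schedule$distractor_location)
  distrHP <- distr & !is.na(schedule$hp_location) &
    schedule$distractor_location == schedule$hp_location
  mu <- effects$baseline_ms -
    effects$hp_benefit_ms * atHP -
    effects$rep_benefit_ms * schedule$target_repeat +
    effects$distractor_cost_ms * distr +
    effects$hp_distractor_cost_ms * distrHP
  if (any(mu <= 0))
    stop("parameter error: expected RT is not positive", call. = FALSE)
  withSeed(seed, {
    n <- nrow(schedule)
    noise <- stats::rnorm(n, 0, effects$sigma_ms)
    if (effects$tau_ms > 0)
      noise <- noise + stats::rexp(n, 1 / effects$tau_ms)
    schedule$rt_ms <- pmax(mu + noise, 1)
    schedule$correct <- stats::runif(n) >= effects$error_rate
  })
  schedule
}
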