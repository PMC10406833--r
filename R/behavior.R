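#' Clean behavioral data
#'
#' Applies the behavioral exclusion cascade, in order: (1) flag subjects
#' whose overall accuracy falls more than \code{sd_mult} SDs below the group
#' mean; (2) restrict to correct trials; (3) trim, per subject, trials with
#' RTs more than \code{sd_mult} SDs from that subject's mean; (4) flag
#' subjects whose trimmed mean RT falls outside the group mean +/-
#' \code{sd_mult} SDs. Practice-block trials are removed up front. Flagged
#' subjects' trials are excluded from the retained table.
#'
#' @param trials multi-subject trial table with \code{rt_ms}/\code{correct}
#'   filled (see \code{\link{generateBehavior}}).
#' @param sd_mult SD multiplier for all exclusion rules (2.5).
#' @return list of class \code{CleanBehavior} with elements \code{trials}
#'   (retained rows), \code{report} (per-subject accuracy, trimmed fraction,
#'   excluded flag and reason) and \code{sd_mult}.
#' @export
cleanBehavior <- function(trials, sd_mult = 2.5) {
  trials <- trials[!trials$practice, , drop = FALSE]
  subjects <- sort(unique(trials$subject_id))
  acc <- vapply(subjects, function(s)
    mean(trials$correct[trials$subject_id == s]), numeric(1))
  accBad <- acc < mean(acc) - sd_mult * stats::sd(acc)
  accBad[is.na(accBad)] <- FALSE

  kept <- trials[trials$correct &
                   !(trials$subject_id %in% subjects[accBad]), , drop = FALSE]
  trimFrac <- stats::setNames(rep(NA_real_, length(subjects)),
                              subjects)
  degenerate <- stats::setNames(rep(FALSE, length(subjects)), subjects)
  keepRows <- logical(nrow(kept))
  for (s in subjects[!accBad]) {
    i <- which(kept$subject_id == s)
    if (length(i) < 2) {
      degenerate[as.character(s)] <- TRUE
      trimFrac[as.character(s)] <- NA_real_
      next
    }
    m <- mean(kept$rt_ms[i])
    sdv <- stats::sd(kept$rt_ms[i])
    ok <- abs(kept$rt_ms[i] - m) <= sd_mult * sdv
    keepRows[i] <- ok
    trimFrac[as.character(s)] <- mean(!ok)
  }
  kept <- kept[keepRows, , drop = FALSE]

  mrt <- vapply(subjects, function(s) {
    i <- kept$subject_id == s
    if (!any(i)) NA_real_ else mean(kept$rt_ms[i])
  }, numeric(1))
  ok <- !is.na(mrt)
  rtBad <- rep(FALSE, length(subjects))
  if (sum(ok) >= 2)
    rtBad[ok] <- abs(mrt[ok] - mean(mrt[ok])) > sd_mult * stats::sd(mrt[ok])
  kept <- kept[!(kept$subject_id %in% subjects[rtBad]), , drop = FALSE]

  excluded <- accBad | rtBad | degenerate
  reason <- rep("", length(subjects))
  reason[accBad] <- "low accuracy"
  reason[rtBad] <- "outlying mean RT"
  reason[degenerate] <- "too few correct trials"
  report <- data.frame(subject_id = subjects, accuracy = acc,
                       mean_rt_ms = mrt, trimmed_fraction = trimFrac,
                       excluded = excluded, reason = reason,
                       stringsAsFactors = FALSE)
  structure(list(trials = kept, report = report, sd_mult = sd_mult),
            class = "CleanBehavior")
}

# Paired t-test summary: t, df, two-sided p, within-subject effect size
# d_z = t / sqrt(n), and the 95% CI of the mean difference (ms).
pairedTest <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2 || stats::sd(d) == 0 || !is.finite(stats::sd(d)))
    return(list(t = NA_real_, df = n - 1, p = NA_real_, d_z = NA_real_,
                ci95 = c(NA_real_, NA_real_), mean_diff = mean(d), n = n,
                degenerate = TRUE))
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d_z = unname(tt$statistic) / sqrt(n),
       ci95 = as.numeric(tt$conf.int), mean_diff = mean(d), n = n,
       degenerate = FALSE)
}

# Per-subject mean RT under a row filter; NA when the cell is empty.
cellMeans <- function(trials, subjects, cond) {
  vapply(subjects, function(s) {
    i <- trials$subject_id == s & cond
    if (!any(i)) NA_real_ else mean(trials$rt_ms[i])
  }, numeric(1))
}

contrastFrom <- function(a, b, label) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(!ok))
    warning(sprintf("%s: %d subject(s) omitted (empty cell)", label,
                    sum(!ok)))
  pairedTest(a[ok], b[ok])
}

#' Condition contrasts on cleaned behavior
#'
#' Computes the paired reaction-time contrasts of the paradigm, each as a
#' two-sided paired t-test on per-subject condition means with
#' \code{d_z = t / sqrt(n)} and a 95\% CI of the difference in ms:
#' \describe{
#'   \item{hp_vs_lp}{low- minus high-probability target RT, biased blocks.}
#'   \item{repeat_vs_switch}{switch minus exact-repeat target RT.}
#'   \item{hp_vs_lp_norep}{as hp_vs_lp after removing target-repeat trials.}
#'   \item{distractor_present}{present minus absent distractor RT.}
#'   \item{distractor_at_hp}{distractor-at-HP minus distractor-elsewhere RT,
#'     biased blocks.}
#'   \item{neutral_prev_hp}{in neutral blocks, previous block's HP location
#'     minus all other locations.}
#' }
#' Positive mean differences correspond to the expected effect direction.
#'
#' @param clean a \code{\link{cleanBehavior}} result.
#' @return named list of test summaries.
#' @export
behaviorContrasts <- function(clean) {
  tr <- clean$trials
  subjects <- sort(unique(tr$subject_id))
  biased <- tr$block_type == "biased"
  atHP <- biased & tr$target_location == tr$hp_location

  # previous block's HP location, for the neutral-block extinction check
  prevHP <- rep(NA_integer_, nrow(tr))
  neutral <- which(tr$block_type == "neutral")
  if (length(neutral)) {
    key <- paste(tr$subject_id, tr$block_index)
    hpByBlock <- tapply(tr$hp_location, key, function(x) x[1])
    prevKey <- paste(tr$subject_id[neutral], tr$block_index[neutral] - 1L)
    prevHP[neutral] <- as.integer(hpByBlock[prevKey])
  }

  list(
    hp_vs_lp = contrastFrom(
      cellMeans(tr, subjects, biased & !atHP),
      cellMeans(tr, subjects, atHP), "hp_vs_lp"),
    repeat_vs_switch = contrastFrom(
      cellMeans(tr, subjects, !tr$target_repeat & tr$trial_in_block > 1),
      cellMeans(tr, subjects, tr$target_repeat), "repeat_vs_switch"),
    hp_vs_lp_norep = contrastFrom(
      cellMeans(tr, subjects, biased & !atHP & !tr$target_repeat),
      cellMeans(tr, subjects, atHP & !tr$target_repeat), "hp_vs_lp_norep"),
    distractor_present = contrastFrom(
      cellMeans(tr, subjects, !is.na(tr$distractor_location)),
      cellMeans(tr, subjects, is.na(tr$distractor_location)),
      "distractor_present"),
    distractor_at_hp = contrastFrom(
      cellMeans(tr, subjects, biased & !is.na(tr$distractor_location) &
                  tr$distractor_location == tr$hp_location),
      cellMeans(tr, subjects, biased & !is.na(tr$distractor_location) &
                  tr$distractor_location != tr$hp_location),
      "distractor_at_hp"),
    neutral_prev_hp = contrastFrom(
      cellMeans(tr, subjects, !is.na(prevHP) &
                  tr$target_location == prevHP),
      cellMeans(tr, subjects, !is.na(prevHP) &
                  tr$target_location != prevHP), "neutral_prev_hp")
  )
}

#' Repeated-measures ANOVA: target location by experiment phase
#'
#' A 2 x 4 within-subject ANOVA on per-subject cell mean RTs with factors
#' target location (HP vs LP) and experiment phase (which HP location of the
#' cycle is active, 1-4), on biased blocks. Fitted with
#' \code{aov(... Error(subject/(location*phase)))}; generalized eta squared
#' is computed from the effect and subject-related error sums of squares.
#'
#' @param clean a \code{\link{cleanBehavior}} result.
#' @return data.frame with one row per effect: F, df pair, p,
#'   \code{eta_sq_g}.
#' @export
phaseAnova <- function(clean) {
  tr <- clean$trials[clean$trials$block_type == "biased", , drop = FALSE]
  # phase = position of the active HP location in the cycle, per subject
  tr$phase <- NA_integer_
  for (s in unique(tr$subject_id)) {
    i <- tr$subject_id == s
    firsts <- tapply(tr$block_index[i], tr$hp_location[i], min)
    lev <- names(sort(firsts))
    tr$phase[i] <- match(as.character(tr$hp_location[i]), lev)
  }
  tr$loc <- ifelse(tr$target_location == tr$hp_location, "HP", "LP")

  agg <- stats::aggregate(rt_ms ~ subject_id + loc + phase, tr, mean)
  counts <- table(agg$subject_id)
  full <- names(counts)[counts == 8]
  dropped <- setdiff(names(counts), full)
  if (length(dropped))
    warning(sprintf("%d subject(s) dropped from ANOVA (missing cells)",
                    length(dropped)))
  agg <- agg[agg$subject_id %in% full, , drop = FALSE]
  agg$subject_id <- factor(agg$subject_id)
  agg$loc <- factor(agg$loc)
  agg$phase <- factor(agg$phase)

  fit <- stats::aov(rt_ms ~ loc * phase +
                      Error(subject_id / (loc * phase)), data = agg)
  sm <- summary(fit)
  ssSubj <- sum(vapply(names(sm), function(s) {
    tb <- sm[[s]][[1]]
    i <- grep("Residuals", trimws(rownames(tb)))
    if (length(i)) sum(tb[i, "Sum Sq"]) else 0
  }, numeric(1)))
  effects <- list(loc = c("Error: subject_id:loc", "loc"),
                  phase = c("Error: subject_id:phase", "phase"),
                  `loc:phase` = c("Error: subject_id:loc:phase",
                                  "loc:phase"))
  out <- do.call(rbind, lapply(names(effects), function(e) {
    st <- effects[[e]][1]
    tb <- sm[[st]][[1]]
    i <- match(effects[[e]][2], trimws(rownames(tb)))
    j <- grep("Residuals", trimws(rownames(tb)))
    ss <- tb[i, "Sum Sq"]
    data.frame(effect = e,
               F = tb[i, "F value"],
               df1 = tb[i, "Df"], df2 = tb[j, "Df"],
               p = tb[i, "Pr(>F)"],
               eta_sq_g = ss / (ss + ssSubj),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
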