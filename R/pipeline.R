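#' Pipeline run configuration
#'
#' Bundles every stage's configuration for an end-to-end run on synthetic
#' data. All stochastic stages derive their seeds from the single top-level
#' seed, so a fixed seed reproduces the run bit-for-bit.
#'
#' @param n_subjects simulated subjects.
#' @param design a \code{\link{designConfig}}.
#' @param effects a \code{\link{behaviorEffects}}.
#' @param model a \code{\link{signalModel}}.
#' @param gaze_bias a \code{\link{gazeBias}}, or NULL to skip gaze.
#' @param decode a \code{\link{decodeConfig}}.
#' @param rejection a \code{\link{rejectionConfig}}.
#' @param variants decoding variants to run (see \code{\link{runVariant}}).
#' @param preprocess run the EMG scan and gaze exclusion stages?
#' @param epoch_window EEG epoch window in ms.
#' @param n_permutations,alpha cluster-test settings.
#' @param seed master seed.
#' @param out_dir optional output directory for the JSON report.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(n_subjects = 6,
                      design = designConfig(),
                      effects = behaviorEffects(),
                      model = signalModel(),
                      gaze_bias = gazeBias(),
                      decode = decodeConfig(),
                      rejection = rejectionConfig(),
                      variants = c("hp_ping", "hp_noping"),
                      preprocess = TRUE,
                      epoch_window = c(-700, 1100),
                      n_permutations = 1024,
                      alpha = 0.05,
                      seed = 1L,
                      out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' \code{\link{runConfig}}; nested maps (\code{design}, \code{effects},
#' \code{model}, \code{gaze_bias}, \code{decode}, \code{rejection}) are
#' passed to the corresponding constructors so every field is validated.
#'
#' @param path YAML file path.
#' @return a \code{RunConfig}.
#' @export
loadRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  ctor <- list(design = designConfig, effects = behaviorEffects,
               model = signalModel, gaze_bias = gazeBias,
               decode = decodeConfig, rejection = rejectionConfig)
  for (nm in names(y)) {
    args[[nm]] <- if (nm %in% names(ctor)) do.call(ctor[[nm]], y[[nm]])
    else y[[nm]]
  }
  do.call(runConfig, args)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, per subject: schedule and behavior generation, EEG epoch
#' generation, optional artifact rejection (EMG scan with spline repair,
#' gaze-based trial exclusion), gaze preprocessing, and every requested
#' decoding variant. Group level: behavioral cleaning, condition
#' contrasts and the location-by-phase ANOVA, cluster-based permutation
#' tests of each variant's AUC against chance (and ping vs no-ping when
#' both are present), and the towardness summary. Every exclusion decision
#' is logged. A machine-readable report is returned and optionally written
#' as JSON.
#'
#' @param cfg a \code{\link{runConfig}} (or a YAML path accepted by
#'   \code{\link{loadRunConfig}}).
#' @return list of class \code{RunReport}.
#' @export
runPipeline <- function(cfg = runConfig()) {
  if (is.character(cfg)) cfg <- loadRunConfig(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  allTrials <- list()
  aucs <- stats::setNames(vector("list", length(cfg$variants)),
                          cfg$variants)
  toward <- list()
  exclusions <- list()

  for (s in seq_len(cfg$n_subjects)) {
    sseed <- subSeed(cfg$seed, 17 * s)
    des <- cfg$design
    des$seed <- sseed
    sched <- stage("synth", generateSchedule(des, subject_id = s))
    sched <- stage("behavior",
                   generateBehavior(sched, cfg$effects,
                                    seed = subSeed(sseed, 1)))
    allTrials[[s]] <- sched

    epochs <- stage("eeg", generateEEG(sched, cfg$model,
                                       seed = subSeed(sseed, 2),
                                       window = cfg$epoch_window))
    epochs <- stage("preproc", rereference(epochs))

    gazeEp <- NULL
    if (!is.null(cfg$gaze_bias)) {
      rec <- stage("gaze", generateGaze(sched, cfg$gaze_bias,
                                        seed = subSeed(sseed, 3)))
      gazeEp <- stage("gaze", preprocessGaze(rec, trials = sched))
      gazeRaw <- stage("gaze", preprocessGaze(rec, trials = sched,
                                              baseline = NULL))
    }
    if (cfg$preprocess) {
      epochs <- stage("preproc", emgScanRepair(epochs, cfg$rejection))
      if (!is.null(gazeEp))
        epochs <- stage("preproc",
                        excludeByGaze(epochs, gazeEp, cfg$rejection))
    }
    exclusions[[s]] <- epochs@flags

    dcfg <- cfg$decode
    dcfg$seed <- subSeed(sseed, 4)
    for (v in cfg$variants) {
      a <- stage(paste0("decoding:", v),
                 runVariant(epochs, v, dcfg,
                            gaze = if (v == "gaze_features") gazeEp))
      aucs[[v]] <- if (is.null(aucs[[v]])) a else
        new("AUCTimecourse",
            auc = rbind(aucs[[v]]@auc, a@auc), times = a@times,
            chance = 0.5, variant = v)
    }
    if (!is.null(gazeEp) && all(c(0, 2, 4, 6) %in% cfg$design$hp_cycle)) {
      # towardness needs every opposing HP pair in the design
      tw <- stage("gaze", towardness(matchTrials(gazeRaw, epochs),
                                     cfg$design$stimulus_eccentricity_px))
      toward[[s]] <- tw
    }
  }

  trials <- do.call(rbind, allTrials)
  clean <- stage("behavior", cleanBehavior(trials))
  behav <- list(contrasts = stage("behavior", behaviorContrasts(clean)),
                report = clean$report)
  behav$anova <- tryCatch(suppressWarnings(phaseAnova(clean)),
                          error = function(e) NULL)

  statsOut <- list()
  if (cfg$n_subjects >= 6) {
    for (v in cfg$variants)
      statsOut[[v]] <- stage("stats",
                             clusterPermTime(aucs[[v]], 0.5,
                                             n_permutations =
                                               cfg$n_permutations,
                                             alpha = cfg$alpha,
                                             seed = subSeed(cfg$seed, 99)))
    if (all(c("hp_ping", "hp_noping") %in% cfg$variants))
      statsOut$ping_vs_noping <- stage("stats",
        clusterPermTime(aucs$hp_ping, aucs$hp_noping,
                        n_permutations = cfg$n_permutations,
                        alpha = cfg$alpha, seed = subSeed(cfg$seed, 98)))
  }

  towardSummary <- NULL
  if (length(toward)) {
    tmat <- do.call(rbind, lapply(toward, function(t)
      colMeans(t$towardness)))
    towardSummary <- list(mean = colMeans(tmat), times = toward[[1]]$times)
  }

  report <- structure(list(
    config = cfg,
    behavior = behav,
    auc = aucs,
    cluster_tests = statsOut,
    towardness = towardSummary,
    exclusions = exclusions), class = "RunReport")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(reportJSON(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (v in names(aucs))
      writeAUC(aucs[[v]], file.path(cfg$out_dir, paste0("auc_", v, ".tsv")))
  }
  report
}

# JSON-friendly view of a run report (statistics only, no raw arrays).
reportJSON <- function(report) {
  con <- lapply(report$behavior$contrasts, function(ct)
    ct[c("t", "df", "p", "d_z", "mean_diff", "ci95", "n")])
  cl <- lapply(report$cluster_tests, function(cr) {
    tb <- cr@clusters
    tb$cells <- NULL
    list(n_permutations = cr@nPermutations, alpha = cr@alpha,
         clusters = tb)
  })
  aucSummary <- lapply(report$auc, function(a)
    list(n_subjects = nrow(a@auc), mean_auc = mean(a@auc),
         peak_auc = max(colMeans(a@auc)),
         peak_time_ms = a@times[which.max(colMeans(a@auc))]))
  list(seed = report$config$seed,
       n_subjects = report$config$n_subjects,
       behavior = list(contrasts = con,
                       anova = report$behavior$anova,
                       exclusion_report = report$behavior$report),
       auc = aucSummary,
       cluster_tests = cl,
       excluded_trials = lapply(report$exclusions, function(f)
         list(dropped = which(!f$keep), reasons = f$reason[!f$keep])))
}
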