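#' Decoding configuration
#'
#' Parameters of the time-resolved multiclass decoding pipeline:
#' pseudo-trial averaging over \code{avg_k} same-class trials, baselining on
#' -200..0 ms, downsampling to 128 Hz, 10 stratified folds, per-fold,
#' per-timepoint PCA (components explaining \code{pca_variance_kept} of the
#' training variance) followed by linear discriminant analysis, scored by
#' macro-averaged one-vs-rest AUC (chance 0.5 for any class count).
#'
#' @param avg_k pseudo-trial size (3; 5 for previous-target decoding, 1
#'   disables averaging).
#' @param n_folds cross-validation folds (10).
#' @param baseline_window baseline in ms (c(-200, 0)).
#' @param downsample_to target rate in Hz (128).
#' @param decode_window scored window in ms (c(-200, 600)).
#' @param pca_variance_kept fraction of training variance kept (0.99).
#' @param seed integer seed for pseudo-trial grouping and fold assignment.
#' @return list of class \code{DecodeConfig}.
#' @export
decodeConfig <- function(avg_k = 3, n_folds = 10,
                         baseline_window = c(-200, 0),
                         downsample_to = 128,
                         decode_window = c(-200, 600),
                         pca_variance_kept = 0.99, seed = 1L) {
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  if (avg_k < 1) stop("avg_k must be at least 1", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "DecodeConfig"
  cfg
}

#' Average same-class trials into pseudo-trials
#'
#' Within each class, trials are randomly grouped into disjoint sets of
#' \code{avg_k} and averaged; the remainder (class count mod \code{avg_k})
#' is dropped. \code{avg_k = 1} is the identity.
#'
#' @param data trials x features x time array (or trials x features matrix).
#' @param labels class label per trial.
#' @param avg_k pseudo-trial size.
#' @param seed integer seed.
#' @return list with \code{data} (pseudo-trials x features x time) and
#'   \code{labels}.
#' @export
makePseudotrials <- function(data, labels, avg_k, seed = 1L) {
  if (avg_k == 1) return(list(data = data, labels = labels))
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1)
  classes <- unique(labels)
  short <- classes[table(factor(labels, classes))[as.character(classes)] <
                     avg_k]
  if (length(short))
    stop("class with fewer than avg_k trials: ",
         paste(short, collapse = ", "), call. = FALSE)
  withSeed(seed, {
    outD <- list()
    outL <- list()
    for (cl in classes) {
      i <- sample(which(labels == cl))
      ng <- floor(length(i) / avg_k)
      i <- i[seq_len(ng * avg_k)]
      grp <- matrix(i, nrow = avg_k)
      av <- array(0, c(ng, dim(data)[2], dim(data)[3]))
      for (g in seq_len(ng))
        av[g, , ] <- colMeans(data[grp[, g], , , drop = FALSE])
      outD[[length(outD) + 1]] <- av
      outL[[length(outL) + 1]] <- rep(cl, ng)
    }
    d1 <- sum(vapply(outD, function(a) dim(a)[1], numeric(1)))
    dat <- array(0, c(d1, dim(data)[2], dim(data)[3]))
    at <- 0
    for (a in outD) {
      dat[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    list(data = dat, labels = unlist(outL))
  })
}

# Stratified fold assignment with exactly equal class counts in every fold:
# each class contributes m = floor(min(class count) / n_folds) pseudo-trials
# per fold (random subsample, so class imbalance is resolved by subsampling
# to the minimum class count). Returns fold index per trial (NA = unused).
foldAssign <- function(labels, n_folds) {
  counts <- table(labels)
  m <- floor(min(counts) / n_folds)
  if (m == 0)
    stop("class ", names(counts)[which.min(counts)],
         " has fewer pseudo-trials than folds", call. = FALSE)
  if (max(counts) - min(counts) >= n_folds)
    warning("class imbalance: stratified-subsampling to the minimum ",
            "class count")
  fold <- rep(NA_integer_, length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))[seq_len(m * n_folds)]
    fold[i] <- rep(seq_len(n_folds), each = m)
  }
  fold
}

# Macro one-vs-rest AUC from a posterior matrix (rows = trials, columns
# named by class).
macroAUC <- function(post, labels) {
  mean(vapply(colnames(post), function(cl)
    rankAUC(post[, cl], labels == cl), numeric(1)), na.rm = TRUE)
}

# PCA + LDA for one fold and timepoint. Returns AUC on the held-out fold.
foldAUC <- function(Xtr, ytr, Xte, yte, pca_keep) {
  mu <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, mu)
  pc <- La.svd(Xc, nu = 0)
  ev <- pc$d^2
  keep <- which(cumsum(ev) / sum(ev) >= pca_keep - 1e-12)[1]
  keep <- max(keep, 1)
  # guard directions with numerically zero variance
  keep <- min(keep, sum(pc$d > max(pc$d) * 1e-8))
  V <- t(pc$vt)[, seq_len(keep), drop = FALSE]
  Ztr <- Xc %*% V
  Zte <- sweep(Xte, 2, mu) %*% V
  # PCA already controls dimensionality; residual within-class collinearity
  # at low n is benign for the decision values, so silence lda's warning
  fit <- suppressWarnings(MASS::lda(Ztr, grouping = factor(ytr)))
  post <- stats::predict(fit, Zte)$posterior
  macroAUC(post, yte)
}

#' Time-resolved decoding of one subject
#'
#' Runs the full decoding pipeline on one subject's epochs: baseline
#' correction, block-average downsampling to 128 Hz, pseudo-trial
#' averaging, stratified 10-fold cross-validation, and per-timepoint,
#' per-fold PCA (fit on the training fold only) followed by LDA, scored by
#' macro-averaged one-vs-rest AUC on the held-out fold.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} (only kept trials are
#'   used), or a plain trials x features x time array.
#' @param labels class label per (kept) trial.
#' @param cfg a \code{\link{decodeConfig}}.
#' @param features for \code{EpochSet} input, channel names to use
#'   (default: the 64 scalp channels).
#' @param times time stamps when \code{epochs} is an array.
#' @param srate sampling rate when \code{epochs} is an array.
#' @param variant label stored in the result.
#' @return an \code{\linkS4class{AUCTimecourse}} with one row.
#' @export
decodeTimecourse <- function(epochs, labels, cfg = decodeConfig(),
                             features = scalpChannels(), times = NULL,
                             srate = NULL, variant = "custom") {
  if (is(epochs, "EpochSet")) {
    keep <- epochs@flags$keep
    dat <- epochs@data[keep, match(features, epochs@channels), ,
                       drop = FALSE]
    labels <- labels[keep]
    times <- epochs@times
    srate <- epochs@srate
  } else {
    dat <- epochs
    if (is.null(times) || is.null(srate))
      stop("array input needs times and srate", call. = FALSE)
  }
  stopifnot(length(labels) == dim(dat)[1])

  # baseline, then downsample (in that order)
  bi <- timeIndex(times, cfg$baseline_window)
  if (length(bi)) {
    mu <- rowMeans(dat[, , bi, drop = FALSE], dims = 2)
    dat <- dat - array(mu, dim = dim(dat))
  }
  factor <- max(1, round(srate / cfg$downsample_to))
  dat <- blockDecimate(dat, factor)
  dtimes <- colMeans(matrix(times[seq_len(dim(dat)[3] * factor)], factor))
  wi <- timeIndex(dtimes, cfg$decode_window)
  dat <- dat[, , wi, drop = FALSE]
  dtimes <- dtimes[wi]

  ps <- makePseudotrials(dat, labels, cfg$avg_k, seed = cfg$seed)
  auc <- withSeed(subSeed(cfg$seed, 1), {
    fold <- foldAssign(ps$labels, cfg$n_folds)
    used <- !is.na(fold)
    X <- ps$data[used, , , drop = FALSE]
    y <- ps$labels[used]
    fold <- fold[used]
    ntp <- dim(X)[3]
    out <- numeric(ntp)
    for (tp in seq_len(ntp)) {
      Xt <- X[, , tp, drop = TRUE]
      if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = 1)
      a <- vapply(seq_len(cfg$n_folds), function(f) {
        tr <- fold != f
        foldAUC(Xt[tr, , drop = FALSE], y[tr],
                Xt[!tr, , drop = FALSE], y[!tr], cfg$pca_variance_kept)
      }, numeric(1))
      out[tp] <- mean(a)
    }
    out
  })
  new("AUCTimecourse", auc = matrix(auc, 1), times = dtimes, chance = 0.5,
      variant = variant)
}

#' Run a named decoding variant
#'
#' Applies the trial selection, label definition and averaging parameter of
#' each analysis variant, then calls \code{\link{decodeTimecourse}}:
#' \describe{
#'   \item{hp_ping / hp_noping}{4 HP-location classes, biased blocks, ping
#'     (or matched no-ping) trials, avg_k = 3.}
#'   \item{prev_target}{8 classes = previous trial's target location, all
#'     experiment blocks including neutral, avg_k = 5.}
#'   \item{dummy}{3 temporal-phase labels; phase i spans the last biased
#'     block of HP sequence i, its neutral block and the first two biased
#'     blocks of sequence i+1 (224 trials per phase at design defaults);
#'     ping trials, avg_k = 3.}
#'   \item{hp_exclusion}{hp_ping after dropping trials whose preceding
#'     trial's target was at the current HP location.}
#'   \item{hp_only}{only trials whose preceding target was at the current
#'     HP location; avg_k = 1 (trial counts are too low for averaging).}
#'   \item{gaze_features}{hp_ping labels with the two gaze coordinates as
#'     features (pass a \code{GazeEpochSet} via \code{gaze}).}
#' }
#'
#' @param epochs an \code{\linkS4class{EpochSet}} of one subject (all
#'   trials; flags select kept ones).
#' @param variant one of the names above.
#' @param cfg a \code{\link{decodeConfig}}; \code{avg_k} is overridden per
#'   variant unless \code{keep_avg_k = TRUE}.
#' @param gaze a \code{\linkS4class{GazeEpochSet}} for
#'   \code{variant = "gaze_features"}.
#' @param keep_avg_k do not override \code{cfg$avg_k}.
#' @return an \code{\linkS4class{AUCTimecourse}} (one subject row).
#' @export
runVariant <- function(epochs, variant, cfg = decodeConfig(), gaze = NULL,
                       keep_avg_k = FALSE) {
  known <- c("hp_ping", "hp_noping", "prev_target", "dummy",
             "hp_exclusion", "hp_only", "gaze_features")
  if (!variant %in% known)
    stop("unknown variant: ", variant, call. = FALSE)
  tr <- epochs@trials
  keep <- epochs@flags$keep

  selBias <- !tr$practice & tr$block_type == "biased"
  prevAtHP <- !is.na(tr$prev_target_location) & !is.na(tr$hp_location) &
    tr$prev_target_location == tr$hp_location

  sel <- switch(variant,
    hp_ping = selBias & tr$ping,
    hp_noping = selBias & !tr$ping,
    prev_target = !tr$practice & tr$ping & !is.na(tr$prev_target_location),
    dummy = dummyPhase(tr) > 0 & tr$ping,
    hp_exclusion = selBias & tr$ping & !prevAtHP,
    hp_only = selBias & tr$ping & prevAtHP,
    gaze_features = selBias & tr$ping)
  labels <- switch(variant,
    hp_ping = , hp_noping = , hp_exclusion = , hp_only = ,
    gaze_features = tr$hp_location,
    prev_target = tr$prev_target_location,
    dummy = dummyPhase(tr))
  avg <- switch(variant,
    prev_target = 5, hp_only = 1,
    hp_ping = , hp_noping = , dummy = , hp_exclusion = ,
    gaze_features = 3)
  if (!keep_avg_k) cfg$avg_k <- avg

  if (variant == "gaze_features") {
    if (is.null(gaze)) stop("gaze_features needs gaze epochs", call. = FALSE)
    use <- which(sel & keep)
    return(decodeTimecourse(gaze@data[use, , , drop = FALSE], labels[use],
                            cfg, times = gaze@times, srate = gaze@srate,
                            variant = variant))
  }
  sub <- epochs
  sub@flags$keep <- keep & sel
  sub@flags$reason[!sub@flags$keep & sub@flags$reason == ""] <-
    "not in variant selection"
  decodeTimecourse(sub, labels, cfg, variant = variant)
}

# Dummy temporal phases: 0 = unused, 1..3. Phase i covers the last biased
# block of HP sequence i, the following neutral block, and the first two
# biased blocks of sequence i+1.
dummyPhase <- function(tr) {
  ph <- integer(nrow(tr))
  exp <- !tr$practice
  bt <- tr$block_type
  bi <- tr$block_index
  # sequence boundaries from the neutral blocks
  neutrals <- sort(unique(bi[exp & bt == "neutral"]))
  if (length(neutrals) < 3)
    stop("dummy phases need at least three neutral blocks", call. = FALSE)
  if (any(diff(neutrals[1:3]) < 4))
    stop("dummy windows overlap ambiguously", call. = FALSE)
  for (i in seq_len(3)) {
    nb <- neutrals[i]
    ph[exp & bi %in% (nb - 1):(nb + 2)] <- i
  }
  ph
}
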