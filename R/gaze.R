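#' Preprocess a gaze recording into epochs
#'
#' Converts native tracker coordinates (top-left origin, y down) to
#' fixation-centered, y-up pixels; linearly interpolates across blink
#' windows padded by 200 ms on each side; epochs around the ping trigger;
#' optionally subtracts the -200..0 ms pre-ping baseline; and resamples to
#' 500 Hz (polyphase) when the tracker ran faster. Trials whose baseline is
#' fully covered by a blink are flagged.
#'
#' @param raw a \code{\linkS4class{GazeRecording}}.
#' @param trials trial table aligned with \code{raw@events} (one row per
#'   event).
#' @param window epoch window in ms (default c(-700, 600)).
#' @param baseline baseline window in ms, or NULL to skip (default
#'   c(-200, 0)).
#' @param blink_pad_ms pad applied before and after each blink (200).
#' @param target_srate output sampling rate (500).
#' @return a \code{\linkS4class{GazeEpochSet}}.
#' @export
preprocessGaze <- function(raw, trials = NULL, window = c(-700, 600),
                           baseline = c(-200, 0), blink_pad_ms = 200,
                           target_srate = 500) {
  s <- raw@samples
  x <- s$x - raw@screen[1]
  y <- raw@screen[2] - s$y          # y-up, fixation-centered
  tm <- s$time_ms

  # blink interpolation with pads
  if (nrow(raw@blinks)) {
    for (b in seq_len(nrow(raw@blinks))) {
      w <- which(tm >= raw@blinks$start_ms[b] - blink_pad_ms &
                 tm <= raw@blinks$end_ms[b] + blink_pad_ms)
      if (!length(w)) next
      lo <- min(w) - 1
      hi <- max(w) + 1
      if (lo < 1 || hi > length(tm)) {     # blink touches an edge: hold
        x[w] <- x[if (lo < 1) hi else lo]
        y[w] <- y[if (lo < 1) hi else lo]
      } else {
        frac <- (tm[w] - tm[lo]) / (tm[hi] - tm[lo])
        x[w] <- x[lo] + frac * (x[hi] - x[lo])
        y[w] <- y[lo] + frac * (y[hi] - y[lo])
      }
    }
  }

  srate <- raw@srate
  step <- 1000 / srate
  pre <- round(-window[1] / step)
  post <- round(window[2] / step)
  times <- (seq_len(pre + post + 1) - pre - 1) * step
  ntrial <- nrow(raw@events)
  dat <- array(NA_real_, c(ntrial, 2, length(times)))
  flags <- data.frame(keep = rep(TRUE, ntrial), reason = rep("", ntrial),
                      stringsAsFactors = FALSE)
  for (tr in seq_len(ntrial)) {
    ctr <- which.min(abs(tm - raw@events$onset_ms[tr]))
    idx <- (ctr - pre):(ctr + post)
    if (idx[1] < 1 || idx[length(idx)] > length(tm))
      stop("event epoch outside recording", call. = FALSE)
    dat[tr, 1, ] <- x[idx]
    dat[tr, 2, ] <- y[idx]
    if (nrow(raw@blinks) && !is.null(baseline)) {
      bwin <- raw@events$onset_ms[tr] + baseline
      cover <- any(raw@blinks$start_ms - blink_pad_ms <= bwin[1] &
                   raw@blinks$end_ms + blink_pad_ms >= bwin[2])
      if (cover) {
        flags$keep[tr] <- FALSE
        flags$reason[tr] <- "blink covers baseline"
      }
    }
  }

  if (!is.null(baseline)) {
    bi <- timeIndex(times, baseline)
    mu <- apply(dat[, , bi, drop = FALSE], c(1, 2), mean)
    dat <- dat - array(mu, dim = dim(dat))
  }

  if (srate > target_srate) {
    p <- 1
    q <- srate / target_srate
    stopifnot(q == round(q))
    nt <- floor(length(times) / q)
    out <- array(NA_real_, c(ntrial, 2, nt))
    for (tr in seq_len(ntrial)) for (ch in 1:2) {
      # remove the epoch mean before polyphase resampling so the filter's
      # zero-padded edges do not ring against the DC offset
      mu <- mean(dat[tr, ch, ])
      out[tr, ch, ] <- signal::resample(dat[tr, ch, ] - mu, p,
                                        q)[seq_len(nt)] + mu
    }
    dat <- out
    times <- times[seq(1, by = q, length.out = nt)]
    srate <- target_srate
  }

  trl <- if (is.null(trials))
    data.frame(trial = raw@events$trial) else trials
  new("GazeEpochSet", data = dat, srate = srate, times = times,
      baselined = !is.null(baseline), trials = trl, flags = flags)
}

#' Match gaze epochs to retained EEG trials
#'
#' Restricts a gaze epoch set to the trials kept in a preprocessed EEG
#' epoch set, so both containers describe the same trial set.
#'
#' @param gaze a \code{\linkS4class{GazeEpochSet}} (one epoch per schedule
#'   trial).
#' @param epochs an \code{\linkS4class{EpochSet}} whose flags mark kept
#'   trials.
#' @return the reduced \code{GazeEpochSet}.
#' @export
matchTrials <- function(gaze, epochs) {
  keep <- which(epochs@flags$keep)
  gaze@data <- gaze@data[keep, , , drop = FALSE]
  gaze@trials <- gaze@trials[keep, , drop = FALSE]
  rownames(gaze@trials) <- NULL
  gaze@flags <- gaze@flags[keep, , drop = FALSE]
  rownames(gaze@flags) <- NULL
  gaze
}

#' Gaze density maps per HP condition
#'
#' For each subject and HP condition, pools all gaze samples in the 0-600 ms
#' post-ping window, rounds positions to the nearest grid cell
#' (quarter-pixel by default), and forms an occupancy grid (proportion of
#' samples; sums to 1). Samples outside the grid extent are clipped to the
#' border cells and counted. The difference grid of each condition is its
#' occupancy minus the average of the other three conditions' occupancy
#' (difference grids sum to 0).
#'
#' @param gaze a baselined \code{\linkS4class{GazeEpochSet}} whose trial
#'   table carries \code{hp_location}.
#' @param window pooling window in ms (c(0, 600)).
#' @param extent_px half-width of the grid around fixation (100).
#' @param cell_px grid cell size in px (0.25 = quarter pixel).
#' @return list of class \code{DensityMaps}: \code{occupancy} and
#'   \code{difference}, each a named list (one matrix per HP condition,
#'   rows = x cells, cols = y cells), plus the cell-centre coordinates.
#' @export
densityMaps <- function(gaze, window = c(0, 600), extent_px = 100,
                        cell_px = 0.25) {
  hp <- gaze@trials$hp_location
  conds <- sort(unique(hp[!is.na(hp)]))
  if (length(conds) != 4)
    stop("all four HP conditions must be present", call. = FALSE)
  ti <- timeIndex(gaze@times, window)
  breaksN <- round(2 * extent_px / cell_px) + 1
  centers <- seq(-extent_px, extent_px, by = cell_px)
  occ <- list()
  for (cc in conds) {
    i <- which(!is.na(hp) & hp == cc)
    if (!length(i)) stop("empty HP condition", call. = FALSE)
    xs <- as.numeric(gaze@data[i, 1, ti])
    ys <- as.numeric(gaze@data[i, 2, ti])
    # round to grid, clip to border cells
    cx <- pmin(pmax(round(xs / cell_px), -(breaksN - 1) / 2),
               (breaksN - 1) / 2) + (breaksN - 1) / 2 + 1
    cy <- pmin(pmax(round(ys / cell_px), -(breaksN - 1) / 2),
               (breaksN - 1) / 2) + (breaksN - 1) / 2 + 1
    g <- matrix(0, breaksN, breaksN)
    tb <- table(factor(cx, levels = seq_len(breaksN)),
                factor(cy, levels = seq_len(breaksN)))
    g[] <- as.numeric(tb)
    occ[[as.character(cc)]] <- g / sum(g)
  }
  diffs <- lapply(names(occ), function(nm) {
    others <- occ[setdiff(names(occ), nm)]
    occ[[nm]] - Reduce(`+`, others) / length(others)
  })
  names(diffs) <- names(occ)
  structure(list(occupancy = occ, difference = diffs, centers = centers,
                 window = window),
            class = "DensityMaps")
}

#' Gaze towardness toward the HP location
#'
#' Quantifies the gaze-position bias toward the current HP location as a
#' percentage of target eccentricity, per timepoint. Trials are split by
#' whether the HP location lies on the horizontal (left/right) or vertical
#' (top/bottom) axis; the toward-axis coordinate is averaged per condition;
#' opposing conditions are subtracted and halved with the sign arranged so
#' that positive = toward the HP location; the result is divided by the
#' stimulus eccentricity and multiplied by 100, then averaged over the two
#' axes. Ping and no-ping trials are scored separately.
#'
#' @param gaze an un-baselined \code{\linkS4class{GazeEpochSet}} spanning
#'   -700..600 ms, trial table carrying \code{hp_location} and \code{ping}.
#' @param eccentricity_px stimulus eccentricity (185 px).
#' @return list of class \code{TowardnessCurve}: \code{times} (ms) and a
#'   \code{towardness} matrix with rows "ping"/"noping" (percent of
#'   eccentricity).
#' @export
towardness <- function(gaze, eccentricity_px = 185) {
  hp <- gaze@trials$hp_location
  tw <- matrix(NA_real_, 2, length(gaze@times),
               dimnames = list(c("ping", "noping"), NULL))
  for (pp in 1:2) {
    sel <- if (pp == 1) gaze@trials$ping else !gaze@trials$ping
    avg <- function(loc, axis) {
      i <- which(sel & !is.na(hp) & hp == loc)
      if (!length(i)) stop("missing opposing HP condition", call. = FALSE)
      colMeans(matrix(gaze@data[i, axis, ], nrow = length(i)))
    }
    # horizontal: x of HP-right (0) minus x of HP-left (4), halved
    horiz <- (avg(0, 1) - avg(4, 1)) / 2
    # vertical: y of HP-top (2) minus y of HP-bottom (6), halved
    vert <- (avg(2, 2) - avg(6, 2)) / 2
    tw[pp, ] <- (horiz + vert) / 2 / eccentricity_px * 100
  }
  structure(list(times = gaze@times, towardness = tw,
                 eccentricity_px = eccentricity_px),
            class = "TowardnessCurve")
}
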