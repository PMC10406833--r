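# Plain-text and native-container I/O.

#' Read and write trial tables
#'
#' Trial tables (one row per trial) are exchanged as tab-separated text.
#'
#' @param trials a schedule/behavior data.frame.
#' @param path file path.
#' @return \code{readTrialTable} returns the data.frame.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE)
}

#' Write and read gaze recordings in an ASC-like text format
#'
#' Whitespace-delimited sample lines (\code{time x y}) preceded by
#' \code{BLINK <start> <end>} event lines and \code{MSG <time> TRIAL <i>}
#' trigger lines, in the spirit of video-tracker ASCII exports.
#'
#' @param gaze a \code{\linkS4class{GazeRecording}}.
#' @param path file path.
#' @return \code{readGazeASC} returns a \code{GazeRecording}.
#' @export
writeGazeASC <- function(gaze, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("** RATE %g", gaze@srate), con)
  writeLines(sprintf("** SCREEN %g %g", gaze@screen[1], gaze@screen[2]),
             con)
  for (i in seq_len(nrow(gaze@events)))
    writeLines(sprintf("MSG %.3f TRIAL %d", gaze@events$onset_ms[i],
                       gaze@events$trial[i]), con)
  for (i in seq_len(nrow(gaze@blinks)))
    writeLines(sprintf("BLINK %.3f %.3f", gaze@blinks$start_ms[i],
                       gaze@blinks$end_ms[i]), con)
  utils::write.table(gaze@samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGazeASC
#' @export
readGazeASC <- function(path) {
  lines <- readLines(path)
  rate <- as.numeric(sub("^\\*\\* RATE ", "", grep("^\\*\\* RATE",
                                                   lines, value = TRUE)))
  scr <- as.numeric(strsplit(sub("^\\*\\* SCREEN ", "",
                                 grep("^\\*\\* SCREEN", lines,
                                      value = TRUE)), " ")[[1]])
  msg <- grep("^MSG", lines, value = TRUE)
  ev <- do.call(rbind, lapply(strsplit(msg, "[ \t]+"), function(p)
    data.frame(trial = as.integer(p[4]), onset_ms = as.numeric(p[2]))))
  bl <- grep("^BLINK", lines, value = TRUE)
  blinks <- if (length(bl))
    do.call(rbind, lapply(strsplit(bl, "[ \t]+"), function(p)
      data.frame(start_ms = as.numeric(p[2]), end_ms = as.numeric(p[3]))))
  else data.frame(start_ms = numeric(0), end_ms = numeric(0))
  smp <- lines[grep("^[0-9]", lines)]
  m <- do.call(rbind, strsplit(smp, "\t"))
  samples <- data.frame(time_ms = as.numeric(m[, 1]),
                        x = as.numeric(m[, 2]), y = as.numeric(m[, 3]))
  new("GazeRecording", samples = samples, blinks = blinks,
      events = ev[order(ev$trial), , drop = FALSE], srate = rate,
      screen = scr, log = list())
}

#' Save and load epoch containers
#'
#' Epoch containers are persisted in the package's native serialized form.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} or
#'   \code{\linkS4class{GazeEpochSet}}.
#' @param path file path.
#' @return \code{loadEpochs} returns the saved object.
#' @export
saveEpochs <- function(epochs, path) {
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname saveEpochs
#' @export
loadEpochs <- function(path) readRDS(path)

#' Export an AUC time course as tab-separated text
#'
#' @param auc an \code{\linkS4class{AUCTimecourse}}.
#' @param path file path.
#' @export
writeAUC <- function(auc, path) {
  df <- data.frame(time_ms = auc@times, t(auc@auc))
  names(df)[-1] <- paste0("subject", seq_len(nrow(auc@auc)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
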