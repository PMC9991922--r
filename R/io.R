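# Plain-format session I/O: movies as multi-page float TIFF, trial tables
# as CSV (click-time lists serialized as ";"-joined fields), configs as
# YAML.

#' Write a session to a directory
#'
#' Writes \code{blue.tif} and \code{violet.tif} (multi-page 32-bit float),
#' \code{trials.csv}, \code{movement.csv}, \code{video.csv} and
#' \code{meta.yaml} (dims, frame rate, timestamps).
#'
#' @param session a [RawSession-class]
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toPages <- function(m, dims) {
    mx <- max(abs(m))
    lapply(seq_len(ncol(m)), function(i) matrix(m[, i] / mx, dims[1], dims[2]))
  }
  for (chan in c("blue", "violet")) {
    m <- slot(session, chan)
    tiff::writeTIFF(toPages(m, session@dims),
                    file.path(dir, paste0(chan, ".tif")),
                    bits.per.sample = 32L)
  }
  tr <- session@trials
  tr$clickTimesLeft <- vapply(tr$clickTimesLeft, paste, "", collapse = ";")
  tr$clickTimesRight <- vapply(tr$clickTimesRight, paste, "", collapse = ";")
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(session@movement, file.path(dir, "movement.csv"),
                   row.names = FALSE)
  utils::write.csv(session@video, file.path(dir, "video.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(dims = as.integer(session@dims),
                        frameRate = session@frameRate,
                        scaleBlue = max(abs(session@blue)),
                        scaleViolet = max(abs(session@violet)),
                        blueTimes = session@blueTimes,
                        violetTimes = session@violetTimes),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a session written by [writeSession()]
#'
#' @param dir session directory
#' @return a [RawSession-class]
#' @export
readSession <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  readChan <- function(chan, scale) {
    pages <- tiff::readTIFF(file.path(dir, paste0(chan, ".tif")), all = TRUE)
    scale * sapply(pages, as.vector)
  }
  tr <- utils::read.csv(file.path(dir, "trials.csv"),
                        stringsAsFactors = FALSE)
  parse <- function(s) lapply(strsplit(ifelse(is.na(s), "", s), ";"),
                              function(v) as.numeric(v[nzchar(v)]))
  tr$clickTimesLeft <- parse(tr$clickTimesLeft)
  tr$clickTimesRight <- parse(tr$clickTimesRight)
  new("RawSession",
      blue = readChan("blue", meta$scaleBlue),
      violet = readChan("violet", meta$scaleViolet),
      blueTimes = as.numeric(meta$blueTimes),
      violetTimes = as.numeric(meta$violetTimes),
      dims = as.integer(meta$dims), frameRate = meta$frameRate,
      trials = tr,
      movement = as.matrix(utils::read.csv(file.path(dir, "movement.csv"))),
      video = as.matrix(utils::read.csv(file.path(dir, "video.csv"))))
}

#' Write a task configuration as YAML
#' @param config a [TaskConfig-class]
#' @param path output file
#' @export
writeTaskConfig <- function(config, path) {
  yaml::write_yaml(list(
    frameRate = config@frameRate,
    handleHoldRange = config@handleHoldRange,
    stimDurationRange = config@stimDurationRange,
    delayMax = config@delayMax,
    clickRateLeft = config@clickRateLeft,
    clickRateRight = config@clickRateRight,
    clickWidth = config@clickWidth,
    nTrials = config@nTrials,
    psychometric = as.list(config@psychometric)), path)
  invisible(path)
}

#' Read a task configuration from YAML
#' @param path YAML file written by [writeTaskConfig()]
#' @return a [TaskConfig-class]
#' @export
readTaskConfig <- function(path) {
  y <- yaml::read_yaml(path)
  taskConfig(frameRate = y$frameRate,
             handleHoldRange = as.numeric(y$handleHoldRange),
             stimDurationRange = as.numeric(y$stimDurationRange),
             delayMax = y$delayMax,
             clickRateLeft = y$clickRateLeft,
             clickRateRight = y$clickRateRight,
             clickWidth = y$clickWidth, nTrials = y$nTrials,
             psychometric = unlist(y$psychometric))
}
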