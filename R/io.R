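#' Write a simulated session to a plain-text directory container
#'
#' Layout of the container (all text formats): \code{gaze.tsv} (EyeLink-ASC
#' style samples: time_ms, x, y), \code{meg.tsv} (samples x channels, header
#' = channel ids), \code{photodiode.tsv}, \code{events.tsv},
#' \code{layout.json}, \code{truth.json} (kernels are stored by their
#' parameters' evaluated envelopes on the epoch grid, not as closures).
#'
#' @param session a [SimSession-class]
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGazeTsv(session@gaze, file.path(dir, "gaze.tsv"))
  meg <- as.data.frame(t(session@meg))
  names(meg) <- session@channels
  utils::write.table(cbind(sample = seq_len(nrow(meg)) - 1L, meg),
                     file.path(dir, "meg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = seq_along(session@photodiode) - 1L,
                                value = session@photodiode),
                     file.path(dir, "photodiode.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(session@events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLayoutJson(session@layout, file.path(dir, "layout.json"))
  tr <- session@truth
  jsonlite::write_json(list(theta = tr$theta, betaTrue = tr$betaTrue,
                            weights = tr$weights,
                            residualAmplitude = tr$residualAmplitude,
                            sfreq = session@sfreq),
                       file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read the MEG matrix and events back from a session container
#'
#' @param dir session directory written by [writeSession()]
#' @return list: \code{meg} (channels x samples), \code{photodiode},
#'   \code{events}, \code{gaze} ([GazeRecording-class]), \code{layout},
#'   \code{sfreq}
#' @export
readSession <- function(dir) {
  meg <- utils::read.table(file.path(dir, "meg.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(meg = t(as.matrix(meg[, -1L, drop = FALSE])),
       photodiode = utils::read.table(file.path(dir, "photodiode.tsv"),
                                      header = TRUE, sep = "\t")$value,
       events = utils::read.table(file.path(dir, "events.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE),
       gaze = readGazeTsv(file.path(dir, "gaze.tsv")),
       layout = readLayoutJson(file.path(dir, "layout.json")),
       sfreq = truth$sfreq)
}
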