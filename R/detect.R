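#' Saccade detector parameters
#'
#' Parameters of the adaptive velocity-threshold saccade detector
#' (Nystrom-Holmqvist family): events shorter than
#' \code{minSaccadeDur} are discarded and events separated by less than
#' \code{minFixationDur} are merged; the peak-detection threshold is found by
#' fixed-point iteration \code{PT <- mean + k * sd} over velocity samples
#' below the current threshold.
#'
#' @param minFixationDur minimum fixation duration (s, default 0.040)
#' @param minSaccadeDur minimum saccade duration (s, default 0.010)
#' @param peakThresholdInit initial peak threshold (deg/s)
#' @param thresholdK threshold multiplier k (default 6)
#' @param smoothingWindow Savitzky-Golay differentiation window (s, default 0.014)
#' @param convergenceTol threshold-iteration convergence tolerance (deg/s)
#' @param onsetFraction fraction of the converged threshold used when walking
#'   outward from a velocity peak to refine onset/offset (default 0.7)
#' @param microsaccadeMaxAmp amplitude bound (deg) at or below which an event
#'   counts as a microsaccade (inclusive)
#' @param blinkPadding window (s) by which invalid samples are expanded on
#'   each side before exclusion
#' @return a named list of detector parameters
#' @export
detectorParams <- function(minFixationDur = 0.040, minSaccadeDur = 0.010,
                           peakThresholdInit = 100, thresholdK = 6,
                           smoothingWindow = 0.014, convergenceTol = 1,
                           onsetFraction = 0.7, microsaccadeMaxAmp = 0.5,
                           blinkPadding = 0.050) {
  p <- list(minFixationDur = minFixationDur, minSaccadeDur = minSaccadeDur,
            peakThresholdInit = peakThresholdInit, thresholdK = thresholdK,
            smoothingWindow = smoothingWindow, convergenceTol = convergenceTol,
            onsetFraction = onsetFraction,
            microsaccadeMaxAmp = microsaccadeMaxAmp,
            blinkPadding = blinkPadding)
  if (any(unlist(p[c("minFixationDur", "minSaccadeDur", "smoothingWindow",
                     "convergenceTol")]) <= 0) || thresholdK <= 0)
    stop("detector durations and thresholdK must be positive", call. = FALSE)
  p
}

# Gaze speed (deg/s) from Savitzky-Golay local-polynomial differentiation.
.gazeSpeed <- function(gaze, p) {
  n <- max(5L, round(p$smoothingWindow * gaze@sfreq))
  if (n %% 2L == 0L) n <- n + 1L
  vx <- signal::sgolayfilt(gaze@x, p = 2, n = n, m = 1, ts = 1 / gaze@sfreq)
  vy <- signal::sgolayfilt(gaze@y, p = 2, n = n, m = 1, ts = 1 / gaze@sfreq)
  sqrt(vx^2 + vy^2)
}

# Fixed-point peak-threshold iteration; returns converged PT.
.adaptiveThreshold <- function(speed, p) {
  pt <- p$peakThresholdInit
  for (it in seq_len(100L)) {
    below <- speed[speed < pt]
    if (length(below) < 10L) break
    new <- mean(below) + p$thresholdK * stats::sd(below)
    if (!is.finite(new)) break
    done <- abs(new - pt) < p$convergenceTol
    pt <- new
    if (done) return(pt)
  }
  if (it >= 100L)
    warning("peak-threshold iteration did not converge within 100 iterations")
  pt
}

#' Detect saccades with an adaptive velocity threshold
#'
#' Velocity is estimated by Savitzky-Golay differentiation of the gaze trace;
#' the peak-detection threshold is data-driven (fixed-point iteration
#' \code{PT <- mean + k * sd} over sub-threshold samples). Each velocity peak
#' is refined by walking outward to the first sample below
#' \code{onsetFraction * PT}. Events shorter than the minimum saccade
#' duration are discarded, and events separated by less than the minimum
#' fixation duration are merged. Samples flagged invalid (padded by
#' \code{blinkPadding}) are excluded from threshold estimation, and events
#' touching them are dropped.
#'
#' @param gaze a [GazeRecording-class] (degrees, uniform rate, >= 100 ms)
#' @param params a [detectorParams()] list
#' @return a [SaccadeEvents-class]; indices are 0-based with half-open
#'   \code{[onset, offset)} extents
#' @export
detectSaccades <- function(gaze, params = detectorParams()) {
  stopifnot(methods::is(gaze, "GazeRecording"))
  n <- length(gaze@t)
  if (n < round(0.1 * gaze@sfreq))
    stop("need at least 100 ms of gaze data", call. = FALSE)
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      onset_idx = integer(0), offset_idx = integer(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      start_x = numeric(0), start_y = numeric(0),
                      end_x = numeric(0), end_y = numeric(0))
  bad <- !gaze@valid
  if (all(bad)) {
    warning("all gaze samples invalid; no events detected")
    return(methods::new("SaccadeEvents", events = empty, params = params))
  }
  if (any(bad)) {
    pad <- round(params$blinkPadding * gaze@sfreq)
    bi <- which(bad)
    ext <- unique(unlist(lapply(bi, function(i)
      max(1L, i - pad):min(n, i + pad))))
    bad[ext] <- TRUE
  }
  speed <- .gazeSpeed(gaze, params)
  pt <- .adaptiveThreshold(speed[!bad], params)
  loc <- params$onsetFraction * pt

  supra <- speed >= pt & !bad
  runs <- .trueRuns(supra)
  if (nrow(runs) == 0L)
    return(methods::new("SaccadeEvents", events = empty,
                        params = c(params, peakThreshold = pt)))
  ev <- lapply(seq_len(nrow(runs)), function(r) {
    a <- unname(runs[r, "start"]); b <- a + unname(runs[r, "length"]) - 1L
    pk <- a - 1L + which.max(speed[a:b])
    i <- pk
    while (i > 1L && speed[i - 1L] >= loc && !bad[i - 1L]) i <- i - 1L
    j <- pk
    while (j < n && speed[j + 1L] >= loc && !bad[j + 1L]) j <- j + 1L
    c(onset = i, offset = j + 1L, peak = max(speed[a:b]))  # half-open
  })
  ev <- do.call(rbind, ev)
  ev <- ev[!duplicated(ev[, "onset"]), , drop = FALSE]

  # minimum saccade duration, then merge events separated by short fixations
  dur <- (ev[, "offset"] - ev[, "onset"]) / gaze@sfreq
  ev <- ev[dur >= params$minSaccadeDur, , drop = FALSE]
  if (nrow(ev) > 1L) {
    keep <- list(ev[1L, ])
    for (r in 2L:nrow(ev)) {
      last <- keep[[length(keep)]]
      gap <- (ev[r, "onset"] - last["offset"]) / gaze@sfreq
      if (gap < params$minFixationDur) {
        last["offset"] <- max(last["offset"], ev[r, "offset"])
        last["peak"] <- max(last["peak"], ev[r, "peak"])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- ev[r, ]
    }
    ev <- do.call(rbind, keep)
  }
  if (nrow(ev) == 0L)
    return(methods::new("SaccadeEvents", events = empty,
                        params = c(params, peakThreshold = pt)))
  on <- as.integer(ev[, "onset"]); off <- as.integer(pmin(ev[, "offset"], n))
  events <- data.frame(
    onset_t = gaze@t[on], offset_t = gaze@t[off],
    onset_idx = on - 1L, offset_idx = off - 1L,
    amplitude = sqrt((gaze@x[off] - gaze@x[on])^2 +
                     (gaze@y[off] - gaze@y[on])^2),
    peak_velocity = ev[, "peak"],
    start_x = gaze@x[on], start_y = gaze@y[on],
    end_x = gaze@x[off], end_y = gaze@y[off])
  events <- events[order(events$onset_t), , drop = FALSE]
  rownames(events) <- NULL
  methods::new("SaccadeEvents", events = events,
               params = c(params, peakThreshold = pt))
}

#' Split events into saccades and microsaccades
#'
#' Events with amplitude at or below the bound (inclusive) are
#' microsaccades; the partition is exhaustive and disjoint.
#'
#' @param events a [SaccadeEvents-class]
#' @param params a [detectorParams()] list (uses \code{microsaccadeMaxAmp})
#' @return list with [SaccadeEvents-class] elements \code{saccades} and
#'   \code{microsaccades}
#' @export
classifyMicrosaccades <- function(events, params = detectorParams()) {
  stopifnot(methods::is(events, "SaccadeEvents"))
  e <- events@events
  micro <- e$amplitude <= params$microsaccadeMaxAmp
  list(saccades = methods::new("SaccadeEvents",
                               events = e[!micro, , drop = FALSE],
                               params = events@params),
       microsaccades = methods::new("SaccadeEvents",
                                    events = e[micro, , drop = FALSE],
                                    params = events@params))
}

#' @describeIn detectSaccades event-table accessor
#' @param object a \code{SaccadeEvents}
#' @param ... unused
#' @export
setMethod("eventTable", "SaccadeEvents", function(object, ...) object@events)

setMethod("show", "SaccadeEvents", function(object) {
  e <- object@events
  cat(sprintf("SaccadeEvents: %d events", nrow(e)))
  if (nrow(e))
    cat(sprintf(" (amplitude %.2f-%.2f deg, peak velocity up to %.0f deg/s)",
                min(e$amplitude), max(e$amplitude), max(e$peak_velocity)))
  cat("\n")
})

#' Write detected events as a tab-separated table
#'
#' @param events a [SaccadeEvents-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writeEventsTsv <- function(events, path) {
  e <- events@events
  utils::write.table(
    e[, c("onset_t", "offset_t", "amplitude", "peak_velocity")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
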