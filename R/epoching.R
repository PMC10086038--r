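#' Attenuate line noise with a discrete-Fourier (DFT) filter
#'
#' For each listed frequency a sine/cosine pair is fitted by least squares
#' over the whole recording (per channel, jointly with a free mean term) and
#' subtracted. On windows containing an integer number of cycles this removes
#' the line component exactly while leaving all other frequencies untouched
#' up to numerical error.
#'
#' @param x numeric matrix, channels x samples (a vector is treated as one
#'   channel)
#' @param sfreq sampling rate (Hz)
#' @param freqs frequencies to attenuate (default 50, 100, 150 Hz)
#' @return matrix of the same shape
#' @export
dftNotch <- function(x, sfreq, freqs = c(50, 100, 150)) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (any(freqs >= sfreq / 2))
    stop("notch frequencies must be below the Nyquist frequency",
         call. = FALSE)
  n <- ncol(x)
  tt <- (seq_len(n) - 1L) / sfreq
  D <- cbind(1, do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt)))))
  cf <- solve(crossprod(D), crossprod(D, t(x)))  # (1 + 2F) x channels
  x - t(D[, -1L, drop = FALSE] %*% cf[-1L, , drop = FALSE])
}

#' Cut continuous recordings into epochs
#'
#' @param x numeric matrix, channels x samples of a continuous recording
#' @param sfreq sampling rate (Hz)
#' @param onsets event times (s) to lock to (sample 0 of each epoch)
#' @param window length-2 window (s) around each onset; samples from
#'   \code{round(window[1]*sfreq)} to \code{round(window[2]*sfreq)} inclusive
#' @param meta data.frame of per-trial metadata (one row per onset)
#' @param lock lock-event label
#' @param channels channel ids (defaults to rownames of \code{x})
#' @return an [EpochSet-class]; trials whose window falls outside the
#'   recording are dropped with a warning
#' @export
makeEpochs <- function(x, sfreq, onsets, window, meta = NULL,
                       lock = "stimulus_onset", channels = rownames(x)) {
  if (is.null(channels)) channels <- sprintf("ch%03d", seq_len(nrow(x)))
  k1 <- round(window[1] * sfreq); k2 <- round(window[2] * sfreq)
  rel <- k1:k2
  i0 <- round(onsets * sfreq) + 1L
  ok <- (i0 + k1) >= 1L & (i0 + k2) <= ncol(x)
  if (!all(ok))
    warning(sprintf("%d trial(s) without full window coverage dropped",
                    sum(!ok)))
  i0 <- i0[ok]
  if (is.null(meta)) meta <- data.frame(trial = seq_along(onsets))
  meta <- meta[ok, , drop = FALSE]
  nt <- length(i0); nc <- nrow(x); ns <- length(rel)
  d <- array(0, dim = c(nt, nc, ns))
  for (i in seq_len(nt))
    d[i, , ] <- x[, i0[i] + rel, drop = FALSE]
  methods::new("EpochSet", data = d, t = rel / sfreq, sfreq = sfreq,
               meta = meta, lock = lock, channels = channels)
}

#' Downsample epochs with an anti-alias FIR filter
#'
#' Zero-phase linear-phase FIR low-pass (cutoff 0.4 x target rate) followed
#' by decimation. The target rate must divide the current rate.
#'
#' @param epochs an [EpochSet-class]
#' @param target target sampling rate (Hz, default 500)
#' @return the downsampled [EpochSet-class]
#' @export
downsampleEpochs <- function(epochs, target = 500) {
  stopifnot(methods::is(epochs, "EpochSet"))
  q <- epochs@sfreq / target
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the sampling rate", call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  d <- epochs@data
  nt <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  b <- signal::fir1(64, 0.8 * target / epochs@sfreq)
  b <- b / sum(b)                               # unit DC gain exactly
  m <- t(matrix(d, nt * nc, ns))                # samples x (trials*channels)
  m <- .firFilterMat(m, b)
  sel <- seq(1L, ns, by = q)
  m <- m[sel, , drop = FALSE]
  epochs@data <- aperm(array(t(m), dim = c(nt, nc, length(sel))), c(1, 2, 3))
  epochs@t <- epochs@t[sel]
  epochs@sfreq <- target
  epochs
}

#' Convert a raw photodiode trace to a trinary signal
#'
#' Four linearly spaced boundary values spanning the observed range (min and
#' max included by default) classify each sample as black (-1), grey (0) or
#' white (+1): values below the second boundary are -1, values between the
#' second and third boundary (inclusive) are 0, values above the third are
#' +1. With \code{includeExtremes = FALSE} the four boundaries are interior
#' points of the range instead.
#'
#' @param raw numeric photodiode samples
#' @param includeExtremes logical; boundaries include min and max (default)
#' @return integer vector in \{-1, 0, 1\}
#' @export
photodiodeTrinary <- function(raw, includeExtremes = TRUE) {
  rng <- range(raw)
  if (diff(rng) == 0)
    stop("photodiode trace has zero range", call. = FALSE)
  b <- if (includeExtremes) seq(rng[1], rng[2], length.out = 4L)
       else seq(rng[1], rng[2], length.out = 6L)[2:5]
  out <- integer(length(raw))
  out[raw < b[2]] <- -1L
  out[raw > b[3]] <- 1L
  out
}

#' Visual onset times from a trinary photodiode signal
#'
#' Every sample where the absolute difference of the trinary signal is
#' non-zero marks a visual transition; the reported time is the 0-based
#' index of the later sample of the changing pair divided by the rate.
#'
#' @param trinary integer vector in \{-1, 0, 1\}
#' @param sfreq sampling rate (Hz)
#' @return numeric vector of onset times (s), possibly empty
#' @export
visualOnsets <- function(trinary, sfreq) {
  j <- which(abs(diff(trinary)) > 0)
  j / sfreq
}

#' Apply the saccade-trial inclusion rules
#'
#' A saccade trial survives iff (1) exactly one saccade occurs between
#' stimulus onset and the second-stimulus onset, (2) the saccade endpoint is
#' at least 4 degrees past the vertical midline on the far side, (3) the
#' endpoint is no lower than 2 degrees below the horizontal midline, and
#' (4) the saccade latency lies in [0.150, 0.500] s (inclusive bounds). The
#' rejection log records the first violated rule per excluded trial.
#'
#' @param trials data.frame with one row per trial: \code{trial},
#'   \code{n_saccades} (count within the stimulus-to-S2 window),
#'   \code{end_x}, \code{end_y} (endpoint, deg, relative to the screen
#'   midlines), \code{latency} (s).
#' @param geom list of screen geometry: \code{midlineX} (deg, vertical
#'   midline), \code{midlineY}, \code{crossingMargin} (default 4),
#'   \code{verticalMargin} (default 2), \code{direction} (-1 for leftward
#'   saccades).
#' @param latencyBounds inclusive latency window (s)
#' @return list: \code{keep} logical per trial, \code{log} data.frame
#'   (\code{trial}, \code{rule}) for rejected trials
#' @export
selectSaccadeTrials <- function(trials,
                                geom = list(midlineX = 0, midlineY = 0,
                                            crossingMargin = 4,
                                            verticalMargin = 2,
                                            direction = -1),
                                latencyBounds = c(0.150, 0.500)) {
  need <- c("trial", "n_saccades", "end_x", "end_y", "latency")
  if (!all(need %in% names(trials)))
    stop("trials table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  crossed <- geom$direction * (trials$end_x - geom$midlineX) >=
    geom$crossingMargin
  highEnough <- trials$end_y >= geom$midlineY - geom$verticalMargin
  latOk <- !is.na(trials$latency) &
    trials$latency >= latencyBounds[1] & trials$latency <= latencyBounds[2]
  rule <- rep(NA_character_, nrow(trials))
  rule[is.na(rule) & trials$n_saccades != 1L] <- "single_saccade"
  rule[is.na(rule) & !crossed] <- "endpoint_crossing"
  rule[is.na(rule) & !highEnough] <- "endpoint_height"
  rule[is.na(rule) & !latOk] <- "latency_window"
  keep <- is.na(rule)
  list(keep = keep,
       log = data.frame(trial = trials$trial[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

#' Apply the fixation-trial inclusion rules
#'
#' A fixation trial survives iff gaze stays within \code{maxExcursion}
#' degrees of the fixation point over the entire epoch and no microsaccade
#' larger than \code{maxMicrosaccade} degrees occurs.
#'
#' @param trials data.frame with one row per trial: \code{trial},
#'   \code{max_gaze_excursion} (deg from fixation over the epoch),
#'   \code{max_microsaccade} (deg; largest detected event amplitude, NA or 0
#'   if none).
#' @param maxExcursion excursion bound (deg, default 2)
#' @param maxMicrosaccade microsaccade amplitude bound (deg, default 0.5)
#' @return list: \code{keep}, \code{log} as in [selectSaccadeTrials()]
#' @export
selectFixationTrials <- function(trials, maxExcursion = 2,
                                 maxMicrosaccade = 0.5) {
  need <- c("trial", "max_gaze_excursion", "max_microsaccade")
  if (!all(need %in% names(trials)))
    stop("trials table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ms <- trials$max_microsaccade
  ms[is.na(ms)] <- 0
  rule <- rep(NA_character_, nrow(trials))
  rule[trials$max_gaze_excursion > maxExcursion] <- "gaze_excursion"
  rule[is.na(rule) & ms > maxMicrosaccade] <- "microsaccade"
  keep <- is.na(rule)
  list(keep = keep,
       log = data.frame(trial = trials$trial[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

#' Relock stimulus-locked epochs to saccade onset
#'
#' Cuts a \code{[-0.6, 0]} s window ending at the saccade-onset sample out of
#' each stimulus-locked epoch. The sample at t = 0 is the saccade-onset
#' sample; trials whose window is not fully covered are dropped and logged.
#'
#' @param epochs an [EpochSet-class] locked to stimulus onset
#' @param onsets per-trial saccade onset (s, relative to the epoch lock)
#' @param window saccade-locked window (s), default \code{c(-0.6, 0)}
#' @return list: \code{epochs} (saccade-locked [EpochSet-class]),
#'   \code{dropped} (integer indices of trials without coverage)
#' @export
relockToSaccade <- function(epochs, onsets, window = c(-0.6, 0)) {
  stopifnot(methods::is(epochs, "EpochSet"))
  if (length(onsets) != dim(epochs@data)[1])
    stop("one saccade onset per trial required", call. = FALSE)
  sf <- epochs@sfreq
  nwin <- round((window[2] - window[1]) * sf) + 1L
  i0 <- round((onsets - epochs@t[1]) * sf) + 1L    # onset sample, 1-based
  ok <- !is.na(i0) & (i0 - nwin + 1L) >= 1L & i0 <= length(epochs@t)
  d <- epochs@data
  out <- array(0, dim = c(sum(ok), dim(d)[2], nwin))
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    out[j, , ] <- d[i, , (i0[i] - nwin + 1L):i0[i]]
  }
  relocked <- methods::new("EpochSet", data = out,
               t = window[2] + (seq_len(nwin) - nwin) / sf,
               sfreq = sf, meta = epochs@meta[ok, , drop = FALSE],
               lock = "saccade_onset", channels = epochs@channels)
  list(epochs = relocked, dropped = which(!ok))
}

#' @describeIn makeEpochs data array accessor (trials x channels x samples)
#' @param object an \code{EpochSet}
#' @export
setMethod("epochData", "EpochSet", function(object, ...) object@data)

#' @describeIn makeEpochs time-axis accessor
#' @export
setMethod("epochTimes", "EpochSet", function(object, ...) object@t)

#' @describeIn makeEpochs metadata accessor
#' @export
setMethod("epochMeta", "EpochSet", function(object, ...) object@meta)

#' @describeIn makeEpochs trial count
#' @export
setMethod("nTrials", "EpochSet", function(object, ...) dim(object@data)[1])

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples, locked to %s, %g Hz, t in [%.3f, %.3f] s\n",
              d[1], d[2], d[3], object@lock, object@sfreq,
              min(object@t), max(object@t)))
})

#' Annotate artifact trials by amplitude and z-score thresholds
#'
#' Reproducible stand-in for visual artifact inspection: a trial is flagged
#' when any sample of any channel exceeds \code{absThreshold} in absolute
#' value, or deviates from that channel's across-trial mean by more than
#' \code{zThreshold} robust standard deviations (median absolute deviation
#' scaled to the normal). An optional manual mask (logical per trial, or a
#' text file with one 0-based trial index per line) is OR-ed in.
#'
#' @param epochs an [EpochSet-class]
#' @param zThreshold robust z-score bound (default 6)
#' @param absThreshold optional absolute amplitude bound (same units as the
#'   data)
#' @param manualMask logical vector per trial, or path of a text file of
#'   0-based trial indices to reject
#' @return list: \code{keep} logical per trial, \code{log} data.frame
#'   (\code{trial}, \code{rule}) for flagged trials
#' @export
annotateArtifacts <- function(epochs, zThreshold = 6, absThreshold = NULL,
                              manualMask = NULL) {
  stopifnot(methods::is(epochs, "EpochSet"))
  d <- epochs@data
  nt <- dim(d)[1]
  center <- apply(d, c(2, 3), stats::median)   # robust across-trial centre
  # one robust scale per channel, over all trials and samples
  spread <- vapply(seq_len(dim(d)[2]), function(c)
    stats::mad(d[, c, ]), numeric(1))
  spread[spread == 0] <- max(spread, 1e-12)
  rule <- rep(NA_character_, nt)
  for (i in seq_len(nt)) {
    z <- abs(d[i, , ] - center) / spread
    if (!is.null(absThreshold) && max(abs(d[i, , ])) > absThreshold)
      rule[i] <- "amplitude"
    else if (max(z) > zThreshold) rule[i] <- "zscore"
  }
  if (!is.null(manualMask)) {
    if (is.character(manualMask)) {
      idx <- as.integer(readLines(manualMask)) + 1L
      manualMask <- seq_len(nt) %in% idx
    }
    rule[is.na(rule) & manualMask] <- "manual"
  }
  keep <- is.na(rule)
  trial <- if ("trial" %in% names(epochs@meta)) epochs@meta$trial
           else seq_len(nt)
  list(keep = keep, log = data.frame(trial = trial[!keep], rule = rule[!keep],
                                     stringsAsFactors = FALSE))
}
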