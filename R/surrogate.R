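#' Kernel density estimate of saccade latencies
#'
#' Gaussian-kernel density over the latencies of one participant and one
#' stimulus-feature combination (orientation x spatial frequency x phase; 8
#' cells). Bandwidth follows Silverman's rule with a 5 ms floor. Mass
#' outside the support is handled by rejection at sampling time, so drawn
#' onsets always lie inside the inclusive support.
#'
#' @param latencies numeric latencies (s); at least 5 required
#' @param support inclusive latency window (s), default \code{c(0.15, 0.5)}
#' @param bandwidth optional bandwidth override (s)
#' @param participant,featureKey identifier strings
#' @return a [LatencyKde-class]
#' @export
fitLatencyKde <- function(latencies, support = c(0.15, 0.5),
                          bandwidth = NULL, participant = "P01",
                          featureKey = "all") {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) < 5L)
    stop("need at least 5 latencies; pool across cells for sparse ones",
         call. = FALSE)
  if (is.null(bandwidth)) {
    sd0 <- stats::sd(latencies)
    iqr <- stats::IQR(latencies) / 1.34
    spread <- min(sd0, if (iqr > 0) iqr else sd0)
    if (!is.finite(spread) || spread == 0) spread <- 0.005
    bandwidth <- max(0.005, 0.9 * spread * length(latencies)^(-1 / 5))
  }
  methods::new("LatencyKde", latencies = latencies, bandwidth = bandwidth,
               support = support, participant = participant,
               featureKey = featureKey)
}

#' Evaluate a latency KDE
#'
#' Density truncated and renormalized to the support (the sampling-time
#' rejection is equivalent to this truncation).
#'
#' @param kde a [LatencyKde-class]
#' @param at evaluation points (s)
#' @return numeric density values
#' @export
evalLatencyKde <- function(kde, at) {
  raw <- function(x)
    rowMeans(outer(x, kde@latencies,
                   function(a, b) stats::dnorm(a, b, kde@bandwidth)))
  z <- stats::integrate(raw, kde@support[1], kde@support[2],
                        rel.tol = 1e-8)$value
  out <- raw(at) / z
  out[at < kde@support[1] | at > kde@support[2]] <- 0
  out
}

#' Fit per-feature latency KDEs for one participant
#'
#' One KDE per feature combination. Cells with fewer than 5 latencies fall
#' back to the participant's pooled latencies, with a warning.
#'
#' @param latencies numeric latencies (s)
#' @param features data.frame (same rows) with columns \code{orientation},
#'   \code{spatial_frequency}, \code{phase}
#' @param support inclusive latency window (s)
#' @param participant id string
#' @return named list of [LatencyKde-class], keys
#'   \code{"<orientation>|<sf>|<phase>"}
#' @export
fitLatencyKdes <- function(latencies, features, support = c(0.15, 0.5),
                           participant = "P01") {
  key <- featureKey(features)
  out <- list()
  sparse <- character(0)
  for (k in unique(key)) {
    lat <- latencies[key == k]
    if (sum(!is.na(lat)) < 5L) {
      sparse <- c(sparse, k)
      lat <- latencies
    }
    out[[k]] <- fitLatencyKde(lat, support = support,
                              participant = participant, featureKey = k)
  }
  if (length(sparse))
    warning("feature cell(s) with < 5 latencies use the pooled KDE: ",
            paste(sparse, collapse = ", "))
  out
}

#' Feature-combination key strings
#'
#' @param features data.frame with \code{orientation},
#'   \code{spatial_frequency}, \code{phase}
#' @return character vector of cell keys
#' @export
featureKey <- function(features) {
  sprintf("%g|%g|%g", features$orientation, features$spatial_frequency,
          round(features$phase, 6))
}

#' Sample surrogate saccade onsets
#'
#' For every Stimulus-only trial, draws \code{nDraws} surrogate saccade
#' latencies from the KDE matching the trial's stimulus features (Gaussian
#' kernel smoothing of a resampled source latency, with rejection outside
#' the support). Draw k of every trial belongs to surrogate iteration k.
#'
#' @param kdes named list from [fitLatencyKdes()] (or a single
#'   [LatencyKde-class] used for all trials)
#' @param features data.frame of trial features (one row per Stimulus-only
#'   trial), or NULL when a single KDE is given
#' @param nDraws draws per trial (default 1000)
#' @param seed integer seed; draws are deterministic given the seed
#' @return numeric matrix, trials x nDraws of latencies (s)
#' @export
sampleOnsets <- function(kdes, features = NULL, nDraws = 1000, seed = 1L) {
  if (methods::is(kdes, "LatencyKde")) {
    kl <- list(all = kdes)
    key <- rep("all", if (is.null(features)) 1L else nrow(features))
  } else {
    kl <- kdes
    key <- featureKey(features)
    miss <- setdiff(unique(key), names(kl))
    if (length(miss))
      stop("no KDE for feature cell(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  set.seed(as.integer(seed))
  nTr <- length(key)
  out <- matrix(NA_real_, nTr, nDraws)
  for (i in seq_len(nTr)) {
    kde <- kl[[key[i]]]
    need <- nDraws
    got <- numeric(0)
    while (need > 0L) {
      src <- kde@latencies[sample.int(length(kde@latencies), 2L * need + 8L,
                                      replace = TRUE)]
      x <- src + stats::rnorm(length(src), 0, kde@bandwidth)
      x <- x[x >= kde@support[1] & x <= kde@support[2]]
      got <- c(got, x)
      need <- nDraws - length(got)
    }
    out[i, ] <- got[seq_len(nDraws)]
  }
  out
}

# Shifted-window trial averaging: for stimulus-locked epochs (trials x
# channels x samples) and a trials x draws matrix of onset sample indices
# (1-based index of the t = 0-of-saccade sample), returns the average over
# trials of the [-win, 0] window for every draw: array nwin x draws x channels.
.shiftedAverage <- function(d, onsetIdx, nwin) {
  nTr <- dim(d)[1]; nC <- dim(d)[2]
  dp <- aperm(d, c(3, 1, 2))              # sample-major for the C kernel
  acc <- .shiftedAccumulate(dp, dim(dp), onsetIdx, as.integer(nwin))
  array(acc / nTr, dim = c(nwin, ncol(onsetIdx), nC))
}

#' Surrogate Stimulus-only regressors and GLM residuals
#'
#' The core surrogate engine. For every draw k, each Stimulus-only trial is
#' relocked to its k-th sampled saccade onset (window \code{[-0.6, 0]} s),
#' trials are averaged per channel, gradiometer pairs are combined and the
#' baseline subtracted -- exactly the chain applied to the real conditions.
#' The resulting surrogate Stimulus-only template enters the
#' condition-template GLM together with the fixed Saccade-only template, and
#' the per-draw residual traces are reduced to their element-wise median per
#' site.
#'
#' @param stimEpochs [EpochSet-class] of Stimulus-only trials locked to
#'   stimulus onset (must cover \code{[latency - 0.6, latency]} for every
#'   sampled latency)
#' @param onsets trials x draws latency matrix from [sampleOnsets()] (s,
#'   relative to stimulus onset)
#' @param layout a [SensorLayout-class]
#' @param y [EvokedGradient-class] of the Saccade+stimulus condition
#' @param xSaccade [EvokedGradient-class] of the Saccade-only condition
#' @param window saccade-locked window (s)
#' @param baseline baseline window (s)
#' @param seed integer recorded in the result
#' @param keepBetas retain per-draw GLM weights (sites x draws matrices)
#' @return a [SurrogateResult-class]
#' @export
surrogateResiduals <- function(stimEpochs, onsets, layout, y, xSaccade,
                               window = c(-0.6, 0), baseline = c(-0.6, -0.5),
                               seed = NA_integer_, keepBetas = FALSE) {
  stopifnot(methods::is(stimEpochs, "EpochSet"),
            methods::is(layout, "SensorLayout"))
  sf <- stimEpochs@sfreq
  nwin <- round((window[2] - window[1]) * sf) + 1L
  d <- stimEpochs@data
  if (nrow(onsets) != dim(d)[1])
    stop("one row of onsets per Stimulus-only trial required", call. = FALSE)
  onsetIdx <- round((onsets - stimEpochs@t[1]) * sf) + 1L
  if (any(onsetIdx - nwin + 1L < 1L) || any(onsetIdx > length(stimEpochs@t)))
    stop("sampled onsets fall outside the epoch coverage", call. = FALSE)

  avg <- .shiftedAverage(d, onsetIdx, nwin)          # nwin x draws x channels
  nD <- ncol(onsetIdx)
  tWin <- window[2] + (seq_len(nwin) - nwin) / sf
  bsel <- tWin >= baseline[1] & tWin < baseline[2]

  p <- layout@pairs
  chIdx <- match(c(p$ch1, p$ch2), stimEpochs@channels)
  S <- nrow(p)
  x1m <- xSaccade@values; ym <- y@values
  med <- matrix(0, S, nwin, dimnames = list(p$site, NULL))
  b1m <- b2m <- if (keepBetas) matrix(0, S, nD) else matrix(0, S, 0)
  b1med <- b2med <- r2med <- numeric(S)
  for (s in seq_len(S)) {
    g1 <- matrix(avg[, , chIdx[s]], nwin, nD)
    g2 <- matrix(avg[, , chIdx[S + s]], nwin, nD)
    X2 <- sqrt(g1^2 + g2^2)                          # nwin x draws
    X2 <- sweep(X2, 2L, colMeans(X2[bsel, , drop = FALSE]), "-")
    x1 <- x1m[s, ]; yv <- ym[s, ]
    a <- sum(x1^2)
    b <- as.vector(crossprod(X2, x1))
    cc <- colSums(X2^2)
    dd <- sum(x1 * yv)
    e <- as.vector(crossprod(X2, yv))
    det <- a * cc - b^2
    # degenerate stimulus regressor (e.g. zero template): saccade-only fit
    dg <- det <= (a * cc) * 1e-12 | !is.finite(det)
    det[dg] <- 1
    b1 <- (cc * dd - b * e) / det
    b2 <- (a * e - b * dd) / det
    b1[dg] <- if (a > 0) dd / a else 0
    b2[dg] <- 0
    resid <- (yv - outer(x1, b1)) - sweep(X2, 2L, b2, "*")  # nwin x draws
    med[s, ] <- .rowMedians(resid)
    sst <- sum((yv - mean(yv))^2)
    b1med[s] <- stats::median(b1)
    b2med[s] <- stats::median(b2)
    r2med[s] <- if (sst > 0) stats::median(1 - colSums(resid^2) / sst)
                else NA_real_
    if (keepBetas) { b1m[s, ] <- b1; b2m[s, ] <- b2 }
  }
  methods::new("SurrogateResult", median = med, nDraws = as.integer(nD),
               seed = as.integer(seed), sites = p$site, t = tWin,
               betaSaccade = b1m, betaStimulus = b2m,
               betaSaccadeMedian = b1med, betaStimulusMedian = b2med,
               r2Median = r2med)
}

#' Element-wise median of residual traces
#'
#' Reduces per-draw residual traces (draws x sites x samples array, or a
#' list of sites x samples matrices) to their element-wise median,
#' validating the draw count.
#'
#' @param residuals array draws x sites x samples, or list of matrices
#' @param nDraws expected number of draws (error if the input disagrees)
#' @param sites,t,seed metadata stored in the result
#' @return a [SurrogateResult-class]
#' @export
medianResiduals <- function(residuals, nDraws = NULL, sites = NULL, t = NULL,
                            seed = NA_integer_) {
  if (is.list(residuals))
    residuals <- aperm(simplify2array(residuals), c(3, 1, 2))
  nD <- dim(residuals)[1]
  if (!is.null(nDraws) && nD != nDraws)
    stop(sprintf("expected %d draws, got %d", nDraws, nD), call. = FALSE)
  med <- apply(residuals, c(2, 3), stats::median)
  if (is.null(sites)) sites <- sprintf("S%03d", seq_len(dim(residuals)[2]))
  if (is.null(t)) t <- seq_len(dim(residuals)[3])
  S <- dim(residuals)[2]
  methods::new("SurrogateResult", median = med, nDraws = as.integer(nD),
               seed = as.integer(seed), sites = sites, t = as.numeric(t),
               betaSaccade = matrix(0, S, 0), betaStimulus = matrix(0, S, 0),
               betaSaccadeMedian = numeric(S), betaStimulusMedian = numeric(S),
               r2Median = rep(NA_real_, S))
}

#' @describeIn surrogateResiduals median residual traces (sites x samples)
#' @param object a \code{SurrogateResult}
#' @param ... unused
#' @export
setMethod("medianResidualTraces", "SurrogateResult",
          function(object, ...) object@median)

setMethod("show", "SurrogateResult", function(object) {
  cat(sprintf("SurrogateResult: median over %d draws, %d sites x %d samples\n",
              object@nDraws, nrow(object@median), ncol(object@median)))
})
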