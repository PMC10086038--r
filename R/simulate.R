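#' Configuration for the synthetic session generator
#'
#' Bundles every parameter of [simulateSession()]. The defaults mirror the
#' study design the package emulates: three conditions with 416
#' Saccade+stimulus, 208 Saccade-only and 208 Stimulus-only trials; a 14
#' degree leftward saccade from a fixation point 7 degrees right of the
#' vertical midline; stimulus features crossing orientation (-30/+30 deg),
#' spatial frequency (0.33/1.33 cyc/deg) and phase (0/pi); saccade latencies
#' on [0.15, 0.5] s (truncated log-normal, median about 230 ms); a stimulus
#' evoking right-lateralized activity; 1000 Hz sampling for both MEG-like
#' sensors and gaze.
#'
#' @param trialsPerCondition named counts for conditions
#'   \code{saccade_stimulus}, \code{saccade_only}, \code{stimulus_only}.
#' @param sfreqMeg,sfreqEye sampling rates (Hz).
#' @param latency list: \code{meanlog}, \code{sdlog} of the log-normal latency
#'   distribution and its inclusive \code{support} (s); draws outside the
#'   support are rejected and redrawn.
#' @param saccadeAmplitude saccade size in degrees (leftward).
#' @param stimFeatures list of factor levels \code{orientation},
#'   \code{spatial_frequency}, \code{phase}.
#' @param kernels list of component kernels \code{saccade}, \code{stimulus},
#'   \code{residual} (see [saccadeComponent()]); the residual component is
#'   present only in Saccade+stimulus trials.
#' @param betaTrue length-2 numeric: scaling of the saccade and stimulus
#'   templates inside the Saccade+stimulus condition.
#' @param noise named numeric: per-channel per-sample standard deviations of
#'   the \code{white} and \code{pink} (1/f) noise components. One pink
#'   realization per channel per trial (no across-trial correlation).
#' @param preS1 length-2 interval (s) for the fixation period before stimulus
#'   onset (uniform draw per trial); \code{postS1} fixed trial time after it.
#' @param stimDuration length-2 interval (s) of stimulus presence.
#' @param gazeJitterSd fixational gaze jitter sd (deg).
#' @param microsaccadeRate expected number of injected microsaccades per
#'   Stimulus-only trial (amplitudes 0.1-0.4 deg).
#' @param photodiodeLevels named levels \code{black}, \code{grey},
#'   \code{white} of the raw photodiode trace; \code{photodiodeNoise} its
#'   additive noise sd.
#' @param layout a [SensorLayout-class]; default \code{makeLayout(102)}.
#' @param participant participant id string.
#' @param seed integer; fully determines the session.
#' @return a validated config list of class \code{"simConfig"}
#' @export
simConfig <- function(trialsPerCondition = c(saccade_stimulus = 416,
                                             saccade_only = 208,
                                             stimulus_only = 208),
                      sfreqMeg = 1000, sfreqEye = 1000,
                      latency = list(meanlog = log(0.23), sdlog = 0.25,
                                     support = c(0.15, 0.5)),
                      saccadeAmplitude = 14,
                      stimFeatures = list(orientation = c(-30, 30),
                                          spatial_frequency = c(0.33, 1.33),
                                          phase = c(0, pi)),
                      kernels = list(saccade = saccadeComponent(),
                                     stimulus = stimulusComponent(),
                                     residual = residualComponent()),
                      betaTrue = c(saccade = 1.3, stimulus = 0.7),
                      noise = c(white = 1, pink = 1),
                      preS1 = c(1.0, 1.5), postS1 = 1.6,
                      stimDuration = c(0.5, 0.7),
                      gazeJitterSd = 0.03, microsaccadeRate = 0.3,
                      photodiodeLevels = c(black = 0.1, grey = 0.5,
                                           white = 0.9),
                      photodiodeNoise = 0.005,
                      layout = NULL, participant = "P01", seed = 1L) {
  if (!all(c("saccade_stimulus", "saccade_only", "stimulus_only") %in%
           names(trialsPerCondition)))
    stop("trialsPerCondition must name all three conditions", call. = FALSE)
  if (any(trialsPerCondition < 1))
    stop("each condition needs at least one trial", call. = FALSE)
  sup <- latency$support
  if (length(sup) != 2L || sup[1] >= sup[2] || sup[1] < 0)
    stop("latency$support must be an increasing non-negative interval",
         call. = FALSE)
  if (!all(is.finite(betaTrue)) || length(betaTrue) != 2L)
    stop("betaTrue must be two finite values", call. = FALSE)
  if (any(noise < 0)) stop("noise sds must be non-negative", call. = FALSE)
  cfg <- list(trialsPerCondition = trialsPerCondition, sfreqMeg = sfreqMeg,
              sfreqEye = sfreqEye, latency = latency,
              saccadeAmplitude = saccadeAmplitude, stimFeatures = stimFeatures,
              kernels = kernels, betaTrue = betaTrue, noise = noise,
              preS1 = preS1, postS1 = postS1, stimDuration = stimDuration,
              gazeJitterSd = gazeJitterSd, microsaccadeRate = microsaccadeRate,
              photodiodeLevels = photodiodeLevels,
              photodiodeNoise = photodiodeNoise, layout = layout,
              participant = participant, seed = as.integer(seed))
  class(cfg) <- c("simConfig", "list")
  cfg
}

# Truncated log-normal latency draws (rejection sampling; never emits a value
# outside the support).
.drawLatencies <- function(n, latency) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 8L,
                       latency$meanlog, latency$sdlog)
    out <- c(out, x[x >= latency$support[1] & x <= latency$support[2]])
  }
  out[seq_len(n)]
}

# Minimum-jerk displacement profile on [0, 1].
.minJerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Main-sequence saccade duration (s): ~2.2 ms/deg + 21 ms.
.saccadeDuration <- function(amplitude) 0.0022 * amplitude + 0.021

#' Simulate one MEG + gaze + photodiode session
#'
#' Generates a continuous synthetic session with known ground truth. Per
#' trial, every site's scheduled component amplitude A(t) (a weighted sum of
#' the configured kernels) is split over the site's gradiometer pair as
#' (A cos(theta), A sin(theta)) with a fixed per-site angle theta, so the
#' root-sum-of-squares of the pair recovers A(t) exactly when the noise sd is
#' zero. Saccade trials carry a leftward saccade (minimum-jerk gaze profile,
#' main-sequence duration) at the drawn latency; Stimulus-only trials contain
#' no saccade and keep gaze jitter well below 0.5 degrees. The photodiode
#' steps from grey to white at stimulus onset on stimulus trials and to black
#' at the end of every trial.
#'
#' @param cfg a [simConfig()]
#' @return a [SimSession-class]
#' @examples
#' cfg <- simConfig(trialsPerCondition = c(saccade_stimulus = 4,
#'                                         saccade_only = 2,
#'                                         stimulus_only = 2),
#'                  layout = makeLayout(4), sfreqMeg = 250, sfreqEye = 250,
#'                  preS1 = c(0.6, 0.6), postS1 = 0.7, seed = 7)
#' ses <- simulateSession(cfg)
#' head(eventTable(ses))
#' @export
simulateSession <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  layout <- cfg$layout
  if (is.null(layout)) layout <- makeLayout(102L, seed = cfg$seed)
  S <- nSites(layout)
  sf <- cfg$sfreqMeg

  # trial schedule -----------------------------------------------------------
  counts <- cfg$trialsPerCondition
  cond <- sample(rep(names(counts), counts))
  n <- length(cond)
  # stimulus onsets are locked to the acquisition grid (display refresh and
  # online event timing are sample-quantized in the emulated setup)
  preS1 <- round(stats::runif(n, cfg$preS1[1], cfg$preS1[2]) * sf) / sf
  stimDur <- stats::runif(n, cfg$stimDuration[1], cfg$stimDuration[2])
  trialDur <- round((preS1 + cfg$postS1) * sf) / sf
  trialStart <- c(0, cumsum(trialDur))[seq_len(n)]
  s1Time <- trialStart + preS1
  hasSacc <- cond %in% c("saccade_stimulus", "saccade_only")
  hasStim <- cond %in% c("saccade_stimulus", "stimulus_only")
  latency <- rep(NA_real_, n)
  # latencies quantized to the eye-tracker sample grid, as a sample-based
  # detector would report them
  latency[hasSacc] <- round(.drawLatencies(sum(hasSacc), cfg$latency) *
                              cfg$sfreqEye) / cfg$sfreqEye
  saccOnset <- ifelse(hasSacc, s1Time + latency, NA_real_)
  saccDur <- .saccadeDuration(cfg$saccadeAmplitude)
  saccOffset <- saccOnset + saccDur

  # balanced stimulus features for stimulus-bearing trials
  fg <- expand.grid(orientation = cfg$stimFeatures$orientation,
                    spatial_frequency = cfg$stimFeatures$spatial_frequency,
                    phase = cfg$stimFeatures$phase)
  feat <- data.frame(orientation = rep(NA_real_, n),
                     spatial_frequency = NA_real_, phase = NA_real_)
  for (cc in c("saccade_stimulus", "stimulus_only")) {
    idx <- which(cond == cc)
    rows <- sample(rep(seq_len(nrow(fg)), length.out = length(idx)))
    feat[idx, ] <- fg[rows, ]
  }

  # component truth ----------------------------------------------------------
  ker <- cfg$kernels
  w <- lapply(ker, .kernelWeights, layout = layout)
  theta <- stats::runif(S, 0, 2 * pi)
  scale <- cbind(
    saccade = ifelse(cond == "saccade_stimulus", cfg$betaTrue[1],
                     ifelse(cond == "saccade_only", 1, 0)),
    stimulus = ifelse(cond == "saccade_stimulus", cfg$betaTrue[2],
                      ifelse(cond == "stimulus_only", 1, 0)),
    residual = ifelse(cond == "saccade_stimulus", 1, 0))

  # MEG assembly --------------------------------------------------------------
  nsamp <- round(sum(trialDur) * sf)
  C <- 2L * S
  meg <- matrix(0, C, nsamp)
  pairIdx1 <- seq(1L, C, by = 2L)
  pairIdx2 <- pairIdx1 + 1L
  cosT <- cos(theta); sinT <- sin(theta)
  pd <- rep(cfg$photodiodeLevels["grey"], nsamp)
  for (i in seq_len(n)) {
    i0 <- round(trialStart[i] * sf) + 1L
    nt <- round(trialDur[i] * sf)
    idx <- i0:(i0 + nt - 1L)
    tt <- (seq_len(nt) - 1L) / sf - preS1[i]      # time rel. stimulus onset
    A <- matrix(0, S, nt)
    if (scale[i, "saccade"] > 0) {
      k <- ker$saccade$amplitude * ker$saccade$time(tt - latency[i])
      A <- A + scale[i, "saccade"] * tcrossprod(w$saccade, k)
    }
    if (scale[i, "stimulus"] > 0) {
      k <- ker$stimulus$amplitude * ker$stimulus$time(tt)
      A <- A + scale[i, "stimulus"] * tcrossprod(w$stimulus, k)
    }
    if (scale[i, "residual"] > 0 && ker$residual$amplitude != 0) {
      k <- ker$residual$amplitude * ker$residual$time(tt - latency[i])
      A <- A + scale[i, "residual"] * tcrossprod(w$residual, k)
    }
    sig <- matrix(0, C, nt)
    sig[pairIdx1, ] <- A * cosT
    sig[pairIdx2, ] <- A * sinT
    meg[, idx] <- sig
    # photodiode: grey fixation, white during the stimulus (stimulus trials),
    # black in the final 100 ms of every trial
    if (hasStim[i]) {
      srel <- tt >= 0 & tt < stimDur[i]
      pd[idx[srel]] <- cfg$photodiodeLevels["white"]
    }
    black <- seq.int(nt - round(0.1 * sf) + 1L, nt)
    pd[idx[black]] <- cfg$photodiodeLevels["black"]
  }
  if (cfg$noise["white"] > 0)
    meg <- meg + cfg$noise["white"] * matrix(stats::rnorm(C * nsamp), C, nsamp)
  if (cfg$noise["pink"] > 0) {
    # one independent pink realization per channel per trial; trials grouped
    # by equal length so the spectral shaping is batched
    lens <- round(trialDur * sf)
    for (L in unique(lens)) {
      tr <- which(lens == L)
      pk <- .pinkNoise(L, C * length(tr))
      for (k in seq_along(tr)) {
        i0 <- round(trialStart[tr[k]] * sf) + 1L
        cols <- ((k - 1L) * C + 1L):(k * C)
        meg[, i0:(i0 + L - 1L)] <- meg[, i0:(i0 + L - 1L)] +
          cfg$noise["pink"] * t(pk[, cols, drop = FALSE])
      }
    }
  }
  if (cfg$photodiodeNoise > 0)
    pd <- pd + stats::rnorm(nsamp, 0, cfg$photodiodeNoise)
  channels <- as.vector(t(as.matrix(layout@pairs[, c("ch1", "ch2")])))
  rownames(meg) <- channels

  # gaze ----------------------------------------------------------------------
  gf <- cfg$sfreqEye
  ng <- round(sum(trialDur) * gf)
  gt <- (seq_len(ng) - 1L) / gf
  gx <- rep(7, ng) + stats::rnorm(ng, 0, cfg$gazeJitterSd)
  gy <- stats::rnorm(ng, 0, cfg$gazeJitterSd)
  amp <- cfg$saccadeAmplitude
  for (i in seq_len(n)) {
    tEnd <- trialStart[i] + trialDur[i]
    if (hasSacc[i]) {
      gx <- .addStep(gx, gt, saccOnset[i], saccDur, -amp)
      # re-fixation saccade during the inter-trial blanking period
      gx <- .addStep(gx, gt, tEnd - 0.09, saccDur, amp)
    } else if (cfg$microsaccadeRate > 0) {
      nms <- stats::rpois(1L, cfg$microsaccadeRate)
      if (nms > 0) {
        for (k in seq_len(nms)) {
          a <- stats::runif(1, 0.1, 0.4)
          ang <- stats::runif(1, 0, 2 * pi)
          t0 <- stats::runif(1, trialStart[i] + 0.05, tEnd - 0.2)
          d <- .saccadeDuration(a)
          gx <- .addStep(gx, gt, t0, d, a * cos(ang))
          gx <- .addStep(gx, gt, t0 + 3 * d, d, -a * cos(ang))
          gy <- .addStep(gy, gt, t0, d, a * sin(ang))
          gy <- .addStep(gy, gt, t0 + 3 * d, d, -a * sin(ang))
        }
      }
    }
  }
  gaze <- methods::new("GazeRecording", t = gt, x = gx, y = gy, sfreq = gf,
                       valid = rep(TRUE, ng),
                       unitsMeta = list(units = "deg"))

  events <- data.frame(trial = seq_len(n), condition = cond,
                       trial_start = trialStart, trial_end = trialStart + trialDur,
                       s1_time = s1Time, stim_duration = stimDur,
                       saccade_onset = saccOnset, saccade_offset = saccOffset,
                       latency = latency, feat,
                       stringsAsFactors = FALSE)
  truth <- list(weights = w, theta = theta, betaTrue = cfg$betaTrue,
                kernels = ker, componentScale = scale,
                residualAmplitude = ker$residual$amplitude)
  methods::new("SimSession", meg = meg, sfreq = sf, channels = channels,
               gaze = gaze, photodiode = as.numeric(pd), events = events,
               truth = truth, layout = layout, config = unclass(cfg))
}

# Add a smoothed position step (minimum-jerk displacement of size `delta`
# starting at t0, duration dur) to g in place; t must be uniform from 0.
.addStep <- function(g, t, t0, dur, delta) {
  sf <- 1 / (t[2] - t[1])
  n <- length(g)
  i1 <- max(1L, floor(t0 * sf) + 1L)
  i2 <- min(n, ceiling((t0 + dur) * sf) + 1L)
  if (i1 > n) return(g)
  g[i1:i2] <- g[i1:i2] + delta * .minJerk((t[i1:i2] - t0) / dur)
  if (i2 < n) g[(i2 + 1L):n] <- g[(i2 + 1L):n] + delta
  g
}

#' Ground-truth event table of a simulated session
#'
#' One row per trial with the true saccade onset, latency and stimulus
#' features; Stimulus-only rows carry \code{NA} saccade times.
#'
#' @param session a [SimSession-class]
#' @return data.frame
#' @export
groundTruthTable <- function(session) {
  stopifnot(methods::is(session, "SimSession"))
  session@events[, c("trial", "condition", "s1_time", "saccade_onset",
                     "saccade_offset", "latency", "orientation",
                     "spatial_frequency", "phase")]
}

#' @describeIn simulateSession event-table accessor
#' @param object a \code{SimSession}
#' @export
setMethod("eventTable", "SimSession", function(object, ...) object@events)

setMethod("show", "SimSession", function(object) {
  ev <- object@events
  cat(sprintf("SimSession '%s': %d trials (%s), %d channels, %.1f s at %g Hz\n",
              object@config$participant, nrow(ev),
              paste(sprintf("%s=%d", names(table(ev$condition)),
                            as.integer(table(ev$condition))), collapse = ", "),
              nrow(object@meg), ncol(object@meg) / object@sfreq,
              object@sfreq))
})
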