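#' Simulate a cohort and compute surrogate median residuals
#'
#' Reduced experiment harness for validation studies: for each simulated
#' participant, generates a session, epochs it around stimulus onset,
#' relocks the saccade conditions to the ground-truth saccade onsets,
#' computes the evoked combined planar gradients, fits per-feature latency
#' KDEs, samples surrogate onsets for the Stimulus-only trials and returns
#' every participant's median residual traces. Compared with
#' [runPipeline()], this harness skips saccade detection (truth onsets are
#' used directly; detector accuracy is validated separately) and line-noise
#' filtering (the generator injects none), which makes cohort-level
#' resampling studies practical.
#'
#' @param nParticipants cohort size
#' @param layout a [SensorLayout-class]
#' @param trialsPerCondition named trial counts (see [simConfig()])
#' @param residualAmplitude peak amplitude of the injected residual
#'   component (0 = null cohort)
#' @param residualLateralization \code{"bilateral"}, \code{"left"} or
#'   \code{"right"}
#' @param noise named white/pink noise sds (see [simConfig()])
#' @param nDraws surrogate draws per Stimulus-only trial
#' @param seed master integer seed
#' @param sfreq sampling rate for MEG and gaze (Hz)
#' @param stimulusLateralization lateralization of the stimulus component
#' @return list: \code{residuals} (participants x sites x samples array of
#'   median residual traces), \code{t} (time axis, s), \code{layout},
#'   \code{betaSaccade}, \code{betaStimulus}, \code{r2} (participants x
#'   sites matrices of per-draw medians), \code{residualTruth} (sites x
#'   samples matrix of the injected residual component, same units)
#' @export
runCohort <- function(nParticipants = 20L, layout = makeLayout(12L, seed = 1L),
                      trialsPerCondition = c(saccade_stimulus = 40,
                                             saccade_only = 20,
                                             stimulus_only = 20),
                      residualAmplitude = 0, residualLateralization = "bilateral",
                      noise = c(white = 1, pink = 1), nDraws = 200L,
                      seed = 1L, sfreq = 500,
                      stimulusLateralization = "right") {
  S <- nSites(layout)
  ker <- list(saccade = saccadeComponent(),
              stimulus = stimulusComponent(
                lateralization = stimulusLateralization),
              residual = residualComponent(
                amplitude = residualAmplitude,
                lateralization = residualLateralization))
  epochWindow <- c(-0.46, 0.51)
  glmWindow <- c(-0.6, 0)
  nT <- round(diff(glmWindow) * sfreq) + 1L
  residuals <- array(0, dim = c(nParticipants, S, nT))
  b1 <- b2 <- r2 <- matrix(0, nParticipants, S)
  tAxis <- NULL
  for (p in seq_len(nParticipants)) {
    scfg <- simConfig(trialsPerCondition = trialsPerCondition,
                      sfreqMeg = sfreq, sfreqEye = sfreq,
                      preS1 = c(0.5, 0.5), postS1 = 0.55,
                      noise = noise, kernels = ker, layout = layout,
                      microsaccadeRate = 0,
                      participant = sprintf("P%02d", p),
                      seed = .childSeed(seed, p))
    ses <- simulateSession(scfg)
    ev <- ses@events
    epochs <- makeEpochs(ses@meg, sfreq, ev$s1_time, epochWindow,
                         meta = ev, channels = ses@channels)
    meta <- epochMeta(epochs)
    sub <- function(rows) {
      e <- epochs
      e@data <- e@data[rows, , , drop = FALSE]
      e@meta <- meta[rows, , drop = FALSE]
      e
    }
    rSS <- which(meta$condition == "saccade_stimulus")
    rSO <- which(meta$condition == "saccade_only")
    rST <- which(meta$condition == "stimulus_only")
    yEv <- evokedGradient(
      relockToSaccade(sub(rSS), meta$latency[rSS], glmWindow)$epochs,
      layout, condition = "saccade_stimulus",
      participant = scfg$participant)
    xsEv <- evokedGradient(
      relockToSaccade(sub(rSO), meta$latency[rSO], glmWindow)$epochs,
      layout, condition = "saccade_only", participant = scfg$participant)
    kdes <- fitLatencyKdes(meta$latency[rSS],
                           meta[rSS, c("orientation", "spatial_frequency",
                                       "phase")],
                           participant = scfg$participant)
    onsets <- sampleOnsets(kdes,
                           meta[rST, c("orientation", "spatial_frequency",
                                       "phase")],
                           nDraws = nDraws, seed = .childSeed(seed, 5000L + p))
    sres <- surrogateResiduals(sub(rST), onsets, layout, yEv, xsEv,
                               window = glmWindow,
                               seed = .childSeed(seed, 5000L + p))
    residuals[p, , ] <- medianResidualTraces(sres)
    b1[p, ] <- sres@betaSaccadeMedian
    b2[p, ] <- sres@betaStimulusMedian
    r2[p, ] <- sres@r2Median
    if (is.null(tAxis)) tAxis <- sres@t
  }
  wres <- .kernelWeights(ker$residual, layout)
  truth <- residualAmplitude * tcrossprod(wres, ker$residual$time(tAxis))
  list(residuals = residuals, t = tAxis, layout = layout,
       betaSaccade = b1, betaStimulus = b2, r2 = r2,
       residualTruth = truth)
}
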