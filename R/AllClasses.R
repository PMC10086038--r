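#' @import methods
NULL

#' Sensor layout of combined planar-gradiometer sites
#'
#' Describes the helmet-plane geometry of a set of gradiometer sites. Each
#' site carries exactly two orthogonal planar gradiometer channels; the
#' root-sum-of-squares of the pair yields the combined planar gradient.
#' Hemisphere labels follow the sign of the helmet-plane x coordinate
#' (left: x < 0, right: x > 0, midline: x == 0).
#'
#' @slot sites data.frame with columns \code{site}, \code{x}, \code{y},
#'   \code{hemisphere} (\code{"left"}, \code{"right"} or \code{"midline"}) and
#'   \code{region} (free-form grouping label, e.g. \code{"occipital"}).
#' @slot pairs data.frame with columns \code{site}, \code{ch1}, \code{ch2}
#'   naming the two gradiometer channels of every site.
#' @slot neighborRadius numeric scalar; sites closer than this (layout units)
#'   are spatial neighbours for cluster statistics.
#'
#' @seealso [makeLayout()], [adjacencyFromLayout()]
#' @export
setClass("SensorLayout",
  slots = c(sites = "data.frame", pairs = "data.frame",
            neighborRadius = "numeric"))

setValidity("SensorLayout", function(object) {
  s <- object@sites
  p <- object@pairs
  msg <- character()
  need <- c("site", "x", "y", "hemisphere")
  if (!all(need %in% names(s)))
    msg <- c(msg, "sites must have columns site, x, y, hemisphere")
  if (!all(c("site", "ch1", "ch2") %in% names(p)))
    msg <- c(msg, "pairs must have columns site, ch1, ch2")
  if (length(msg) == 0L) {
    if (!identical(sort(as.character(s$site)), sort(as.character(p$site))))
      msg <- c(msg, "every site needs exactly one gradiometer pair")
    hemi <- ifelse(s$x < 0, "left", ifelse(s$x > 0, "right", "midline"))
    if (!all(s$hemisphere == hemi))
      msg <- c(msg, "hemisphere labels must follow sign(x)")
    ch <- c(p$ch1, p$ch2)
    if (anyDuplicated(ch))
      msg <- c(msg, "gradiometer channel ids must be unique")
  }
  if (length(object@neighborRadius) != 1L || object@neighborRadius <= 0)
    msg <- c(msg, "neighborRadius must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Calibrated gaze recording
#'
#' A uniformly sampled eye-position time series in degrees of visual angle.
#'
#' @slot t numeric, sample times in seconds (strictly increasing, constant
#'   step).
#' @slot x,y numeric, gaze position in degrees of visual angle.
#' @slot sfreq numeric scalar, sampling rate in Hz.
#' @slot valid logical, per-sample validity flag (FALSE during blinks/dropouts).
#' @slot unitsMeta list of calibration metadata (pixel-to-degree mapping,
#'   screen geometry).
#'
#' @export
setClass("GazeRecording",
  slots = c(t = "numeric", x = "numeric", y = "numeric", sfreq = "numeric",
            valid = "logical", unitsMeta = "list"))

setValidity("GazeRecording", function(object) {
  n <- length(object@t)
  msg <- character()
  if (length(object@x) != n || length(object@y) != n ||
      length(object@valid) != n)
    msg <- c(msg, "t, x, y, valid must have equal length")
  if (n > 1L) {
    dt <- diff(object@t)
    if (any(dt <= 0)) msg <- c(msg, "t must be strictly increasing")
    if (diff(range(dt)) > 1e-6) msg <- c(msg, "t must have a constant step")
  }
  if (any(!is.finite(object@x[object@valid])) ||
      any(!is.finite(object@y[object@valid])))
    msg <- c(msg, "x and y must be finite where valid")
  if (length(msg)) msg else TRUE
})

#' Detected saccade events
#'
#' Container for the output of [detectSaccades()]: one row per event with
#' onset/offset times and indices (0-based, half-open \code{[onset, offset)}),
#' amplitude (Euclidean start-to-end distance in degrees), peak velocity and
#' endpoints.
#'
#' @slot events data.frame with columns \code{onset_t}, \code{offset_t},
#'   \code{onset_idx}, \code{offset_idx}, \code{amplitude}, \code{peak_velocity},
#'   \code{start_x}, \code{start_y}, \code{end_x}, \code{end_y}.
#' @slot params list, detector parameters used (see [detectorParams()]).
#' @export
setClass("SaccadeEvents",
  slots = c(events = "data.frame", params = "list"))

setValidity("SaccadeEvents", function(object) {
  e <- object@events
  need <- c("onset_t", "offset_t", "onset_idx", "offset_idx",
            "amplitude", "peak_velocity")
  if (!all(need %in% names(e)))
    return("events must have onset/offset times and indices, amplitude, peak_velocity")
  if (nrow(e) && any(e$offset_t <= e$onset_t))
    return("offset_t must exceed onset_t")
  if (nrow(e) && any(e$amplitude < 0))
    return("amplitude must be non-negative")
  TRUE
})

#' Simulated recording session
#'
#' One synthetic participant session: continuous MEG-like gradiometer
#' recordings, gaze, a photodiode channel, the event table and the full
#' generative ground truth.
#'
#' @slot meg numeric matrix, channels x samples; row names are channel ids.
#' @slot sfreq numeric scalar, MEG sampling rate (Hz).
#' @slot channels character, channel ids in row order of \code{meg}.
#' @slot gaze [GazeRecording-class] at the eye-tracker rate.
#' @slot photodiode numeric, raw photodiode trace at the MEG rate.
#' @slot events data.frame, one row per trial (condition, stimulus onset,
#'   true saccade onset/offset/latency, stimulus features).
#' @slot truth list with the generating kernels, spatial weights, pair-split
#'   angles and per-trial component amplitudes.
#' @slot layout [SensorLayout-class] used for the simulation.
#' @slot config list, the [simConfig()] the session was generated from.
#' @export
setClass("SimSession",
  slots = c(meg = "matrix", sfreq = "numeric", channels = "character",
            gaze = "GazeRecording", photodiode = "numeric",
            events = "data.frame", truth = "list", layout = "SensorLayout",
            config = "list"))

#' Epoched sensor data
#'
#' Trials x channels x time array locked to a named event, with per-trial
#' metadata. All trials share the same time axis.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot t numeric, time in seconds relative to the lock event.
#' @slot sfreq numeric scalar, sampling rate (Hz).
#' @slot meta data.frame, one row per trial (condition, stimulus features,
#'   saccade latency, inclusion flags).
#' @slot lock character, \code{"stimulus_onset"} or \code{"saccade_onset"}.
#' @slot channels character, channel ids (second dimension of \code{data}).
#' @export
setClass("EpochSet",
  slots = c(data = "array", t = "numeric", sfreq = "numeric",
            meta = "data.frame", lock = "character", channels = "character"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x samples")
  else {
    if (d[3] != length(object@t)) msg <- c(msg, "time axis length mismatch")
    if (d[2] != length(object@channels)) msg <- c(msg, "channel count mismatch")
    if (d[1] != nrow(object@meta)) msg <- c(msg, "meta rows must equal trials")
  }
  if (length(object@t) > 1L &&
      diff(range(diff(object@t))) > 1e-6)
    msg <- c(msg, "t must be uniform")
  if (length(msg)) msg else TRUE
})

#' Evoked combined planar gradient
#'
#' Per-site combined planar gradient time course: trials averaged per
#' gradiometer channel, pairs combined by root-sum-of-squares, baseline
#' corrected. Values are non-negative after combination (before baseline
#' subtraction).
#'
#' @slot values numeric matrix, sites x samples.
#' @slot t numeric, time in seconds relative to the lock event.
#' @slot sfreq numeric scalar.
#' @slot baselineWindow numeric length-2, baseline window in seconds
#'   (half-open \code{[b1, b2)}).
#' @slot condition character, condition label.
#' @slot participant character, participant id.
#' @slot sites character, site ids (row order of \code{values}).
#' @export
setClass("EvokedGradient",
  slots = c(values = "matrix", t = "numeric", sfreq = "numeric",
            baselineWindow = "numeric", condition = "character",
            participant = "character", sites = "character"))

setValidity("EvokedGradient", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@sites))
    msg <- c(msg, "values rows must match sites")
  if (ncol(object@values) != length(object@t))
    msg <- c(msg, "values columns must match t")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Condition-template GLM fit for one participant
#'
#' Per-site ordinary least-squares fit of the Saccade+stimulus evoked
#' gradient onto the Saccade-only and Stimulus-only condition templates:
#' Y = beta_saccade * X_saccade + beta_stimulus * X_stimulus + residual.
#'
#' @slot betaSaccade,betaStimulus numeric, one weight per site.
#' @slot r2 numeric, proportion of variance explained per site
#'   (1 - SS_res/SS_tot with SS_tot about the mean of Y).
#' @slot residuals numeric matrix, sites x samples, Y - Yhat.
#' @slot fitted numeric matrix, sites x samples, Yhat.
#' @slot sites character site ids; @slot t numeric time axis.
#' @slot participant character participant id.
#' @export
setClass("GlmResult",
  slots = c(betaSaccade = "numeric", betaStimulus = "numeric", r2 = "numeric",
            residuals = "matrix", fitted = "matrix", sites = "character",
            t = "numeric", participant = "character"))

setValidity("GlmResult", function(object) {
  n <- length(object@sites)
  msg <- character()
  if (length(object@betaSaccade) != n || length(object@betaStimulus) != n ||
      length(object@r2) != n)
    msg <- c(msg, "betas and r2 must have one value per site")
  if (nrow(object@residuals) != n || ncol(object@residuals) != length(object@t))
    msg <- c(msg, "residuals must be sites x samples")
  if (length(msg)) msg else TRUE
})

#' Latency kernel-density estimate
#'
#' Gaussian kernel density over saccade latencies for one participant and one
#' stimulus-feature combination, truncated to the latency inclusion window by
#' rejection at sampling time.
#'
#' @slot latencies numeric, source latencies (s).
#' @slot bandwidth numeric scalar, Gaussian kernel bandwidth (s).
#' @slot support numeric length-2, inclusive latency support (s).
#' @slot participant,featureKey character identifiers.
#' @export
setClass("LatencyKde",
  slots = c(latencies = "numeric", bandwidth = "numeric", support = "numeric",
            participant = "character", featureKey = "character"))

setValidity("LatencyKde", function(object) {
  msg <- character()
  if (length(object@support) != 2L || diff(object@support) <= 0)
    msg <- c(msg, "support must be an increasing length-2 interval")
  if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Surrogate-resampling result
#'
#' Element-wise median over the per-draw GLM residual traces obtained by
#' relocking Stimulus-only trials to sampled surrogate saccade onsets.
#'
#' @slot median numeric matrix, sites x samples: element-wise median residual.
#' @slot nDraws integer, number of surrogate draws the median is taken over.
#' @slot seed integer seed that produced the draws.
#' @slot sites character; @slot t numeric time axis.
#' @slot betaSaccade,betaStimulus numeric matrix (sites x draws) of per-draw
#'   GLM weights (may be 0-column when not retained).
#' @slot betaSaccadeMedian,betaStimulusMedian,r2Median numeric, per-site
#'   medians over draws of the GLM weights and variance explained.
#' @export
setClass("SurrogateResult",
  slots = c(median = "matrix", nDraws = "integer", seed = "integer",
            sites = "character", t = "numeric",
            betaSaccade = "matrix", betaStimulus = "matrix",
            betaSaccadeMedian = "numeric", betaStimulusMedian = "numeric",
            r2Median = "numeric"))

#' Spatiotemporal cluster statistics
#'
#' Output of the one-sample cluster-permutation test: suprathreshold
#' (site, sample) points grouped into spatiotemporally connected clusters,
#' with max-cluster-mass permutation p-values.
#'
#' @slot clusters data.frame: \code{cluster}, \code{sign}, \code{mass}
#'   (summed t), \code{n_points}, \code{p}.
#' @slot members list of integer matrices (site index, sample index) per
#'   cluster.
#' @slot sigMask logical matrix sites x samples: membership in a cluster with
#'   p <= alpha.
#' @slot tmap numeric matrix sites x samples of one-sample t values.
#' @slot alpha numeric; @slot nPerm integer; @slot seed integer.
#' @slot t numeric time axis; @slot sites character; @slot sfreq numeric.
#' @export
setClass("ClusterStats",
  slots = c(clusters = "data.frame", members = "list", sigMask = "matrix",
            tmap = "matrix", alpha = "numeric", nPerm = "integer",
            seed = "integer", t = "numeric", sites = "character",
            sfreq = "numeric"))

setValidity("ClusterStats", function(object) {
  msg <- character()
  if (nrow(object@clusters) != length(object@members))
    msg <- c(msg, "one member set per cluster row")
  if (nrow(object@clusters) &&
      (any(object@clusters$p < 0) || any(object@clusters$p > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
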