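# Component kernels for the session generator.
#
# A component kernel is a list with
#   time:  function(t) -> non-negative amplitude envelope (peak scaled to 1),
#          t in seconds relative to the component's lock event
#   lock:  "saccade" or "stimulus"
#   lateralization: "bilateral", "left" or "right"
#   amplitude: peak amplitude in sensor units
#   spatialFun: function(sites data.frame) -> per-site weight in [0, 1]
#
# Envelopes are non-negative by construction: the combined planar gradient is
# a magnitude, and the generator's pair-split identity (root-sum-of-squares of
# the gradiometer pair recovers the scheduled amplitude) requires component
# amplitudes that do not change sign.

#' Default component kernels of the session generator
#'
#' \code{saccadeComponent()}: gamma-shaped envelope rising shortly before and
#' peaking 30 ms after saccade onset, broad bilateral central topography.
#' \code{stimulusComponent()}: gamma envelope peaking 120 ms after stimulus
#' onset; with \code{lateralization = "right"} (default, matching a
#' left-hemifield stimulus) its spatial weights are exactly zero on
#' left-hemisphere sites. \code{residualComponent()}: half-Hanning ramp that
#' starts 112 ms before saccade onset and peaks at saccade onset, bilateral
#' occipital topography; amplitude 0 by default (no injected effect).
#'
#' @param amplitude peak amplitude in sensor units
#' @param lateralization \code{"bilateral"}, \code{"left"} or \code{"right"}
#' @param rampStart time (s, negative = before saccade onset) at which the
#'   residual ramp leaves zero
#' @return a component-kernel list (see source for the contract)
#' @export
saccadeComponent <- function(amplitude = 5) {
  tf <- function(t) {
    z <- stats::dgamma(t + 0.05, shape = 2, rate = 12.5)
    z / stats::dgamma(0.08, shape = 2, rate = 12.5)
  }
  list(time = tf, lock = "saccade", lateralization = "bilateral",
       amplitude = amplitude,
       spatialFun = function(s) exp(-((s$x)^2 + (s$y - 0.2)^2) / (2 * 0.55^2)))
}

#' @rdname saccadeComponent
#' @export
stimulusComponent <- function(amplitude = 3, lateralization = "right") {
  tf <- function(t) {
    z <- stats::dgamma(t, shape = 3, rate = 50 / 3)
    z / stats::dgamma(0.12, shape = 3, rate = 50 / 3)
  }
  sf <- function(s) {
    w <- exp(-((abs(s$x) - 0.5)^2 + (s$y + 0.5)^2) / (2 * 0.4^2))
    if (lateralization == "right") w[s$x < 0] <- 0
    if (lateralization == "left") w[s$x > 0] <- 0
    w
  }
  list(time = tf, lock = "stimulus", lateralization = lateralization,
       amplitude = amplitude, spatialFun = sf)
}

#' @rdname saccadeComponent
#' @export
residualComponent <- function(amplitude = 0, rampStart = -0.112,
                              lateralization = "bilateral") {
  tf <- function(t) {
    z <- numeric(length(t))
    rising <- t >= rampStart & t <= 0
    z[rising] <- 0.5 * (1 - cos(pi * (t[rising] - rampStart) / (-rampStart)))
    z[t > 0] <- exp(-t[t > 0] / 0.02)   # rapid decay after onset
    z
  }
  sf <- function(s) {
    w <- exp(-((abs(s$x) - 0.45)^2 + (s$y + 0.5)^2) / (2 * 0.45^2))
    if (lateralization == "right") w[s$x < 0] <- 0
    if (lateralization == "left") w[s$x > 0] <- 0
    w
  }
  list(time = tf, lock = "saccade", lateralization = lateralization,
       amplitude = amplitude, spatialFun = sf)
}

# Evaluate a kernel's spatial weights on a layout.
.kernelWeights <- function(kernel, layout) {
  w <- kernel$spatialFun(layout@sites)
  w[!is.finite(w)] <- 0
  w
}
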