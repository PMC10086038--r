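#' Average epochs per channel
#'
#' Arithmetic mean over trials for every channel and sample. Averaging is
#' performed on the raw gradiometer channels, before pair combination
#' (average-then-combine).
#'
#' @param epochs an [EpochSet-class] with at least one trial
#' @return numeric matrix, channels x samples (rownames = channel ids)
#' @export
averageEvoked <- function(epochs) {
  stopifnot(methods::is(epochs, "EpochSet"))
  d <- epochs@data
  if (dim(d)[1] < 1L) stop("no trials to average", call. = FALSE)
  out <- colMeans(d)                      # mean over the trial dimension
  rownames(out) <- epochs@channels
  out
}

#' Combine averaged planar-gradiometer pairs
#'
#' Root-sum-of-squares of the two orthogonal gradiometers of each site:
#' \code{sqrt(g1^2 + g2^2)} per site and sample. The output is non-negative
#' and invariant under sign flips of either pair member.
#'
#' @param avg numeric matrix, channels x samples with rownames matching the
#'   layout's channel ids
#' @param layout a [SensorLayout-class]
#' @return numeric matrix, sites x samples (rownames = site ids)
#' @export
combinePlanar <- function(avg, layout) {
  stopifnot(methods::is(layout, "SensorLayout"))
  p <- layout@pairs
  miss <- !(c(p$ch1, p$ch2) %in% rownames(avg))
  if (any(miss)) {
    bad <- unique(p$site[matrix(miss, ncol = 2)[, 1] |
                         matrix(miss, ncol = 2)[, 2]])
    stop("missing gradiometer channel(s) for site(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sqrt(avg[p$ch1, , drop = FALSE]^2 + avg[p$ch2, , drop = FALSE]^2)
  rownames(out) <- p$site
  out
}

#' Baseline-correct combined planar gradients
#'
#' Subtracts, per site, the mean over the baseline window (half-open
#' \code{[window[1], window[2])}) from the entire trace.
#'
#' @param values numeric matrix, sites x samples
#' @param t time axis (s) matching the columns of \code{values}
#' @param window baseline window (s), default \code{c(-0.6, -0.5)}
#' @param sfreq sampling rate (Hz)
#' @param condition,participant labels stored in the result
#' @return an [EvokedGradient-class]
#' @export
baselineCorrect <- function(values, t, window = c(-0.6, -0.5), sfreq = NULL,
                            condition = "unknown", participant = "unknown") {
  sel <- t >= window[1] & t < window[2]
  if (!any(sel))
    stop("baseline window lies outside the epoch time axis", call. = FALSE)
  if (is.null(sfreq)) sfreq <- 1 / stats::median(diff(t))
  base <- rowMeans(values[, sel, drop = FALSE])
  methods::new("EvokedGradient", values = values - base, t = t, sfreq = sfreq,
               baselineWindow = window, condition = condition,
               participant = participant,
               sites = if (is.null(rownames(values)))
                 sprintf("S%03d", seq_len(nrow(values))) else rownames(values))
}

#' Saccade-locked evoked combined planar gradient
#'
#' The canonical evoked chain applied in fixed order with no temporal
#' filtering at any point: average over trials per gradiometer channel, then
#' combine each site's pair by root-sum-of-squares, then subtract the mean of
#' the baseline window.
#'
#' @param epochs a saccade-locked [EpochSet-class]
#' @param layout a [SensorLayout-class]
#' @param baseline baseline window (s)
#' @param condition,participant labels
#' @return an [EvokedGradient-class]
#' @export
evokedGradient <- function(epochs, layout, baseline = c(-0.6, -0.5),
                           condition = "unknown", participant = "unknown") {
  avg <- averageEvoked(epochs)
  comb <- combinePlanar(avg, layout)
  baselineCorrect(comb, epochs@t, window = baseline, sfreq = epochs@sfreq,
                  condition = condition, participant = participant)
}

#' @describeIn evokedGradient values accessor (sites x samples)
#' @param object an \code{EvokedGradient}
#' @param ... unused
#' @export
setMethod("evokedValues", "EvokedGradient", function(object, ...) object@values)

setMethod("show", "EvokedGradient", function(object) {
  cat(sprintf("EvokedGradient [%s, %s]: %d sites x %d samples, t in [%.3f, %.3f] s, baseline [%.2f, %.2f) s\n",
              object@condition, object@participant, nrow(object@values),
              ncol(object@values), min(object@t), max(object@t),
              object@baselineWindow[1], object@baselineWindow[2]))
})

#' Export an evoked gradient as a long TSV table
#'
#' @param evoked an [EvokedGradient-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writeEvokedTsv <- function(evoked, path) {
  df <- data.frame(site = rep(evoked@sites, times = length(evoked@t)),
                   t = rep(evoked@t, each = length(evoked@sites)),
                   value = as.vector(evoked@values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
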