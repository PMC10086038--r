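#' Pixel / degree conversion factors for a flat screen
#'
#' Central (small-angle) conversion between screen pixels and degrees of
#' visual angle for a viewer at \code{distanceCm} from a flat screen of
#' \code{widthCm} rendered at \code{widthPx} horizontal pixels. The same
#' factor applies vertically for square pixels.
#'
#' @param distanceCm viewing distance (cm)
#' @param widthCm physical screen width (cm)
#' @param widthPx horizontal resolution (pixels)
#' @return degrees of visual angle per pixel at screen centre
#' @examples
#' degPerPixel(100, 51, 1440)   # the default geometry of the emulated setup
#' @export
degPerPixel <- function(distanceCm = 100, widthCm = 51, widthPx = 1440) {
  (180 / pi) * atan((widthCm / widthPx) / distanceCm)
}

#' Calibrate raw eye-tracker channels to degrees
#'
#' Applies an affine volt-to-pixel mapping followed by the central
#' pixel-to-degree conversion, producing a [GazeRecording-class] in degrees
#' of visual angle.
#'
#' @param t sample times (s), uniform
#' @param xRaw,yRaw raw channel values (e.g. volts)
#' @param mapping list with affine terms \code{gainX}, \code{offsetX},
#'   \code{gainY}, \code{offsetY} (raw -> pixels; default identity), screen
#'   geometry \code{distanceCm}, \code{widthCm}, \code{widthPx} and optional
#'   pixel origin \code{centerPx} (length 2) subtracted before the
#'   pixel-to-degree step. Set \code{pixelInput = TRUE} in the list if the raw
#'   channels are already pixels.
#' @param valid optional logical validity mask
#' @return a [GazeRecording-class] (x, y in degrees)
#' @export
calibrateGaze <- function(t, xRaw, yRaw, mapping = list(), valid = NULL) {
  m <- utils::modifyList(list(gainX = 1, offsetX = 0, gainY = 1, offsetY = 0,
                              distanceCm = 100, widthCm = 51, widthPx = 1440,
                              centerPx = c(0, 0)), mapping)
  if (!all(is.finite(c(m$gainX, m$offsetX, m$gainY, m$offsetY))))
    stop("volt-to-pixel mapping must be finite", call. = FALSE)
  px <- m$gainX * xRaw + m$offsetX - m$centerPx[1]
  py <- m$gainY * yRaw + m$offsetY - m$centerPx[2]
  k <- degPerPixel(m$distanceCm, m$widthCm, m$widthPx)
  if (is.null(valid)) valid <- rep(TRUE, length(t))
  sfreq <- 1 / stats::median(diff(t))
  methods::new("GazeRecording", t = as.numeric(t), x = px * k, y = py * k,
               sfreq = sfreq, valid = valid,
               unitsMeta = list(units = "deg", degPerPixel = k, mapping = m))
}

#' Align eye-tracker and MEG clocks
#'
#' Compensates a fixed acquisition lag by shifting all gaze timestamps
#' earlier by \code{lag} seconds relative to the MEG clock (a gaze sample
#' recorded at MEG time t actually occurred at t - lag). With the default
#' 7 ms at 1000 Hz this is a 7-sample shift.
#'
#' @param gaze a [GazeRecording-class]
#' @param lag lag in seconds (default 0.007)
#' @return the shifted [GazeRecording-class]
#' @export
alignClocks <- function(gaze, lag = 0.007) {
  stopifnot(methods::is(gaze, "GazeRecording"))
  dur <- diff(range(gaze@t))
  if (lag > dur) stop("lag exceeds the recording length", call. = FALSE)
  gaze@t <- gaze@t - lag
  gaze
}

#' Read / write gaze samples in a tab-separated EyeLink-ASC-like dialect
#'
#' Three columns: \code{time_ms}, \code{x}, \code{y} (x/y in the recording's
#' units; invalid samples written as a dot, as in ASC sample lines).
#'
#' @param gaze a [GazeRecording-class]; @param path file path
#' @return \code{writeGazeTsv}: path invisibly; \code{readGazeTsv}: a
#'   [GazeRecording-class]
#' @export
writeGazeTsv <- function(gaze, path) {
  x <- ifelse(gaze@valid, format(gaze@x, digits = 10), ".")
  y <- ifelse(gaze@valid, format(gaze@y, digits = 10), ".")
  df <- data.frame(time_ms = round(gaze@t * 1000, 6), x = x, y = y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGazeTsv
#' @export
readGazeTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character", "character"))
  valid <- df$x != "." & df$y != "."
  x <- suppressWarnings(as.numeric(df$x)); x[!valid] <- 0
  y <- suppressWarnings(as.numeric(df$y)); y[!valid] <- 0
  t <- df$time_ms / 1000
  methods::new("GazeRecording", t = t, x = x, y = y,
               sfreq = 1 / stats::median(diff(t)), valid = valid,
               unitsMeta = list(units = "deg"))
}
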