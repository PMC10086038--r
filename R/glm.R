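#' Fit the condition-template GLM for one site
#'
#' Ordinary least squares over the time samples of the saccade-locked window:
#' \code{y = betaSaccade * xSaccade + betaStimulus * xStimulus + e}, with no
#' intercept by default (all traces are baseline-corrected to zero over the
#' same window, and the model comprises exactly the two condition
#' regressors). Perfectly collinear regressors are handled by the
#' minimum-norm (pseudoinverse) solution with a warning.
#'
#' @param y numeric, the Saccade+stimulus combined planar gradient
#' @param xSaccade,xStimulus numeric, the Saccade-only / Stimulus-only
#'   condition templates (same length as \code{y})
#' @param intercept logical; add a free mean term (sensitivity analyses)
#' @return list: \code{beta} (named, \code{saccade}, \code{stimulus}, and
#'   \code{intercept} if requested), \code{fitted}, \code{residual},
#'   \code{r2} (1 - SS_res/SS_tot about the mean of y; \code{NA} with a
#'   warning when y has zero variance)
#' @examples
#' t <- seq(-0.6, 0, by = 0.002)
#' x1 <- exp(-((t + 0.05) / 0.1)^2); x2 <- exp(-((t + 0.3) / 0.1)^2)
#' f <- fitConditionGlm(1.3 * x1 + 0.7 * x2, x1, x2)
#' f$beta
#' @export
fitConditionGlm <- function(y, xSaccade, xStimulus, intercept = FALSE) {
  n <- length(y)
  if (length(xSaccade) != n || length(xStimulus) != n)
    stop("y and regressors must have equal length", call. = FALSE)
  if (all(xSaccade == 0) && all(xStimulus == 0))
    stop("regressors must not both be identically zero", call. = FALSE)
  X <- cbind(saccade = xSaccade, stimulus = xStimulus)
  if (intercept) X <- cbind(X, intercept = 1)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-12) {
    warning("regressors are collinear; using the minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- drop(solve(XtX, Xty))
  }
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  residual <- y - fitted
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("response has zero variance; R^2 undefined")
    r2 <- NA_real_
  } else r2 <- 1 - sum(residual^2) / sst
  list(beta = beta, fitted = fitted, residual = residual, r2 = r2)
}

#' Fit the condition-template GLM across all sites of a participant
#'
#' Applies [fitConditionGlm()] site-wise to three evoked gradients sharing
#' the same time axis and site order.
#'
#' @param y [EvokedGradient-class] of the Saccade+stimulus condition
#' @param xSaccade [EvokedGradient-class] of the Saccade-only condition
#' @param xStimulus [EvokedGradient-class] of the Stimulus-only condition
#'   (surrogate-relocked)
#' @param intercept logical, see [fitConditionGlm()]
#' @return a [GlmResult-class]
#' @export
fitEvokedGlm <- function(y, xSaccade, xStimulus, intercept = FALSE) {
  stopifnot(methods::is(y, "EvokedGradient"),
            methods::is(xSaccade, "EvokedGradient"),
            methods::is(xStimulus, "EvokedGradient"))
  if (!identical(y@sites, xSaccade@sites) ||
      !identical(y@sites, xStimulus@sites))
    stop("evoked gradients must share the same sites", call. = FALSE)
  S <- length(y@sites); nT <- length(y@t)
  bS <- bX <- r2 <- numeric(S)
  res <- fit <- matrix(0, S, nT, dimnames = list(y@sites, NULL))
  for (s in seq_len(S)) {
    f <- fitConditionGlm(y@values[s, ], xSaccade@values[s, ],
                         xStimulus@values[s, ], intercept = intercept)
    bS[s] <- f$beta["saccade"]; bX[s] <- f$beta["stimulus"]
    r2[s] <- f$r2; res[s, ] <- f$residual; fit[s, ] <- f$fitted
  }
  methods::new("GlmResult", betaSaccade = bS, betaStimulus = bX, r2 = r2,
               residuals = res, fitted = fit, sites = y@sites, t = y@t,
               participant = y@participant)
}

#' Proportion of variance explained
#'
#' @param result a [GlmResult-class] or a single fit from [fitConditionGlm()]
#' @return numeric R^2 per site (or scalar)
#' @export
varianceExplained <- function(result) {
  if (methods::is(result, "GlmResult")) return(result@r2)
  result$r2
}

#' Hemispheric median of a per-site quantity
#'
#' Median over the sites of one hemisphere; midline sites are excluded.
#'
#' @param values named numeric vector (names = site ids) or unnamed vector in
#'   layout site order
#' @param layout a [SensorLayout-class]
#' @param side \code{"left"} or \code{"right"}
#' @return scalar median
#' @export
hemisphericMedian <- function(values, layout, side = c("left", "right")) {
  side <- match.arg(side)
  s <- layout@sites
  sel <- s$hemisphere == side
  if (!any(sel)) stop("hemisphere '", side, "' has no sites", call. = FALSE)
  if (!is.null(names(values))) values <- values[s$site]
  stats::median(values[sel])
}

#' @describeIn fitEvokedGlm residual traces accessor (sites x samples)
#' @param object a \code{GlmResult}
#' @param ... unused
#' @export
setMethod("residualTraces", "GlmResult", function(object, ...) object@residuals)

#' @describeIn fitEvokedGlm per-site coefficient table
#' @export
setMethod("betaTable", "GlmResult", function(object, ...) {
  data.frame(participant = object@participant, site = object@sites,
             beta_saccade = object@betaSaccade,
             beta_stimulus = object@betaStimulus, r2 = object@r2,
             stringsAsFactors = FALSE)
})

setMethod("show", "GlmResult", function(object) {
  cat(sprintf("GlmResult [%s]: %d sites, beta_saccade median %.3f, beta_stimulus median %.3f, R^2 median %.3f\n",
              object@participant, length(object@sites),
              stats::median(object@betaSaccade),
              stats::median(object@betaStimulus),
              stats::median(object@r2, na.rm = TRUE)))
})
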