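# Connected components of suprathreshold (site, sample) points under
# spatial adjacency x temporal contiguity. mask: sites x samples logical;
# adjList: list of integer neighbour site indices per site.
# Returns list of integer vectors of linear (column-major) indices.
.connComp <- function(mask, adjList) {
  S <- nrow(mask); nT <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  lab <- integer(S * nT)
  comps <- list()
  nc <- 0L
  stack <- integer(length(idx))
  for (seed in idx) {
    if (lab[seed]) next
    nc <- nc + 1L
    lab[seed] <- nc
    top <- 1L
    stack[1L] <- seed
    members <- integer(0)
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      members <- c(members, cur)
      s <- ((cur - 1L) %% S) + 1L
      tcol <- ((cur - 1L) %/% S) + 1L
      nb <- integer(0)
      if (tcol > 1L) nb <- c(nb, cur - S)
      if (tcol < nT) nb <- c(nb, cur + S)
      an <- adjList[[s]]
      if (length(an)) nb <- c(nb, (tcol - 1L) * S + an)
      for (v in nb) {
        if (mask[v] && !lab[v]) {
          lab[v] <- nc
          top <- top + 1L
          stack[top] <- v
        }
      }
    }
    comps[[nc]] <- members
  }
  comps
}

# Max |cluster statistic| over positive and negative suprathreshold sets.
.maxClusterMass <- function(tv, tcrit, adjList, statistic = "mass") {
  m <- 0
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tv > tcrit else tv < -tcrit
    if (!any(mask)) next
    for (cmp in .connComp(mask, adjList))
      m <- max(m, if (statistic == "mass") abs(sum(tv[cmp]))
               else length(cmp))
  }
  m
}

#' One-sample spatiotemporal cluster-permutation test
#'
#' Tests per-(site, sample) deviations of residual traces from zero across
#' participants with one-sample t-tests, corrected for multiple comparisons
#' in time and space by cluster-based permutation (two-tailed). Points
#' exceeding the two-tailed parametric critical t (df = n - 1) are grouped
#' into spatiotemporally connected clusters (spatial adjacency from the
#' layout graph, temporal adjacency between consecutive samples), separately
#' for positive and negative deviations; a cluster's mass is its summed t.
#' The null distribution of the maximum absolute cluster mass is built by
#' random sign-flips of participants; p = (1 + #\{null >= observed\}) /
#' (1 + nPerm). With \code{exhaustive = TRUE} all 2^n sign patterns are
#' enumerated and p = #\{null >= observed\} / 2^n.
#'
#' @param residuals numeric array, participants x sites x samples
#' @param adjacency logical sites x sites matrix (see
#'   [adjacencyFromLayout()]); a 1 x 1 matrix for purely temporal clustering
#' @param alpha two-tailed alpha for both the cluster-forming threshold and
#'   cluster significance (default 0.05)
#' @param nPerm number of random sign-flip permutations (ignored when
#'   \code{exhaustive})
#' @param seed integer seed for the permutation draws
#' @param exhaustive enumerate all sign patterns (participants <= 16)
#' @param statistic cluster statistic: \code{"mass"} (summed t, default) or
#'   \code{"size"} (number of suprathreshold points)
#' @param t,sites,sfreq optional axis metadata carried into the result
#' @return a [ClusterStats-class]
#' @export
clusterOneSampleTest <- function(residuals, adjacency, alpha = 0.05,
                                 nPerm = 1000L, seed = 1L,
                                 exhaustive = FALSE,
                                 statistic = c("mass", "size"), t = NULL,
                                 sites = NULL, sfreq = NA_real_) {
  statistic <- match.arg(statistic)
  dm <- dim(residuals)
  if (length(dm) != 3L)
    stop("residuals must be participants x sites x samples", call. = FALSE)
  P <- dm[1]; S <- dm[2]; nT <- dm[3]
  if (P < 2L) stop("need at least 2 participants", call. = FALSE)
  if (!exhaustive && nPerm < 1L) stop("nPerm must be >= 1", call. = FALSE)
  if (nrow(adjacency) != S)
    stop("adjacency must cover all sites", call. = FALSE)
  adjList <- lapply(seq_len(S), function(s) which(adjacency[s, ]))
  X <- matrix(residuals, P, S * nT)
  ss <- colSums(X^2)
  tcrit <- stats::qt(1 - alpha / 2, df = P - 1L)
  tOf <- function(m) {
    v <- (ss - P * m^2) / (P - 1L)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / P)
  }
  tobs <- tOf(colMeans(X))
  tmat <- matrix(tobs, S, nT)

  obs <- list(); sign <- numeric(0)
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tmat > tcrit else tmat < -tcrit
    cmp <- .connComp(mask, adjList)
    obs <- c(obs, cmp)
    sign <- c(sign, rep(sgn, length(cmp)))
  }
  masses <- if (statistic == "mass")
    vapply(obs, function(m) sum(tmat[m]), numeric(1))
  else vapply(obs, function(m) base::sign(sum(tmat[m])) * length(m),
              numeric(1))

  if (exhaustive) {
    if (P > 16L) stop("exhaustive enumeration limited to 16 participants",
                      call. = FALSE)
    nPerm <- as.integer(2^P)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), P)))
  } else {
    set.seed(as.integer(seed))
    signs <- matrix(sample(c(1, -1), as.integer(nPerm) * P, replace = TRUE),
                    as.integer(nPerm), P)
  }
  M <- (signs %*% X) / P
  maxNull <- numeric(nrow(signs))
  for (k in seq_len(nrow(signs)))
    maxNull[k] <- .maxClusterMass(matrix(tOf(M[k, ]), S, nT), tcrit, adjList,
                                  statistic)

  p <- if (length(masses)) {
    if (exhaustive)
      vapply(abs(masses), function(m) mean(maxNull >= m - 1e-12), numeric(1))
    else
      vapply(abs(masses), function(m)
        (1 + sum(maxNull >= m - 1e-12)) / (1 + nrow(signs)), numeric(1))
  } else numeric(0)

  ord <- order(p, -abs(masses))
  obs <- obs[ord]; masses <- masses[ord]; sign <- sign[ord]; p <- p[ord]
  sig <- matrix(FALSE, S, nT)
  for (i in seq_along(obs)) if (p[i] <= alpha) sig[obs[[i]]] <- TRUE
  members <- lapply(obs, function(m)
    cbind(site = ((m - 1L) %% S) + 1L, sample = ((m - 1L) %/% S) + 1L))
  if (is.null(sites)) sites <- sprintf("S%03d", seq_len(S))
  if (is.null(t)) t <- seq_len(nT)
  dimnames(sig) <- dimnames(tmat) <- list(sites, NULL)
  methods::new("ClusterStats",
               clusters = data.frame(cluster = seq_along(obs), sign = sign,
                                     mass = masses,
                                     n_points = lengths(obs), p = p),
               members = members, sigMask = sig, tmap = tmat, alpha = alpha,
               nPerm = as.integer(nrow(signs)), seed = as.integer(seed),
               t = as.numeric(t), sites = sites, sfreq = as.numeric(sfreq))
}

#' Minimum-duration mask over significant sites
#'
#' Flags sites whose significance mask contains a contiguous run spanning at
#' least \code{minDur} seconds. The span of a run of n samples is
#' (n - 1) / sfreq by default (\code{convention = "span"}); the alternative
#' n / sfreq reading is available as \code{convention = "count"}.
#'
#' @param stats a [ClusterStats-class]
#' @param minDur minimum duration (s), default 0.0125
#' @param sfreq sampling rate (Hz); defaults to the rate stored in
#'   \code{stats}
#' @param convention \code{"span"} or \code{"count"}
#' @return named logical vector over sites
#' @export
durationMask <- function(stats, minDur = 0.0125, sfreq = NULL,
                         convention = c("span", "count")) {
  convention <- match.arg(convention)
  stopifnot(methods::is(stats, "ClusterStats"))
  if (is.null(sfreq)) sfreq <- stats@sfreq
  if (!is.finite(sfreq)) stop("sampling rate required", call. = FALSE)
  apply(stats@sigMask, 1L, function(row) {
    runs <- .trueRuns(row)
    if (!nrow(runs)) return(FALSE)
    len <- max(runs[, "length"])
    span <- if (convention == "span") (len - 1) / sfreq else len / sfreq
    span >= minDur
  })
}

#' Hemispheric lateralization time course of residuals
#'
#' Per participant and time sample: the median residual over left-hemisphere
#' sites minus the median over right-hemisphere sites, followed by a
#' one-sample cluster-permutation test over time only. An optional site
#' subset (e.g. an occipital or parietal selection) restricts both medians.
#'
#' @param residuals numeric array, participants x sites x samples (site
#'   order = layout order)
#' @param layout a [SensorLayout-class]
#' @param siteSubset optional character vector of site ids (or logical mask)
#' @param alpha,nPerm,seed,t,sfreq passed to [clusterOneSampleTest()]
#' @return list: \code{difference} (participants x samples matrix),
#'   \code{test} (a [ClusterStats-class] with a single pseudo-site)
#' @export
lateralizationTimecourse <- function(residuals, layout, siteSubset = NULL,
                                     alpha = 0.05, nPerm = 1000L, seed = 1L,
                                     t = NULL, sfreq = NA_real_) {
  s <- layout@sites
  keep <- rep(TRUE, nrow(s))
  if (!is.null(siteSubset))
    keep <- if (is.logical(siteSubset)) siteSubset else s$site %in% siteSubset
  left <- which(keep & s$hemisphere == "left")
  right <- which(keep & s$hemisphere == "right")
  if (!length(left) || !length(right))
    stop("both hemispheres must be non-empty", call. = FALSE)
  P <- dim(residuals)[1]; nT <- dim(residuals)[3]
  diffs <- matrix(0, P, nT)
  for (p in seq_len(P)) {
    diffs[p, ] <- apply(residuals[p, left, , drop = FALSE], 3L, stats::median) -
      apply(residuals[p, right, , drop = FALSE], 3L, stats::median)
  }
  arr <- array(diffs, dim = c(P, 1L, nT))
  test <- clusterOneSampleTest(arr, adjacency = matrix(FALSE, 1, 1),
                               alpha = alpha, nPerm = nPerm, seed = seed,
                               t = t, sites = "left_minus_right",
                               sfreq = sfreq)
  list(difference = diffs, test = test)
}

#' Paired hemispheric t-test
#'
#' One-sample t-test on per-participant left-minus-right differences
#' (df = n - 1). A zero-variance non-zero difference is reported as a signed
#' infinite-t sentinel with p = 0.
#'
#' @param left,right numeric vectors, one value per participant
#' @return list: \code{t}, \code{df}, \code{p}, \code{meanDiff}
#' @export
pairedHemisphereTtest <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right must be paired", call. = FALSE)
  n <- length(left)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)
  d <- left - right
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1, meanDiff = 0))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                meanDiff = mean(d)))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = mean(d))
}

#' Chi-square and Bayes factor tests on significant-sensor counts
#'
#' Compares the number of significantly active sensors between hemispheres:
#' a Pearson chi-square test on the 2 x 2 table (significant / not x
#' hemisphere; df = 1, no continuity correction) with a Bonferroni-adjusted
#' p over the tested time windows, and a Bayes factor for H1 (different
#' proportions, independent Beta(a, a) priors) against H0 (a common
#' proportion, Beta(a, a) prior), computed by numerical integration of the
#' binomial marginal likelihoods. BF < 1 favours H0.
#'
#' @param countLeftSig,nLeft significant and total sensor counts, left
#'   hemisphere
#' @param countRightSig,nRight same for the right hemisphere
#' @param priorConcentration Beta prior concentration a (default 1)
#' @param nWindows Bonferroni factor (default 2, one per tested pre-saccadic
#'   window)
#' @return list: \code{chi2} (statistic, df, p, pAdjusted), \code{bf}
#'   (Bayes factor BF10)
#' @export
proportionTests <- function(countLeftSig, nLeft, countRightSig, nRight,
                            priorConcentration = 1, nWindows = 2L) {
  if (nLeft <= 0 || nRight <= 0) stop("zero totals", call. = FALSE)
  if (countLeftSig > nLeft || countRightSig > nRight)
    stop("counts cannot exceed totals", call. = FALSE)
  tab <- rbind(left = c(sig = countLeftSig, ns = nLeft - countLeftSig),
               right = c(sig = countRightSig, ns = nRight - countRightSig))
  if (any(colSums(tab) == 0)) {
    # degenerate table (e.g. no significant sensor in either hemisphere):
    # no evidence of a difference
    chi <- list(statistic = 0, parameter = 1L, p.value = 1)
  } else {
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  a <- priorConcentration
  margBinom <- function(k, n) {
    f <- function(p) stats::dbinom(k, n, p) * stats::dbeta(p, a, a)
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  margCommon <- function() {
    f <- function(p) stats::dbinom(countLeftSig, nLeft, p) *
      stats::dbinom(countRightSig, nRight, p) * stats::dbeta(p, a, a)
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  bf10 <- (margBinom(countLeftSig, nLeft) *
           margBinom(countRightSig, nRight)) / margCommon()
  list(chi2 = list(statistic = unname(chi$statistic),
                   df = unname(chi$parameter), p = chi$p.value,
                   pAdjusted = min(1, nWindows * chi$p.value)),
       bf = bf10)
}

#' @describeIn clusterOneSampleTest cluster summary table
#' @param object a \code{ClusterStats}
#' @param ... unused
#' @export
setMethod("clusterTable", "ClusterStats", function(object, ...) object@clusters)

#' @describeIn clusterOneSampleTest significance mask (sites x samples)
#' @export
setMethod("significanceMask", "ClusterStats",
          function(object, ...) object@sigMask)

setMethod("show", "ClusterStats", function(object) {
  cl <- object@clusters
  nsig <- sum(cl$p <= object@alpha)
  cat(sprintf("ClusterStats: %d cluster(s), %d significant at alpha=%.3g (%d permutations)\n",
              nrow(cl), nsig, object@alpha, object@nPerm))
  if (nrow(cl)) {
    print(utils::head(cl, 5))
    if (nrow(cl) > 5) cat(sprintf("  ... %d more\n", nrow(cl) - 5L))
  }
})
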