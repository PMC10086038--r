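# Shared fixtures: all synthetic, built in code at test time.

tinyLayout <- function(n = 8, seed = 2) makeLayout(n, seed = seed)

# A small zero-noise session with bilateral components (both betas
# identifiable at every site) plus its epochs and condition row indices.
zeroNoiseSetup <- function(nPer = 12, seed = 11, layout = tinyLayout(),
                           betaTrue = c(saccade = 1.3, stimulus = 0.7),
                           residualAmplitude = 0, noise = c(white = 0, pink = 0)) {
  ker <- list(saccade = saccadeComponent(),
              stimulus = stimulusComponent(lateralization = "bilateral"),
              residual = residualComponent(amplitude = residualAmplitude))
  cfg <- simConfig(trialsPerCondition = c(saccade_stimulus = nPer,
                                          saccade_only = nPer,
                                          stimulus_only = nPer),
                   sfreqMeg = 500, sfreqEye = 500, noise = noise,
                   preS1 = c(0.6, 0.6), postS1 = 0.7, photodiodeNoise = 0,
                   kernels = ker, betaTrue = betaTrue,
                   microsaccadeRate = 0, layout = layout, seed = seed)
  ses <- simulateSession(cfg)
  ev <- eventTable(ses)
  epochs <- makeEpochs(ses@meg, ses@sfreq, ev$s1_time, c(-0.5, 0.6),
                       meta = ev, channels = ses@channels)
  meta <- epochMeta(epochs)
  list(cfg = cfg, session = ses, epochs = epochs, meta = meta,
       rows = split(seq_len(nrow(meta)), meta$condition))
}

subsetEpochs <- function(epochs, rows) {
  epochs@data <- epochs@data[rows, , , drop = FALSE]
  epochs@meta <- epochs@meta[rows, , drop = FALSE]
  epochs
}

# Evoked chain for a condition subset, relocked to the given onsets.
relockedEvoked <- function(setup, cond, layout, onsets = NULL) {
  rows <- setup$rows[[cond]]
  if (is.null(onsets)) onsets <- setup$meta$latency[rows]
  ep <- relockToSaccade(subsetEpochs(setup$epochs, rows), onsets)$epochs
  evokedGradient(ep, layout, condition = cond)
}

# A gaze trace with known minimum-jerk saccades; returns recording + truth.
syntheticGaze <- function(onsets, amplitudes, duration = 3, sfreq = 1000,
                          jitterSd = 0.05, seed = 1) {
  set.seed(seed)
  tt <- seq(0, duration, by = 1 / sfreq)
  x <- stats::rnorm(length(tt), 0, jitterSd)
  y <- stats::rnorm(length(tt), 0, jitterSd)
  for (i in seq_along(onsets)) {
    d <- 0.0022 * amplitudes[i] + 0.021
    sgn <- if (i %% 2 == 0) 1 else -1
    x <- x + sgn * amplitudes[i] *
      presaccade:::.minJerk((tt - onsets[i]) / d)
  }
  methods::new("GazeRecording", t = tt, x = x, y = y, sfreq = sfreq,
               valid = rep(TRUE, length(tt)), unitsMeta = list())
}

# Independent brute-force max-cluster-mass oracle (re-implemented naively,
# no shared code with the package internals).
bruteMaxMass <- function(M, S, Tn, adj, tcrit) {
  P <- nrow(M)
  tm <- matrix(apply(M, 2, function(v) mean(v) / (stats::sd(v) / sqrt(P))),
               S, Tn)
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tm > tcrit else tm < -tcrit
    seen <- matrix(FALSE, S, Tn)
    for (s in seq_len(S)) for (tt in seq_len(Tn)) {
      if (!mask[s, tt] || seen[s, tt]) next
      stack <- list(c(s, tt)); seen[s, tt] <- TRUE; mass <- 0
      while (length(stack)) {
        nd <- stack[[1]]; stack <- stack[-1]
        mass <- mass + tm[nd[1], nd[2]]
        for (dt in c(-1, 1)) {
          v <- c(nd[1], nd[2] + dt)
          if (v[2] >= 1 && v[2] <= Tn && mask[v[1], v[2]] &&
              !seen[v[1], v[2]]) {
            seen[v[1], v[2]] <- TRUE; stack <- c(stack, list(v))
          }
        }
        for (s2 in which(adj[nd[1], ])) {
          if (mask[s2, nd[2]] && !seen[s2, nd[2]]) {
            seen[s2, nd[2]] <- TRUE; stack <- c(stack, list(c(s2, nd[2])))
          }
        }
      }
      best <- max(best, abs(mass))
    }
  }
  best
}

# Exhaustive sign-flip p-values computed by the brute-force oracle.
brutePvalues <- function(residuals, adj, alpha = 0.05) {
  P <- dim(residuals)[1]; S <- dim(residuals)[2]; Tn <- dim(residuals)[3]
  M <- matrix(residuals, P, S * Tn)
  tcrit <- stats::qt(1 - alpha / 2, P - 1)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), P)))
  null <- vapply(seq_len(nrow(signs)), function(k)
    bruteMaxMass(M * signs[k, ], S, Tn, adj, tcrit), numeric(1))
  obs <- clusterOneSampleTest(residuals, adj, alpha = alpha,
                              exhaustive = TRUE)
  list(impl = clusterTable(obs)$p,
       oracle = vapply(abs(clusterTable(obs)$mass), function(m)
         mean(null >= m - 1e-12), numeric(1)))
}
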