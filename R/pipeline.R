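#' Build a pipeline run configuration
#'
#' Assembles and validates the per-stage parameters of [runPipeline()].
#' Two scale presets are provided: \code{"full"} (28 participants,
#' 102 sites, 416/208/208 trials at 1000 Hz, 1000 surrogate draws, 1000
#' permutations) and \code{"test"} (8 participants, 16 sites, 60/30/30
#' trials simulated directly at 500 Hz, 50 draws, 200 permutations), with
#' every analysis constant (baseline window, latency bounds, 12.5 ms
#' duration criterion, alpha) identical between presets. Unknown keys in
#' \code{...} overrides are rejected.
#'
#' @param preset \code{"test"} or \code{"full"}
#' @param seed master integer seed; every stage derives its stream from it
#' @param ... named overrides of top-level sections (\code{participants},
#'   \code{sim}, \code{epoch}, \code{detect}, \code{select}, \code{glm},
#'   \code{surrogate}, \code{stats}); each a list replacing keys of that
#'   section
#' @return validated config list of class \code{"pipelineConfig"}
#' @export
pipelineConfig <- function(preset = c("test", "full"), seed = 1L, ...) {
  preset <- match.arg(preset)
  test <- preset == "test"
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    participants = if (test) 8L else 28L,
    sim = list(
      nSites = if (test) 16L else 102L,
      trialsPerCondition = if (test)
        c(saccade_stimulus = 60, saccade_only = 30, stimulus_only = 30)
      else c(saccade_stimulus = 416, saccade_only = 208,
             stimulus_only = 208),
      sfreqMeg = if (test) 500 else 1000,
      sfreqEye = if (test) 500 else 1000,
      preS1 = if (test) c(0.6, 0.6) else c(1.0, 1.5),
      postS1 = if (test) 0.7 else 1.6,
      noise = c(white = 1, pink = 1),
      residualAmplitude = 0,
      betaTrue = c(saccade = 1.3, stimulus = 0.7)),
    epoch = list(window = if (test) c(-0.5, 0.6) else c(-0.5, 1.5),
                 downsampleTo = 500, notch = TRUE,
                 notchFreqs = c(50, 100, 150)),
    detect = c(detectorParams(), clockLag = 0),
    select = list(latencyBounds = c(0.150, 0.500),
                  s2Window = if (test) 0.6 else 0.8,
                  crossingMargin = 4, verticalMargin = 2,
                  maxExcursion = 2, maxMicrosaccade = 0.5),
    glm = list(intercept = FALSE, window = c(-0.6, 0),
               baseline = c(-0.6, -0.5)),
    surrogate = list(nDraws = if (test) 50L else 1000L),
    stats = list(alpha = 0.05, nPerm = if (test) 200L else 1000L,
                 minDuration = 0.0125,
                 windows = list(early = c(-0.112, -0.05),
                                late = c(-0.05, 0))))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      unknown <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(unknown))
        stop("unknown key(s) in section '", nm, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

# Canonical md5 hash of a config (JSON-serialized, stable key order).
.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(unclass(cfg)))], tmp, digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

# Process one simulated participant end to end; returns group-level pieces.
.processParticipant <- function(cfg, layout, pid, masterSeed) {
  simSeed <- .childSeed(masterSeed, pid)
  ker <- list(saccade = saccadeComponent(), stimulus = stimulusComponent(),
              residual = residualComponent(
                amplitude = cfg$sim$residualAmplitude))
  scfg <- simConfig(trialsPerCondition = cfg$sim$trialsPerCondition,
                    sfreqMeg = cfg$sim$sfreqMeg, sfreqEye = cfg$sim$sfreqEye,
                    preS1 = cfg$sim$preS1, postS1 = cfg$sim$postS1,
                    noise = cfg$sim$noise, kernels = ker,
                    betaTrue = cfg$sim$betaTrue, layout = layout,
                    participant = sprintf("P%02d", pid), seed = simSeed)
  ses <- simulateSession(scfg)
  ev <- ses@events

  gaze <- ses@gaze
  if (cfg$detect$clockLag > 0) gaze <- alignClocks(gaze, cfg$detect$clockLag)
  detp <- detectorParams(minFixationDur = cfg$detect$minFixationDur,
                         minSaccadeDur = cfg$detect$minSaccadeDur)
  det <- detectSaccades(gaze, detp)
  parts <- classifyMicrosaccades(det, detp)
  sacc <- eventTable(parts$saccades)
  micro <- eventTable(parts$microsaccades)

  # photodiode cross-check of stimulus onsets (grey-to-white transitions)
  tri <- photodiodeTrinary(ses@photodiode)
  on <- visualOnsets(tri, ses@sfreq)
  rises <- on[tri[round(on * ses@sfreq) + 1L] == 1L]
  stimTrials <- which(ev$condition %in% c("saccade_stimulus", "stimulus_only"))
  pdMatch <- vapply(ev$s1_time[stimTrials], function(tt)
    any(abs(rises - tt) < 0.01), logical(1))

  meg <- ses@meg
  if (isTRUE(cfg$epoch$notch))
    meg <- dftNotch(meg, ses@sfreq, cfg$epoch$notchFreqs)
  epochs <- makeEpochs(meg, ses@sfreq, ev$s1_time, cfg$epoch$window,
                       meta = ev, channels = ses@channels)
  epochs <- downsampleEpochs(epochs, cfg$epoch$downsampleTo)
  meta <- epochMeta(epochs)

  # per-trial saccade bookkeeping from the detector
  s2w <- cfg$select$s2Window
  trialSacc <- lapply(seq_len(nrow(meta)), function(i) {
    w <- sacc$onset_t >= meta$s1_time[i] &
      sacc$onset_t <= meta$s1_time[i] + s2w
    sacc[w, , drop = FALSE]
  })
  nSacc <- vapply(trialSacc, nrow, integer(1))
  endX <- vapply(trialSacc, function(e)
    if (nrow(e) == 1L) e$end_x else NA_real_, numeric(1))
  endY <- vapply(trialSacc, function(e)
    if (nrow(e) == 1L) e$end_y else NA_real_, numeric(1))
  detLat <- vapply(seq_len(nrow(meta)), function(i) {
    e <- trialSacc[[i]]
    if (nrow(e) == 1L) e$onset_t - meta$s1_time[i] else NA_real_
  }, numeric(1))

  isSaccCond <- meta$condition %in% c("saccade_stimulus", "saccade_only")
  saccTab <- data.frame(trial = meta$trial, n_saccades = nSacc,
                        end_x = endX, end_y = endY, latency = detLat)
  selS <- selectSaccadeTrials(
    saccTab[isSaccCond, , drop = FALSE],
    geom = list(midlineX = 0, midlineY = 0,
                crossingMargin = cfg$select$crossingMargin,
                verticalMargin = cfg$select$verticalMargin, direction = -1),
    latencyBounds = cfg$select$latencyBounds)

  # fixation rules over the epoch window, per Stimulus-only trial
  isFix <- meta$condition == "stimulus_only"
  gexc <- mamp <- rep(NA_real_, nrow(meta))
  for (i in which(isFix)) {
    t0 <- meta$s1_time[i] + cfg$epoch$window[1]
    t1 <- meta$s1_time[i] + cfg$epoch$window[2]
    gsel <- gaze@t >= t0 & gaze@t <= t1
    gexc[i] <- max(sqrt((gaze@x[gsel] - 7)^2 + gaze@y[gsel]^2))
    mw <- micro$onset_t >= t0 & micro$onset_t <= t1
    sw <- sacc$onset_t >= t0 & sacc$onset_t <= t1
    mamp[i] <- max(0, micro$amplitude[mw], sacc$amplitude[sw])
  }
  selF <- selectFixationTrials(
    data.frame(trial = meta$trial, max_gaze_excursion = gexc,
               max_microsaccade = mamp)[isFix, , drop = FALSE],
    maxExcursion = cfg$select$maxExcursion,
    maxMicrosaccade = cfg$select$maxMicrosaccade)

  keepSacc <- meta$trial[isSaccCond][selS$keep]
  keepFix <- meta$trial[isFix][selF$keep]
  subEpochs <- function(rows) {
    e <- epochs
    e@data <- e@data[rows, , , drop = FALSE]
    e@meta <- meta[rows, , drop = FALSE]
    e
  }
  rowsSS <- which(meta$condition == "saccade_stimulus" &
                  meta$trial %in% keepSacc)
  rowsSO <- which(meta$condition == "saccade_only" & meta$trial %in% keepSacc)
  rowsST <- which(isFix & meta$trial %in% keepFix)
  if (length(rowsSS) < 2L || length(rowsSO) < 2L || length(rowsST) < 2L)
    stop(sprintf("participant %d: too few trials after selection", pid),
         call. = FALSE)

  glmw <- cfg$glm$window
  rl <- function(rows) {
    lat <- detLat[rows]
    relockToSaccade(subEpochs(rows), lat, window = glmw)$epochs
  }
  yEv <- evokedGradient(rl(rowsSS), layout, baseline = cfg$glm$baseline,
                        condition = "saccade_stimulus",
                        participant = scfg$participant)
  xsEv <- evokedGradient(rl(rowsSO), layout, baseline = cfg$glm$baseline,
                         condition = "saccade_only",
                         participant = scfg$participant)

  kdes <- fitLatencyKdes(detLat[rowsSS],
                         meta[rowsSS, c("orientation", "spatial_frequency",
                                        "phase")],
                         support = cfg$select$latencyBounds,
                         participant = scfg$participant)
  onsets <- sampleOnsets(kdes,
                         meta[rowsST, c("orientation", "spatial_frequency",
                                        "phase")],
                         nDraws = cfg$surrogate$nDraws,
                         seed = .childSeed(masterSeed, 7000L + pid))
  sres <- surrogateResiduals(subEpochs(rowsST), onsets, layout, yEv, xsEv,
                             window = glmw, baseline = cfg$glm$baseline,
                             seed = .childSeed(masterSeed, 7000L + pid))

  trueSacc <- ev$trial[!is.na(ev$latency)]
  detected <- sum(!is.na(detLat[meta$trial %in% trueSacc]))
  list(participant = scfg$participant, surrogate = sres,
       t = sres@t,
       counts = data.frame(
         participant = scfg$participant,
         n_trials = nrow(ev),
         n_sacc_kept = length(keepSacc), n_fix_kept = length(keepFix),
         n_sacc_rejected = sum(!selS$keep), n_fix_rejected = sum(!selF$keep),
         detection_rate = detected / length(trueSacc),
         pd_onset_match = mean(pdMatch)),
       rejectLog = rbind(
         if (nrow(selS$log)) cbind(selS$log, stage = "saccade_rules"),
         if (nrow(selF$log)) cbind(selF$log, stage = "fixation_rules")))
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Orchestrates simulate -> detect -> epoch -> select -> relock -> evoked ->
#' GLM -> surrogate -> group statistics for a cohort of simulated
#' participants, writing all artifacts as plain-text tables plus a JSON
#' manifest with content hashes. Rerunning with an identical configuration
#' over an existing run directory verifies the manifest hashes and is a
#' no-op; a hash mismatch raises an error naming the corrupt file.
#'
#' @param cfg a [pipelineConfig()]
#' @param outDir run directory
#' @param overwrite force recomputation even if a valid cached run exists
#' @return (invisibly) list with the group results: \code{residuals}
#'   (participants x sites x samples), \code{clusterStats},
#'   \code{durationMask}, \code{lateralization}, \code{hemisphereTests},
#'   \code{counts}, \code{files}, \code{cached}
#' @export
runPipeline <- function(cfg, outDir, overwrite = FALSE) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  hash <- .configHash(cfg)
  manifestPath <- file.path(outDir, "run_manifest.json")
  if (!overwrite && file.exists(manifestPath)) {
    man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    if (identical(man$configHash, unname(hash))) {
      files <- file.path(outDir, names(man$fileHashes))
      cur <- unname(tools::md5sum(files))
      bad <- which(is.na(cur) | cur != unlist(man$fileHashes))
      if (length(bad))
        stop("checksum mismatch for file(s): ",
             paste(basename(files[bad]), collapse = ", "), call. = FALSE)
      message("configuration unchanged and artifacts intact; skipping rerun")
      return(invisible(list(files = files, cached = TRUE)))
    }
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "log.txt")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logFile, append = TRUE)
  cat(sprintf("pipeline run started, preset=%s seed=%d\n",
              cfg$preset, cfg$seed), file = logFile)

  layout <- makeLayout(cfg$sim$nSites, seed = cfg$seed)
  writeLayoutJson(layout, file.path(outDir, "layout.json"))
  P <- cfg$participants
  parts <- vector("list", P)
  for (p in seq_len(P)) {
    parts[[p]] <- .processParticipant(cfg, layout, p, cfg$seed)
    logLine("participant %02d: %d saccade trials kept, %d fixation trials kept (%.1f%% / %.1f%% rejected), detection rate %.3f",
            p, parts[[p]]$counts$n_sacc_kept, parts[[p]]$counts$n_fix_kept,
            100 * parts[[p]]$counts$n_sacc_rejected /
              (parts[[p]]$counts$n_sacc_kept +
                 parts[[p]]$counts$n_sacc_rejected),
            100 * parts[[p]]$counts$n_fix_rejected /
              (parts[[p]]$counts$n_fix_kept +
                 parts[[p]]$counts$n_fix_rejected),
            parts[[p]]$counts$detection_rate)
  }
  tAxis <- parts[[1L]]$t
  S <- nSites(layout); nT <- length(tAxis)
  residuals <- array(0, dim = c(P, S, nT))
  for (p in seq_len(P))
    residuals[p, , ] <- medianResidualTraces(parts[[p]]$surrogate)

  adj <- adjacencyFromLayout(layout)
  cs <- clusterOneSampleTest(residuals, adj, alpha = cfg$stats$alpha,
                             nPerm = cfg$stats$nPerm,
                             seed = .childSeed(cfg$seed, 999L),
                             t = tAxis, sites = layout@sites$site,
                             sfreq = cfg$epoch$downsampleTo)
  dmask <- durationMask(cs, minDur = cfg$stats$minDuration)
  lat <- lateralizationTimecourse(residuals, layout,
                                  alpha = cfg$stats$alpha,
                                  nPerm = cfg$stats$nPerm,
                                  seed = .childSeed(cfg$seed, 998L),
                                  t = tAxis, sfreq = cfg$epoch$downsampleTo)
  hemi <- layout@sites$hemisphere
  r2mat <- t(vapply(parts, function(pp) pp$surrogate@r2Median, numeric(S)))
  bsmat <- t(vapply(parts, function(pp) pp$surrogate@betaSaccadeMedian,
                    numeric(S)))
  bxmat <- t(vapply(parts, function(pp) pp$surrogate@betaStimulusMedian,
                    numeric(S)))
  medSide <- function(m, side)
    apply(m[, hemi == side, drop = FALSE], 1L, stats::median)
  hemiTests <- list(
    r2 = pairedHemisphereTtest(medSide(r2mat, "left"), medSide(r2mat, "right")),
    betaSaccade = pairedHemisphereTtest(medSide(bsmat, "left"),
                                        medSide(bsmat, "right")),
    betaStimulus = pairedHemisphereTtest(medSide(bxmat, "left"),
                                         medSide(bxmat, "right")))
  propTests <- lapply(cfg$stats$windows, function(w) {
    inWin <- tAxis >= w[1] & tAxis <= w[2]
    sigSite <- rowSums(cs@sigMask[, inWin, drop = FALSE]) > 0
    proportionTests(sum(sigSite & hemi == "left"), sum(hemi == "left"),
                    sum(sigSite & hemi == "right"), sum(hemi == "right"),
                    nWindows = length(cfg$stats$windows))
  })

  # artifacts -----------------------------------------------------------------
  wt <- function(df, name) {
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  counts <- do.call(rbind, lapply(parts, `[[`, "counts"))
  rejects <- do.call(rbind, lapply(parts, function(pp)
    if (!is.null(pp$rejectLog) && nrow(pp$rejectLog))
      cbind(participant = pp$participant, pp$rejectLog)))
  betas <- do.call(rbind, lapply(parts, function(pp)
    data.frame(participant = pp$participant, site = layout@sites$site,
               beta_saccade = pp$surrogate@betaSaccadeMedian,
               beta_stimulus = pp$surrogate@betaStimulusMedian,
               r2 = pp$surrogate@r2Median)))
  medres <- do.call(rbind, lapply(seq_len(P), function(p)
    data.frame(participant = parts[[p]]$participant,
               site = rep(layout@sites$site, times = nT),
               t = rep(tAxis, each = S),
               value = as.vector(residuals[p, , ]))))
  files <- c(
    wt(counts, "participants.tsv"),
    if (!is.null(rejects)) wt(rejects, "rejections.tsv"),
    wt(betas, "betas.tsv"),
    wt(medres, "median_residuals.tsv"),
    wt(clusterTable(cs), "clusters.tsv"),
    wt(data.frame(site = layout@sites$site,
                  duration_mask = unname(dmask),
                  any_significant = rowSums(cs@sigMask) > 0),
       "duration_mask.tsv"),
    wt(data.frame(site = rep(layout@sites$site, times = nT),
                  t = rep(tAxis, each = S),
                  significant = as.vector(cs@sigMask)), "sig_mask.tsv"),
    wt(data.frame(participant = rep(counts$participant, times = nT),
                  t = rep(tAxis, each = P),
                  diff = as.vector(lat$difference)), "lateralization.tsv"),
    "layout.json")
  jsonlite::write_json(
    list(hemisphereTests = hemiTests,
         proportionTests = propTests,
         lateralizationClusters = clusterTable(lat$test)),
    file.path(outDir, "hemisphere_tests.json"), digits = NA,
    auto_unbox = TRUE, force = TRUE)
  files <- c(files, "hemisphere_tests.json")
  jsonlite::write_json(
    list(configHash = unname(hash), seed = cfg$seed, preset = cfg$preset,
         package = as.character(utils::packageVersion("presaccade")),
         fileHashes = as.list(
           stats::setNames(unname(tools::md5sum(file.path(outDir, files))),
                           files))),
    manifestPath, digits = NA, auto_unbox = TRUE)
  logLine("group stats: %d cluster(s), %d significant; %d duration-masked sensor(s)",
          nrow(clusterTable(cs)),
          sum(clusterTable(cs)$p <= cfg$stats$alpha), sum(dmask))
  invisible(list(residuals = residuals, clusterStats = cs,
                 durationMask = dmask, lateralization = lat,
                 hemisphereTests = hemiTests, proportionTests = propTests,
                 counts = counts, t = tAxis, layout = layout,
                 files = file.path(outDir, files), cached = FALSE))
}
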