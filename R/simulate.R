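# Synthetic EEG + behaviour generator. Emulates the statistical structure
# the decoding pipeline assumes: phase-locked SSVEPs at the flicker
# frequencies and their second harmonics with an attention gain,
# random-phase alpha activity, 1/f background noise, motion-locked
# transients, sporadic high-amplitude artifacts, an 8-bit trigger channel
# and frame-wise behavioural responses.

#' Simulation configuration
#'
#' Assembles and validates the parameter set of the synthetic-data
#' generator. Defaults reproduce the study design: 1200 Hz sampling from
#' five occipital electrodes, 2 s cue + 15 s stimulation trials, SSVEP
#' amplitudes of 1.47/1.33 uV at 6.0 Hz (cued/uncued) and 1.05/0.93 uV at
#' 7.5 Hz, and behavioural accuracy/RT means of 62.17%/0.64 s (distractor
#' present) and 87.74%/0.58 s (absent).
#'
#' @param fs sampling rate (Hz).
#' @param channels EEG channel labels.
#' @param ssvepAmp named numeric: single-sided SSVEP amplitude (uV) for
#'   keys "6_cued", "6_uncued", "7.5_cued", "7.5_uncued" (distractor
#'   present) and "6_absent", "7.5_absent" (the amplitude of the single
#'   presented frequency on distractor-absent trials, which is lower
#'   than the cued-present amplitude because stimulus competition and
#'   attentional engagement differ between the display configurations).
#' @param harmonicRatio second-harmonic amplitude as a fraction of the
#'   fundamental.
#' @param gainSpread per-electrode multiplicative gain spread; electrode
#'   gains follow a fixed mean-one pattern scaled by this value, making
#'   the topography non-degenerate without biasing the electrode average.
#' @param ampJitterSd log-normal SD of the per-trial attentional-state
#'   fluctuation. Each trial draws one attention state g ~ N(0, sd^2);
#'   the cued amplitude is multiplied by exp(+g) and, when a distractor
#'   is present, the uncued amplitude by exp(-g) (both mean-corrected),
#'   modelling selectivity as push-pull: stronger selection of the cued
#'   colour simultaneously enhances its tag and suppresses the
#'   distractor's. Distractor-absent trials carry only the exp(+g)
#'   modulation of the single presented tag.
#' @param alphaAmp amplitude (uV) of 10 Hz alpha activity with per-trial
#'   random phase.
#' @param noiseExponent spectral exponent beta of the 1/f^beta background.
#' @param noiseScale standard deviation (uV) of the background noise.
#' @param erpAmp peak amplitude (uV) of the 1 s motion-locked transient.
#' @param artifactRate artifact events per minute.
#' @param artifactAmp artifact peak amplitude (uV); above the 150 uV
#'   rejection threshold by default.
#' @param behavAcc named numeric: mean accuracy (percent) per distractor
#'   condition.
#' @param behavAccSd between-participant SD of accuracy (percent).
#' @param behavRtMean named numeric: mean RT (s) per distractor condition.
#' @param behavRtSd between-participant SD of mean RT (s).
#' @param cueDur,stimDur,itiDur trial phase durations (s).
#' @param frameRate display refresh rate (Hz) for behavioural streams.
#' @return a validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(fs = 1200,
                             channels = c("Iz", "O1", "O2", "Oz", "POz"),
                             ssvepAmp = c("6_cued" = 1.47, "6_uncued" = 1.33,
                                          "7.5_cued" = 1.05,
                                          "7.5_uncued" = 0.93,
                                          "6_absent" = 1.30,
                                          "7.5_absent" = 0.90),
                             harmonicRatio = 0.4,
                             gainSpread = 0.1,
                             ampJitterSd = 0.12,
                             alphaAmp = 0.4,
                             noiseExponent = 1.0,
                             noiseScale = 1.6,
                             erpAmp = 4,
                             artifactRate = 2,
                             artifactAmp = 220,
                             behavAcc = c(present = 62.17, absent = 87.74),
                             behavAccSd = c(present = 16.46, absent = 14.07),
                             behavRtMean = c(present = 0.64, absent = 0.58),
                             behavRtSd = c(present = 0.08, absent = 0.06),
                             cueDur = 2, stimDur = 15, itiDur = 1,
                             frameRate = 120) {
  cfg <- list(fs = fs, channels = channels, ssvepAmp = ssvepAmp,
              harmonicRatio = harmonicRatio, gainSpread = gainSpread,
              ampJitterSd = ampJitterSd, alphaAmp = alphaAmp,
              noiseExponent = noiseExponent, noiseScale = noiseScale,
              erpAmp = erpAmp, artifactRate = artifactRate,
              artifactAmp = artifactAmp, behavAcc = behavAcc,
              behavAccSd = behavAccSd, behavRtMean = behavRtMean,
              behavRtSd = behavRtSd, cueDur = cueDur, stimDur = stimDur,
              itiDur = itiDur, frameRate = frameRate)
  need <- c("6_cued", "6_uncued", "7.5_cued", "7.5_uncued",
            "6_absent", "7.5_absent")
  if (!all(need %in% names(cfg$ssvepAmp)))
    stop("ssvepAmp must name all of: ", paste(need, collapse = ", "))
  if (any(cfg$ssvepAmp < 0)) stop("SSVEP amplitudes must be non-negative")
  if (cfg$fs <= 2 * 15) stop("fs must exceed twice the highest tag harmonic")
  if (any(c(cfg$alphaAmp, cfg$noiseScale, cfg$erpAmp, cfg$artifactRate,
            cfg$ampJitterSd, cfg$gainSpread) < 0))
    stop("amplitudes, rates and jitters must be non-negative")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Fixed mean-one electrode gain pattern scaled by gainSpread.
electrodeGains <- function(cfg) {
  1 + cfg$gainSpread * c(1, -1, 0.5, -0.5, 0)[seq_along(cfg$channels)]
}

# Gaussian 1/f^beta noise of length n with standard deviation sd.
oneOverFNoise <- function(n, beta, sd) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (beta == 0) return(w * sd / stats::sd(w))
  k <- seq_len(n) - 1
  fIdx <- pmin(k, n - k)              # symmetric frequency index
  H <- ifelse(fIdx == 0, 0, fIdx^(-beta / 2))
  x <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Truncated-normal draw by rejection.
rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Simulate one participant's EEG recording and behaviour
#'
#' Generates the continuous recording for a full session under `schedule`
#' plus the matching behavioural record. During each stimulation period
#' every presented flicker frequency contributes phase-locked sinusoids
#' at f and 2f whose amplitude depends on whether that frequency was
#' cued; distractor-absent trials contain only the cued frequency. Alpha
#' activity has per-trial random phase, the background is 1/f^beta
#' Gaussian noise, a transient follows each motion onset for 1 s, and
#' artifacts are >150 uV excursions at Poisson times. The trigger channel
#' carries the canonical event codes as rectangular pulses.
#'
#' @param config a [simulationConfig()].
#' @param sched trial schedule from [buildTrialSchedule()].
#' @param seed integer seed; output is a deterministic function of
#'   (config, sched, seed).
#' @param participantId identifier stored in the recording.
#' @return list with elements `recording` ([EEGRecording-class]) and
#'   `behaviour` ([BehaviouralRecord-class]).
#' @export
simulateParticipant <- function(config, sched, seed = 1,
                                participantId = "sub-01") {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    fs <- config$fs
    nCh <- length(config$channels)
    nTrials <- nrow(sched)
    trialDur <- config$cueDur + config$stimDur + config$itiDur
    nSamp <- round(nTrials * trialDur * fs)
    stimSamp <- round(config$stimDur * fs)
    gains <- electrodeGains(config)

    data <- matrix(0, nCh, nSamp)
    for (ch in seq_len(nCh))
      data[ch, ] <- oneOverFNoise(nSamp, config$noiseExponent,
                                  config$noiseScale)
    trig <- numeric(nSamp)

    tRel <- (seq_len(stimSamp) - 1) / fs
    map <- canonicalTriggerMap()
    pulseSamp <- round(0.05 * fs)

    for (tr in seq_len(nTrials)) {
      spec <- sched[tr, ]
      s0 <- round((tr - 1) * trialDur * fs + config$cueDur * fs)
      idx <- s0 + seq_len(stimSamp)

      presented <- data.frame(freq = spec$cued_freq, cued = TRUE)
      if (spec$distractor == "present")
        presented <- rbind(presented,
                           data.frame(freq = spec$uncued_freq, cued = FALSE))
      wave <- numeric(stimSamp)
      g <- if (config$ampJitterSd > 0)
        stats::rnorm(1, 0, config$ampJitterSd) else 0
      for (r in seq_len(nrow(presented))) {
        key <- paste0(ifelse(presented$freq[r] == 6, "6", "7.5"),
                      if (spec$distractor == "absent") "_absent"
                      else if (presented$cued[r]) "_cued" else "_uncued")
        amp <- config$ssvepAmp[[key]]
        if (config$ampJitterSd > 0) {
          sgn <- if (presented$cued[r]) 1 else -1
          amp <- amp * exp(sgn * g - config$ampJitterSd^2 / 2)
        }
        f <- presented$freq[r]
        wave <- wave + amp * (sin(2 * pi * f * tRel) +
                              config$harmonicRatio * sin(2 * pi * 2 * f * tRel))
      }
      if (config$alphaAmp > 0)
        wave <- wave + config$alphaAmp *
          sin(2 * pi * 10 * tRel + stats::runif(1, 0, 2 * pi))
      if (config$erpAmp > 0) {
        for (k in 1:5) {
          on <- spec[[paste0("onset_", k)]]
          ei <- which(tRel >= on & tRel < on + 1)
          wave[ei] <- wave[ei] +
            config$erpAmp * sin(pi * (tRel[ei] - on))
        }
      }
      for (ch in seq_len(nCh)) data[ch, idx] <- data[ch, idx] + gains[ch] * wave

      ev <- encodeTriggers(spec, map, cueDur = config$cueDur,
                           stimDur = config$stimDur)
      for (e in seq_len(nrow(ev))) {
        p0 <- round((tr - 1) * trialDur * fs + ev$time[e] * fs)
        trig[p0 + seq_len(pulseSamp)] <- ev$code[e]
      }
    }

    # artifacts: brief high-amplitude excursions on one channel
    nArt <- stats::rpois(1, config$artifactRate * nSamp / fs / 60)
    if (nArt > 0 && config$artifactAmp > 0) {
      artDurS <- round(0.3 * fs)
      shape <- config$artifactAmp * sin(pi * seq_len(artDurS) / artDurS)^2
      for (a in seq_len(nArt)) {
        a0 <- sample.int(nSamp - artDurS, 1)
        ch <- sample.int(nCh, 1)
        data[ch, a0 + seq_len(artDurS)] <- data[ch, a0 + seq_len(artDurS)] +
          sample(c(-1, 1), 1) * shape
      }
    }

    rownames(data) <- config$channels
    rec <- new("EEGRecording", data = data, trig = trig, fs = fs,
               participantId = participantId)
    behav <- simulateBehaviour(config, sched)
    list(recording = rec, behaviour = behav)
  })
}

# Behavioural generator: draws participant-level accuracy and RT means
# around the configured group values, places key presses in the frame
# stream, then scores them with the same scorer the analysis uses, so
# ACC/RT are consistent with RESPONSE by construction.
simulateBehaviour <- function(config, sched) {
  nTrials <- nrow(sched)
  nFrames <- round(config$stimDur * config$frameRate)
  response <- matrix(0L, nTrials, nFrames)
  pAcc <- rtMean <- numeric(2)
  names(pAcc) <- names(rtMean) <- c("present", "absent")
  for (cond in c("present", "absent")) {
    pAcc[cond] <- rtruncnorm1(config$behavAcc[[cond]],
                              config$behavAccSd[[cond]], 5, 99.9) / 100
    rtMean[cond] <- rtruncnorm1(config$behavRtMean[[cond]],
                                config$behavRtSd[[cond]], 0.30, 1.10)
  }
  rtShift <- 0.2
  sigma <- 0.3
  for (tr in seq_len(nTrials)) {
    cond <- sched$distractor[tr]
    mu <- log(rtMean[cond] - rtShift) - sigma^2 / 2
    for (k in 1:5) {
      onset <- sched[[paste0("onset_", k)]][tr]
      dirKey <- match(sched[[paste0("dir_", k)]][tr], .directionLevels)
      u <- stats::runif(1)
      if (u < pAcc[cond]) key <- dirKey
      else if (u < pAcc[cond] + 0.3 * (1 - pAcc[cond]))
        key <- sample(setdiff(1:4, dirKey), 1)
      else next                                     # miss: no press
      repeat {
        rt <- rtShift + stats::rlnorm(1, mu, sigma)
        if (rt < 1.45) break
      }
      f0 <- round((onset + rt) * config$frameRate) + 1L
      fHold <- f0:min(f0 + 5L, nFrames)
      response[tr, fHold] <- key
    }
  }
  acc <- matrix(0L, nTrials, 5)
  rt <- matrix(NA_real_, nTrials, 5)
  for (tr in seq_len(nTrials)) {
    sc <- scoreResponses(response[tr, ], sched[tr, ],
                         frameRate = config$frameRate)
    acc[tr, ] <- sc$acc
    rt[tr, ] <- sc$rt
  }
  new("BehaviouralRecord", trialTable = sched, acc = acc, rt = rt,
      response = response, frameRate = config$frameRate)
}

#' Simulate a multi-participant study
#'
#' Convenience wrapper: builds one schedule and one recording per
#' participant with seeds derived from `seed`.
#'
#' @param config a [simulationConfig()].
#' @param nParticipants number of participants.
#' @param seed integer base seed.
#' @param nBlocks,trialsPerBlock schedule size (defaults 8 x 20).
#' @return named list (sub-01, sub-02, ...) of lists with elements
#'   `schedule`, `recording` and `behaviour`.
#' @export
simulateStudy <- function(config, nParticipants, seed = 1, nBlocks = 8,
                          trialsPerBlock = 20) {
  out <- vector("list", nParticipants)
  names(out) <- sprintf("sub-%02d", seq_len(nParticipants))
  for (p in seq_len(nParticipants)) {
    sched <- buildTrialSchedule(nBlocks, trialsPerBlock,
                                seed = deriveSeed(seed, 2 * p))
    sim <- simulateParticipant(config, sched, seed = deriveSeed(seed, 2 * p + 1),
                               participantId = names(out)[p])
    out[[p]] <- list(schedule = sched, recording = sim$recording,
                     behaviour = sim$behaviour)
  }
  out
}
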