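# Shared fixtures, built in code. Simulations here use a reduced 16-trial
# session (2 blocks x 8 trials) that still covers all 8 counterbalancing
# cells; full-scale sessions are built inside the tests that need them.

noiselessConfig <- function(...) {
  simulationConfig(noiseScale = 0, alphaAmp = 0, erpAmp = 0,
                   artifactRate = 0, ampJitterSd = 0, ...)
}

smallSchedule <- function(seed = 11) buildTrialSchedule(2, 8, seed = seed)

# One small default-config participant, decoded into trials; memoised so
# several test files can share it.
.fixtureCache <- new.env(parent = emptyenv())
smallParticipant <- function() {
  if (is.null(.fixtureCache$part)) {
    sched <- smallSchedule()
    sim <- simulateParticipant(simulationConfig(), sched, seed = 21,
                               participantId = "sub-01")
    ev <- parseTriggerChannel(triggerChannel(sim$recording),
                              samplingRate(sim$recording))
    trials <- decodeTrials(ev, canonicalTriggerMap(), sim$recording)
    .fixtureCache$part <- list(schedule = sched, sim = sim, events = ev,
                               trials = trials)
  }
  .fixtureCache$part
}

# Minimal schedule row for constructing synthetic specs by hand.
specRow <- function(distractor = "present", cued_colour = "black",
                    pairing = "black6_white7.5",
                    onsets = c(2, 5, 7.5, 10, 12.5),
                    dirs = c(0, 90, 180, 270, 0)) {
  row <- data.frame(block = 1L, trial = 1L, distractor = distractor,
                    cued_colour = cued_colour, pairing = pairing,
                    cued_freq = ifelse((cued_colour == "black") ==
                                         (pairing == "black6_white7.5"),
                                       6.0, 7.5),
                    uncued_freq = NA_real_, stringsAsFactors = FALSE)
  for (k in 1:5) {
    row[[paste0("onset_", k)]] <- onsets[k]
    row[[paste0("dir_", k)]] <- dirs[k]
  }
  row
}

# Hand-built EpochSet around fabricated epoch data.
makeEpochSet <- function(epochs, window, fs = 1200, onset = NULL,
                         trial = NULL, labels = NULL) {
  n <- dim(epochs)[1]
  new("EpochSet", epochs = epochs, fs = fs, window = window, step = 0.25,
      trial = trial %||% rep(1L, n),
      onset = onset %||% rep(0, n),
      labels = labels %||% rep(c("black", "white"), length.out = n),
      strata = data.frame(distractor = rep("present", n),
                          pairing = rep("black6_white7.5", n),
                          stringsAsFactors = FALSE),
      valid = rep(TRUE, n), reason = rep("ok", n))
}

# Hand-built FeatureMatrix for classifier tests: 5 channels x {6, 7.5} Hz.
makeFeatureMatrix <- function(X, y, trial = NULL,
                              distractor = "present",
                              pairing = "black6_white7.5") {
  n <- nrow(X)
  fi <- data.frame(channel = rep(paste0("ch", 1:5), each = 2),
                   freq = rep(c(6.0, 7.5), 5), stringsAsFactors = FALSE)
  stopifnot(ncol(X) == 10)
  new("FeatureMatrix", X = X, featureIndex = fi, variant = "simple",
      y = y, trial = as.integer(trial %||% seq_len(n)),
      strata = data.frame(distractor = rep(distractor, n),
                          pairing = rep(pairing, n),
                          stringsAsFactors = FALSE),
      fs = 1200)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
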