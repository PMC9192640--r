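#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording: a channels-by-samples data
#' matrix in microvolts, an auxiliary trigger channel carrying 8-bit event
#' codes as rectangular voltage pulses from a 0 uV baseline, the sampling
#' rate and channel labels.
#'
#' @slot data numeric matrix, channels x samples, in uV; rownames are the
#'   channel labels.
#' @slot trig numeric vector of trigger-channel samples (0-255 uV).
#' @slot fs sampling rate in Hz.
#' @slot participantId participant identifier, e.g. "sub-01".
#' @export
setClass("EEGRecording",
  representation(data = "matrix", trig = "numeric", fs = "numeric",
                 participantId = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@trig) != ncol(object@data))
    msg <- c(msg, "trig length must equal the sample count")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (is.null(rownames(object@data)))
    msg <- c(msg, "data must carry channel labels as rownames")
  if (length(msg)) msg else TRUE
})

#' Labelled 15 s stimulation trials cut from a recording
#'
#' The stimulation period of every trial of a session, cut from the
#' continuous recording and labelled with the trial schedule.
#'
#' @slot data numeric array, trials x channels x samples (uV).
#' @slot schedule data.frame of trial conditions (one row per trial).
#' @slot fs sampling rate in Hz.
#' @slot t0 numeric vector of trial-onset times (s from recording start).
#' @slot channelLabels character vector of EEG channel labels.
#' @export
setClass("TrialSet",
  representation(data = "array", schedule = "data.frame", fs = "numeric",
                 t0 = "numeric", channelLabels = "character"))

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
  else {
    if (d[1] != nrow(object@schedule))
      msg <- c(msg, "trial count must match the schedule")
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channel count must match channelLabels")
    if (length(object@t0) != d[1])
      msg <- c(msg, "t0 must have one entry per trial")
  }
  if (length(msg)) msg else TRUE
})

#' Sliding-window epochs with validity flags
#'
#' Fixed-length windows slid over labelled trials, before or after
#' artifact and motion-contamination screening.
#'
#' @slot epochs numeric array, epochs x channels x samples (uV).
#' @slot fs sampling rate in Hz.
#' @slot window window length in s.
#' @slot step slide step in s.
#' @slot trial integer vector: source trial index per epoch.
#' @slot onset numeric vector: epoch start within the trial (s).
#' @slot labels character vector: cued colour per epoch.
#' @slot strata data.frame with columns distractor and pairing per epoch.
#' @slot valid logical flags set by the exclusion rules.
#' @slot reason character reason codes: ok, amplitude, motion_overlap,
#'   balance.
#' @export
setClass("EpochSet",
  representation(epochs = "array", fs = "numeric", window = "numeric",
                 step = "numeric", trial = "integer", onset = "numeric",
                 labels = "character", strata = "data.frame",
                 valid = "logical", reason = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array")
  else {
    n <- d[1]
    for (nm in c("trial", "onset", "labels", "valid", "reason"))
      if (length(slot(object, nm)) != n)
        msg <- c(msg, sprintf("%s must have one entry per epoch", nm))
    if (nrow(object@strata) != n)
      msg <- c(msg, "strata must have one row per epoch")
  }
  if (length(msg)) msg else TRUE
})

#' FFT amplitude features with class labels
#'
#' @slot X numeric matrix, epochs x features (uV amplitude).
#' @slot featureIndex data.frame with columns channel and freq describing
#'   each column of X (channel-major, frequency-minor order).
#' @slot variant feature-set variant name.
#' @slot y character vector of class labels (cued colour).
#' @slot trial integer vector: source trial per epoch.
#' @slot strata data.frame with columns distractor and pairing per epoch.
#' @slot fs sampling rate in Hz.
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", featureIndex = "data.frame",
                 variant = "character", y = "character", trial = "integer",
                 strata = "data.frame", fs = "numeric"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@featureIndex) != ncol(object@X))
    msg <- c(msg, "featureIndex must describe every column of X")
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "y must have one label per row of X")
  if (length(object@trial) != nrow(object@X))
    msg <- c(msg, "trial must have one entry per row of X")
  if (length(msg)) msg else TRUE
})

#' Decoding accuracy grid
#'
#' Tidy accuracy table over the decoding design cells.
#'
#' @slot results data.frame with columns participant, classifier, window,
#'   variant, regime, pairing, accuracy (percent) and n_epochs.
#' @export
setClass("DecodingResult", representation(results = "data.frame"))

setValidity("DecodingResult", function(object) {
  need <- c("participant", "classifier", "window", "variant", "regime",
            "pairing", "accuracy", "n_epochs")
  miss <- setdiff(need, names(object@results))
  if (length(miss))
    paste("results is missing columns:", paste(miss, collapse = ", "))
  else if (nrow(object@results) &&
           (any(object@results$accuracy < 0) ||
            any(object@results$accuracy > 100)))
    "accuracy must lie in [0, 100]"
  else TRUE
})

#' Saturating accuracy-vs-window model fit
#'
#' Least-squares fit of ACC = a * (1 - exp(-s * (T - i))), the saturating
#' inverse-exponential model of decoding accuracy as a function of the
#' sliding-window size T.
#'
#' @slot a asymptotic accuracy (percent).
#' @slot s scaling factor (1/s).
#' @slot i x-axis intercept (s); the model value is 0 at T = i.
#' @slot sse residual sum of squares.
#' @slot cov covariance matrix of the estimates (may carry NAs when the
#'   fit is exact).
#' @slot T window sizes used for the fit (s).
#' @slot acc observed accuracies (percent).
#' @slot fitted fitted accuracies (percent).
#' @export
setClass("WindowModelFit",
  representation(a = "numeric", s = "numeric", i = "numeric",
                 sse = "numeric", cov = "matrix", T = "numeric",
                 acc = "numeric", fitted = "numeric"))

setValidity("WindowModelFit", function(object) {
  msg <- character()
  if (object@a <= 0 || object@a > 100) msg <- c(msg, "a must be in (0, 100]")
  if (object@s <= 0) msg <- c(msg, "s must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-participant behavioural record
#'
#' Behavioural data of one session: the trial table, per-target response
#' accuracy codes (0 miss, 1 correct, 2 incorrect), reaction times (s,
#' defined only where the response was correct) and the raw frame-wise
#' key-press stream sampled at the display refresh rate.
#'
#' @slot trialTable data.frame mirroring the trial schedule.
#' @slot acc integer matrix, trials x targets.
#' @slot rt numeric matrix, trials x targets (NA where acc != 1).
#' @slot response integer matrix, trials x frames (0 none, 1..4 the four
#'   arrow keys mapped to 0/90/180/270 degrees).
#' @slot frameRate display refresh rate in Hz.
#' @export
setClass("BehaviouralRecord",
  representation(trialTable = "data.frame", acc = "matrix", rt = "matrix",
                 response = "matrix", frameRate = "numeric"))

setValidity("BehaviouralRecord", function(object) {
  msg <- character()
  if (!all(object@acc %in% 0:2)) msg <- c(msg, "acc codes must be 0, 1 or 2")
  if (!identical(dim(object@acc), dim(object@rt)))
    msg <- c(msg, "acc and rt must have the same shape")
  bad <- !is.na(object@rt) & object@acc != 1L
  if (any(bad)) msg <- c(msg, "rt must be defined only where acc == 1")
  if (any(object@rt[!is.na(object@rt)] <= 0))
    msg <- c(msg, "rt must be positive")
  if (length(msg)) msg else TRUE
})
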