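# Trial schedule, motion-target timing, trigger encoding and behavioural
# scoring for the cued motion-discrimination task: two intermingled
# random-dot fields (black, white) flicker at 6.0 and 7.5 Hz; on each
# trial one colour is cued and five 500 ms coherent-motion targets appear
# in the cued colour only.

.distractorLevels <- c("present", "absent")
.colourLevels     <- c("black", "white")
.pairingLevels    <- c("black6_white7.5", "black7.5_white6")
.directionLevels  <- c(0, 90, 180, 270)

# Flicker frequency of a colour under a pairing.
colourFrequency <- function(colour, pairing) {
  ifelse(pairing == "black6_white7.5",
         ifelse(colour == "black", 6.0, 7.5),
         ifelse(colour == "black", 7.5, 6.0))
}

#' Sample coherent-motion onset times for one trial
#'
#' Onsets are rejection-sampled uniformly over the admissible interval
#' until every spacing constraint holds: each onset falls more than
#' `minAfterOnset` after display onset, more than `minGap` after the
#' offset of the previous 500 ms motion burst, and at least
#' `minBeforeEnd` before the end of the trial.
#'
#' @param duration trial stimulation duration (s).
#' @param nTargets number of motion targets.
#' @param minAfterOnset minimum time after display onset (s).
#' @param minGap minimum gap from previous target offset to next onset (s).
#' @param minBeforeEnd minimum time from onset to trial end (s).
#' @param targetDur coherent-motion burst duration (s).
#' @param maxAttempts rejection-sampling cap.
#' @param seed optional integer seed; NULL draws from the ambient RNG
#'   stream.
#' @return numeric vector of `nTargets` strictly increasing onset times (s).
#' @examples
#' set.seed(42)
#' sampleMotionOnsets()
#' @export
sampleMotionOnsets <- function(duration = 15, nTargets = 5,
                               minAfterOnset = 1.0, minGap = 1.5,
                               minBeforeEnd = 1.5, targetDur = 0.5,
                               maxAttempts = 1e5, seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed, sampleMotionOnsets(duration, nTargets,
                                             minAfterOnset, minGap,
                                             minBeforeEnd, targetDur,
                                             maxAttempts)))
  packing <- minAfterOnset + nTargets * targetDur +
    (nTargets - 1) * minGap + minBeforeEnd
  if (packing > duration)
    stop("infeasible motion-onset constraints: need ", packing,
         " s but trial lasts ", duration, " s")
  lo <- minAfterOnset
  hi <- duration - minBeforeEnd
  for (att in seq_len(maxAttempts)) {
    on <- sort(stats::runif(nTargets, lo, hi))
    if (on[1] > minAfterOnset &&
        (nTargets < 2 || all(diff(on) >= targetDur + minGap)))
      return(on)
  }
  stop("motion-onset sampling failed after ", maxAttempts, " attempts")
}

#' Build a counterbalanced trial schedule
#'
#' Generates the full session schedule: the eight cells of
#' distractor (present, absent) x cued colour (black, white) x
#' colour-flicker pairing occur equally often, motion directions are
#' counterbalanced within every (distractor, pairing) stratum, and
#' motion-onset times satisfy all spacing constraints. Trial order is
#' randomised by `seed`.
#'
#' @param nBlocks number of blocks (default 8).
#' @param trialsPerBlock trials per block (default 20).
#' @param seed integer seed; the schedule is a deterministic function of it.
#' @param duration stimulation duration per trial (s).
#' @return a data.frame with one row per trial: block, trial, distractor,
#'   cued_colour, pairing, cued_freq, uncued_freq (NA when the distractor
#'   is absent), onset_1..onset_5 (s) and dir_1..dir_5 (degrees).
#' @export
buildTrialSchedule <- function(nBlocks = 8, trialsPerBlock = 20, seed = 1,
                               duration = 15) {
  n <- nBlocks * trialsPerBlock
  if (n %% 8L != 0L)
    stop("nBlocks * trialsPerBlock must be divisible by the 8 design cells")
  withSeed(seed, {
    cells <- expand.grid(distractor = .distractorLevels,
                         cued_colour = .colourLevels,
                         pairing = .pairingLevels,
                         stringsAsFactors = FALSE)
    sched <- cells[rep(seq_len(8L), each = n / 8L), ]
    sched <- sched[sample.int(n), , drop = FALSE]
    rownames(sched) <- NULL
    sched$block <- rep(seq_len(nBlocks), each = trialsPerBlock)
    sched$trial <- seq_len(n)
    sched$cued_freq <- colourFrequency(sched$cued_colour, sched$pairing)
    uncol <- ifelse(sched$cued_colour == "black", "white", "black")
    sched$uncued_freq <- ifelse(sched$distractor == "present",
                                colourFrequency(uncol, sched$pairing), NA)
    ons <- t(vapply(seq_len(n),
                    function(i) sampleMotionOnsets(duration = duration),
                    numeric(5)))
    colnames(ons) <- paste0("onset_", 1:5)

    # directions counterbalanced over all targets of each
    # (distractor, pairing) stratum
    dirs <- matrix(NA_real_, n, 5)
    for (d in .distractorLevels) for (p in .pairingLevels) {
      idx <- which(sched$distractor == d & sched$pairing == p)
      nt <- length(idx) * 5L
      pool <- sample(rep(.directionLevels, length.out = nt))
      dirs[idx, ] <- matrix(pool, length(idx), 5, byrow = TRUE)
    }
    colnames(dirs) <- paste0("dir_", 1:5)
    cbind(sched[, c("block", "trial", "distractor", "cued_colour",
                    "pairing", "cued_freq", "uncued_freq")],
          as.data.frame(ons), as.data.frame(dirs))
  })
}

#' Canonical trigger-code map
#'
#' Maps condition tuples to 8-bit trigger codes. Cue onsets use codes
#' 1-8 and trial onsets 11-18 over the (cued frequency x cued colour x
#' distractor) cells; motion onsets use 101-132 with motion direction as
#' a fourth dimension; the feedback code is always 222.
#'
#' @return a list with 3-d arrays `cue_onset` and `trial_onset`
#'   (freq x colour x distractor), a 4-d array `motion_onset`
#'   (freq x colour x distractor x direction) and scalar `feedback`.
#' @export
canonicalTriggerMap <- function() {
  dn3 <- list(freq = c("6", "7.5"), colour = .colourLevels,
              distractor = .distractorLevels)
  base <- array(0L, dim = c(2, 2, 2), dimnames = dn3)
  k <- 0L
  for (d in 1:2) for (co in 1:2) for (f in 1:2) {
    k <- k + 1L
    base[f, co, d] <- k
  }
  motion <- array(0L, dim = c(2, 2, 2, 4),
                  dimnames = c(dn3, list(direction = as.character(
                    .directionLevels))))
  k <- 0L
  for (dir in 1:4) for (d in 1:2) for (co in 1:2) for (f in 1:2) {
    k <- k + 1L
    motion[f, co, d, dir] <- 100L + k
  }
  map <- list(cue_onset = base, trial_onset = base + 10L,
              motion_onset = motion, feedback = 222L)
  validateTriggerMap(map)
  map
}

validateTriggerMap <- function(map) {
  codes <- c(map$cue_onset, map$trial_onset, map$motion_onset, map$feedback)
  if (anyDuplicated(codes)) stop("trigger map contains colliding codes")
  if (any(codes < 1 | codes > 255)) stop("trigger codes must lie in 1-255")
  if (map$feedback != 222L) stop("feedback code must be 222")
  invisible(TRUE)
}

.mapIdx <- function(spec) {
  c(f = if (spec$cued_freq == 6.0) 1L else 2L,
    co = match(spec$cued_colour, .colourLevels),
    d = match(spec$distractor, .distractorLevels))
}

#' Encode one trial as a trigger event stream
#'
#' Produces the per-trial event sequence: one cue onset, one trial
#' (stimulation) onset, five motion onsets and one feedback event, with
#' times relative to cue onset.
#'
#' @param spec one row of a trial schedule (data.frame or list).
#' @param map trigger map (see [canonicalTriggerMap()]).
#' @param cueDur cue duration (s) before stimulation onset.
#' @param stimDur stimulation duration (s).
#' @return data.frame with columns time (s), code (integer) and kind.
#' @export
encodeTriggers <- function(spec, map = canonicalTriggerMap(), cueDur = 2,
                           stimDur = 15) {
  validateTriggerMap(map)
  ix <- .mapIdx(spec)
  ons <- as.numeric(spec[paste0("onset_", 1:5)])
  dirIx <- match(as.numeric(spec[paste0("dir_", 1:5)]), .directionLevels)
  mcodes <- vapply(dirIx, function(k)
    map$motion_onset[ix["f"], ix["co"], ix["d"], k], integer(1))
  data.frame(
    time = c(0, cueDur, cueDur + ons, cueDur + stimDur),
    code = as.integer(c(map$cue_onset[ix["f"], ix["co"], ix["d"]],
                        map$trial_onset[ix["f"], ix["co"], ix["d"]],
                        mcodes, map$feedback)),
    kind = c("cue_onset", "trial_onset", rep("motion_onset", 5), "feedback"),
    stringsAsFactors = FALSE)
}

#' Decode a trigger code back to its condition tuple
#'
#' Inverse of the trigger map: looks a code up in the cue, trial and
#' motion tables.
#'
#' @param code integer trigger code.
#' @param map trigger map.
#' @return list with kind and, where applicable, cued_freq, cued_colour,
#'   distractor and direction.
#' @export
decodeTriggerCode <- function(code, map = canonicalTriggerMap()) {
  freqs <- c(6.0, 7.5)
  for (kind in c("cue_onset", "trial_onset")) {
    hit <- which(map[[kind]] == code, arr.ind = TRUE)
    if (nrow(hit))
      return(list(kind = kind, cued_freq = freqs[hit[1, 1]],
                  cued_colour = .colourLevels[hit[1, 2]],
                  distractor = .distractorLevels[hit[1, 3]]))
  }
  hit <- which(map$motion_onset == code, arr.ind = TRUE)
  if (nrow(hit))
    return(list(kind = "motion_onset", cued_freq = freqs[hit[1, 1]],
                cued_colour = .colourLevels[hit[1, 2]],
                distractor = .distractorLevels[hit[1, 3]],
                direction = .directionLevels[hit[1, 4]]))
  if (code == map$feedback) return(list(kind = "feedback"))
  stop("unknown trigger code: ", code)
}

#' Score a frame-wise response stream against one trial
#'
#' Attributes the first key press within `window` seconds after each
#' motion onset to that target: a press matching the motion direction
#' scores correct (1) with the reaction time from motion onset to key
#' press; a mismatching first press scores incorrect (2); no press in
#' the window scores a miss (0). Presses outside every attribution
#' window are ignored.
#'
#' @param response integer vector of key codes per display frame
#'   (0 none, 1..4 for 0/90/180/270 degrees).
#' @param spec one row of a trial schedule.
#' @param window response-attribution window after motion onset (s).
#' @param frameRate display refresh rate (Hz).
#' @param minGap,targetDur the schedule's spacing constants, used to check
#'   that attribution windows cannot overlap.
#' @return list with integer `acc` (codes 0/1/2) and numeric `rt`
#'   (s, NA unless correct), each of length 5.
#' @export
scoreResponses <- function(response, spec, window = 1.5, frameRate = 120,
                           minGap = 1.5, targetDur = 0.5) {
  if (window > minGap + targetDur)
    stop("attribution window exceeds the minimum onset spacing; ",
         "responses would not attribute uniquely")
  ons <- as.numeric(spec[paste0("onset_", 1:5)])
  dirs <- as.numeric(spec[paste0("dir_", 1:5)])
  keyOf <- match(dirs, .directionLevels)
  acc <- integer(5)
  rt <- rep(NA_real_, 5)
  frameT <- (seq_along(response) - 1) / frameRate
  # a press spanning several frames counts once, at its first frame
  pressStart <- response != 0 & c(TRUE, diff(response) != 0 |
                                    response[-length(response)] == 0)
  for (k in 1:5) {
    inWin <- which(pressStart & frameT > ons[k] & frameT <= ons[k] + window)
    if (!length(inWin)) { acc[k] <- 0L; next }
    first <- inWin[1]
    if (response[first] == keyOf[k]) {
      acc[k] <- 1L
      rt[k] <- frameT[first] - ons[k]
    } else acc[k] <- 2L
  }
  list(acc = acc, rt = rt)
}

#' Serialise a schedule as a tab-separated trial table
#'
#' Writes the schedule with the behavioural-container column conventions:
#' BLOCK, TRIAL, ATTENTIONCOND (1 present, 2 absent), cued/uncued colour
#' and per-colour frequency codes, and motion onsets both as seconds and
#' as display-frame indices.
#'
#' @param sched schedule data.frame from [buildTrialSchedule()].
#' @param path output TSV path.
#' @param frameRate display refresh rate (Hz) for frame indices.
#' @return the written data.frame, invisibly.
#' @export
writeTrialTable <- function(sched, path, frameRate = 120) {
  tt <- data.frame(
    BLOCK = sched$block,
    TRIAL = sched$trial,
    ATTENTIONCOND = match(sched$distractor, .distractorLevels),
    COL_ATTD = match(sched$cued_colour, .colourLevels),
    COL_UNATTD = 3L - match(sched$cued_colour, .colourLevels),
    FREQ_BLACK = ifelse(colourFrequency("black", sched$pairing) == 6, 1L, 2L),
    FREQ_WHITE = ifelse(colourFrequency("white", sched$pairing) == 6, 1L, 2L))
  for (k in 1:5) {
    tt[[paste0("MOVEONSET_S_", k)]] <- sched[[paste0("onset_", k)]]
    tt[[paste0("MOVEFRAME_", k)]] <-
      as.integer(round(sched[[paste0("onset_", k)]] * frameRate)) + 1L
    tt[[paste0("MOVEDIR_", k)]] <- sched[[paste0("dir_", k)]]
  }
  utils::write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tt)
}
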