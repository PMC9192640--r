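# BIDS-EEG I/O: BrainVision (.vhdr/.eeg/.vmrk) reader and writer,
# events/channels sidecars, raw trigger-channel decoding and the HDF5
# behavioural container.

.taskName <- "FeatAttnDec"

# ---- BrainVision ---------------------------------------------------------

parseIniSections <- function(lines) {
  out <- list()
  section <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]][key] <- val
    }
  }
  out
}

#' Write a recording in the BrainVision format
#'
#' Writes the three-file BrainVision set: an INI-style text header
#' (.vhdr), a multiplexed IEEE float32 binary data file (.eeg) holding
#' the EEG channels plus the TRIG channel in uV, and a marker file
#' (.vmrk).
#'
#' @param recording an [EEGRecording-class].
#' @param vhdrPath output header path; .eeg and .vmrk are written next
#'   to it.
#' @return the header path, invisibly.
#' @export
writeBrainVision <- function(recording, vhdrPath) {
  base <- sub("\\.vhdr$", "", basename(vhdrPath))
  dir <- dirname(vhdrPath)
  eegFile <- paste0(base, ".eeg")
  vmrkFile <- paste0(base, ".vmrk")
  labels <- c(channelLabels(recording), "TRIG")
  nCh <- length(labels)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", eegFile),
    paste0("MarkerFile=", vmrkFile),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nCh),
    paste0("SamplingInterval=", sprintf("%.12g", 1e6 / samplingRate(recording))),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nCh), labels))
  writeLines(hdr, vhdrPath, useBytes = FALSE)

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", eegFile),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0")
  writeLines(mrk, file.path(dir, vmrkFile))

  x <- rbind(channelData(recording), triggerChannel(recording))
  con <- file(file.path(dir, eegFile), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(vhdrPath)
}

#' Read a BrainVision recording
#'
#' Parses the .vhdr header and loads the companion binary data file.
#' Supports multiplexed IEEE float32 and int16 (scaled by the
#' per-channel resolution) layouts; the channel labelled TRIG is split
#' off as the trigger channel.
#'
#' @param vhdrPath path to the .vhdr header.
#' @param participantId identifier stored on the recording; defaults to
#'   a sub-* prefix of the filename when present.
#' @return an [EEGRecording-class].
#' @export
readBrainVision <- function(vhdrPath, participantId = NULL) {
  if (!file.exists(vhdrPath)) stop("header not found: ", vhdrPath)
  ini <- parseIniSections(readLines(vhdrPath, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("malformed header: missing [Common Infos]")
  eegPath <- file.path(dirname(vhdrPath), ci[["DataFile"]])
  if (is.na(ci["DataFile"]) || !file.exists(eegPath))
    stop("missing companion data file referenced by DataFile")
  sz <- file.info(eegPath)$size
  if (is.na(sz) || sz == 0) stop("empty data file: ", eegPath)
  if (!identical(toupper(ci[["DataOrientation"]]), "MULTIPLEXED"))
    stop("unsupported DataOrientation: ", ci[["DataOrientation"]])
  nCh <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  fs <- round(fs, 6)
  fmt <- toupper(ini[["Binary Infos"]][["BinaryFormat"]])
  chInfo <- ini[["Channel Infos"]]
  labels <- character(nCh)
  resol <- rep(1, nCh)
  for (k in seq_len(nCh)) {
    parts <- strsplit(chInfo[[paste0("Ch", k)]], ",")[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resol[k] <- as.numeric(parts[3])
  }
  con <- file(eegPath, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    if (sz %% (4L * nCh) != 0)
      stop("data file size is not a whole number of float32 frames")
    raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    if (sz %% (2L * nCh) != 0)
      stop("data file size is not a whole number of int16 frames")
    raw <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  x <- matrix(raw, nrow = nCh)
  x <- x * resol
  rownames(x) <- labels
  isTrig <- labels == "TRIG"
  trig <- if (any(isTrig)) as.numeric(x[which(isTrig)[1], ])
          else numeric(ncol(x))
  data <- x[!isTrig, , drop = FALSE]
  if (is.null(participantId)) {
    m <- regmatches(basename(vhdrPath),
                    regexpr("^sub-[A-Za-z0-9]+", basename(vhdrPath)))
    participantId <- if (length(m)) m else "unknown"
  }
  new("EEGRecording", data = data, trig = trig, fs = fs,
      participantId = participantId)
}

# ---- trigger channel -----------------------------------------------------

#' Decode events from a raw trigger channel
#'
#' Events are rectangular pulses rising from the 0 uV baseline; the
#' plateau amplitude is the trigger value (taken as the median of the
#' samples until the channel returns to 0, rounded to the nearest
#' integer) and the first supra-zero sample marks the event onset.
#'
#' @param trig numeric trigger-channel samples.
#' @param fs sampling rate (Hz).
#' @return data.frame with columns time (s) and code (integer).
#' @export
parseTriggerChannel <- function(trig, fs) {
  nz <- trig != 0
  if (!any(nz)) return(data.frame(time = numeric(), code = integer()))
  starts <- which(nz & !c(FALSE, nz[-length(nz)]))
  ends <- which(!nz & c(FALSE, nz[-length(nz)])) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, length(trig))
  code <- vapply(seq_along(starts), function(k)
    round(stats::median(trig[starts[k]:ends[k]])), numeric(1))
  if (any(code < 0 | code > 255))
    stop("trigger value outside the 8-bit range 0-255")
  data.frame(time = (starts - 1) / fs, code = as.integer(code))
}

#' Cut and label the stimulation period of every trial
#'
#' Uses the decoded event stream to locate every trial onset, checks the
#' trial-onset condition against the preceding cue, and extracts the
#' stimulation-period samples with the condition labels and motion-onset
#' times.
#'
#' @param events data.frame from [parseTriggerChannel()] (columns time,
#'   code).
#' @param map trigger map (see [canonicalTriggerMap()]).
#' @param recording an [EEGRecording-class].
#' @param stimDur stimulation duration (s).
#' @return a [TrialSet-class]; the schedule carries distractor,
#'   cued_colour, pairing, cued_freq, uncued_freq, onset_* and dir_*.
#' @export
decodeTrials <- function(events, map = canonicalTriggerMap(), recording,
                         stimDur = 15) {
  fs <- samplingRate(recording)
  stimSamp <- round(stimDur * fs)
  cueCodes <- as.vector(map$cue_onset)
  trialCodes <- as.vector(map$trial_onset)
  motionCodes <- as.vector(map$motion_onset)
  tix <- which(events$code %in% trialCodes)
  n <- length(tix)
  if (!n) stop("no trial-onset events found")
  dat <- channelData(recording)
  arr <- array(0, dim = c(n, nrow(dat), stimSamp))
  rows <- vector("list", n)
  t0s <- numeric(n)
  for (j in seq_len(n)) {
    e <- tix[j]
    lab <- decodeTriggerCode(events$code[e], map)
    prevCue <- rev(which(events$code[seq_len(e - 1)] %in% cueCodes))
    if (length(prevCue)) {
      cueLab <- decodeTriggerCode(events$code[prevCue[1]], map)
      same <- identical(cueLab[c("cued_freq", "cued_colour", "distractor")],
                        lab[c("cued_freq", "cued_colour", "distractor")])
      if (!same)
        stop("cue/trial trigger condition mismatch at trial ", j)
    }
    t0 <- events$time[e]
    i0 <- round(t0 * fs)
    if (i0 + stimSamp > ncol(dat))
      stop("trial ", j, " extends beyond the end of the recording")
    arr[j, , ] <- dat[, i0 + seq_len(stimSamp), drop = FALSE]
    t0s[j] <- t0
    inTrial <- which(events$code %in% motionCodes &
                       events$time >= t0 & events$time < t0 + stimDur)
    mlab <- lapply(events$code[inTrial], decodeTriggerCode, map = map)
    ons <- events$time[inTrial] - t0
    dirs <- vapply(mlab, function(l) l$direction, numeric(1))
    pairing <- if ((lab$cued_colour == "black") == (lab$cued_freq == 6.0))
      "black6_white7.5" else "black7.5_white6"
    row <- data.frame(trial = j, distractor = lab$distractor,
                      cued_colour = lab$cued_colour, pairing = pairing,
                      cued_freq = lab$cued_freq,
                      uncued_freq = if (lab$distractor == "present")
                        ifelse(lab$cued_freq == 6.0, 7.5, 6.0) else NA_real_,
                      stringsAsFactors = FALSE)
    for (k in seq_len(5)) {
      row[[paste0("onset_", k)]] <- if (k <= length(ons)) ons[k] else NA_real_
      row[[paste0("dir_", k)]] <- if (k <= length(dirs)) dirs[k] else NA_real_
    }
    rows[[j]] <- row
  }
  sched <- do.call(rbind, rows)
  new("TrialSet", data = arr, schedule = sched, fs = fs, t0 = t0s,
      channelLabels = channelLabels(recording))
}

# ---- BIDS dataset --------------------------------------------------------

bidsEegDir <- function(outDir, id) file.path(outDir, id, "eeg")
bidsBehDir <- function(outDir, id) file.path(outDir, id, "beh")
bidsBase <- function(id) sprintf("%s_task-%s", id, .taskName)

#' Write a simulated study as a BIDS-EEG dataset
#'
#' Creates the dataset tree: per participant a BrainVision triple plus
#' _eeg.json, _events.tsv and _channels.tsv sidecars under sub-*/eeg/,
#' and an HDF5 behavioural container (datasets TRIAL_TABLE, RESPONSE,
#' ACC, RT) under sub-*/beh/.
#'
#' @param study named list as returned by [simulateStudy()].
#' @param outDir output directory.
#' @param overwrite overwrite an existing non-empty directory.
#' @return `outDir`, invisibly.
#' @export
writeBidsDataset <- function(study, outDir, overwrite = FALSE) {
  if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
    stop("output directory exists and is not empty: ", outDir,
         " (use overwrite = TRUE)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(Name = "Synthetic feature-based attention SSVEP study",
         BIDSVersion = "1.0.2", DatasetType = "raw",
         GeneratedBy = list(list(Name = "ssvepDecode"))),
    file.path(outDir, "dataset_description.json"), auto_unbox = TRUE,
    pretty = TRUE)
  for (id in names(study)) {
    p <- study[[id]]
    eegDir <- bidsEegDir(outDir, id)
    behDir <- bidsBehDir(outDir, id)
    dir.create(eegDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(behDir, recursive = TRUE, showWarnings = FALSE)
    base <- bidsBase(id)
    writeBrainVision(p$recording, file.path(eegDir, paste0(base, "_eeg.vhdr")))

    rec <- p$recording
    ev <- parseTriggerChannel(triggerChannel(rec), samplingRate(rec))
    utils::write.table(
      data.frame(onset = ev$time, duration = 0.05, value = ev$code),
      file.path(eegDir, paste0(base, "_events.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    labels <- channelLabels(rec)
    utils::write.table(
      data.frame(name = c(labels, "TRIG"),
                 type = c(rep("EEG", length(labels)), "TRIG"),
                 units = "µV",
                 sampling_frequency = samplingRate(rec),
                 status = "good"),
      file.path(eegDir, paste0(base, "_channels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(TaskName = .taskName,
           SamplingFrequency = samplingRate(rec),
           PowerLineFrequency = 50,
           EEGChannelCount = length(labels),
           TriggerChannelCount = 1,
           EEGReference = "earclip",
           HardwareFilters = list(
             BandPass = list(LowCutoff = 1, HighCutoff = 100),
             Notch = list(LowCutoff = 48, HighCutoff = 52)),
           RecordingDuration = ncol(channelData(rec)) / samplingRate(rec)),
      file.path(eegDir, paste0(base, "_eeg.json")), auto_unbox = TRUE,
      pretty = TRUE)
    writeBehaviour(p$behaviour,
                   file.path(behDir, paste0(base, "_behav.h5")))
  }
  invisible(outDir)
}

#' Write a behavioural record as an HDF5 container
#'
#' Datasets: TRIAL_TABLE (compound, one row per trial), RESPONSE
#' (trials x frames key codes at the display frame rate), ACC
#' (trials x targets; 0 miss, 1 correct, 2 incorrect) and RT
#' (trials x targets seconds; NaN where no correct response).
#'
#' @param behaviour a [BehaviouralRecord-class].
#' @param path output .h5 path.
#' @return `path`, invisibly.
#' @export
writeBehaviour <- function(behaviour, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rt <- behaviour@rt
  rt[is.na(rt)] <- NaN
  rhdf5::h5write(behaviour@trialTable, path, "TRIAL_TABLE")
  rhdf5::h5write(behaviour@response, path, "RESPONSE")
  rhdf5::h5write(behaviour@acc, path, "ACC")
  rhdf5::h5write(rt, path, "RT")
  rhdf5::h5write(behaviour@frameRate, path, "FRAMERATE")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a behavioural HDF5 container
#'
#' Validates the coding conventions: ACC values must be 0/1/2 (anything
#' else is an error) and RT should be defined only where ACC == 1
#' (violations raise a warning and the offending RTs are dropped).
#'
#' @param path .h5 path.
#' @return a [BehaviouralRecord-class].
#' @export
readBehaviour <- function(path) {
  if (!file.exists(path)) stop("behavioural container not found: ", path)
  have <- rhdf5::h5ls(path)$name
  need <- c("TRIAL_TABLE", "RESPONSE", "ACC", "RT")
  miss <- setdiff(need, have)
  if (length(miss))
    stop("behavioural container is missing datasets: ",
         paste(miss, collapse = ", "))
  tt <- rhdf5::h5read(path, "TRIAL_TABLE")
  resp <- rhdf5::h5read(path, "RESPONSE")
  acc <- rhdf5::h5read(path, "ACC")
  rt <- rhdf5::h5read(path, "RT")
  fr <- if ("FRAMERATE" %in% have) as.numeric(rhdf5::h5read(path, "FRAMERATE"))
        else 120
  rhdf5::h5closeAll()
  if (!all(acc %in% 0:2))
    stop("ACC contains values outside the {0, 1, 2} coding")
  rt[is.nan(rt)] <- NA_real_
  stray <- !is.na(rt) & acc != 1
  if (any(stray)) {
    warning("RT defined where ACC != 1 for ", sum(stray),
            " targets; dropping those RTs")
    rt[stray] <- NA_real_
  }
  tt <- as.data.frame(tt, stringsAsFactors = FALSE)
  tt[] <- lapply(tt, function(col) { dim(col) <- NULL; col })
  new("BehaviouralRecord", trialTable = tt,
      acc = matrix(as.integer(acc), nrow(acc)), rt = rt,
      response = matrix(as.integer(resp), nrow(resp)), frameRate = fr)
}

#' Structural check of a BIDS dataset tree
#'
#' Verifies that the dataset description and, for every participant, the
#' six EEG files (.vhdr/.eeg/.vmrk, _eeg.json, _events.tsv,
#' _channels.tsv) and the behavioural container are present.
#'
#' @param dir dataset root.
#' @return TRUE invisibly if the tree is complete; otherwise an error
#'   listing the missing files.
#' @export
validateBidsTree <- function(dir) {
  problems <- character()
  if (!file.exists(file.path(dir, "dataset_description.json")))
    problems <- c(problems, "dataset_description.json")
  subs <- list.files(dir, pattern = "^sub-")
  if (!length(subs)) problems <- c(problems, "no sub-* folders")
  for (id in subs) {
    base <- bidsBase(id)
    want <- c(file.path(bidsEegDir(dir, id),
                        paste0(base, c("_eeg.vhdr", "_eeg.eeg", "_eeg.vmrk",
                                       "_eeg.json", "_events.tsv",
                                       "_channels.tsv"))),
              file.path(bidsBehDir(dir, id), paste0(base, "_behav.h5")))
    problems <- c(problems, want[!file.exists(want)])
  }
  if (length(problems))
    stop("incomplete BIDS tree:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Read one participant from a BIDS dataset
#'
#' @param dir dataset root.
#' @param id participant folder name, e.g. "sub-01".
#' @return list with `recording`, `behaviour` and `events`.
#' @export
readBidsParticipant <- function(dir, id) {
  base <- bidsBase(id)
  rec <- readBrainVision(file.path(bidsEegDir(dir, id),
                                   paste0(base, "_eeg.vhdr")),
                         participantId = id)
  beh <- readBehaviour(file.path(bidsBehDir(dir, id),
                                 paste0(base, "_behav.h5")))
  ev <- utils::read.table(file.path(bidsEegDir(dir, id),
                                    paste0(base, "_events.tsv")),
                          header = TRUE, sep = "\t")
  list(recording = rec, behaviour = beh, events = ev)
}
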