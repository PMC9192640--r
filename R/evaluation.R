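# Group-level evaluation: behavioural accuracy/RT summaries, trial-average
# SSVEP amplitude spectra with the cued-vs-uncued attention effect, the
# saturating accuracy-vs-window model, and cross-participant aggregation
# of decoding results.

#' Behavioural accuracy and reaction-time summary
#'
#' Per participant and distractor condition: accuracy is the percentage
#' of targets answered correctly (ACC code 1) and RT is averaged over
#' correct targets only. Group means, SDs and a paired t-test between
#' conditions are attached.
#'
#' @param behaviours list of [BehaviouralRecord-class] (one per
#'   participant); names are used as participant ids.
#' @return list with `perParticipant` (data.frame participant,
#'   distractor, acc, meanRt), `group` (data.frame distractor, meanAcc,
#'   sdAcc, meanRt, sdRt) and `tests` (paired t-tests for acc and RT,
#'   when n > 1).
#' @export
behaviouralSummary <- function(behaviours) {
  ids <- names(behaviours) %||% sprintf("sub-%02d", seq_along(behaviours))
  rows <- list()
  for (i in seq_along(behaviours)) {
    b <- behaviours[[i]]
    cond <- b@trialTable$distractor
    for (dc in unique(cond)) {
      tr <- which(cond == dc)
      acc <- 100 * mean(b@acc[tr, ] == 1L)
      rts <- b@rt[tr, ][b@acc[tr, ] == 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = ids[i], distractor = dc, acc = acc,
        meanRt = mean(rts, na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  pp <- do.call(rbind, rows)
  grp <- do.call(rbind, lapply(split(pp, pp$distractor), function(d)
    data.frame(distractor = d$distractor[1], meanAcc = mean(d$acc),
               sdAcc = stats::sd(d$acc), meanRt = mean(d$meanRt),
               sdRt = stats::sd(d$meanRt), stringsAsFactors = FALSE)))
  rownames(grp) <- NULL
  tests <- NULL
  if (length(behaviours) > 1 &&
      all(c("present", "absent") %in% pp$distractor)) {
    wide <- merge(pp[pp$distractor == "present", ],
                  pp[pp$distractor == "absent", ], by = "participant",
                  suffixes = c(".present", ".absent"))
    if (nrow(wide) > 1) tests <- list(
      acc = stats::t.test(wide$acc.absent, wide$acc.present, paired = TRUE),
      rt = stats::t.test(wide$meanRt.absent, wide$meanRt.present,
                         paired = TRUE))
  }
  list(perParticipant = pp, group = grp, tests = tests)
}

#' Trial-average SSVEP amplitudes and the attention effect
#'
#' Within each (distractor, pairing, cued frequency) cell the trial time
#' series are averaged across trials per electrode, the average is
#' submitted to an FFT without padding, and the amplitudes at 6.0 and
#' 7.5 Hz are read per electrode. Because SSVEPs are phase-locked across
#' trials while alpha and noise are not, trial averaging isolates the
#' tagged responses. The analysis window is truncated to the largest
#' whole multiple of the 2 s common period of the 0.5 Hz frequency grid
#' (14 s of a 15 s trial), so that every tag frequency falls exactly on
#' an FFT bin and the two tags are orthogonal over the window --
#' otherwise the 7.5 Hz tag (112.5 cycles in 15 s) would be read off-bin
#' with spectral leakage.
#'
#' @param trials a [TrialSet-class].
#' @return list with `perElectrode` (data.frame distractor, pairing,
#'   cued_freq, electrode, freq, cued, amplitude), `summary` (amplitude
#'   averaged over electrodes and pairings per (distractor, freq, cued))
#'   and `attentionEffect` (cued minus uncued amplitude per electrode
#'   and distractor condition).
#' @export
ssvepAmplitudes <- function(trials) {
  sch <- schedule(trials)
  labs <- channelLabels(trials)
  fs <- samplingRate(trials)
  # integer-cycle window: whole multiples of the 2 s grid period
  nUse <- max(1, floor(dim(trials@data)[3] / (2 * fs))) * 2 * fs
  rows <- list()
  for (dc in unique(sch$distractor)) for (pr in unique(sch$pairing))
    for (cf in unique(sch$cued_freq)) {
      idx <- which(sch$distractor == dc & sch$pairing == pr &
                     sch$cued_freq == cf)
      if (!length(idx)) next
      avg <- apply(trials@data[idx, , seq_len(nUse), drop = FALSE],
                   c(2, 3), mean)
      sp <- computeSpectrum(avg, fs, padTo = 0)
      for (f in c(6.0, 7.5)) {
        bin <- which.min(abs(sp$freq - f))
        rows[[length(rows) + 1L]] <- data.frame(
          distractor = dc, pairing = pr, cued_freq = cf,
          electrode = labs, freq = f, cued = (f == cf),
          amplitude = sp$amp[, bin], stringsAsFactors = FALSE)
      }
    }
  pe <- do.call(rbind, rows)
  rownames(pe) <- NULL
  summary <- stats::aggregate(amplitude ~ distractor + freq + cued, pe, mean)
  eff <- NULL
  cuedTab <- stats::aggregate(amplitude ~ distractor + electrode,
                              pe[pe$cued, ], mean)
  uncuedTab <- stats::aggregate(amplitude ~ distractor + electrode,
                                pe[!pe$cued, ], mean)
  eff <- merge(cuedTab, uncuedTab, by = c("distractor", "electrode"),
               suffixes = c(".cued", ".uncued"))
  eff$effect <- eff$amplitude.cued - eff$amplitude.uncued
  list(perElectrode = pe, summary = summary, attentionEffect = eff)
}

#' Fit the saturating accuracy-vs-window model
#'
#' Least-squares fit of ACC = a * (1 - exp(-s * (T - i))) by multistart
#' Levenberg-Marquardt over a small grid of starting values, with bounds
#' a in (50, 100], s > 0, i < min(T).
#'
#' @param T window sizes (s), at least 3.
#' @param acc accuracies (percent) at those windows.
#' @return a [WindowModelFit-class].
#' @export
fitWindowModel <- function(T, acc) {
  if (length(T) < 3 || length(T) != length(acc))
    stop("need at least 3 (T, acc) points of equal length")
  if (stats::sd(acc) < 1e-12)
    stop("accuracy is constant across windows; the scaling factor is ",
         "unidentifiable")
  df <- data.frame(T = T, acc = acc)
  starts <- expand.grid(a = c(55, 65, 75), s = c(0.1, 0.5, 2),
                        i = c(-1, 0, 0.2))
  lower <- c(a = 50 + 1e-9, s = 1e-9, i = -1e3)
  upper <- c(a = 100, s = 1e3, i = min(T) - 1e-9)
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    st <- pmin(pmax(unlist(starts[r, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(acc ~ a * (1 - exp(-s * (T - i))), data = df,
                        start = as.list(st), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("window-model fit failed to converge from every start")
  cf <- stats::coef(best$fit)
  cov <- tryCatch(stats::vcov(best$fit),
                  error = function(e) matrix(NA_real_, 3, 3))
  new("WindowModelFit", a = unname(cf["a"]), s = unname(cf["s"]),
      i = unname(cf["i"]), sse = best$sse, cov = cov, T = T, acc = acc,
      fitted = unname(stats::fitted(best$fit)))
}

#' Evaluate the window model
#'
#' @param fit a [WindowModelFit-class].
#' @param T window sizes (s).
#' @return model accuracy (percent) at each T.
#' @export
predictWindowModel <- function(fit, T) {
  fit@a * (1 - exp(-fit@s * (T - fit@i)))
}

#' Window size reaching a fraction of the asymptote
#'
#' Solves a * (1 - exp(-s (T - i))) = q * a for T, giving
#' T = i + ln(1 / (1 - q)) / s.
#'
#' @param fit a [WindowModelFit-class].
#' @param q fraction of the asymptote (default 0.99).
#' @return window size T (s).
#' @export
windowForFraction <- function(fit, q = 0.99) {
  stopifnot(q > 0, q < 1)
  fit@i + log(1 / (1 - q)) / fit@s
}

#' Aggregate decoding results across participants
#'
#' Pairing-averaged accuracies are summarised as group means per
#' (classifier, regime, window, variant), a per-participant maximum
#' accuracy table over (window, variant) per classifier and regime, and
#' Bonferroni-corrected paired t-tests of each classifier against the
#' z-score baseline within the cross-validated regime.
#'
#' @param results list of [DecodingResult-class] or a combined
#'   data.frame of their rows.
#' @return list with `groupMeans`, `maxTable` and `vsZscore`.
#' @export
aggregateResults <- function(results) {
  df <- if (is.data.frame(results)) results
        else do.call(rbind, lapply(results, accuracyTable))
  pa <- stats::aggregate(
    accuracy ~ participant + classifier + window + variant + regime,
    df, mean)  # pairing average
  groupMeans <- stats::aggregate(accuracy ~ classifier + regime + window +
                                   variant, pa, mean)
  groupMeans <- groupMeans[order(groupMeans$regime, groupMeans$classifier,
                                 groupMeans$window, groupMeans$variant), ]
  rownames(groupMeans) <- NULL
  maxTable <- stats::aggregate(accuracy ~ participant + classifier + regime,
                               pa, max)
  vsZscore <- NULL
  cvrows <- pa[pa$regime == "train_present_cv10", ]
  if ("zscore" %in% cvrows$classifier &&
      length(unique(cvrows$participant)) > 1) {
    base <- stats::aggregate(accuracy ~ participant,
                             cvrows[cvrows$classifier == "zscore", ], mean)
    others <- setdiff(unique(cvrows$classifier), "zscore")
    tt <- lapply(others, function(cl) {
      x <- stats::aggregate(accuracy ~ participant,
                            cvrows[cvrows$classifier == cl, ], mean)
      m <- merge(x, base, by = "participant", suffixes = c(".cl", ".z"))
      ht <- tryCatch(stats::t.test(m$accuracy.cl, m$accuracy.z,
                                   paired = TRUE),
                     error = function(e)
                       list(statistic = NA_real_, parameter = NA_real_,
                            p.value = NA_real_))
      data.frame(classifier = cl, meanDiff = mean(m$accuracy.cl -
                                                    m$accuracy.z),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, stringsAsFactors = FALSE)
    })
    vsZscore <- do.call(rbind, tt)
    vsZscore$pBonferroni <- pmin(1, vsZscore$p * nrow(vsZscore))
  }
  list(groupMeans = groupMeans, maxTable = maxTable, vsZscore = vsZscore)
}
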