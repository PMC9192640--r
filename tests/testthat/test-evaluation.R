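# Behavioural summaries, SSVEP amplitude summaries and the window model.

test_that("behavioural summary reproduces hand-counted means", {
  mk <- function(accRow, rtRow, distractor) {
    nT <- length(distractor)
    tt <- data.frame(trial = seq_len(nT), distractor = distractor,
                     stringsAsFactors = FALSE)
    acc <- matrix(rep(accRow, nT), nT, 5, byrow = TRUE)
    rt <- matrix(rep(rtRow, nT), nT, 5, byrow = TRUE)
    new("BehaviouralRecord", trialTable = tt, acc = acc, rt = rt,
        response = matrix(0L, nT, 10), frameRate = 120)
  }
  # participant 1: 3/5 correct on present trials, 4/5 on absent
  b1 <- mk(c(1L, 1L, 1L, 0L, 2L), c(0.5, 0.7, 0.6, NA, NA),
           rep("present", 4))
  b2 <- mk(c(1L, 1L, 1L, 1L, 0L), c(0.4, 0.4, 0.5, 0.3, NA),
           rep("absent", 4))
  sum1 <- behaviouralSummary(list(s1 = b1, s2 = b2))
  pp <- sum1$perParticipant
  expect_equal(pp$acc[pp$participant == "s1"], 60)
  expect_equal(pp$acc[pp$participant == "s2"], 80)
  expect_equal(pp$meanRt[pp$participant == "s1"], mean(c(0.5, 0.7, 0.6)))
  expect_equal(pp$meanRt[pp$participant == "s2"], 0.4)
  expect_equal(sum1$group$meanAcc[sum1$group$distractor == "present"], 60)

  # the class forbids RTs on non-correct targets (Table-3 semantics)
  expect_error(mk(c(0L, 1L, 1L, 1L, 1L), c(0.5, 0.5, 0.5, 0.5, 0.5),
                  rep("present", 2)), "acc == 1")
})

test_that("trial-average spectra recover the generator amplitudes", {
  sched <- smallSchedule(seed = 51)
  sim <- simulateParticipant(noiselessConfig(), sched, seed = 52)
  ev <- parseTriggerChannel(triggerChannel(sim$recording), 1200)
  trials <- decodeTrials(ev, canonicalTriggerMap(), sim$recording)
  ss <- ssvepAmplitudes(trials)
  s <- ss$summary
  get <- function(d, f, cued)
    s$amplitude[s$distractor == d & s$freq == f & s$cued == cued]
  expect_equal(get("present", 6, TRUE), 1.47, tolerance = 1e-6)
  expect_equal(get("present", 6, FALSE), 1.33, tolerance = 1e-6)
  expect_equal(get("present", 7.5, TRUE), 1.05, tolerance = 1e-6)
  expect_equal(get("present", 7.5, FALSE), 0.93, tolerance = 1e-6)
  # absent trials: uncued frequency is at the (zero) noise floor
  expect_lt(get("absent", 6, FALSE), 1e-9)
  expect_lt(get("absent", 7.5, FALSE), 1e-9)

  # attention effect is positive at every electrode and ordered by the
  # generator's electrode gains
  eff <- ss$attentionEffect
  effP <- eff[eff$distractor == "present", ]
  expect_true(all(effP$effect > 0))
  gains <- 1 + 0.1 * c(1, -1, 0.5, -0.5, 0)
  names(gains) <- c("Iz", "O1", "O2", "Oz", "POz")
  expect_equal(order(effP$effect[match(names(gains), effP$electrode)]),
               order(gains))
})

test_that("window model recovers noiseless parameters exactly", {
  T <- c(0.25, 0.5, 1, 2, 4)
  a <- 64.67; s <- 0.5; i <- 0
  acc <- a * (1 - exp(-s * (T - i)))
  fit <- fitWindowModel(T, acc)
  expect_equal(fit@a, a, tolerance = 1e-6)
  expect_equal(fit@s, s, tolerance = 1e-6)
  expect_equal(fit@i, i, tolerance = 1e-6)
  expect_lt(fit@sse, 1e-10)
  # the model value is zero at T = i
  expect_equal(predictWindowModel(fit, fit@i), 0)
  # constant accuracy is degenerate
  expect_error(fitWindowModel(T, rep(60, 5)), "constant")
  expect_error(fitWindowModel(1:2, c(50, 60)), "at least 3")
})

test_that("windowForFraction solves the asymptote-fraction equation", {
  fit <- new("WindowModelFit", a = 64.67, s = log(100) / 10, i = 0,
             sse = 0, cov = matrix(NA_real_, 3, 3),
             T = c(1, 2, 3), acc = c(1, 2, 3), fitted = c(1, 2, 3))
  expect_equal(windowForFraction(fit, 0.99), 10, tolerance = 1e-12)
  expect_equal(windowForFraction(fit, 1e-9), fit@i, tolerance = 1e-6)

  # bisection oracle on a recovered fit
  T <- c(0.25, 0.5, 1, 2, 4)
  fit2 <- fitWindowModel(T, 62 * (1 - exp(-0.8 * (T + 0.1))))
  q <- 0.99
  f <- function(x) predictWindowModel(fit2, x) - q * fit2@a
  lo <- fit2@i; hi <- fit2@i + 1000
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(windowForFraction(fit2, q), (lo + hi) / 2, tolerance = 1e-9)
})

test_that("window-model recovery tolerates small accuracy noise", {
  # the model's operating range: windows up to where it saturates
  T <- seq(0.5, 12, by = 0.5)
  a <- 64.67; s <- log(100) / 11.25; i <- 0
  set.seed(61)
  err <- replicate(30, {
    acc <- a * (1 - exp(-s * (T - i))) + rnorm(length(T), 0, 1)
    fitWindowModel(T, acc)@a - a
  })
  expect_lt(max(abs(err)), 2)
})

test_that("aggregation is invariant to participant order", {
  mkRes <- function(p, shift) {
    grid <- expand.grid(classifier = c("zscore", "lda"), window = c(1, 4),
                        variant = "simple",
                        regime = "train_present_cv10",
                        pairing = c("black6_white7.5", "black7.5_white6"),
                        stringsAsFactors = FALSE)
    grid$participant <- p
    grid$accuracy <- 50 + shift + seq_len(nrow(grid))
    grid$n_epochs <- 100
    new("DecodingResult", results = grid)
  }
  r1 <- mkRes("sub-01", 0); r2 <- mkRes("sub-02", 5); r3 <- mkRes("sub-03", 2)
  a <- aggregateResults(list(r1, r2, r3))
  b <- aggregateResults(list(r3, r1, r2))
  expect_equal(a$groupMeans, b$groupMeans)
  expect_equal(a$maxTable[order(a$maxTable$participant,
                                a$maxTable$classifier), ],
               b$maxTable[order(b$maxTable$participant,
                                b$maxTable$classifier), ],
               ignore_attr = TRUE)
  # max table picks the per-participant maximum of the pairing-averaged
  # accuracies over windows
  df1 <- accuracyTable(r1)
  lda1 <- df1[df1$classifier == "lda", ]
  expected <- max(tapply(lda1$accuracy, lda1$window, mean))
  mt <- a$maxTable
  expect_equal(mt$accuracy[mt$participant == "sub-01" &
                             mt$classifier == "lda"], expected)
})
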