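# Sliding windows, exclusion rules, balancing, spectra, feature assembly.

test_that("epoch counts per trial match the closed form", {
  part <- smallParticipant()
  counts <- c("0.25" = 60, "0.5" = 59, "1" = 57, "2" = 53, "4" = 45)
  for (w in names(counts)) {
    es <- slideEpochs(part$trials, as.numeric(w), whichTrials = 1L)
    expect_equal(dim(epochArray(es))[1], unname(counts[w]))
    expect_equal(dim(epochArray(es))[1],
                 floor((15 - as.numeric(w)) / 0.25) + 1)
  }
  expect_equal(dim(epochArray(slideEpochs(part$trials, 15,
                                          whichTrials = 1L)))[1], 1)
  expect_error(slideEpochs(part$trials, 16, whichTrials = 1L), "exceeds")
})

test_that("amplitude rejection is a strict > 150 uV rule", {
  ep <- array(0, dim = c(3, 2, 10))
  ep[1, 1, 4] <- -151        # excluded
  ep[2, 2, ] <- c(150, -150, rep(0, 8))  # boundary: kept
  es <- rejectAmplitude(makeEpochSet(ep, window = 0.25))
  expect_equal(validFlags(es), c(FALSE, TRUE, TRUE))
  expect_equal(es@reason, c("amplitude", "ok", "ok"))
})

test_that("exclusion flags equal a brute-force rescan on random epochs", {
  set.seed(99)
  n <- 1000
  ep <- array(rnorm(n * 2 * 24, sd = 80), dim = c(n, 2, 24))
  # force boundary cases into the set
  ep[1, , ] <- 150
  ep[2, , ] <- -150
  ep[3, 1, 5] <- 150.0001
  es <- makeEpochSet(ep, window = 1.0,
                     onset = runif(n, 0, 14),
                     trial = rep(1L, n))
  onsets <- matrix(c(2, 5, 7.5, 10, 12.5), nrow = 1)
  es1 <- rejectAmplitude(es)
  es2 <- rejectMotionOverlap(es1, motionOnsets = onsets)

  # independent brute-force oracle
  for (i in seq_len(n)) {
    okAmp <- max(abs(ep[i, , ])) <= 150
    ov <- 0
    for (on in onsets[1, ])
      ov <- ov + max(0, min(es@onset[i] + 1, on + 1) - max(es@onset[i], on))
    okMot <- (ov / 1) <= 1 / 3 + 1e-12
    expect_equal(es2@valid[i], okAmp && okMot)
  }
})

test_that("motion-overlap boundary cases follow the strict 1/3 rule", {
  onsets <- matrix(c(3, 8, 10, 12, 13.4), nrow = 1)
  mk <- function(window, start) {
    es <- makeEpochSet(array(0, dim = c(1, 1, 8)), window = window,
                       onset = start)
    rejectMotionOverlap(es, motionOnsets = onsets)
  }
  expect_false(validFlags(mk(0.25, 3))[1])     # 100% overlap
  expect_true(validFlags(mk(4, 2.5))[1])       # 1.0/4 = 25%
  expect_false(validFlags(mk(2, 3.3))[1])      # 0.7/2 = 35%
  # exactly one third is kept: 1 s window overlapping 1/3 s
  expect_true(validFlags(mk(1, 3 + 2 / 3))[1])
})

test_that("class balancing equalises counts within strata, reproducibly", {
  ep <- array(0, dim = c(220, 1, 4))
  labels <- rep(c("black", "white"), c(120, 100))
  es <- makeEpochSet(ep, window = 0.25, labels = labels)
  b1 <- balanceClasses(es, seed = 4)
  expect_equal(as.integer(table(b1@labels[b1@valid])), c(100L, 100L))
  expect_equal(sum(b1@reason == "balance"), 20)
  b2 <- balanceClasses(es, seed = 4)
  expect_identical(validFlags(b1), validFlags(b2))
  expect_false(identical(validFlags(b1),
                         validFlags(balanceClasses(es, seed = 5))))
  # already-equal classes are untouched
  esEq <- makeEpochSet(ep[1:200, , , drop = FALSE], window = 0.25,
                       labels = rep(c("black", "white"), 100))
  expect_true(all(validFlags(balanceClasses(esEq, seed = 1))))
})

test_that("computeSpectrum matches a direct DFT with 2/N_signal scaling", {
  fs <- 1200
  # 2 s pure 6 Hz sinusoid of amplitude A: integer cycles, exact bin
  A <- 2.7
  x <- A * sin(2 * pi * 6 * (0:(2 * fs - 1)) / fs)
  sp <- computeSpectrum(x, fs)
  expect_equal(sp$amp[1, which.min(abs(sp$freq - 6))], A, tolerance = 1e-9)
  expect_equal(sp$freq[2] - sp$freq[1], 0.5)

  # zero epoch
  expect_true(all(computeSpectrum(numeric(300), fs)$amp == 0))

  # 0.25 s epoch padded to 2 s: equals the brute-force DFT of the padded
  # vector under the same scaling
  set.seed(7)
  y <- rnorm(300)
  sp <- computeSpectrum(y, fs)
  pad <- c(y, numeric(2 * fs - 300))
  k <- which.min(abs(sp$freq - 6))
  n <- length(pad)
  Xk <- sum(pad * exp(-2i * pi * (k - 1) * (0:(n - 1)) / n))
  expect_equal(sp$amp[1, k], 2 / 300 * Mod(Xk), tolerance = 1e-9)
})

test_that("the spectrum preserves signal energy (Parseval)", {
  fs <- 1200
  set.seed(8)
  x <- rnorm(2 * fs)
  sp <- computeSpectrum(x, fs, padTo = 0)
  N <- length(x)
  mag2 <- (sp$amp[1, ] * N / 2)^2       # |X_k|^2 on the single side
  nyq <- N / 2 + 1
  total <- mag2[1] + mag2[nyq] + 2 * sum(mag2[2:(nyq - 1)])
  expect_equal(total / N, sum(x^2), tolerance = 1e-6)
})

test_that("feature matrices have the advertised dimensions and order", {
  part <- smallParticipant()
  es <- slideEpochs(part$trials, 1.0, whichTrials = 1:2)
  fmS <- buildFeatures(es, "simple")
  expect_equal(ncol(featureData(fmS)), 10)     # 2 freqs x 5 channels
  fmA <- buildFeatures(es, "simple+alpha+harmonic")
  expect_equal(ncol(featureData(fmA)), 65)     # (2+2+9) x 5
  expect_equal(ncol(featureData(buildFeatures(es, "simple+harmonic"))), 20)
  expect_equal(ncol(featureData(buildFeatures(es, "simple+alpha"))), 55)

  # channel-major, frequency-minor ordering
  fi <- featureIndex(fmA)
  expect_equal(fi$freq[1:13], c(6, 7.5, 12, 15, seq(8, 12, 0.5)))
  expect_equal(unique(fi$channel), c("Iz", "O1", "O2", "Oz", "POz"))

  # permuting channels permutes feature blocks identically
  perm <- c(3, 1, 2, 5, 4)
  esP <- es
  esP@epochs <- es@epochs[, perm, , drop = FALSE]
  fmP <- buildFeatures(esP, "simple")
  blocks <- function(X, ch) X[, (ch - 1) * 2 + 1:2]
  for (j in seq_along(perm))
    expect_equal(blocks(featureData(fmP), j),
                 blocks(featureData(fmS), perm[j]), ignore_attr = TRUE)

  # feature values equal the padded-FFT spectrum read at the grid bins
  sp <- computeSpectrum(es@epochs[5, , ], samplingRate(part$trials))
  for (ch in 1:5) for (f in c(6, 7.5))
    expect_equal(featureData(fmS)[5, (ch - 1) * 2 + (f == 7.5) + 1],
                 sp$amp[ch, which.min(abs(sp$freq - f))],
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the extraction pipeline screens, balances and labels epochs", {
  part <- smallParticipant()
  sch <- schedule(part$trials)
  idx <- which(sch$pairing == "black6_white7.5" &
                 sch$distractor == "present")
  fm <- extractFeatureMatrix(subsetTrials(part$trials, idx), 1.0, "simple",
                             seed = 2)
  tab <- table(classLabels(fm))
  expect_equal(unname(tab[1]), unname(tab[2]))  # balanced
  expect_true(all(fm@strata$distractor == "present"))
  expect_true(all(fm@strata$pairing == "black6_white7.5"))
  # every epoch's label matches its trial's cued colour
  sub <- schedule(subsetTrials(part$trials, idx))
  expect_equal(classLabels(fm), sub$cued_colour[fm@trial])
})
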