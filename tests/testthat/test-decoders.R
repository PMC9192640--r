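# Classifiers and training regimes.

test_that("z-score classifier equals an independently coded oracle", {
  set.seed(123)
  n <- 500
  # amplitudes: lognormal-ish positive features, 5 channels x 2 freqs
  X <- matrix(exp(rnorm(n * 10, 0, 0.4)), n, 10)
  y <- rep(c("black", "white"), length.out = n)
  fm <- makeFeatureMatrix(X, y)
  st <- populationStats(fm)
  pred <- zscoreClassify(fm, st, seed = 17)

  # oracle: recompute from first principles
  a6 <- rowMeans(X[, seq(1, 9, 2)])
  a75 <- rowMeans(X[, seq(2, 10, 2)])
  z6 <- (a6 - mean(a6)) / sd(a6)
  z75 <- (a75 - mean(a75)) / sd(a75)
  oracle <- ifelse(z6 > z75, "black", "white")   # pairing black6_white7.5
  expect_identical(pred, oracle)

  # constructed cases
  Xc <- matrix(rep(colMeans(X), 2), 2, 10, byrow = TRUE)
  Xc[2, seq(1, 9, 2)] <- mean(a6) + 2 * sd(a6)
  fmc <- makeFeatureMatrix(Xc, c("black", "white"))
  expect_equal(zscoreClassify(fmc, st, seed = 3)[2], "black")
  # exact tie: seeded fair coin, deterministic under the seed
  t1 <- zscoreClassify(fmc, st, seed = 3)[1]
  expect_identical(t1, zscoreClassify(fmc, st, seed = 3)[1])
  expect_true(t1 %in% c("black", "white"))
})

test_that("degenerate populations are an error", {
  X <- matrix(1, 20, 10)
  fm <- makeFeatureMatrix(X, rep(c("black", "white"), 10))
  expect_error(populationStats(fm), "degenerate")
})

test_that("all six classifiers solve a widely separated two-class problem", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c("black", "white"), each = n / 2)
  X[y == "black", seq(1, 9, 2)] <- X[y == "black", seq(1, 9, 2)] + 10
  X[y == "white", seq(2, 10, 2)] <- X[y == "white", seq(2, 10, 2)] + 10
  Xt <- matrix(rnorm(40 * 10), 40, 10)
  yt <- rep(c("black", "white"), each = 20)
  Xt[yt == "black", seq(1, 9, 2)] <- Xt[yt == "black", seq(1, 9, 2)] + 10
  Xt[yt == "white", seq(2, 10, 2)] <- Xt[yt == "white", seq(2, 10, 2)] + 10
  for (kind in c("lda", "lr", "svm", "mlp", "knn")) {
    model <- trainClassifier(kind, X, y, seed = 9)
    expect_identical(predictClassifier(model, Xt), yt)
  }
  st <- populationStats(makeFeatureMatrix(X, y))
  expect_identical(zscoreClassify(makeFeatureMatrix(Xt, yt), st, seed = 1),
                   yt)
  expect_error(trainClassifier("lda", X, rep("black", n)), "single class")
})

test_that("label permutation yields chance accuracy for every classifier", {
  set.seed(31)
  nTrials <- 40
  perTrial <- 10
  n <- nTrials * perTrial
  X <- matrix(exp(rnorm(n * 10, 0, 0.3)), n, 10)
  trial <- rep(seq_len(nTrials), each = perTrial)
  y <- rep(sample(rep(c("black", "white"), nTrials / 2)), each = perTrial)
  fm <- makeFeatureMatrix(X, y, trial = trial)
  ciHalf <- 100 * qnorm(0.995) * sqrt(0.25 / n)
  for (kind in c("zscore", "lda", "lr", "svm", "mlp", "knn")) {
    acc <- crossvalidatePresent(fm, kind, k = 10, seed = 13)
    expect_lt(abs(as.numeric(acc) - 50), ciHalf + 1e-9,
              label = paste(kind, "accuracy", round(as.numeric(acc), 2)))
  }
})

test_that("LDA predictions follow the pooled-covariance closed form", {
  set.seed(77)
  n <- 100
  mu1 <- c(1, 0); mu2 <- c(-1, 0.5)
  S <- matrix(c(1, 0.3, 0.3, 0.6), 2)
  L <- chol(S)
  X <- rbind(matrix(rnorm(n * 2), n) %*% L + rep(mu1, each = n),
             matrix(rnorm(n * 2), n) %*% L + rep(mu2, each = n))
  y <- rep(c("a", "b"), each = n)
  model <- trainClassifier("lda", X, y)
  pred <- predictClassifier(model, X)

  # closed form: w = S_pooled^-1 (mu1 - mu2), threshold at the midpoint
  m1 <- colMeans(X[1:n, ]); m2 <- colMeans(X[n + 1:n, ])
  Sp <- (crossprod(sweep(X[1:n, ], 2, m1)) +
         crossprod(sweep(X[n + 1:n, ], 2, m2))) / (2 * n - 2)
  w <- solve(Sp, m1 - m2)
  score <- as.vector(X %*% w) - sum(w * (m1 + m2)) / 2
  expect_identical(pred, ifelse(score > 0, "a", "b"))
})

test_that("trial-wise folds never leak trials between train and test", {
  part <- smallParticipant()
  sch <- schedule(part$trials)
  idx <- which(sch$pairing == sch$pairing[1] & sch$distractor == "present")
  fm <- extractFeatureMatrix(subsetTrials(part$trials, idx), 0.5, "simple",
                             seed = 1)
  acc <- crossvalidatePresent(fm, "lda", k = 4, seed = 2, foldAudit = TRUE)
  folds <- attr(acc, "folds")
  allTrials <- sort(unique(fm@trial))
  expect_equal(unname(sort(unlist(folds))), allTrials)      # a partition
  for (j in seq_along(folds)) {
    train <- setdiff(allTrials, folds[[j]])
    expect_length(intersect(train, folds[[j]]), 0)
  }
  # epochs duplicated within a trial still cannot leak
  fm2 <- fm
  fm2@X <- rbind(fm@X, fm@X)
  fm2@y <- c(fm@y, fm@y)
  fm2@trial <- c(fm@trial, fm@trial)
  fm2@strata <- rbind(fm@strata, fm@strata)
  acc2 <- crossvalidatePresent(fm2, "lda", k = 4, seed = 2,
                               foldAudit = TRUE)
  expect_equal(unname(sort(unlist(attr(acc2, "folds")))), allTrials)

  expect_error(crossvalidatePresent(fm, "lda", k = 100), "fewer distinct")
})

test_that("noiseless simulated trials decode perfectly", {
  sched <- smallSchedule(seed = 41)
  sim <- simulateParticipant(noiselessConfig(), sched, seed = 42)
  ev <- parseTriggerChannel(triggerChannel(sim$recording), 1200)
  trials <- decodeTrials(ev, canonicalTriggerMap(), sim$recording)
  sch <- schedule(trials)
  idx <- which(sch$pairing == "black6_white7.5" &
                 sch$distractor == "present")
  fm <- extractFeatureMatrix(subsetTrials(trials, idx), 1.0, "simple",
                             seed = 1)
  # amplitudes are exactly class-determined; nearest neighbour is exact
  acc <- crossvalidatePresent(fm, "knn", k = 4, seed = 3)
  expect_equal(as.numeric(acc), 100)
})

test_that("decoding results are deterministic under fixed seeds", {
  part <- smallParticipant()
  sch <- schedule(part$trials)
  idx <- which(sch$pairing == sch$pairing[1] & sch$distractor == "present")
  fm <- extractFeatureMatrix(subsetTrials(part$trials, idx), 2.0, "simple",
                             seed = 6)
  for (kind in c("zscore", "lr", "mlp")) {
    a <- crossvalidatePresent(fm, kind, k = 4, seed = 8)
    b <- crossvalidatePresent(fm, kind, k = 4, seed = 8)
    expect_identical(as.numeric(a), as.numeric(b))
  }
})

test_that("train-absent/test-present uses disjoint trial sets", {
  part <- smallParticipant()
  sch <- schedule(part$trials)
  pr <- sch$pairing[1]
  presIdx <- which(sch$pairing == pr & sch$distractor == "present")
  absIdx <- which(sch$pairing == pr & sch$distractor == "absent")
  expect_length(intersect(presIdx, absIdx), 0)
  fmP <- extractFeatureMatrix(subsetTrials(part$trials, presIdx), 2.0,
                              "simple", seed = 1)
  fmA <- extractFeatureMatrix(subsetTrials(part$trials, absIdx), 2.0,
                              "simple", seed = 1)
  for (kind in c("zscore", "lda")) {
    acc <- trainAbsentTestPresent(fmA, fmP, kind, seed = 2)
    expect_true(as.numeric(acc) >= 0 && as.numeric(acc) <= 100)
    expect_equal(attr(acc, "n"), nrow(featureData(fmP)))
  }
})

test_that("runGrid fills every requested cell for both pairings", {
  part <- smallParticipant()
  res <- runGrid(part$trials, participant = "sub-01",
                 classifiers = c("zscore", "lda"),
                 windows = c(1, 4), variants = c("simple"),
                 k = 4, seed = 5)
  df <- accuracyTable(res)
  # 2 classifiers x 2 windows x 2 regimes x 2 pairings
  expect_equal(nrow(df), 16)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 100))
  pa <- pairingAverage(res)
  expect_equal(nrow(pa), 8)
  one <- df[df$classifier == "lda" & df$window == 4 &
              df$regime == "train_present_cv10", ]
  expect_equal(pa$accuracy[pa$classifier == "lda" & pa$window == 4 &
                             pa$regime == "train_present_cv10"],
               mean(one$accuracy))
})
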