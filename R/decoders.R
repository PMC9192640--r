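# The six classification approaches (z-score difference, LDA, logistic
# regression by SGD, RBF-SVM, 2x10 MLP, 1-NN) and the two training
# regimes: 10-fold trial-wise cross-validation on distractor-present
# data, and a single train-on-absent / test-on-present pass. Classifiers
# are always fitted within one colour-flicker pairing; pairing-averaged
# accuracies are the benchmark summary.

.classifierKinds <- c("zscore", "lda", "lr", "svm", "mlp", "knn")
.regimes <- c("train_present_cv10", "train_absent_test_present")

# ---- z-score difference --------------------------------------------------

#' Population statistics of channel-averaged SSVEP amplitudes
#'
#' For each (frequency, distractor, pairing) cell, the mean and SD over
#' epochs of the channel-averaged FFT amplitude at that flicker
#' frequency. These are the normalising populations of the z-score
#' difference classifier.
#'
#' @param fm a [FeatureMatrix-class] of training epochs whose variant
#'   includes the 6.0 and 7.5 Hz features.
#' @return data.frame with columns distractor, pairing, freq, mean, sd.
#' @export
populationStats <- function(fm) {
  out <- list()
  key <- paste(fm@strata$distractor, fm@strata$pairing)
  for (s in unique(key)) {
    rows <- which(key == s)
    for (f in c(6.0, 7.5)) {
      a <- rowMeans(fm@X[rows, fm@featureIndex$freq == f, drop = FALSE])
      sd <- stats::sd(a)
      if (!is.finite(sd) || sd <= 0)
        stop("degenerate amplitude population (sd = 0) for ", s,
             " at ", f, " Hz")
      out[[length(out) + 1L]] <- data.frame(
        distractor = fm@strata$distractor[rows[1]],
        pairing = fm@strata$pairing[rows[1]],
        freq = f, mean = mean(a), sd = sd, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify epochs by the z-score difference rule
#'
#' Channel-averaged SSVEP amplitudes at 6.0 and 7.5 Hz are z-scored
#' against the training populations of the epoch's (distractor, pairing)
#' cell; the flicker frequency with the larger z-score is classified as
#' attended and mapped to its colour under the pairing. Exact ties are
#' broken by a seeded fair coin.
#'
#' @param fm a [FeatureMatrix-class] of epochs to classify.
#' @param stats population statistics from [populationStats()].
#' @param seed seed for tie-breaking.
#' @return character vector of predicted cued colours.
#' @export
zscoreClassify <- function(fm, stats, seed = 1) {
  a6 <- rowMeans(fm@X[, fm@featureIndex$freq == 6.0, drop = FALSE])
  a75 <- rowMeans(fm@X[, fm@featureIndex$freq == 7.5, drop = FALSE])
  n <- nrow(fm@X)
  pred <- character(n)
  withSeed(seed, {
    for (i in seq_len(n)) {
      st <- stats[stats$distractor == fm@strata$distractor[i] &
                    stats$pairing == fm@strata$pairing[i], ]
      if (nrow(st) < 2)
        stop("no population statistics for stratum ",
             fm@strata$distractor[i], "/", fm@strata$pairing[i])
      z6 <- (a6[i] - st$mean[st$freq == 6.0]) / st$sd[st$freq == 6.0]
      z75 <- (a75[i] - st$mean[st$freq == 7.5]) / st$sd[st$freq == 7.5]
      winFreq <- if (z6 > z75) 6.0 else if (z75 > z6) 7.5
                 else sample(c(6.0, 7.5), 1)
      pred[i] <- if (fm@strata$pairing[i] == "black6_white7.5")
        (if (winFreq == 6.0) "black" else "white")
      else
        (if (winFreq == 6.0) "white" else "black")
    }
  })
  pred
}

# ---- feature standardisation --------------------------------------------

.fitScaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
.applyScaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# ---- model fitting -------------------------------------------------------

#' Train one classifier
#'
#' Families: `lda` (pooled-covariance linear discriminant), `lr`
#' (logistic regression fitted by stochastic gradient descent with L2
#' penalty lambda = 1/n), `svm` (RBF kernel; kernel scale from the
#' median pairwise distance of up to 1000 subsampled training points),
#' `mlp` (fully connected 2x10 tanh network with a sigmoid output,
#' trained by batch gradient descent with momentum and an adaptive
#' learning rate on squared-error loss) and `knn` (1-nearest neighbour,
#' Euclidean). Features are standardised by training-set statistics for
#' the scale-sensitive families (lr, svm, mlp, knn); LDA consumes raw
#' amplitudes.
#'
#' @param kind one of "lda", "lr", "svm", "mlp", "knn".
#' @param X numeric training matrix (epochs x features).
#' @param y class labels (two classes).
#' @param seed integer seed for stochastic fitting.
#' @return an opaque model object for [predictClassifier()].
#' @export
trainClassifier <- function(kind, X, y, seed = 1) {
  kind <- match.arg(kind, setdiff(.classifierKinds, "zscore"))
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) < 2) stop("training set contains a single class")
  model <- switch(kind,
    lda = list(fit = MASS::lda(X, grouping = factor(y, levels = lev))),
    lr = withSeed(seed, .fitLogisticSGD(X, y, lev)),
    svm = withSeed(seed, .fitSvmRbf(X, y, lev)),
    mlp = withSeed(seed, .fitMlp(X, y, lev)),
    knn = .fitKnn(X, y, lev))
  structure(c(model, list(kind = kind, levels = lev)), class = "ssvepModel")
}

.fitLogisticSGD <- function(X, y, lev, passes = 200) {
  sc <- .fitScaler(X)
  Xs <- cbind(1, .applyScaler(X, sc))
  yy <- as.numeric(y == lev[2])
  n <- nrow(Xs); p <- ncol(Xs)
  lambda <- 1 / n
  w <- numeric(p)
  t <- 0
  for (pass in seq_len(passes)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 0.5 / (1 + 0.005 * t)
      mu <- 1 / (1 + exp(-sum(Xs[i, ] * w)))
      g <- (mu - yy[i]) * Xs[i, ]
      g[-1] <- g[-1] + lambda * w[-1]       # do not penalise the bias
      w <- w - eta * g
    }
  }
  list(w = w, scaler = sc)
}

.fitSvmRbf <- function(X, y, lev) {
  sc <- .fitScaler(X)
  Xs <- .applyScaler(X, sc)
  sub <- if (nrow(Xs) > 1000) Xs[sample.int(nrow(Xs), 1000), , drop = FALSE]
         else Xs
  md <- stats::median(stats::dist(sub))
  if (!is.finite(md) || md <= 0) md <- 1
  fit <- e1071::svm(Xs, factor(y, levels = lev), kernel = "radial",
                    gamma = 1 / (2 * md^2), scale = FALSE)
  list(fit = fit, scaler = sc)
}

.fitKnn <- function(X, y, lev) {
  sc <- .fitScaler(X)
  list(train = .applyScaler(X, sc), y = factor(y, levels = lev), scaler = sc)
}

# 2x10 tanh network, sigmoid output, squared-error loss; batch gradient
# descent with momentum 0.9 and an adaptive learning rate (grow 1.05 on
# improvement; shrink 0.7 and reject the step when the loss rises by
# more than 4%).
.fitMlp <- function(X, y, lev, hidden = c(10, 10), maxPasses = 500,
                    tol = 1e-6, patience = 20) {
  sc <- .fitScaler(X)
  Xs <- .applyScaler(X, sc)
  yy <- as.numeric(y == lev[2])
  n <- nrow(Xs)
  sizes <- c(ncol(Xs), hidden, 1)
  W <- V <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::runif((sizes[l] + 1) * sizes[l + 1], -0.5, 0.5) /
                       sqrt(sizes[l] + 1), sizes[l] + 1, sizes[l + 1])
    V[[l]] <- W[[l]] * 0
  }
  forward <- function(W) {
    A <- list(Xs)
    for (l in 1:2) A[[l + 1]] <- tanh(cbind(1, A[[l]]) %*% W[[l]])
    z <- cbind(1, A[[3]]) %*% W[[3]]
    A[[4]] <- 1 / (1 + exp(-z))
    A
  }
  lossOf <- function(A) mean((A[[4]] - yy)^2)
  A <- forward(W)
  loss <- lossOf(A)
  lr <- 0.05
  mom <- 0.9
  best <- loss
  sinceBest <- 0
  for (pass in seq_len(maxPasses)) {
    out <- A[[4]]
    d <- 2 * (out - yy) / n * out * (1 - out)          # n x 1
    grads <- vector("list", 3)
    delta <- d
    for (l in 3:1) {
      grads[[l]] <- crossprod(cbind(1, A[[l]]), delta)
      if (l > 1)
        delta <- (delta %*% t(W[[l]][-1, , drop = FALSE])) *
          (1 - A[[l]]^2)
    }
    Wnew <- W
    for (l in 1:3) {
      V[[l]] <- mom * V[[l]] - lr * grads[[l]]
      Wnew[[l]] <- W[[l]] + V[[l]]
    }
    Anew <- forward(Wnew)
    lossNew <- lossOf(Anew)
    if (lossNew > loss * 1.04) {
      lr <- lr * 0.7
      V <- lapply(V, function(v) v * 0)
    } else {
      if (lossNew < loss) lr <- lr * 1.05
      W <- Wnew; A <- Anew; loss <- lossNew
    }
    if (best - loss > tol) { best <- loss; sinceBest <- 0 }
    else {
      sinceBest <- sinceBest + 1
      if (sinceBest >= patience) break
    }
  }
  list(W = W, scaler = sc)
}

#' Predict labels from a trained classifier
#'
#' @param model object from [trainClassifier()].
#' @param X numeric matrix of epochs to classify.
#' @return character vector of predicted labels.
#' @export
predictClassifier <- function(model, X) {
  lev <- model$levels
  switch(model$kind,
    lda = as.character(stats::predict(model$fit, X)$class),
    lr = {
      Xs <- cbind(1, .applyScaler(X, model$scaler))
      ifelse(as.vector(Xs %*% model$w) > 0, lev[2], lev[1])
    },
    svm = as.character(stats::predict(model$fit,
                                      .applyScaler(X, model$scaler))),
    mlp = {
      A <- .applyScaler(X, model$scaler)
      for (l in 1:2) A <- tanh(cbind(1, A) %*% model$W[[l]])
      z <- cbind(1, A) %*% model$W[[3]]
      ifelse(as.vector(1 / (1 + exp(-z))) > 0.5, lev[2], lev[1])
    },
    knn = as.character(class::knn(model$train,
                                  .applyScaler(X, model$scaler),
                                  model$y, k = 1)))
}

# ---- training regimes ----------------------------------------------------

# Partition unique trials into k folds, stratified by the trial's class
# label so every training split stays near-balanced (as MATLAB's
# cvpartition does).
.trialFolds <- function(trials, k, seed, labels = NULL) {
  u <- unique(trials)
  if (length(u) < k)
    stop("fewer distinct trials (", length(u), ") than folds (", k, ")")
  withSeed(seed, {
    if (is.null(labels)) {
      u <- sample(u)
      return(split(u, rep(seq_len(k), length.out = length(u))))
    }
    lab <- labels[match(u, trials)]
    # deal the shuffled trials of each class into folds in one continuing
    # sequence, so folds are class-balanced and none is left empty
    ordered <- unlist(lapply(sample(unique(lab)), function(cl)
      sample(u[lab == cl])))
    foldId <- sample(k)[1 + (seq_along(ordered) - 1) %% k]
    split(ordered, foldId)
  })
}

#' Trial-wise k-fold cross-validated accuracy
#'
#' Folds partition trial indices, so overlapping epochs from one trial
#' never span the train and test sets. The z-score classifier recomputes
#' its population statistics from the training trials of each fold.
#'
#' @param fm a [FeatureMatrix-class] (one distractor condition and one
#'   pairing for the benchmark regime).
#' @param kind classifier kind, including "zscore".
#' @param k number of folds.
#' @param seed integer seed (fold shuffle and stochastic fitting).
#' @param foldAudit when TRUE, also return the fold assignment for
#'   leakage audits.
#' @return accuracy in percent (with attributes `n` = epochs tested and,
#'   if requested, `folds`).
#' @export
crossvalidatePresent <- function(fm, kind, k = 10, seed = 1,
                                 foldAudit = FALSE) {
  kind <- match.arg(kind, .classifierKinds)
  folds <- .trialFolds(fm@trial, k, seed, labels = fm@y)
  correct <- 0L
  total <- 0L
  for (j in seq_along(folds)) {
    testRows <- fm@trial %in% folds[[j]]
    trainRows <- !testRows
    if (kind == "zscore") {
      st <- populationStats(.subsetFeatures(fm, trainRows))
      pred <- zscoreClassify(.subsetFeatures(fm, testRows), st,
                             seed = deriveSeed(seed, j))
    } else {
      model <- trainClassifier(kind, fm@X[trainRows, , drop = FALSE],
                               fm@y[trainRows], seed = deriveSeed(seed, j))
      pred <- predictClassifier(model, fm@X[testRows, , drop = FALSE])
    }
    correct <- correct + sum(pred == fm@y[testRows])
    total <- total + sum(testRows)
  }
  acc <- 100 * correct / total
  attr(acc, "n") <- total
  if (foldAudit) attr(acc, "folds") <- folds
  acc
}

#' Train on distractor-absent, test on distractor-present
#'
#' A single fit on all distractor-absent epochs of a pairing, tested
#' once on all distractor-present epochs of the same pairing.
#'
#' @param fmAbsent training [FeatureMatrix-class] (distractor absent).
#' @param fmPresent test [FeatureMatrix-class] (distractor present).
#' @param kind classifier kind, including "zscore".
#' @param seed integer seed.
#' @return accuracy in percent (attribute `n` = epochs tested).
#' @export
trainAbsentTestPresent <- function(fmAbsent, fmPresent, kind, seed = 1) {
  kind <- match.arg(kind, .classifierKinds)
  if (kind == "zscore") {
    st <- populationStats(fmAbsent)
    # the test stratum differs in distractor status; normalise with the
    # training (absent) populations of the same pairing
    st$distractor <- "present"
    pred <- zscoreClassify(fmPresent, st, seed = seed)
  } else {
    model <- trainClassifier(kind, fmAbsent@X, fmAbsent@y, seed = seed)
    pred <- predictClassifier(model, fmPresent@X)
  }
  acc <- 100 * mean(pred == fmPresent@y)
  attr(acc, "n") <- length(fmPresent@y)
  acc
}

.subsetFeatures <- function(fm, rows) {
  new("FeatureMatrix", X = fm@X[rows, , drop = FALSE],
      featureIndex = fm@featureIndex, variant = fm@variant,
      y = fm@y[rows], trial = fm@trial[rows],
      strata = fm@strata[rows, , drop = FALSE], fs = fm@fs)
}

#' Subset a trial set
#'
#' @param trials a [TrialSet-class].
#' @param idx integer trial indices to keep.
#' @return a [TrialSet-class].
#' @export
subsetTrials <- function(trials, idx) {
  sch <- schedule(trials)[idx, , drop = FALSE]
  rownames(sch) <- NULL
  new("TrialSet", data = trials@data[idx, , , drop = FALSE],
      schedule = sch, fs = trials@fs, t0 = trials@t0[idx],
      channelLabels = trials@channelLabels)
}

# ---- grid runner ---------------------------------------------------------

#' Run the full decoding grid for one participant
#'
#' For every cell of (classifier x window x variant x regime x pairing):
#' extracts balanced, screened feature matrices for the pairing, runs
#' 10-fold trial-wise cross-validation on distractor-present data and a
#' single train-absent/test-present pass, and records accuracy. The
#' z-score classifier uses only the flicker-frequency features and is
#' reported under the "simple" variant.
#'
#' @param trials a [TrialSet-class] for one participant.
#' @param participant participant label for the result rows.
#' @param classifiers subset of
#'   c("zscore","lda","lr","svm","mlp","knn").
#' @param windows window sizes (s).
#' @param variants feature-set variants.
#' @param regimes subset of the two training regimes.
#' @param k folds for cross-validation.
#' @param seed integer seed.
#' @return a [DecodingResult-class] with one row per cell and pairing.
#' @export
runGrid <- function(trials, participant = "sub-01",
                    classifiers = .classifierKinds,
                    windows = c(0.25, 0.5, 1, 2, 4),
                    variants = c("simple", "simple+harmonic", "simple+alpha",
                                 "simple+alpha+harmonic"),
                    regimes = .regimes, k = 10, seed = 1) {
  sch <- schedule(trials)
  rows <- list()
  cell <- 0L
  for (pairing in unique(sch$pairing)) {
    presIdx <- which(sch$pairing == pairing & sch$distractor == "present")
    absIdx <- which(sch$pairing == pairing & sch$distractor == "absent")
    pres <- subsetTrials(trials, presIdx)
    abs_ <- if (length(absIdx)) subsetTrials(trials, absIdx) else NULL
    for (w in windows) for (v in variants) {
      fmPres <- extractFeatureMatrix(pres, w, v,
                                     seed = deriveSeed(seed, cell + 1L))
      fmAbs <- if (!is.null(abs_) &&
                   "train_absent_test_present" %in% regimes)
        extractFeatureMatrix(abs_, w, v, seed = deriveSeed(seed, cell + 2L))
      else NULL
      for (cl in classifiers) {
        if (cl == "zscore" && v != "simple") next
        for (rg in regimes) {
          cell <- cell + 1L
          acc <- if (rg == "train_present_cv10")
            crossvalidatePresent(fmPres, cl, k = k,
                                 seed = deriveSeed(seed, cell))
          else {
            if (is.null(fmAbs)) next
            trainAbsentTestPresent(fmAbs, fmPres, cl,
                                   seed = deriveSeed(seed, cell))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            participant = participant, classifier = cl, window = w,
            variant = v, regime = rg, pairing = pairing,
            accuracy = as.numeric(acc), n_epochs = attr(acc, "n"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  new("DecodingResult", results = do.call(rbind, rows))
}

#' Average accuracies over the two colour-flicker pairings
#'
#' @param result a [DecodingResult-class].
#' @return data.frame with one row per (participant, classifier, window,
#'   variant, regime), accuracy averaged over pairings.
#' @export
pairingAverage <- function(result) {
  df <- accuracyTable(result)
  agg <- stats::aggregate(
    cbind(accuracy = df$accuracy, n_epochs = df$n_epochs),
    by = df[c("participant", "classifier", "window", "variant", "regime")],
    FUN = mean)
  agg$n_epochs <- NULL
  nsum <- stats::aggregate(
    list(n_epochs = df$n_epochs),
    by = df[c("participant", "classifier", "window", "variant", "regime")],
    FUN = sum)
  merge(agg, nsum)
}
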