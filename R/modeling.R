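#' @include AllClasses.R
NULL

#' Stratified 70/30 cohort split
#'
#' Shuffles each class independently with a seeded stream and assigns
#' \code{round(class_size * trainFraction)} patients per class to training,
#' the remainder to testing. On a 159-patient cohort with 128 mutant and 31
#' wildtype patients this yields 112 training (90 + 22) and 47 testing
#' (38 + 9).
#'
#' @param labels integer/factor vector of per-patient class labels; names
#'   (or indices) identify patients.
#' @param trainFraction proportion assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.7, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  idx <- seq_along(labels)
  train <- integer(0)
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      members <- idx[labels == cl]
      members <- members[sample.int(length(members))]
      nTrain <- round(length(members) * trainFraction)
      train <- c(train, members[seq_len(nTrain)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}

#' Standardise features on training statistics only
#'
#' Each training column is centred on its mean and scaled by its population
#' (divisor n) standard deviation; the same parameters are applied to the
#' test table. Zero-variance columns are dropped with a warning.
#'
#' @param train numeric matrix (patients x features), >= 2 rows.
#' @param test optional numeric matrix with the same columns.
#' @return list with \code{train}, \code{test} (transformed matrices) and
#'   \code{center}, \code{scale} (named numeric parameters).
#' @export
standardizeFeatures <- function(train, test = NULL) {
  stopifnot(is.matrix(train), nrow(train) >= 2L)
  ctr <- colMeans(train)
  scl <- sqrt(colMeans(sweep(train, 2L, ctr)^2))
  keep <- scl > 0
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!keep), paste(colnames(train)[!keep], collapse = ", ")))
  ctr <- ctr[keep]; scl <- scl[keep]
  tf <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2L, ctr), 2L, scl, `/`)
  list(train = tf(train), test = if (!is.null(test)) tf(test),
       center = ctr, scale = scl)
}

#' Remove near-duplicate features by Pearson correlation
#'
#' Features are visited in canonical (alphabetical) order; for every ordered
#' pair with |PCC| above the threshold the later feature is dropped, so the
#' survivor set is deterministic and pairwise satisfies |PCC| <= threshold.
#'
#' @param train numeric matrix (patients x features).
#' @param threshold correlation threshold (default 0.99, strict >).
#' @return character vector of retained feature names.
#' @export
pccFilter <- function(train, threshold = 0.99) {
  stopifnot(is.matrix(train), ncol(train) >= 2L)
  nm <- sort(colnames(train))
  X <- train[, nm, drop = FALSE]
  R <- suppressWarnings(abs(cor(X)))
  R[is.na(R)] <- 0
  keep <- rep(TRUE, length(nm))
  for (i in seq_along(nm)) {
    if (!keep[i]) next
    later <- which(keep & seq_along(nm) > i)
    drop <- later[R[i, later] > threshold]
    keep[drop] <- FALSE
  }
  nm[keep]
}

#' Balanced class weights
#'
#' \code{weight_k = n_total / (n_classes * n_k)}: inversely proportional to
#' class frequency, so each class carries equal total weight.
#'
#' @param labels vector of class labels (both classes present).
#' @return named numeric vector of per-class weights.
#' @export
balancedClassWeights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0L) || length(tab) < 2L)
    stop("balanced weights require at least one member per class")
  w <- length(labels) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

# Weighted L2-penalised logistic regression via Newton iterations.
# Minimises sum_i w_i * logloss_i + 1/(2C) * ||beta||^2 (intercept
# unpenalised). X: n x p (no intercept column), y in {0,1}, w per-sample.
fitWeightedLogistic <- function(X, y, w, C = 1, maxIter = 100L, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- c(0, rep(1 / C, p))
  for (iter in seq_len(maxIter)) {
    eta <- as.vector(Xa %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- as.vector(crossprod(Xa, w * (y - mu))) - pen * beta
    s <- pmax(w * mu * (1 - mu), 1e-12)
    H <- crossprod(Xa * s, Xa) + diag(pen, p + 1L)
    step <- tryCatch(solve(H, g), error = function(e)
      stop(sprintf("logistic fit failed to converge at iteration %d: %s",
                   iter, conditionMessage(e))))
    beta <- beta + step
    if (max(abs(step)) < tol) break
    if (iter == maxIter)
      stop(sprintf("logistic fit did not converge within %d iterations", maxIter))
  }
  list(intercept = unname(beta[1L]), theta = unname(beta[-1L]))
}

#' Recursive feature elimination ranking
#'
#' Repeatedly fits the balanced-weighted L2-penalised logistic regression on
#' the surviving features and removes the feature with the smallest absolute
#' coefficient (one per iteration, ties broken by dropping the alphabetically
#' later name) until one feature remains.
#'
#' @param X standardised numeric matrix (patients x features, >= 2 columns).
#' @param y 0/1 labels.
#' @param C inverse regularisation strength (default 1).
#' @return character vector: the elimination order (first = least important);
#'   the last surviving feature is appended, so the vector ranks all
#'   features worst-to-best.
#' @export
rfeRank <- function(X, y, C = 1) {
  stopifnot(is.matrix(X), ncol(X) >= 2L, !is.null(colnames(X)))
  w <- balancedClassWeights(y)[as.character(y)]
  surviving <- colnames(X)
  removed <- character(0)
  while (length(surviving) > 1L) {
    fit <- fitWeightedLogistic(X[, surviving, drop = FALSE], y, w, C)
    imp <- abs(fit$theta)
    # smallest |coefficient|; on ties drop the alphabetically later feature
    worst <- surviving[imp <= min(imp) + 0]
    worst <- sort(worst)[length(worst)]
    removed <- c(removed, worst)
    surviving <- setdiff(surviving, worst)
  }
  c(removed, surviving)
}

# Stratified fold assignment: shuffles each class and deals members
# round-robin over folds.
stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in sort(unique(y))) {
      members <- which(y == cl)
      members <- members[sample.int(length(members))]
      fold[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  fold
}

#' Choose the number of features by cross-validated RFE
#'
#' For each fold of a stratified k-fold split, the RFE path is recomputed on
#' the fold's training part; for every candidate feature count n the top-n
#' features are refitted and the held-out fold scored. The mean out-of-fold
#' AUC per n selects the optimal count (maximum mean AUC, smallest n on
#' ties).
#'
#' @param X standardised numeric matrix (patients x features).
#' @param y 0/1 labels.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param C inverse regularisation strength.
#' @return list with \code{nSelected} and \code{cvAuc} (mean AUC per
#'   candidate n, one entry per feature count 1..p).
#' @export
selectNumFeatures <- function(X, y, folds = 10L, seed = 1L, C = 1) {
  p <- ncol(X)
  fold <- stratifiedFolds(y, folds, seed)
  aucs <- matrix(NA_real_, folds, p)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
      stop("a fold is missing a class; use fewer folds")
    ranking <- rfeRank(X[tr, , drop = FALSE], y[tr], C)
    w <- balancedClassWeights(y[tr])[as.character(y[tr])]
    for (n in seq_len(p)) {
      feats <- tail(ranking, n)
      fit <- fitWeightedLogistic(X[tr, feats, drop = FALSE], y[tr], w, C)
      probs <- 1 / (1 + exp(-(fit$intercept +
                                X[te, feats, drop = FALSE] %*% fit$theta)))
      aucs[f, n] <- rankAUC(as.vector(probs), y[te])
    }
  }
  cvAuc <- colMeans(aucs)
  list(nSelected = which.max(cvAuc), cvAuc = cvAuc)
}

#' Fit the final balanced logistic model on selected features
#'
#' @param X standardised numeric matrix restricted to the selected features.
#' @param y 0/1 labels.
#' @param center,scale named standardisation parameters used to produce
#'   \code{X} (stored in the model for later application to new data).
#' @param C inverse regularisation strength.
#' @return A [LogisticModel-class].
#' @export
fitFinalModel <- function(X, y, center = NULL, scale = NULL, C = 1) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  cw <- balancedClassWeights(y)
  fit <- fitWeightedLogistic(X, y, cw[as.character(y)], C)
  nm <- colnames(X)
  new(Class = "LogisticModel", features = nm,
      theta = structure(fit$theta, names = nm),
      intercept = fit$intercept, classWeights = cw,
      center = (center %||% structure(rep(0, length(nm)), names = nm))[nm],
      scale = (scale %||% structure(rep(1, length(nm)), names = nm))[nm],
      threshold = 0.5, C = C)
}

#' Predict mutation probability from a fitted model
#'
#' \code{P = 1 / (1 + exp(-(theta0 + sum theta_i x_i)))}; the hard label is
#' positive (TERTp-mutant) iff \code{P > 0.5} (strict).
#'
#' @param model a [LogisticModel-class].
#' @param x named numeric vector or matrix of standardised feature values
#'   covering all selected features.
#' @return list with \code{probability} and \code{positive} (logical).
#' @export
predictProbability <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  missing <- setdiff(selectedFeatures(model), colnames(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  xs <- x[, selectedFeatures(model), drop = FALSE]
  eta <- modelIntercept(model) + as.vector(xs %*% coef(model))
  p <- 1 / (1 + exp(-eta))
  list(probability = p, positive = p > model@threshold)
}

# Mann-Whitney rank AUC with 0.5 credit for ties.
rankAUC <- function(probs, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(probs, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusionMetrics <- function(probs, labels, threshold = 0.5) {
  pred <- probs > threshold
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Evaluate predicted probabilities with bootstrap confidence intervals
#'
#' Point estimates: rank-based AUC (ties get 0.5 credit) and confusion
#' metrics at the strict 0.5 threshold with TERTp-mutation (label 1) as the
#' positive class. 95% CIs are percentile intervals over stratified
#' non-parametric bootstrap resamples of the (probability, label) pairs.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels (both classes present).
#' @param nBootstrap number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @return An [EvaluationReport-class].
#' @export
evaluateModel <- function(probs, labels, nBootstrap = 1000L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("evaluation requires both classes in the labels")
  point <- c(auc = rankAUC(probs, labels), confusionMetrics(probs, labels))
  idx0 <- which(labels == 0L); idx1 <- which(labels == 1L)
  boot <- withSeed(seed, {
    vapply(seq_len(nBootstrap), function(b) {
      take <- c(idx0[sample.int(length(idx0), length(idx0), replace = TRUE)],
                idx1[sample.int(length(idx1), length(idx1), replace = TRUE)])
      c(auc = rankAUC(probs[take], labels[take]),
        confusionMetrics(probs[take], labels[take]))
    }, numeric(6L))
  })
  lo <- apply(boot, 1L, quantile, probs = 0.025, na.rm = TRUE, type = 7)
  hi <- apply(boot, 1L, quantile, probs = 0.975, na.rm = TRUE, type = 7)
  new("EvaluationReport", metrics = point, ciLower = lo, ciUpper = hi,
      nBootstrap = as.integer(nBootstrap))
}

#' Train the full classification pipeline on a feature table
#'
#' Standardisation (training statistics only), PCC de-duplication,
#' cross-validated RFE feature-count selection, final RFE ranking on the
#' full training cohort and balanced logistic fit.
#'
#' @param trainX numeric matrix (patients x features).
#' @param trainY 0/1 labels.
#' @param folds CV folds (default 10).
#' @param pccThreshold correlation threshold (default 0.99).
#' @param seed integer seed (folds).
#' @param C inverse regularisation strength.
#' @return list with the fitted \code{model} ([LogisticModel-class]), the
#'   \code{standardization} parameters over all retained features, the
#'   retained feature names after \code{pccFilter}, and the CV curve.
#' @export
trainModel <- function(trainX, trainY, folds = 10L, pccThreshold = 0.99,
                       seed = 1L, C = 1) {
  std <- standardizeFeatures(trainX)
  kept <- pccFilter(std$train, pccThreshold)
  Xk <- std$train[, kept, drop = FALSE]
  sel <- selectNumFeatures(Xk, trainY, folds = folds, seed = seed, C = C)
  ranking <- rfeRank(Xk, trainY, C)
  feats <- tail(ranking, sel$nSelected)
  model <- fitFinalModel(Xk[, feats, drop = FALSE], trainY,
                         center = std$center, scale = std$scale, C = C)
  list(model = model, standardization = std[c("center", "scale")],
       retained = kept, nSelected = sel$nSelected, cvAuc = sel$cvAuc,
       ranking = ranking)
}

#' Apply a trained model to a raw (unstandardised) feature table
#'
#' @param model a [LogisticModel-class].
#' @param X raw numeric feature matrix containing the selected features.
#' @return list as in [predictProbability()].
#' @export
applyModel <- function(model, X) {
  feats <- selectedFeatures(model)
  missing <- setdiff(feats, colnames(X))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  Xs <- sweep(sweep(X[, feats, drop = FALSE], 2L, model@center),
              2L, model@scale, `/`)
  predictProbability(model, Xs)
}
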