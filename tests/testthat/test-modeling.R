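test_that("stratified splitting reproduces per-class rounding", {
  labels <- c(rep(1L, 128), rep(0L, 31))
  sp <- stratifiedSplit(labels, 0.7, seed = 3)
  expect_length(sp$train, 112L)
  expect_length(sp$test, 47L)
  expect_equal(sum(labels[sp$train] == 0L), 22L)
  expect_equal(sum(labels[sp$test] == 0L), 9L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, stratifiedSplit(labels, 0.7, seed = 3))
  one <- stratifiedSplit(rep(1L, 10), 0.7, seed = 1)
  expect_length(one$train, 7L)
  expect_length(one$test, 3L)
  expect_error(stratifiedSplit(labels, 1.2), "trainFraction")
})

test_that("standardisation uses training statistics only", {
  train <- cbind(a = c(1, 3), b = c(2, 2), c = c(0, 1))
  test <- cbind(a = c(5, 7), b = c(9, 9), c = c(1, 0))
  expect_warning(std <- standardizeFeatures(train, test), "zero-variance")
  expect_equal(colnames(std$train), c("a", "c"))
  expect_equal(unname(std$train[, "a"]), c(-1, 1))
  # population (divisor n) scale: train sd of {1,3} is 1
  expect_equal(unname(std$scale["a"]), 1)
  expect_equal(unname(std$test[, "a"]), c(3, 5))
  expect_equal(colMeans(std$train), c(a = 0, c = 0), tolerance = 1e-12)
  # perturbing the test table must not change the parameters
  expect_warning(std2 <- standardizeFeatures(train, test * 100), "zero-variance")
  expect_identical(std$center, std2$center)
  expect_identical(std$scale, std2$scale)
})

test_that("PCC filtering drops the later of every collinear pair", {
  withSeed(6, {
    n <- 30
    base <- rnorm(n)
    X <- cbind(alpha = base, beta = base, gamma = rnorm(n),
               delta = base * -1, epsilon = rnorm(n))
    kept <- pccFilter(X, 0.99)
    expect_true("alpha" %in% kept)
    expect_false(any(c("beta", "delta") %in% kept))   # |PCC| = 1 with alpha
    expect_true(all(c("gamma", "epsilon") %in% kept))
    R <- abs(cor(X[, kept]))
    expect_true(all(R[upper.tri(R)] <= 0.99))
    # nothing removed when all pairs are below the threshold
    expect_setequal(pccFilter(X[, c("alpha", "gamma", "epsilon")]),
                    c("alpha", "gamma", "epsilon"))
  })
})

test_that("balanced class weights equalise class mass", {
  labels <- c(rep(1L, 90), rep(0L, 22))
  w <- balancedClassWeights(labels)
  expect_equal(unname(w["1"]), 112 / (2 * 90))
  expect_equal(unname(w["0"]), 112 / (2 * 22))
  expect_equal(w[["1"]] * 90, w[["0"]] * 22)
  expect_equal(unname(balancedClassWeights(rep(0:1, 10))), c(1, 1))
  expect_error(balancedClassWeights(rep(1L, 5)), "class")
})

test_that("the penalised weighted fit agrees with glm in the weak-penalty limit", {
  skip_if_not_installed("glmnet")
  withSeed(12, {
    n <- 120
    X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
    y <- rbinom(n, 1, plogis(0.4 + 0.9 * X[, 1] - 0.6 * X[, 2]))
    w <- balancedClassWeights(y)[as.character(y)]
    fit <- dynFET:::fitWeightedLogistic(X, y, w, C = 1e8)
    ref <- suppressWarnings(glm(y ~ X, family = binomial(), weights = w))
    expect_equal(unname(fit$intercept), unname(coef(ref)[1]), tolerance = 1e-5)
    expect_equal(unname(fit$theta), unname(coef(ref)[2:3]), tolerance = 1e-5)
    # and with the ridge penalty, against glmnet's equivalent lambda
    fitC <- dynFET:::fitWeightedLogistic(X, y, w, C = 1)
    gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         weights = w, lambda = 1 / sum(w), standardize = FALSE,
                         thresh = 1e-14)
    expect_equal(unname(fitC$theta), unname(as.vector(gn$beta)), tolerance = 1e-3)
  })
})

test_that("final fits are symmetric and deterministic", {
  withSeed(2, {
    X <- cbind(s = c(rnorm(20, -1), rnorm(20, 1)))
    y <- rep(c(0L, 1L), each = 20)
    m1 <- fitFinalModel(X, y)
    m2 <- fitFinalModel(X, y)
    expect_equal(coef(m1), coef(m2), tolerance = 1e-8)
    flipped <- fitFinalModel(X, 1L - y)
    expect_equal(unname(coef(flipped)), -unname(coef(m1)), tolerance = 1e-8)
    # antisymmetric data: intercept ~ 0
    Xs <- cbind(s = c(-2, -1, 1, 2))
    ms <- fitFinalModel(Xs, c(0L, 0L, 1L, 1L))
    expect_equal(modelIntercept(ms), 0, tolerance = 1e-8)
  })
})

test_that("RFE eliminates noise before planted signal", {
  withSeed(23, {
    n <- 120
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(n, 1, plogis(3 * X[, "f3"]))
    ranking <- rfeRank(X, y)
    expect_length(ranking, 6L)
    expect_equal(ranking[6L], "f3")          # informative feature survives last
    expect_setequal(ranking, colnames(X))
  })
})

test_that("cross-validated selection recovers planted features", {
  withSeed(31, {
    n <- 200; pNoise <- 20
    X <- matrix(rnorm(n * (pNoise + 3)), n,
                dimnames = list(NULL, c(sprintf("noise%02d", 1:pNoise),
                                        "sigA", "sigB", "sigC")))
    y <- rbinom(n, 1, plogis(1.4 * X[, "sigA"] - 1.2 * X[, "sigB"] +
                               1.0 * X[, "sigC"]))
    hits <- 0L
    for (seed in 1:10) {
      sel <- selectNumFeatures(X, y, folds = 10, seed = seed)
      expect_length(sel$cvAuc, ncol(X))
      feats <- tail(rfeRank(X, y), sel$nSelected)
      if (sum(c("sigA", "sigB", "sigC") %in% feats) >= 2L) hits <- hits + 1L
    }
    expect_gte(hits, 8L)
  })
})

test_that("pure-noise features give chance-level cross-validated AUC", {
  withSeed(77, {
    n <- 120
    X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("n", 1:6)))
    y <- rbinom(n, 1, 0.5)
    sel <- selectNumFeatures(X, y, folds = 10, seed = 5)
    expect_lt(max(sel$cvAuc), 0.70)
    expect_gt(min(sel$cvAuc), 0.30)
  })
})

test_that("the logistic probability formula drives the positive call", {
  m0 <- new(Class = "LogisticModel", features = "x1",
            theta = c(x1 = 0), intercept = 0,
            classWeights = c(`0` = 1, `1` = 1),
            center = c(x1 = 0), scale = c(x1 = 1), threshold = 0.5, C = 1)
  p <- predictProbability(m0, c(x1 = 3))
  expect_equal(p$probability, 0.5)
  expect_false(p$positive)                  # strict > 0.5
  expect_error(predictProbability(m0, c(other = 1)), "x1")
  # logistic symmetry about the intercept
  m1 <- new(Class = "LogisticModel", features = c("a", "b"),
            theta = c(a = 0.7, b = -1.1), intercept = 0,
            classWeights = c(`0` = 1, `1` = 1),
            center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
            threshold = 0.5, C = 1)
  x <- c(a = 0.3, b = 0.8)
  expect_equal(predictProbability(m1, x)$probability +
                 predictProbability(m1, -x)$probability, 1)
})

test_that("rank AUC matches the pairwise count and is monotone invariant", {
  expect_equal(dynFET:::rankAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # pairs: (0.9 vs 0.6) win, (0.4 vs 0.6) loss -> 0.5
  expect_equal(dynFET:::rankAUC(c(0.9, 0.6, 0.4), c(1, 0, 1)), 0.5)
  withSeed(9, {
    p <- runif(40); y <- rbinom(40, 1, 0.5)
    expect_equal(dynFET:::rankAUC(qlogis(p), y), dynFET:::rankAUC(p, y))
    skip_if_not_installed("pROC")
    expect_equal(dynFET:::rankAUC(p, y),
                 as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))))
  })
})

test_that("evaluation reports coherent point metrics and bootstrap CIs", {
  probs <- c(0.9, 0.85, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  rep_ <- evaluateModel(probs, labels, nBootstrap = 200, seed = 4)
  m <- rep_@metrics
  expect_equal(unname(m[c("auc", "sensitivity", "specificity")]), c(1, 1, 1))
  tab <- metricTable(rep_)
  expect_true(all(tab$ci_lower <= tab$value + 1e-12))
  expect_true(all(tab$ci_upper >= tab$value - 1e-12))
  expect_error(evaluateModel(probs, rep(1, 6)), "both classes")
  # chance-level probabilities concentrate near AUC 0.5
  withSeed(15, {
    aucs <- replicate(20, {
      pr <- runif(60); yy <- rbinom(60, 1, 0.5)
      dynFET:::rankAUC(pr, yy)
    })
    expect_lt(abs(mean(aucs) - 0.5), 0.08)
  })
})

test_that("trainModel keeps selection consistent with its RFE path", {
  withSeed(41, {
    n <- 90
    X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
    X[, 1] <- X[, 1] + rbinom(n, 1, 0.5) * 0   # keep names stable
    y <- rbinom(n, 1, plogis(2 * X[, 2]))
    fit <- trainModel(X, y, folds = 5, seed = 2)
    expect_s4_class(fit$model, "LogisticModel")
    expect_length(selectedFeatures(fit$model), fit$nSelected)
    expect_setequal(selectedFeatures(fit$model),
                    tail(fit$ranking, fit$nSelected))
    # standardisation parameters stored in the model reproduce applyModel
    pred1 <- applyModel(fit$model, X)
    Xs <- sweep(sweep(X[, selectedFeatures(fit$model), drop = FALSE], 2,
                      fit$model@center), 2, fit$model@scale, `/`)
    pred2 <- predictProbability(fit$model, Xs)
    expect_equal(pred1$probability, pred2$probability)
  })
})
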