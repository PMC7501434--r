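test_that("shrinkage LDA places the boundary between symmetric classes", {
  set.seed(41)
  x <- matrix(c(rnorm(100, -2), rnorm(100, 2)), ncol = 1)
  y <- rep(c("a", "b"), each = 100)
  fit <- fitShrinkageLda(x, y)
  boundary <- mean(fit@classMeans)      # equal priors, equal variances
  expect_lt(abs(boundary), 0.2)
  pred <- predict(fit, matrix(c(-5, 5), ncol = 1))
  expect_equal(as.character(pred), c("a", "b"))
})

test_that("no-signal data trains at chance", {
  set.seed(42)
  X <- matrix(rnorm(200 * 20), 200)
  y <- sample(rep(c("a", "b"), each = 100))
  fit <- fitShrinkageLda(X, y)
  acc <- mean(predict(fit, X) == y)
  expect_lt(acc, 0.65)                  # training accuracy near chance
})

test_that("shrinkage keeps the covariance invertible when E >> n", {
  set.seed(43)
  X <- matrix(rnorm(10 * 435), 10)
  y <- rep(c("a", "b"), each = 5)
  fit <- fitShrinkageLda(X, y)
  expect_gt(fit@shrinkageIntensity, 0)
  ev <- eigen(fit@pooledCov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(fitShrinkageLda(X[1:6, ], c("a", "a", "a", "a", "a", "b")),
               "at least 2 samples")
})

test_that("leave-one-subject-out never trains on the held-out subject", {
  set.seed(44)
  N <- 8
  ids <- sprintf("S%d", seq_len(N))
  # feature 1 encodes the subject index so the mock can observe fold content
  X <- cbind(rep(seq_len(N), each = 3),
             matrix(rnorm(N * 3 * 5), N * 3) +
               outer(rep(c(0, 2, 4), N), rep(1, 5)))
  y <- factor(rep(c("rest", "L1", "L2"), N), levels = c("rest", "L1", "L2"))
  ds <- new("EdgeDataset", X = X, y = y, subject = rep(ids, each = 3),
            labelSpace = levels(y))
  seen <- list()
  orig <- fcnet::fitShrinkageLda
  testthat::local_mocked_bindings(
    fitShrinkageLda = function(X, y, priors = NULL) {
      seen[[length(seen) + 1]] <<- unique(X[, 1])
      orig(X, y, priors)
    }, .package = "fcnet")
  losoCv(ds)
  excluded <- vapply(seen, function(s) setdiff(seq_len(N), s), numeric(1))
  expect_equal(sort(excluded), seq_len(N))  # each subject held out once
})

test_that("separable subjects classify perfectly, shuffled labels at chance", {
  set.seed(45)
  N <- 12
  g <- rep(c("patient", "control"), each = N / 2)
  offset <- ifelse(g == "patient", 4, -4)
  vals <- array(rnorm(N * 3 * 10), dim = c(N, 3, 10)) + offset
  ee <- edgeExperimentFromArray(vals, g)
  ds <- groupDataset(ee, "rest")
  rep1 <- losoCv(ds, task = "group")
  expect_equal(meanAccuracy(rep1), 1)
  expect_equal(unname(rowSums(confusionMatrix(rep1))), c(6, 6))
  # destroy the signal by shuffling group labels at the subject level
  set.seed(46)
  dsNull <- new("EdgeDataset", X = ds@X, y = factor(sample(ds@y),
                                                   levels = ds@labelSpace),
                subject = ds@subject, labelSpace = ds@labelSpace)
  repNull <- losoCv(dsNull, task = "group")
  expect_lt(meanAccuracy(repNull), 0.95)
  expect_error(losoCv(.subsetDatasetForTest(ds, 1:2)), "3 subjects")
})

test_that("reports are invariant to row order", {
  set.seed(47)
  N <- 9
  g <- rep(c("patient", "control", "control"), each = 3)
  vals <- array(rnorm(N * 3 * 6), dim = c(N, 3, 6))
  vals[, 2, ] <- vals[, 2, ] + 1.5
  vals[, 3, ] <- vals[, 3, ] + 3
  ee <- edgeExperimentFromArray(vals, g)
  ds <- conditionDataset(ee)
  perm <- sample(length(ds@y))
  dsP <- new("EdgeDataset", X = ds@X[perm, , drop = FALSE], y = ds@y[perm],
             subject = ds@subject[perm], labelSpace = ds@labelSpace)
  r1 <- losoCv(ds)
  r2 <- losoCv(dsP)
  expect_equal(confusionMatrix(r1), confusionMatrix(r2))
  expect_equal(meanAccuracy(r1), meanAccuracy(r2))
})

test_that("balanced subsampling handles equal and unequal group sizes", {
  set.seed(48)
  N <- 16
  g <- rep(c("patient", "control"), each = 8)
  offset <- ifelse(g == "patient", 3, -3)
  vals <- array(rnorm(N * 3 * 8), dim = c(N, 3, 8)) + offset
  ee <- edgeExperimentFromArray(vals, g)
  ds <- groupDataset(ee, "rest")
  # equal sizes: every iteration uses the full control set
  repEq <- balancedGroupClassification(ds, nIterations = 3, seed = 1)
  expect_equal(sum(confusionMatrix(repEq)), 3 * N)
  expect_equal(meanAccuracy(repEq), 1)
  # controls < patients is an error
  dsBad <- .subsetDatasetForTest(ds, c(1:8, 9:10))
  expect_error(balancedGroupClassification(dsBad, 2, 1), "at least as many")
  # determinism
  r1 <- balancedGroupClassification(ds, nIterations = 4, seed = 7)
  r2 <- balancedGroupClassification(ds, nIterations = 4, seed = 7)
  expect_equal(confusionMatrix(r1), confusionMatrix(r2))
})

test_that("permutation p-values follow the add-one convention", {
  set.seed(49)
  N <- 10
  g <- rep(c("patient", "control"), each = 5)
  vals <- array(rnorm(N * 3 * 6), dim = c(N, 3, 6)) +
    ifelse(g == "patient", 5, -5)
  ee <- edgeExperimentFromArray(vals, g)
  ds <- groupDataset(ee, "rest")
  runner <- function(d) meanAccuracy(losoCv(d, task = "group"))
  obs <- runner(ds)
  perm <- permutationTest(ds, obs, nPermutations = 99, seed = 2,
                          classifierRunner = runner, scheme = "group")
  expect_equal(obs, 1)
  expect_equal(perm$p, (1 + sum(perm$null >= 1)) / 100)
  expect_lte(perm$p, 0.05)
  expect_error(permutationTest(ds, obs, 0, 1, runner), "at least 1")
})

test_that("permutation null is calibrated when the observed value is null", {
  set.seed(50)
  N <- 10
  g <- rep(c("patient", "control"), each = 5)
  runner <- function(d) meanAccuracy(losoCv(d, task = "group"))
  ps <- replicate(25, {
    vals <- array(rnorm(N * 3 * 5), dim = c(N, 3, 5))
    ee <- edgeExperimentFromArray(vals, g)
    ds <- groupDataset(ee, "rest")
    permutationTest(ds, runner(ds), nPermutations = 39,
                    seed = sample.int(1e6, 1),
                    classifierRunner = runner, scheme = "group")$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})
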