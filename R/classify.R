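#' Build classification datasets from a cohort edge table
#'
#' `conditionDataset` labels every run by its condition (3-class task);
#' `groupDataset` keeps one row per subject for a chosen condition and
#' labels it by group (2-class task).
#'
#' @param ee an [EdgeExperiment-class].
#' @param groups which groups to include (condition task).
#' @param condition which condition to use (group task).
#' @return an [EdgeDataset-class].
#' @export
conditionDataset <- function(ee, groups = c("patient", "control")) {
  cd <- colData(ee)
  keep <- cd$group %in% groups
  X <- edgeMatrix(ee)[keep, , drop = FALSE]
  y <- factor(cd$condition[keep], levels = .CONDITIONS)
  new("EdgeDataset", X = X, y = droplevels(y),
      subject = as.character(cd$subject[keep]),
      labelSpace = levels(droplevels(y)))
}

#' @rdname conditionDataset
#' @export
groupDataset <- function(ee, condition = "rest") {
  cd <- colData(ee)
  keep <- cd$condition == condition
  X <- edgeMatrix(ee)[keep, , drop = FALSE]
  y <- factor(cd$group[keep], levels = .GROUPS)
  new("EdgeDataset", X = X, y = droplevels(y),
      subject = as.character(cd$subject[keep]),
      labelSpace = levels(droplevels(y)))
}

.subsetDataset <- function(ds, idx) {
  y <- factor(ds@y[idx], levels = ds@labelSpace)
  new("EdgeDataset", X = ds@X[idx, , drop = FALSE], y = y,
      subject = ds@subject[idx], labelSpace = ds@labelSpace)
}

#' Fit a shrinkage-regularized linear discriminant model
#'
#' The pooled within-class covariance is shrunk toward its diagonal,
#' Sigma* = (1 - gamma) Sigma + gamma diag(Sigma), with gamma the analytic
#' optimal intensity (ratio of the summed sampling variances of the
#' off-diagonal entries to their summed squares), clipped to \[0, 1\]. For
#' gamma > 0 the estimate is positive definite even when features far
#' outnumber samples, which is what makes the 435-edge classifier feasible
#' at cohort sample sizes.
#'
#' @param X N x E feature matrix.
#' @param y labels (factor or character).
#' @param priors per-class priors; default uniform.
#' @return a [ShrinkageLdaModel-class].
#' @export
fitShrinkageLda <- function(X, y, priors = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  L <- length(classes)
  if (L < 2) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2)) stop("every class needs at least 2 samples: ",
                            paste(classes[counts < 2], collapse = ", "))
  n <- nrow(X)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  Z <- X - mu[as.integer(y), , drop = FALSE]
  df <- n - L
  S <- crossprod(Z) / df

  if (ncol(X) > 1) {
    W1 <- crossprod(Z)                      # sum of products
    W2 <- crossprod(Z * Z)                  # sum of squared products
    varS <- n / (n - 1)^3 * (W2 - W1^2 / n)
    sUnb <- W1 / (n - 1)
    off <- upper.tri(S)
    denom <- 2 * sum(sUnb[off]^2)
    gamma <- if (denom > 0) min(1, max(0, 2 * sum(varS[off]) / denom)) else 0
  } else gamma <- 0

  Sigma <- (1 - gamma) * S
  diag(Sigma) <- diag(S)
  # features with zero pooled variance (e.g. edges shrunk to exactly zero in
  # every run) carry no signal; give them a tiny positive variance so the
  # shrunk covariance stays positive definite
  zeroVar <- diag(Sigma) <= 0
  if (all(zeroVar)) stop("all features have zero within-class variance")
  if (any(zeroVar))
    diag(Sigma)[zeroVar] <- 1e-8 * mean(diag(Sigma)[!zeroVar])

  if (is.null(priors)) priors <- rep(1 / L, L)
  names(priors) <- classes
  rownames(mu) <- classes
  new("ShrinkageLdaModel", classMeans = mu, pooledCov = Sigma,
      shrinkageIntensity = gamma, priors = priors)
}

#' Predict classes with a shrinkage-LDA model
#'
#' @param object a [ShrinkageLdaModel-class].
#' @param newdata N x E matrix.
#' @param ... unused.
#' @return factor of predicted labels with a `"scores"` attribute (the
#'   linear discriminant values).
#' @export
setMethod("predict", "ShrinkageLdaModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  mu <- object@classMeans
  A <- solve(object@pooledCov, t(mu))              # E x L
  const <- -0.5 * colSums(t(mu) * A) + log(object@priors)
  scores <- sweep(X %*% A, 2, const, "+")
  pred <- factor(rownames(mu)[max.col(scores, ties.method = "first")],
                 levels = rownames(mu))
  attr(pred, "scores") <- scores
  pred
})

setMethod("show", "ShrinkageLdaModel", function(object) {
  cat("ShrinkageLdaModel:", nrow(object@classMeans), "classes,",
      ncol(object@classMeans), "features\n")
  cat("  shrinkage intensity gamma =",
      signif(object@shrinkageIntensity, 4), "\n")
})

.reportFromConfusion <- function(confusion, task, pPerm = NA_real_,
                                 nPerm = 0L) {
  acc <- diag(confusion) / pmax(1, rowSums(confusion))
  new("ClassificationReport", confusion = confusion,
      perClassAccuracy = acc, meanAccuracy = mean(acc),
      pPerm = pPerm, nPermutations = as.integer(nPerm),
      chanceLevel = 1 / nrow(confusion), task = task)
}

#' Leave-one-subject-out cross-validated classification
#'
#' Every fold holds out all rows of one subject (a subject's runs are
#' dependent, so row-level leave-one-out would leak identity); the model is
#' refit on the remainder and the held-out rows are predicted. The
#' confusion matrix accumulates over folds and the summary accuracy is the
#' mean of the per-class accuracies.
#'
#' @param dataset an [EdgeDataset-class].
#' @param task label of the report ("condition" or "group").
#' @param priors passed to [fitShrinkageLda()].
#' @return a [ClassificationReport-class].
#' @export
losoCv <- function(dataset, task = "condition", priors = NULL) {
  subj <- unique(dataset@subject)
  if (length(subj) < 3) stop("need at least 3 subjects")
  labs <- dataset@labelSpace
  confusion <- matrix(0L, length(labs), length(labs),
                      dimnames = list(true = labs, predicted = labs))
  for (s in subj) {
    test <- which(dataset@subject == s)
    fit <- fitShrinkageLda(dataset@X[-test, , drop = FALSE],
                           dataset@y[-test], priors)
    pred <- predict(fit, dataset@X[test, , drop = FALSE])
    for (k in seq_along(test)) {
      tl <- as.character(dataset@y[test[k]])
      pl <- as.character(pred[k])
      confusion[tl, pl] <- confusion[tl, pl] + 1L
    }
  }
  .reportFromConfusion(confusion, task)
}

#' Group classification with balanced control subsampling
#'
#' To remove the bias of unequal group sizes, controls are repeatedly
#' subsampled (without replacement) to match the patient count; each
#' iteration runs a full leave-one-subject-out cross-validation and the
#' per-class accuracies are averaged across iterations.
#'
#' @param dataset a group-task [EdgeDataset-class] (one row per subject).
#' @param nIterations subsampling iterations (100 at study scale; smaller
#'   desk-scale values are fine for exploration).
#' @param seed integer seed; the report is deterministic given it.
#' @param priors passed to the classifier.
#' @return a [ClassificationReport-class]; the confusion matrix is summed
#'   over iterations, per-class accuracies are iteration means.
#' @export
balancedGroupClassification <- function(dataset, nIterations = 100, seed = 1,
                                        priors = NULL) {
  isPat <- dataset@y == "patient"
  nPat <- sum(isPat)
  ctrlIdx <- which(!isPat)
  if (nPat < 3) stop("need at least 3 patients")
  if (length(ctrlIdx) < nPat) stop("controls must be at least as many as patients")
  set.seed(seed)
  labs <- dataset@labelSpace
  confusion <- matrix(0L, length(labs), length(labs),
                      dimnames = list(true = labs, predicted = labs))
  accSum <- setNames(numeric(length(labs)), labs)
  for (it in seq_len(nIterations)) {
    pick <- sort(c(which(isPat), sample(ctrlIdx, nPat)))
    itRep <- losoCv(.subsetDataset(dataset, pick), task = "group",
                    priors = priors)
    confusion <- confusion + itRep@confusion
    accSum <- accSum + itRep@perClassAccuracy
  }
  acc <- accSum / nIterations
  new("ClassificationReport", confusion = confusion,
      perClassAccuracy = acc, meanAccuracy = mean(acc),
      pPerm = NA_real_, nPermutations = 0L,
      chanceLevel = 1 / length(labs), task = "group")
}

#' Permutation test of classification accuracy
#'
#' Builds an empirical null by rerunning the supplied classifier on
#' label-permuted data: group labels are permuted at the subject level
#' (group task) and condition labels are permuted within each subject
#' across that subject's runs (condition task). The p-value uses the
#' add-one convention, p = (1 + #\{null >= observed\}) / (n + 1), so it is
#' a valid finite-sample p and never exactly zero.
#'
#' @param dataset an [EdgeDataset-class].
#' @param observedAccuracy accuracy of the unpermuted analysis.
#' @param nPermutations number of permutations (>= 1).
#' @param seed integer seed.
#' @param classifierRunner function(dataset) returning an accuracy in
#'   \[0, 1\] (e.g. `function(d) meanAccuracy(losoCv(d))`).
#' @param scheme "group" or "condition" permutation scheme.
#' @return list with elements `p`, `null` (the null accuracies) and
#'   `observed`.
#' @export
permutationTest <- function(dataset, observedAccuracy, nPermutations,
                            seed = 1, classifierRunner,
                            scheme = c("group", "condition")) {
  scheme <- match.arg(scheme)
  if (nPermutations < 1) stop("need at least 1 permutation")
  set.seed(seed)
  nullAcc <- numeric(nPermutations)
  subj <- unique(dataset@subject)
  for (b in seq_len(nPermutations)) {
    yPerm <- dataset@y
    if (scheme == "group") {
      subjLab <- dataset@y[match(subj, dataset@subject)]
      permLab <- sample(subjLab)
      yPerm <- permLab[match(dataset@subject, subj)]
    } else {
      for (s in subj) {
        rows <- which(dataset@subject == s)
        yPerm[rows] <- sample(dataset@y[rows])
      }
    }
    dPerm <- new("EdgeDataset", X = dataset@X,
                 y = factor(yPerm, levels = dataset@labelSpace),
                 subject = dataset@subject, labelSpace = dataset@labelSpace)
    nullAcc[b] <- classifierRunner(dPerm)
  }
  p <- (1 + sum(nullAcc >= observedAccuracy)) / (nPermutations + 1)
  list(p = p, null = nullAcc, observed = observedAccuracy)
}

#' @rdname ClassificationReport-class
#' @param x a ClassificationReport.
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @rdname ClassificationReport-class
#' @export
setMethod("perClassAccuracy", "ClassificationReport",
          function(x) x@perClassAccuracy)

#' @rdname ClassificationReport-class
#' @export
setMethod("meanAccuracy", "ClassificationReport", function(x) x@meanAccuracy)

#' @rdname ClassificationReport-class
#' @export
setMethod("permutationP", "ClassificationReport", function(x) x@pPerm)

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport (", object@task, " task)\n", sep = "")
  print(object@confusion)
  cat("  per-class accuracy:",
      paste(names(object@perClassAccuracy),
            sprintf("%.3f", object@perClassAccuracy),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  mean accuracy: %.3f (chance %.3f)\n",
              object@meanAccuracy, object@chanceLevel))
  if (!is.na(object@pPerm))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                object@pPerm, object@nPermutations))
})

#' Attach a permutation p-value to a report
#'
#' @param report a [ClassificationReport-class].
#' @param perm result of [permutationTest()].
#' @return the report with `pPerm`/`nPermutations` filled in.
#' @export
withPermutationP <- function(report, perm) {
  report@pPerm <- perm$p
  report@nPermutations <- length(perm$null)
  report
}
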