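#' Estimate a regularized precision matrix from node time series
#'
#' Columns are demeaned and variance-normalized internally so the empirical
#' matrix is a correlation matrix, then the L1-penalized Gaussian
#' log-likelihood
#' \deqn{\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\ne j}|\Theta_{ij}|}
#' is maximized over positive-definite \eqn{\Theta} by block coordinate
#' descent (graphical lasso; the diagonal is unpenalized). For
#' `lambda = 0` and T > K the solution is the inverse sample correlation
#' and is computed directly.
#'
#' @param ts T x K time-series matrix (or a K x K correlation matrix when
#'   `isCorrelation = TRUE`).
#' @param lambda nonnegative penalty.
#' @param method `"glasso"` (default) or `"ridge"`, which shrinks the
#'   correlation matrix toward the identity, S* = (1-lambda) S + lambda I,
#'   and inverts — a smooth alternative behind the same interface.
#' @param tol,maxIter convergence controls for the coordinate descent.
#' @param isCorrelation treat `ts` as an already-computed correlation matrix.
#' @return a [PrecisionEstimate-class].
#' @examples
#' S <- matrix(c(1, .8, .8, 1), 2)
#' precisionMatrix(estimatePrecision(S, 0, isCorrelation = TRUE))
#' @export
estimatePrecision <- function(ts, lambda, method = c("glasso", "ridge"),
                              tol = 1e-7, maxIter = 200,
                              isCorrelation = FALSE) {
  method <- match.arg(method)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (isCorrelation) {
    S <- as.matrix(ts)
    K <- ncol(S)
  } else {
    ts <- as.matrix(ts)
    if (nrow(ts) < 2) stop("need at least 2 frames")
    K <- ncol(ts)
    S <- cor(ts)
  }
  if (method == "ridge") {
    theta <- solve((1 - min(lambda, 1 - 1e-8)) * S +
                     min(lambda, 1 - 1e-8) * diag(K) +
                     if (lambda == 0) 1e-12 * diag(K) else 0)
    theta <- (theta + t(theta)) / 2
    return(new("PrecisionEstimate", theta = theta, lambdaUsed = lambda,
               converged = TRUE, iterations = 1L))
  }
  if (lambda == 0) {
    if (!isCorrelation && nrow(ts) <= K)
      stop("lambda = 0 requires T > K (sample correlation must be invertible)")
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    return(new("PrecisionEstimate", theta = theta, lambdaUsed = 0,
               converged = TRUE, iterations = 1L))
  }
  fit <- glasso_cpp(S, lambda, tol = tol, maxIter = as.integer(maxIter))
  theta <- (fit$theta + t(fit$theta)) / 2
  if (!fit$converged)
    warning("graphical lasso did not converge within ", maxIter,
            " sweeps; returning the partial result")
  new("PrecisionEstimate", theta = theta, lambdaUsed = lambda,
      converged = fit$converged, iterations = as.integer(fit$iterations))
}

#' @rdname PrecisionEstimate-class
#' @param x a PrecisionEstimate.
#' @export
setMethod("precisionMatrix", "PrecisionEstimate", function(x) x@theta)

setMethod("show", "PrecisionEstimate", function(object) {
  nz <- sum(abs(.upperVec(object@theta)) > 1e-10)
  cat("PrecisionEstimate:", nrow(object@theta), "nodes, lambda =",
      signif(object@lambdaUsed, 4), "\n")
  cat("  nonzero off-diagonal pairs:", nz, "; converged:",
      object@converged, "in", object@iterations, "sweeps\n")
})

#' Default penalty grid
#'
#' 20 log-spaced values in \[0.01, 1\].
#'
#' @param n grid size.
#' @param range penalty range.
#' @return numeric vector, ascending.
#' @export
lambdaGrid <- function(n = 20, range = c(0.01, 1)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Select the penalty by cross-validated held-out likelihood
#'
#' Splits the frames into contiguous blocks (respecting possible temporal
#' autocorrelation), fits the graphical lasso on the training frames for
#' every grid value (warm-started along the grid), and scores each penalty
#' by the mean held-out Gaussian log-likelihood
#' log det(Theta) - tr(S_test Theta). Ties break toward the smaller
#' penalty. Deterministic given its inputs.
#'
#' @param ts T x K time-series matrix.
#' @param grid ascending penalty grid (default [lambdaGrid()]).
#' @param folds number of contiguous-block folds (>= 2).
#' @param seed integer recorded for provenance (block folds are
#'   deterministic).
#' @return the selected penalty (scalar).
#' @export
selectLambda <- function(ts, grid = lambdaGrid(), folds = 5, seed = 1) {
  ts <- as.matrix(ts)
  nT <- nrow(ts)
  K <- ncol(ts)
  if (length(grid) == 0) stop("grid must be nonempty")
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  if (folds < 2) stop("need at least 2 folds")
  if (nT < 2 * folds) stop("too few frames to split into ", folds, " folds")
  if (length(grid) == 1) return(grid)

  bounds <- floor(seq(0, nT, length.out = folds + 1))
  score <- numeric(length(grid))
  for (f in seq_len(folds)) {
    testIdx <- (bounds[f] + 1):bounds[f + 1]
    train <- .demean(ts[-testIdx, , drop = FALSE], normalize = TRUE)
    test <- .demean(ts[testIdx, , drop = FALSE], normalize = TRUE)
    Strain <- crossprod(train) / (nrow(train) - 1)
    Stest <- crossprod(test) / (nrow(test) - 1)
    wPrev <- NULL
    bPrev <- NULL
    for (g in rev(seq_along(grid))) {      # warm start from strong penalty
      fit <- glasso_cpp(Strain, grid[g], wInit = wPrev, bInit = bPrev)
      wPrev <- fit$w
      bPrev <- fit$B
      th <- (fit$theta + t(fit$theta)) / 2
      score[g] <- score[g] +
        determinant(th, logarithm = TRUE)$modulus - sum(Stest * th)
    }
  }
  grid[which.max(score / folds)]
}

#' Convert a precision estimate to partial-correlation edges
#'
#' matrix\[i, j\] = -Theta_ij / sqrt(Theta_ii Theta_jj) for i != j, unit
#' diagonal; the edge vector enumerates the upper triangle row-major.
#'
#' @param theta a [PrecisionEstimate-class] or a K x K precision matrix.
#' @param nodeLabels optional node names.
#' @return a [ConnectivityEdges-class].
#' @export
precisionToPartial <- function(theta, nodeLabels = NULL) {
  if (is(theta, "PrecisionEstimate")) theta <- theta@theta
  K <- nrow(theta)
  p <- .partialFromTheta(theta)
  if (is.null(nodeLabels)) nodeLabels <- paste0("node_", seq_len(K))
  dimnames(p) <- list(nodeLabels, nodeLabels)
  v <- .upperVec(p)
  names(v) <- edgeLabels(K)
  new("ConnectivityEdges", matrix = p, vector = v, nodeLabels = nodeLabels)
}

#' @rdname ConnectivityEdges-class
#' @param x a ConnectivityEdges.
#' @export
setMethod("edgeVector", "ConnectivityEdges", function(x) x@vector)

#' @rdname ConnectivityEdges-class
#' @export
setMethod("partialMatrix", "ConnectivityEdges", function(x) x@matrix)

setMethod("show", "ConnectivityEdges", function(object) {
  cat("ConnectivityEdges:", length(object@nodeLabels), "nodes,",
      length(object@vector), "edges\n")
  cat("  |partial r| range:",
      paste(signif(range(abs(object@vector)), 3), collapse = " .. "), "\n")
})

#' Estimate partial-correlation edges for every run of a cohort
#'
#' For each subject-by-condition run: standardize the node time series,
#' select the penalty by block cross-validation (per run, unless a fixed
#' `lambda` is supplied), fit the graphical lasso, and store the
#' partial-correlation edge vector.
#'
#' @param cohort a [CohortTimeSeries-class].
#' @param lambda fixed penalty; `NULL` (default) selects per run by CV.
#' @param grid,folds CV controls passed to [selectLambda()].
#' @param method estimator passed to [estimatePrecision()].
#' @return an [EdgeExperiment-class] (edges x runs).
#' @export
cohortEdges <- function(cohort, lambda = NULL, grid = lambdaGrid(),
                        folds = 5, method = "glasso") {
  K <- cohort@nNodes
  E <- countEdges(K)
  sub <- subjects(cohort)
  keys <- names(cohort@series)
  X <- matrix(NA_real_, E, length(keys))
  lam <- numeric(length(keys))
  for (r in seq_along(keys)) {
    ts <- cohort@series[[keys[r]]]
    lamR <- if (is.null(lambda)) selectLambda(ts, grid, folds) else lambda
    est <- estimatePrecision(ts, lamR, method = method)
    X[, r] <- edgeVector(precisionToPartial(est))
    lam[r] <- lamR
  }
  parts <- matrix(unlist(strsplit(keys, ".", fixed = TRUE)), ncol = 2,
                  byrow = TRUE)
  cd <- DataFrame(subject = parts[, 1],
                  group = sub$group[match(parts[, 1], sub$id)],
                  condition = parts[, 2], lambda = lam)
  pr <- edgePairs(K)
  se <- SummarizedExperiment(assays = list(edges = X),
                             rowData = DataFrame(i = pr$i, j = pr$j,
                                                 label = edgeLabels(K)),
                             colData = cd)
  rownames(se) <- edgeLabels(K)
  colnames(se) <- keys
  new("EdgeExperiment", se)
}

#' @rdname EdgeExperiment-class
#' @param x an EdgeExperiment.
#' @return `edgeMatrix` returns the runs x edges matrix (transposed assay).
#' @export
setMethod("edgeMatrix", "EdgeExperiment", function(x) t(assay(x, "edges")))

setMethod("show", "EdgeExperiment", function(object) {
  cd <- colData(object)
  cat("EdgeExperiment:", nrow(object), "edges x", ncol(object), "runs\n")
  cat("  groups:", paste(names(table(cd$group)), table(cd$group),
                         sep = "=", collapse = ", "), "\n")
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
})

#' Write / read the cohort edge table
#'
#' Comma-separated, one row per run: subject_id, group, condition, lambda,
#' then `edge_1_2 ... edge_(K-1)_K` in row-major upper-triangle order.
#' Header comment lines (prefixed `#`) may carry provenance and are skipped
#' on read.
#'
#' @param ee an [EdgeExperiment-class].
#' @param path CSV file.
#' @param headerLines optional character vector of `# `-prefixed provenance
#'   lines.
#' @return `readEdgeTable` returns an [EdgeExperiment-class].
#' @export
writeEdgeTable <- function(ee, path, headerLines = NULL) {
  cd <- as.data.frame(colData(ee))
  tab <- cbind(data.frame(subject_id = cd$subject, group = cd$group,
                          condition = cd$condition, lambda = cd$lambda),
               as.data.frame(edgeMatrix(ee)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(headerLines))
    writeLines(paste0("# ", headerLines), con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeTable
#' @export
readEdgeTable <- function(path) {
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  edgeCols <- grep("^edge_", colnames(tab))
  X <- t(as.matrix(tab[, edgeCols]))
  K <- as.integer((1 + sqrt(1 + 8 * nrow(X))) / 2)
  pr <- edgePairs(K)
  se <- SummarizedExperiment(
    assays = list(edges = unname(X)),
    rowData = DataFrame(i = pr$i, j = pr$j, label = edgeLabels(K)),
    colData = DataFrame(subject = tab$subject_id, group = tab$group,
                        condition = tab$condition, lambda = tab$lambda))
  rownames(se) <- edgeLabels(K)
  colnames(se) <- paste(tab$subject_id, tab$condition, sep = ".")
  new("EdgeExperiment", se)
}
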