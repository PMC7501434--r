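#' @import methods
#' @importFrom stats cor sd pf pt rnorm runif setNames p.adjust
#'   chisq.test predict cov2cor contr.sum
#' @importFrom utils write.table read.table read.csv write.csv head
#' @useDynLib fcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

.GROUPS <- c("patient", "control")
.CONDITIONS <- c("rest", "L1", "L2")

#' Ground-truth generative network model
#'
#' Holds, for every (group, condition) cell of the design, a sparse
#' symmetric positive-definite precision matrix (whose normalized negative
#' off-diagonal entries are the cell's true partial correlations) and a
#' vector of nodal time-series standard deviations (the ground truth for
#' nodal signal variability, SDSA). The effect table records which edges
#' carry condition and group effects.
#'
#' @slot nNodes number of network nodes K.
#' @slot groups,conditions design levels (patient/control; rest/L1/L2).
#' @slot precision named list `group.condition` -> K x K precision matrix.
#' @slot nodeScale named list `group.condition` -> K-vector of SDs.
#' @slot effects data.frame with columns i, j, type and the target partial
#'   correlation per cell (columns named `group.condition`).
#' @slot seed integer seed used to build the model.
#' @export
setClass("GroundTruthModel",
  representation(nNodes = "integer", groups = "character",
                 conditions = "character", precision = "list",
                 nodeScale = "list", effects = "data.frame",
                 seed = "integer"))

setValidity("GroundTruthModel", function(object) {
  K <- object@nNodes
  cells <- as.vector(outer(object@groups, object@conditions, paste, sep = "."))
  if (!all(cells %in% names(object@precision)))
    return("precision must have one matrix per (group, condition) cell")
  for (cell in cells) {
    Th <- object@precision[[cell]]
    if (!is.matrix(Th) || nrow(Th) != K || ncol(Th) != K)
      return(sprintf("precision[[%s]] is not K x K", cell))
    if (max(abs(Th - t(Th))) > 1e-8)
      return(sprintf("precision[[%s]] is not symmetric", cell))
    ev <- min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      return(sprintf("precision[[%s]] is not positive definite", cell))
    sc <- object@nodeScale[[cell]]
    if (is.null(sc) || length(sc) != K || any(sc <= 0))
      return(sprintf("nodeScale[[%s]] must be K strictly positive values", cell))
  }
  if (nrow(object@effects)) {
    if (any(object@effects$i >= object@effects$j))
      return("effect edges must have i < j")
    if (any(object@effects$j > K) || any(object@effects$i < 1))
      return("effect edge node indices out of range")
  }
  TRUE
})

#' Cohort of per-subject, per-condition node time series
#'
#' @slot subjects DataFrame with columns id, group.
#' @slot series named list `id.condition` -> T x K matrix.
#' @slot frames named integer vector of frames per condition.
#' @slot nNodes number of nodes K.
#' @slot seed master seed; per-run seeds are recorded in `runSeeds`.
#' @slot runSeeds named integer vector `id.condition` -> seed.
#' @export
setClass("CohortTimeSeries",
  representation(subjects = "DataFrame", series = "list",
                 frames = "integer", nNodes = "integer",
                 seed = "integer", runSeeds = "integer"))

setValidity("CohortTimeSeries", function(object) {
  ids <- object@subjects$id
  conds <- names(object@frames)
  want <- as.vector(outer(ids, conds, paste, sep = "."))
  if (!all(want %in% names(object@series)))
    return("every subject must have a series for every condition")
  for (nm in want) {
    m <- object@series[[nm]]
    if (!is.matrix(m) || ncol(m) != object@nNodes)
      return(sprintf("series[[%s]] must have nNodes columns", nm))
    if (anyNA(m)) return(sprintf("series[[%s]] contains missing frames", nm))
  }
  TRUE
})

#' Toy 4D volume set for exercising dual regression
#'
#' Voxel-by-time matrices built as maps %*% t(series) plus optional lesion
#' signal confined to a binary mask, plus i.i.d. noise.
#'
#' @slot maps V x K spatial maps.
#' @slot lesionMask V-vector in {0,1}.
#' @slot volumes named list `id.condition` -> V x T matrix.
#' @slot lesionSignal named list `id.condition` -> T-vector (may be empty).
#' @slot gridDim 3D grid used when writing NIfTI.
#' @export
setClass("ToyVolumeSet",
  representation(maps = "matrix", lesionMask = "numeric", volumes = "list",
                 lesionSignal = "list", gridDim = "integer"))

setValidity("ToyVolumeSet", function(object) {
  if (!all(object@lesionMask %in% c(0, 1))) return("lesionMask must be binary")
  V <- nrow(object@maps)
  if (length(object@lesionMask) != V) return("lesionMask length must equal V")
  if (qr(object@maps)$rank < ncol(object@maps))
    return("map columns must be linearly independent")
  if (V < ncol(object@maps) + 1) return("need V >= K + 1 voxels")
  TRUE
})

#' Regularized precision-matrix estimate
#'
#' @slot theta K x K symmetric positive-definite precision matrix.
#' @slot lambdaUsed L1 penalty applied to off-diagonal entries.
#' @slot converged logical convergence flag.
#' @slot iterations outer-loop sweeps used.
#' @export
setClass("PrecisionEstimate",
  representation(theta = "matrix", lambdaUsed = "numeric",
                 converged = "logical", iterations = "integer"))

setValidity("PrecisionEstimate", function(object) {
  Th <- object@theta
  if (max(abs(Th - t(Th))) > 1e-8) return("theta must be symmetric to 1e-8")
  if (min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return("theta must be positive definite")
  if (object@lambdaUsed < 0) return("lambdaUsed must be nonnegative")
  TRUE
})

#' Partial-correlation connectivity matrix and its edge vector
#'
#' The edge vector enumerates the upper triangle in row-major order:
#' (1,2),(1,3),...,(1,K),(2,3),...,(K-1,K); for K = 30 this yields the 435
#' unique edges of the network.
#'
#' @slot matrix K x K partial correlations with unit diagonal.
#' @slot vector length K(K-1)/2 edge vector.
#' @slot nodeLabels node names.
#' @export
setClass("ConnectivityEdges",
  representation(matrix = "matrix", vector = "numeric",
                 nodeLabels = "character"))

setValidity("ConnectivityEdges", function(object) {
  K <- nrow(object@matrix)
  if (length(object@vector) != K * (K - 1) / 2)
    return("vector length must be K(K-1)/2")
  if (any(abs(object@vector) > 1 + 1e-8))
    return("partial correlations must lie in [-1, 1]")
  if (max(abs(diag(object@matrix) - 1)) > 1e-8)
    return("matrix diagonal must be 1")
  v2 <- t(object@matrix)[lower.tri(object@matrix)]
  if (max(abs(v2 - object@vector)) > 1e-8)
    return("vector must match the row-major upper triangle of matrix")
  TRUE
})

#' Cohort-level edge container
#'
#' A SummarizedExperiment whose single assay holds one edge vector per
#' column (one column per subject-by-condition run); rowData carries the
#' node-pair labels, colData the subject id, group, condition and the
#' penalty used for that run.
#'
#' @export
setClass("EdgeExperiment", contains = "SummarizedExperiment")

setValidity("EdgeExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "group", "condition")
  if (!all(need %in% colnames(cd)))
    return("colData must contain subject, group, condition")
  if (!"edges" %in% SummarizedExperiment::assayNames(object))
    return("assay 'edges' is required")
  TRUE
})

#' Labelled feature matrix for classification
#'
#' @slot X N x E matrix of edge strengths (rows = runs or subjects).
#' @slot y factor of labels.
#' @slot subject subject id per row.
#' @slot labelSpace ordered label levels.
#' @export
setClass("EdgeDataset",
  representation(X = "matrix", y = "factor", subject = "character",
                 labelSpace = "character"))

setValidity("EdgeDataset", function(object) {
  if (nrow(object@X) != length(object@y)) return("X rows must match labels")
  if (length(object@subject) != length(object@y))
    return("subject ids must match labels")
  if (anyNA(object@X)) return("X must have no missing entries")
  if (!all(levels(object@y) == object@labelSpace))
    return("labelSpace must equal the label levels")
  TRUE
})

#' Shrinkage-regularized LDA model
#'
#' Pooled within-class covariance shrunk toward its diagonal,
#' Sigma* = (1 - gamma) Sigma + gamma diag(Sigma), with gamma the analytic
#' optimal intensity estimated from the data and clipped to \[0, 1\].
#'
#' @slot classMeans L x E matrix of class mean vectors.
#' @slot pooledCov E x E shrunk covariance.
#' @slot shrinkageIntensity gamma in \[0, 1\].
#' @slot priors per-class prior probabilities (sum to 1).
#' @export
setClass("ShrinkageLdaModel",
  representation(classMeans = "matrix", pooledCov = "matrix",
                 shrinkageIntensity = "numeric", priors = "numeric"))

setValidity("ShrinkageLdaModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-8) return("priors must sum to 1")
  if (object@shrinkageIntensity < 0 || object@shrinkageIntensity > 1)
    return("shrinkage intensity must be in [0, 1]")
  TRUE
})

#' Classification report
#'
#' @slot confusion L x L count matrix, rows = true class, cols = predicted.
#' @slot perClassAccuracy named per-class recall.
#' @slot meanAccuracy mean of per-class accuracies.
#' @slot pPerm permutation p-value (NA until a permutation test is run).
#' @slot nPermutations permutations behind pPerm.
#' @slot chanceLevel analytic chance level 1/L.
#' @slot task "condition" or "group".
#' @export
setClass("ClassificationReport",
  representation(confusion = "matrix", perClassAccuracy = "numeric",
                 meanAccuracy = "numeric", pPerm = "numeric",
                 nPermutations = "integer", chanceLevel = "numeric",
                 task = "character"))

setValidity("ClassificationReport", function(object) {
  acc <- object@perClassAccuracy
  if (any(acc < -1e-12 | acc > 1 + 1e-12)) return("accuracies must be in [0,1]")
  if (nrow(object@confusion) != ncol(object@confusion))
    return("confusion matrix must be square")
  TRUE
})
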