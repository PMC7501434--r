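# Cholesky factor of the model covariance for one design cell:
# Sigma = D R D, where R is the correlation implied by the inverse precision
# and D carries the nodal SD scales (the SDSA ground truth).
.cellCovChol <- function(model, group, condition) {
  cell <- paste(group, condition, sep = ".")
  theta <- model@precision[[cell]]
  if (is.null(theta)) stop("unknown design cell: ", cell)
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("precision matrix is not positive definite")
  C <- solve(theta)
  R <- stats::cov2cor(C)
  sc <- model@nodeScale[[cell]]
  chol(diag(sc) %*% R %*% diag(sc))
}

# draw T i.i.d. zero-mean Gaussian frames with covariance chol'chol
.drawFrames <- function(cholSigma, nFrames, seed, ar = 0) {
  K <- ncol(cholSigma)
  set.seed(seed)
  Z <- matrix(rnorm(nFrames * K), nFrames, K)
  if (ar != 0) {
    # optional AR(1) innovation filter, variance-preserving
    for (t in 2:nFrames) Z[t, ] <- ar * Z[t - 1, ] + sqrt(1 - ar^2) * Z[t, ]
  }
  Z %*% cholSigma
}

#' Sample a node time-series matrix from the generative model
#'
#' Frames are independent draws (optionally AR(1)-filtered) from a zero-mean
#' multivariate normal whose correlation structure is the inverse of the
#' cell's precision matrix and whose column SDs equal the cell's node scale.
#'
#' @param model a [GroundTruthModel-class].
#' @param group,condition design cell.
#' @param nFrames number of frames T (rows).
#' @param seed integer seed.
#' @param ar optional AR(1) coefficient for temporal autocorrelation.
#' @return T x K numeric matrix with columns `node_1..node_K`.
#' @export
sampleTimeSeries <- function(model, group, condition, nFrames, seed, ar = 0) {
  if (!is.numeric(nFrames) || nFrames < 1) stop("nFrames must be at least 1")
  ch <- .cellCovChol(model, group, condition)
  ts <- .drawFrames(ch, as.integer(nFrames), seed, ar)
  colnames(ts) <- paste0("node_", seq_len(ncol(ts)))
  ts
}

#' Generate a full synthetic cohort
#'
#' Samples every subject-by-condition run from the model. Deterministic:
#' the run for subject s and condition c uses seed `seed + 1000 + run index`,
#' so any single run can be regenerated in isolation.
#'
#' @param model a [GroundTruthModel-class].
#' @param nPatients,nControls group sizes (default 44 and 100).
#' @param frames named vector of frames per condition
#'   (default rest 200, tasks 152).
#' @param seed master integer seed.
#' @param ar optional AR(1) coefficient passed to the sampler.
#' @return a [CohortTimeSeries-class].
#' @examples
#' m <- makeGroundTruth(nNodes = 5, sparsity = 0.2, seed = 1)
#' ch <- generateCohort(m, nPatients = 2, nControls = 2,
#'                      frames = c(rest = 40, L1 = 30, L2 = 30), seed = 1)
#' subjects(ch)
#' @export
generateCohort <- function(model, nPatients = 44, nControls = 100,
                           frames = c(rest = 200L, L1 = 152L, L2 = 152L),
                           seed = 1, ar = 0) {
  if (nPatients < 2 || nControls < 2) stop("need at least 2 subjects per group")
  frames <- setNames(as.integer(frames), names(frames))
  if (!all(model@conditions %in% names(frames)))
    stop("frames must name every condition")
  frames <- frames[model@conditions]

  ids <- c(sprintf("P%03d", seq_len(nPatients)),
           sprintf("C%03d", seq_len(nControls)))
  grp <- rep(c("patient", "control"), c(nPatients, nControls))
  subjectTab <- DataFrame(id = ids, group = grp)

  chols <- list()
  for (g in model@groups) for (cond in model@conditions)
    chols[[paste(g, cond, sep = ".")]] <- .cellCovChol(model, g, cond)

  series <- list()
  runSeeds <- integer(0)
  runIdx <- 0L
  for (s in seq_along(ids)) {
    for (cond in model@conditions) {
      runIdx <- runIdx + 1L
      runSeed <- as.integer(seed + 1000L + runIdx)
      key <- paste(ids[s], cond, sep = ".")
      ts <- .drawFrames(chols[[paste(grp[s], cond, sep = ".")]],
                        frames[[cond]], runSeed, ar)
      colnames(ts) <- paste0("node_", seq_len(model@nNodes))
      series[[key]] <- ts
      runSeeds[key] <- runSeed
    }
  }

  new("CohortTimeSeries", subjects = subjectTab, series = series,
      frames = frames, nNodes = model@nNodes, seed = as.integer(seed),
      runSeeds = runSeeds)
}

#' @rdname CohortTimeSeries-class
#' @param x a CohortTimeSeries.
#' @export
setMethod("subjects", "CohortTimeSeries", function(x)
  as.data.frame(x@subjects))

#' @rdname CohortTimeSeries-class
#' @param id,condition run key.
#' @export
setMethod("seriesMatrix", "CohortTimeSeries", function(x, id, condition) {
  m <- x@series[[paste(id, condition, sep = ".")]]
  if (is.null(m)) stop("no series for ", id, " / ", condition)
  m
})

#' @rdname CohortTimeSeries-class
#' @export
setMethod("nNodes", "CohortTimeSeries", function(x) x@nNodes)

setMethod("show", "CohortTimeSeries", function(object) {
  tb <- table(object@subjects$group)
  cat("CohortTimeSeries:", nrow(object@subjects), "subjects (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ")\n")
  cat("  nodes:", object@nNodes, " frames:",
      paste(names(object@frames), object@frames, sep = "=", collapse = ", "),
      "\n")
  cat("  runs:", length(object@series), " seed:", object@seed, "\n")
})

#' Build toy 4D volumes from a cohort for exercising dual regression
#'
#' Each run's voxel-by-time matrix is `maps %*% t(series)` plus, optionally,
#' a lesion signal confined to a binary voxel mask, plus i.i.d. Gaussian
#' noise.
#'
#' @param maps V x K matrix of spatial maps (full column rank).
#' @param cohort a [CohortTimeSeries-class].
#' @param lesion optional list with elements `mask` (V-vector in 0/1) and
#'   `amplitude` (SD of the injected lesion time course).
#' @param noiseSd SD of additive voxel noise.
#' @param seed integer seed for lesion signal and noise.
#' @return a [ToyVolumeSet-class].
#' @export
makeToyVolumes <- function(maps, cohort, lesion = NULL, noiseSd = 0, seed = 1) {
  maps <- as.matrix(maps)
  if (qr(maps)$rank < ncol(maps))
    stop("maps must have full column rank")
  V <- nrow(maps)
  mask <- rep(0, V)
  amp <- 0
  if (!is.null(lesion)) {
    mask <- as.numeric(lesion$mask)
    if (length(mask) != V || !all(mask %in% c(0, 1)))
      stop("lesion$mask must be a binary V-vector")
    amp <- lesion$amplitude
  }
  set.seed(seed)
  volumes <- list()
  lesionSignal <- list()
  for (key in names(cohort@series)) {
    ts <- cohort@series[[key]]
    vol <- maps %*% t(ts)
    if (amp != 0) {
      ls <- amp * rnorm(nrow(ts))
      vol <- vol + outer(mask, ls)
      lesionSignal[[key]] <- ls
    }
    if (noiseSd > 0)
      vol <- vol + matrix(rnorm(length(vol), sd = noiseSd), nrow(vol))
    volumes[[key]] <- vol
  }
  side <- ceiling(V^(1 / 3))
  new("ToyVolumeSet", maps = maps, lesionMask = mask, volumes = volumes,
      lesionSignal = lesionSignal,
      gridDim = as.integer(c(side, side, ceiling(V / side^2))))
}
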