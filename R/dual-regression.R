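# demean columns; optionally scale to unit variance
.demean <- function(m, normalize = FALSE) {
  m <- sweep(m, 2, colMeans(m))
  if (normalize) {
    s <- apply(m, 2, sd)
    if (any(s == 0)) stop("cannot variance-normalize a constant column")
    m <- sweep(m, 2, s, "/")
  }
  m
}

.checkFullRank <- function(X, what) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])
    stop(sprintf("%s is rank deficient; collinear column(s): %s", what,
                 paste(bad, collapse = ", ")))
  }
}

#' Stage-1 (spatial) regression of group maps into a 4D dataset
#'
#' For every time point, regresses the volume's voxel vector on the demeaned
#' group spatial maps (plus, optionally, the lesion mask as an extra spatial
#' regressor), yielding one time series per map.
#'
#' @param volume V x T voxel-by-time matrix.
#' @param maps V x K group spatial maps.
#' @param lesionMask optional V-vector appended as regressor K+1.
#' @param normalize variance-normalize the regressors as well as demeaning
#'   them (off by default; demeaning follows the standard dual-regression
#'   convention).
#' @return T x K (or T x (K+1)) matrix of time series.
#' @export
stage1SpatialRegression <- function(volume, maps, lesionMask = NULL,
                                    normalize = FALSE) {
  X <- as.matrix(maps)
  if (!is.null(lesionMask)) X <- cbind(X, lesion = as.numeric(lesionMask))
  if (nrow(X) != nrow(volume)) stop("maps and volume voxel counts differ")
  if (nrow(X) <= ncol(X)) stop("need more voxels than regressors")
  X <- .demean(X, normalize)
  .checkFullRank(X, "spatial regressor set")
  beta <- solve(crossprod(X), crossprod(X, volume))  # K' x T
  ts <- t(beta)
  K <- ncol(maps)
  nm <- if (!is.null(colnames(maps))) colnames(maps) else
    paste0("node_", seq_len(K))
  colnames(ts) <- if (is.null(lesionMask)) nm else c(nm, "lesion")
  ts
}

#' Stage-2 (temporal) regression of subject time series into the 4D dataset
#'
#' Per-voxel OLS of the volume on the demeaned time series, yielding
#' subject-specific spatial maps.
#'
#' @param volume V x T voxel-by-time matrix.
#' @param timeseries T x K matrix (typically the lesion-discarded stage-1
#'   output).
#' @param normalize also variance-normalize the temporal regressors.
#' @return V x K matrix of subject-specific maps.
#' @export
stage2TemporalRegression <- function(volume, timeseries, normalize = FALSE) {
  X <- .demean(as.matrix(timeseries), normalize)
  if (nrow(X) != ncol(volume)) stop("timeseries frames must match volume")
  if (nrow(X) <= ncol(X)) stop("need more frames than components")
  .checkFullRank(X, "temporal regressor set")
  t(solve(crossprod(X), crossprod(X, t(volume))))
}

#' Separate the lesion time series from a stage-1 result
#'
#' When the lesion mask was included as regressor K+1, its estimated time
#' series is split off and stored; the node time series that go forward to
#' network modelling have exactly K columns.
#'
#' @param timeseries stage-1 output (T x K or T x (K+1)).
#' @param lesionPresent was the lesion regressor included?
#' @param K number of network components.
#' @return list with elements `timeseries` (T x K) and `lesionTimeseries`
#'   (T-vector or NULL).
#' @export
dropLesionComponent <- function(timeseries, lesionPresent, K) {
  timeseries <- as.matrix(timeseries)
  if (lesionPresent) {
    if (ncol(timeseries) != K + 1)
      stop("lesion flagged present but stage-1 output does not have K+1 columns")
    list(timeseries = timeseries[, seq_len(K), drop = FALSE],
         lesionTimeseries = timeseries[, K + 1])
  } else {
    if (ncol(timeseries) != K)
      stop("stage-1 output does not have K columns")
    list(timeseries = timeseries, lesionTimeseries = NULL)
  }
}

#' Run both dual-regression stages for one subject
#'
#' @inheritParams stage1SpatialRegression
#' @return list with `timeseries` (T x K, lesion removed),
#'   `lesionTimeseries` (or NULL) and `subjectMaps` (V x K).
#' @export
dualRegression <- function(volume, maps, lesionMask = NULL,
                           normalize = FALSE) {
  K <- ncol(maps)
  ts1 <- stage1SpatialRegression(volume, maps, lesionMask, normalize)
  dropped <- dropLesionComponent(ts1, !is.null(lesionMask), K)
  subjectMaps <- stage2TemporalRegression(volume, dropped$timeseries,
                                          normalize)
  c(dropped, list(subjectMaps = subjectMaps))
}

#' Regress a confound trace out of node time series
#'
#' Removes the column space of the demeaned confounds (e.g. a T x 6 motion
#' trace) from each node time series.
#'
#' @param timeseries T x K matrix.
#' @param confounds T x C matrix.
#' @return residual T x K matrix (column means restored).
#' @export
regressConfounds <- function(timeseries, confounds) {
  X <- .demean(as.matrix(confounds))
  if (nrow(X) != nrow(timeseries)) stop("confound frames must match series")
  mu <- colMeans(timeseries)
  Yc <- sweep(as.matrix(timeseries), 2, mu)
  res <- Yc - X %*% solve(crossprod(X), crossprod(X, Yc))
  sweep(res, 2, mu, "+")
}

# rotation matrix for small-angle Euler rotations applied in x, y, z order
.rotationMatrix <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Mean frame-to-frame RMS displacement of a rigid-body motion trace
#'
#' For each pair of consecutive frames the relative rigid transform is
#' formed and the RMS displacement of the points of a sphere of radius R
#' under that transform is computed as
#' sqrt(R^2/5 * tr(M'M) + t't), with M the linear part minus the identity
#' and t the relative translation; the metric is the mean over frame pairs.
#'
#' @param params F x 6 matrix: rotations (radians, x/y/z) in columns 1-3,
#'   translations (mm) in columns 4-6.
#' @param sphereRadius sphere radius in mm (default 80, the conventional
#'   value making the metric comparable across studies).
#' @return mean relative RMS displacement in mm.
#' @export
meanRelativeRms <- function(params, sphereRadius = 80) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("params must have 6 columns")
  nF <- nrow(params)
  if (nF < 2) stop("need at least 2 frames for a relative metric")
  rot <- lapply(seq_len(nF), function(f)
    .rotationMatrix(params[f, 1], params[f, 2], params[f, 3]))
  disp <- numeric(nF - 1)
  for (f in 2:nF) {
    Rrel <- rot[[f]] %*% t(rot[[f - 1]])
    M <- Rrel - diag(3)
    tRel <- params[f, 4:6] - Rrel %*% params[f - 1, 4:6]
    disp[f - 1] <- sqrt(sphereRadius^2 / 5 * sum(M * M) + sum(tRel^2))
  }
  mean(disp)
}
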