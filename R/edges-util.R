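#' Number of unique edges among K nodes
#'
#' K(K-1)/2 unordered node pairs; 30 nodes give 435 edges.
#'
#' @param K node count, at least 2.
#' @return integer edge count.
#' @export
countEdges <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || K < 2)
    stop("K must be a single number >= 2")
  as.integer(K * (K - 1) / 2)
}

#' Node-pair enumeration in row-major upper-triangle order
#'
#' The canonical edge ordering used by every edge vector in the package:
#' (1,2),(1,3),...,(1,K),(2,3),...,(K-1,K).
#'
#' @param K node count.
#' @return data.frame with columns i, j (i < j).
#' @export
edgePairs <- function(K) {
  i <- rep.int(seq_len(K - 1), times = (K - 1):1)
  j <- unlist(lapply(seq_len(K - 1), function(a) (a + 1):K))
  data.frame(i = i, j = j)
}

#' @rdname edgePairs
#' @export
edgeLabels <- function(K) {
  p <- edgePairs(K)
  sprintf("edge_%d_%d", p$i, p$j)
}

# row-major upper triangle of a square matrix
.upperVec <- function(m) t(m)[lower.tri(m)]

# inverse of .upperVec
.vecToSym <- function(v, K, diagValue = 1) {
  m <- matrix(0, K, K)
  m[lower.tri(m)] <- v
  m <- t(m)
  m <- m + t(m)
  diag(m) <- diagValue
  m
}

# partial correlations implied by a precision matrix
.partialFromTheta <- function(theta) {
  d <- diag(theta)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  p <- -theta / sqrt(outer(d, d))
  diag(p) <- 1
  p
}
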