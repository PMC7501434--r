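# shared fixtures, all built in code

# 3-node chain precision: nodes 1-2-3 coupled, no direct 1-3 link
chainPrecision3 <- function() {
  matrix(c(1.5, -0.6, 0,
           -0.6, 1.8, -0.6,
           0, -0.6, 1.5), 3, 3)
}

# ground-truth model with the group effect switched off (null group)
makeNullGroupModel <- function(K = 10, seed = 1) {
  makeGroundTruth(nNodes = K, sparsity = 0.15,
                  effects = defaultEffectSpec(K, groupDelta = 0),
                  seed = seed)
}

# tiny EdgeExperiment straight from simulated edge vectors (bypasses the
# estimator) for fast classification/ANOVA tests: values[s, c, e]
edgeExperimentFromArray <- function(values, groupLabels,
                                    conditions = c("rest", "L1", "L2")) {
  N <- dim(values)[1]
  E <- dim(values)[3]
  ids <- sprintf("S%03d", seq_len(N))
  X <- matrix(NA_real_, E, N * length(conditions))
  subj <- character(N * length(conditions))
  cond <- character(N * length(conditions))
  k <- 0
  for (s in seq_len(N)) for (ci in seq_along(conditions)) {
    k <- k + 1
    X[, k] <- values[s, ci, ]
    subj[k] <- ids[s]
    cond[k] <- conditions[ci]
  }
  K <- as.integer(ceiling((1 + sqrt(1 + 8 * E)) / 2))
  pr <- edgePairs(K)[seq_len(E), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edges = X),
    rowData = S4Vectors::DataFrame(i = pr$i, j = pr$j,
                                   label = edgeLabels(K)[seq_len(E)]),
    colData = S4Vectors::DataFrame(subject = subj,
                                   group = rep(as.character(groupLabels),
                                               each = length(conditions)),
                                   condition = cond, lambda = 0))
  rownames(se) <- edgeLabels(K)[seq_len(E)]
  colnames(se) <- paste(subj, cond, sep = ".")
  new("EdgeExperiment", se)
}

# row subset of an EdgeDataset (test-side mirror of the internal helper)
.subsetDatasetForTest <- function(ds, idx) fcnet:::.subsetDataset(ds, idx)

# brute-force split-plot oracle: between stratum by explicit summation on
# subject means, within stratum by QR least-squares model comparison with
# sum contrasts (independent of the package's projection code path)
oracleMixedAnova <- function(Y, g) {
  Y <- as.matrix(Y)
  N <- nrow(Y); C <- ncol(Y)
  g <- factor(g)
  G <- nlevels(g)
  M <- rowMeans(Y)
  gm <- tapply(M, g, mean)
  grand <- mean(M)
  ssg <- C * sum(table(g) * (gm - grand)^2)
  sss <- C * sum((M - gm[as.integer(g)])^2)
  D <- Y - M
  Cc <- stats::contr.sum(C)
  Gc <- stats::contr.sum(G)
  Z1 <- Cc[rep(seq_len(C), each = N), , drop = FALSE]
  Z2full <- NULL
  Gbig <- Gc[as.integer(g), , drop = FALSE][rep(seq_len(N), C), , drop = FALSE]
  for (a in seq_len(G - 1)) for (b in seq_len(C - 1))
    Z2full <- cbind(Z2full, Gbig[, a] * Z1[, b])
  d <- as.vector(D)
  rss <- function(X) sum(lm.fit(X, d)$residuals^2)
  rssF <- rss(cbind(Z1, Z2full))
  ssc <- rss(Z2full) - rssF
  ssi <- rss(Z1) - rssF
  ssres <- rssF
  dfe <- (N - G) * (C - 1)
  list(F_group = (ssg / (G - 1)) / (sss / (N - G)),
       F_condition = (ssc / (C - 1)) / (ssres / dfe),
       F_interaction = (ssi / ((G - 1) * (C - 1))) / (ssres / dfe))
}
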