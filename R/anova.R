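# Split-plot (mixed design) ANOVA core, vectorized over features.
#
# values: N x C x E array (subjects x conditions x features), complete.
# groupLabels: factor of length N.
#
# Decomposition: the between-subject stratum splits into group and
# subject-within-group; the within-subject stratum into condition,
# group x condition, and condition x subject-within-group (the error term
# for both within effects). With unequal group sizes the within-stratum
# fixed effects use Type III (sum-contrast model-comparison) sums of
# squares; for the single between factor Type I and Type III coincide.
.splitPlotCore <- function(values, groupLabels) {
  dims <- dim(values)
  N <- dims[1]; C <- dims[2]; E <- dims[3]
  g <- factor(groupLabels)
  G <- nlevels(g)
  if (G < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("need at least 2 subjects per group")
  if (anyNA(values)) stop("missing cells are not supported (no imputation)")

  flat <- matrix(values, N * C, E)           # condition-major rows
  M <- matrix(0, N, E)                       # subject means
  for (c in seq_len(C)) M <- M + flat[(c - 1) * N + seq_len(N), , drop = FALSE]
  M <- M / C

  # between stratum
  grand <- colMeans(M)
  gm <- rowsum(M, g) / as.vector(table(g))   # G x E group means of subj means
  ssGroup <- C * colSums(as.vector(table(g)) * sweep(gm, 2, grand)^2)
  ssSubj <- C * colSums((M - gm[as.integer(g), , drop = FALSE])^2)

  # within stratum: deviations from subject means
  # (rows of flat are condition-major: row (c-1)N+s)
  D <- flat - do.call(rbind, replicate(C, list(M)))

  Cc <- stats::contr.sum(C)                  # C x (C-1)
  Gc <- stats::contr.sum(G)                  # G x (G-1)
  CcBig <- Cc[rep(seq_len(C), each = N), , drop = FALSE]
  GcBig <- Gc[as.integer(g), , drop = FALSE][rep(seq_len(N), C), , drop = FALSE]
  Z1 <- CcBig
  Z2 <- matrix(0, N * C, (G - 1) * (C - 1))
  k <- 0
  for (a in seq_len(G - 1)) for (b in seq_len(C - 1)) {
    k <- k + 1
    Z2[, k] <- GcBig[, a] * CcBig[, b]
  }

  modelSS <- function(X) {
    B <- solve(crossprod(X), crossprod(X, D))
    colSums((X %*% B) * D)
  }
  ssFull <- modelSS(cbind(Z1, Z2))
  ssCond <- ssFull - modelSS(Z2)             # Type III: drop condition
  ssInt <- ssFull - modelSS(Z1)              # Type III: drop interaction
  ssResid <- colSums(D^2) - ssFull

  dfG <- c(G - 1, N - G)
  dfC <- c(C - 1, (N - G) * (C - 1))
  dfI <- c((G - 1) * (C - 1), (N - G) * (C - 1))

  scale <- pmax(colMeans(flat^2), .Machine$double.eps)
  degenerate <- (ssSubj + ssResid) < 1e-12 * scale * (N * C)

  fstat <- function(ssNum, dfNum, ssErr, dfErr) {
    msErr <- ssErr / dfErr
    f <- ifelse(degenerate | msErr <= 0, 0, (ssNum / dfNum) / msErr)
    p <- ifelse(degenerate | msErr <= 0, 1, pf(f, dfNum, dfErr, lower.tail = FALSE))
    list(F = f, p = p)
  }
  fg <- fstat(ssGroup, dfG[1], ssSubj, dfG[2])
  fc <- fstat(ssCond, dfC[1], ssResid, dfC[2])
  fi <- fstat(ssInt, dfI[1], ssResid, dfI[2])

  data.frame(F_group = fg$F, df1_group = dfG[1], df2_group = dfG[2],
             p_group = fg$p,
             F_condition = fc$F, df1_condition = dfC[1],
             df2_condition = dfC[2], p_condition = fc$p,
             F_interaction = fi$F, df1_interaction = dfI[1],
             df2_interaction = dfI[2], p_interaction = fi$p,
             degenerate = degenerate)
}

#' Mixed-design (split-plot) repeated-measures ANOVA for one measure
#'
#' One between-subject factor (group) and one within-subject factor
#' (condition, all levels observed in every subject). Group is tested
#' against subject-within-group; condition and the group-by-condition
#' interaction against condition-by-subject-within-group. Unequal group
#' sizes are handled with Type III (sum-contrast) sums of squares.
#'
#' @param values N x C matrix, one row per subject, one column per
#'   condition (no missing cells).
#' @param groupLabels factor of length N.
#' @return one-row data.frame with F, df and p for group, condition and
#'   interaction, plus a `degenerate` flag (TRUE when the data carry no
#'   variance, in which case F is reported as 0).
#' @export
mixedAnova <- function(values, groupLabels) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("every subject needs all condition values")
  res <- .splitPlotCore(array(values, dim = c(dim(values), 1)), groupLabels)
  rownames(res) <- NULL
  res
}

#' Edgewise mixed ANOVA over a cohort edge table
#'
#' Runs the split-plot ANOVA for every edge and applies Benjamini-Hochberg
#' FDR separately per effect (group, condition, interaction) at level `q`.
#'
#' @param ee an [EdgeExperiment-class] with all three conditions per
#'   subject.
#' @param q FDR level (default 0.05).
#' @return data.frame, one row per edge: node pair, F/df/p per effect,
#'   and per-effect `nominal_*` (p < .05) and `fdr_*` flags.
#' @export
edgewiseAnova <- function(ee, q = 0.05) {
  arr <- .edgeArray(ee)
  res <- .splitPlotCore(arr$values, arr$groupLabels)
  pr <- as.data.frame(rowData(ee))
  out <- cbind(data.frame(edge = pr$label, i = pr$i, j = pr$j), res)
  for (eff in c("group", "condition", "interaction")) {
    p <- out[[paste0("p_", eff)]]
    out[[paste0("nominal_", eff)]] <- p < 0.05
    out[[paste0("fdr_", eff)]] <- fdrBh(p, q)
  }
  out
}

# reshape an EdgeExperiment into subjects x conditions x edges
.edgeArray <- function(ee) {
  cd <- colData(ee)
  subj <- unique(as.character(cd$subject))
  conds <- intersect(.CONDITIONS, unique(cd$condition))
  X <- assay(ee, "edges")                    # E x runs
  E <- nrow(X)
  values <- array(NA_real_, dim = c(length(subj), length(conds), E))
  for (ci in seq_along(conds)) {
    sel <- which(cd$condition == conds[ci])
    ord <- sel[match(subj, as.character(cd$subject[sel]))]
    if (anyNA(ord)) stop("every subject needs all conditions")
    values[, ci, ] <- t(X[, ord, drop = FALSE])
  }
  groupLabels <- factor(cd$group[match(subj, as.character(cd$subject))],
                        levels = .GROUPS)
  list(values = values, groupLabels = droplevels(groupLabels),
       subjects = subj, conditions = conds)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q` under independence or positive
#' dependence: sort the p-values ascending, find the largest i with
#' p(i) <= i q / m, reject hypotheses 1..i.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q FDR level.
#' @return logical rejection flags (empty input gives empty output).
#' @export
fdrBh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH") <= q
}

#' Nodal signal variability (SDSA) of a time-series matrix
#'
#' Sample standard deviation (denominator T-1) of each node's
#' unstandardized time series — compute this before any unit-variance
#' normalization used for network estimation, which would erase it.
#'
#' @param ts T x K matrix.
#' @return K-vector of SDs.
#' @export
computeSdsa <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 frames")
  apply(ts, 2, sd)
}

#' SDSA table for a whole cohort
#'
#' @param cohort a [CohortTimeSeries-class].
#' @return data.frame: subject, group, condition, then `node_1..node_K`
#'   columns of SDs.
#' @export
cohortSdsa <- function(cohort) {
  sub <- subjects(cohort)
  rows <- list()
  for (s in seq_len(nrow(sub))) for (cond in names(cohort@frames)) {
    key <- paste(sub$id[s], cond, sep = ".")
    v <- computeSdsa(cohort@series[[key]])
    rows[[key]] <- data.frame(subject = sub$id[s], group = sub$group[s],
                              condition = cond, t(v))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nodewise mixed ANOVA of SDSA
#'
#' As [edgewiseAnova()] with nodes in place of edges.
#'
#' @param sdsa data.frame from [cohortSdsa()].
#' @param q FDR level.
#' @return data.frame, one row per node.
#' @export
nodewiseSdsaAnova <- function(sdsa, q = 0.05) {
  nodeCols <- grep("^node_", colnames(sdsa))
  subj <- unique(sdsa$subject)
  conds <- intersect(.CONDITIONS, unique(sdsa$condition))
  values <- array(NA_real_,
                  dim = c(length(subj), length(conds), length(nodeCols)))
  for (ci in seq_along(conds)) {
    sel <- which(sdsa$condition == conds[ci])
    ord <- sel[match(subj, sdsa$subject[sel])]
    if (anyNA(ord)) stop("every subject needs all conditions")
    values[, ci, ] <- as.matrix(sdsa[ord, nodeCols])
  }
  groupLabels <- factor(sdsa$group[match(subj, sdsa$subject)])
  res <- .splitPlotCore(values, groupLabels)
  out <- cbind(data.frame(node = colnames(sdsa)[nodeCols]), res)
  for (eff in c("group", "condition", "interaction")) {
    p <- out[[paste0("p_", eff)]]
    out[[paste0("nominal_", eff)]] <- p < 0.05
    out[[paste0("fdr_", eff)]] <- fdrBh(p, q)
  }
  out
}
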