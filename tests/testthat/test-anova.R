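test_that("balanced designs reproduce the classical split-plot table", {
  set.seed(61)
  N <- 12
  g <- factor(rep(c("patient", "control"), each = N / 2))
  Y <- matrix(rnorm(N * 3), N) +
    outer(rep(1, N), c(0, 1, 2)) + (as.integer(g) - 1.5) * 0.8
  res <- mixedAnova(Y, g)
  df <- data.frame(y = as.vector(Y), subj = factor(rep(seq_len(N), 3)),
                   cond = factor(rep(1:3, each = N)), grp = rep(g, 3))
  a <- summary(stats::aov(y ~ grp * cond + Error(subj / cond), data = df))
  expect_equal(res$F_group, a[[1]][[1]]["grp", "F value"], tolerance = 1e-10)
  expect_equal(res$F_condition, a[[2]][[1]]["cond", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F_interaction, a[[2]][[1]]["grp:cond", "F value"],
               tolerance = 1e-10)
  expect_equal(res$df1_condition, 2)
  expect_equal(res$df2_condition, (N - 2) * 2)
})

test_that("random unbalanced instances match the explicit oracle to 1e-8", {
  set.seed(62)
  for (r in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:7, 1)
    g <- factor(rep(c("patient", "control"), c(n1, n2)),
                levels = c("patient", "control"))
    Y <- matrix(rnorm((n1 + n2) * 3, sd = runif(1, 0.5, 3)), n1 + n2)
    res <- mixedAnova(Y, g)
    orc <- oracleMixedAnova(Y, g)
    expect_equal(res$F_group, orc$F_group, tolerance = 1e-8)
    expect_equal(res$F_condition, orc$F_condition, tolerance = 1e-8)
    expect_equal(res$F_interaction, orc$F_interaction, tolerance = 1e-8)
  }
})

test_that("degenerate data report F = 0 with a flag", {
  Y <- matrix(5, 6, 3)
  res <- mixedAnova(Y, rep(c("patient", "control"), each = 3))
  expect_true(res$degenerate)
  expect_equal(res$F_group, 0)
  expect_equal(res$p_condition, 1)
  expect_error(mixedAnova(cbind(Y[, 1:2], NA), rep(c("a", "b"), each = 3)),
               "condition values")
})

test_that("an additive condition shift loads on condition, not interaction", {
  set.seed(63)
  N <- 100
  g <- rep(c("patient", "control"), each = N / 2)
  Y <- matrix(rnorm(N * 3), N) + outer(rep(1, N), c(0, 1, 2))
  res <- mixedAnova(Y, g)
  expect_gt(res$F_condition, 100)
  expect_lt(res$F_interaction, 5)
  expect_lt(res$p_condition, 1e-10)
})

test_that("balanced F statistics are shift- and relabel-invariant", {
  set.seed(64)
  N <- 10
  g <- rep(c("patient", "control"), each = N / 2)
  Y <- matrix(rnorm(N * 3), N)
  a <- mixedAnova(Y, g)
  b <- mixedAnova(Y + 17.3, g)
  expect_equal(a$F_group, b$F_group, tolerance = 1e-10)
  expect_equal(a$F_condition, b$F_condition, tolerance = 1e-10)
  # consistent relabelling of conditions permutes nothing in the F values
  cPerm <- c(3, 1, 2)
  d <- mixedAnova(Y[, cPerm], g)
  expect_equal(a$F_condition, d$F_condition, tolerance = 1e-10)
  expect_equal(a$F_interaction, d$F_interaction, tolerance = 1e-10)
})

test_that("edgewise ANOVA matches the single-measure path and flags nest", {
  set.seed(65)
  N <- 14
  g <- rep(c("patient", "control"), c(6, 8))
  vals <- array(rnorm(N * 3 * 9), dim = c(N, 3, 9))
  ee <- edgeExperimentFromArray(vals, g)
  tab <- edgewiseAnova(ee)
  expect_equal(nrow(tab), 9)
  one <- mixedAnova(vals[, , 4], g)
  expect_equal(tab$F_condition[4], one$F_condition, tolerance = 1e-10)
  expect_equal(tab$F_group[4], one$F_group, tolerance = 1e-10)
  # FDR-significant edges are a subset of nominally significant ones
  for (eff in c("group", "condition", "interaction"))
    expect_true(all(!tab[[paste0("fdr_", eff)]] |
                      tab[[paste0("nominal_", eff)]]))
})

test_that("BH step-up matches hand computation and is monotone in q", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(fdrBh(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(fdrBh(rep(1, 10))), 0)
  expect_equal(sum(fdrBh(rep(0, 10))), 10)
  expect_equal(fdrBh(numeric(0)), logical(0))
  expect_error(fdrBh(c(0.2, 1.4)), "\\[0, 1\\]")
  # hand step-up on a random vector agrees
  set.seed(66)
  pv <- runif(50)^2
  m <- length(pv)
  ord <- order(pv)
  k <- max(c(0, which(pv[ord] <= seq_len(m) * 0.05 / m)))
  hand <- logical(m)
  if (k > 0) hand[ord[seq_len(k)]] <- TRUE
  expect_equal(fdrBh(pv, 0.05), hand)
  # monotone in q
  qs <- c(0.01, 0.05, 0.1, 0.2)
  nrej <- sapply(qs, function(q) sum(fdrBh(pv, q)))
  expect_true(all(diff(nrej) >= 0))
})

test_that("SDSA equals the column SD with known closed forms", {
  expect_equal(unname(computeSdsa(cbind(rep(3, 100), 1:100)))[1], 0)
  tt <- seq(0, 2 * pi, length.out = 1001)[-1001]
  expect_equal(unname(computeSdsa(cbind(2 * sin(tt)))), 2 / sqrt(2),
               tolerance = 0.01)
  set.seed(67)
  expect_equal(unname(computeSdsa(cbind(rnorm(10000)))), 1, tolerance = 0.03)
  expect_error(computeSdsa(matrix(1, 1, 3)), "2 frames")
})

test_that("nodewise SDSA ANOVA finds injected task modulation", {
  m <- makeGroundTruth(nNodes = 8, sparsity = 0.15,
                       effects = defaultEffectSpec(8, groupDelta = 0,
                                                   nSdsaNodes = 3,
                                                   sdsaFactor = 0.8),
                       seed = 68)
  sdsaNodes <- attr(m@effects, "sdsaNodes")
  ch <- generateCohort(m, 25, 25, frames = c(rest = 152, L1 = 152, L2 = 152),
                       seed = 68)
  tab <- nodewiseSdsaAnova(cohortSdsa(ch))
  hit <- which(tab$fdr_condition)
  expect_true(all(sdsaNodes %in% hit))
  # no group effect was injected: group FDR count stays at zero
  expect_equal(sum(tab$fdr_group), 0)
})

test_that("Welch t from summaries matches t.test on reconstructed data", {
  w <- welchTFromSummary(10, 2, 30, 11.5, 3, 50)
  # reconstruct data with exactly these summaries
  mk <- function(m, s, n) {
    x <- scale(rnorm(n))[, 1]
    m + s * x
  }
  set.seed(69)
  a <- mk(10, 2, 30); b <- mk(11.5, 3, 50)
  tt <- t.test(a, b)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-8)
  expect_equal(w$p, tt$p.value, tolerance = 1e-8)
  expect_equal(welchTFromSummary(5, 2, 10, 5, 2, 10)$t, 0)
  expect_equal(welchTFromSummary(5, 0, 10, 5, 0, 10)$t, 0)
  expect_error(welchTFromSummary(5, 2, 1, 5, 2, 10), "n >= 2")
})

test_that("chi-square independence matches closed forms", {
  expect_equal(chi2Independence(matrix(c(10, 0, 0, 10), 2))$X2, 20)
  eq <- chi2Independence(matrix(c(30, 60, 20, 40), 2))
  expect_equal(eq$X2, 0, tolerance = 1e-12)
  expect_equal(eq$df, 1)
  expect_error(chi2Independence(matrix(c(0, 0, 5, 5), 2)), "marginal")
})
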