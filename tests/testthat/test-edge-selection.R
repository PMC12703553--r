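# build a panel object directly from a value matrix
panelFromMatrix <- function(X, R) {
  new("EdgeDifferencePanel", values = X, edges = dualconn:::upperPairs(R),
      subjectIds = sprintf("s%03d", seq_len(nrow(X))))
}

# behavior table with independent covariates
behaviorTable <- function(y, seed = 1) {
  set.seed(seed)
  n <- length(y)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)), bis_diff = y,
             age = runif(n, 18, 30), gender = rbinom(n, 1, 0.5),
             mean_fd = runif(n, 0.03, 0.15))
}

test_that("difference panels have fixed edge order and antisymmetry", {
  set.seed(70)
  mkFC <- function(v, cond) fcFromMatrix(v, condition = cond)
  v1 <- matrix(rnorm(25), 5); v1 <- (v1 + t(v1)) / 2
  v2 <- matrix(rnorm(25), 5); v2 <- (v2 + t(v2)) / 2
  pairs <- list(
    s1 = list(incompatible = mkFC(v1, "dual-incompatible"),
              compatible = mkFC(v2, "dual-compatible")),
    s2 = list(incompatible = mkFC(v2, "dual-incompatible"),
              compatible = mkFC(v2, "dual-compatible")))
  panel <- buildDifferencePanel(pairs)
  expect_equal(dim(panel@values), c(2L, 10L))
  expect_equal(panel@values[2, ], rep(0, 10))          # identical FCs
  # swapping condition labels negates the panel
  swapped <- lapply(pairs, function(p)
    list(incompatible = p$compatible, compatible = p$incompatible))
  expect_equal(buildDifferencePanel(swapped)@values, -panel@values)
  # R = 200 gives R(R-1)/2 columns
  big <- matrix(0, 200, 200)
  bigPair <- list(s1 = list(incompatible = fcFromMatrix(big),
                            compatible = fcFromMatrix(big)))
  expect_equal(ncol(buildDifferencePanel(bigPair)@values), 19900L)
  # a subject missing a condition is dropped
  pairs$s3 <- list(incompatible = mkFC(v1, "dual-incompatible"))
  expect_equal(nrow(buildDifferencePanel(pairs)@values), 2L)
})

test_that("the Bayes-factor filter is strict at the threshold and powered", {
  cfg <- pipelineConfig()
  set.seed(71)
  # null column: tiny noise around zero stays out
  Xnull <- matrix(rnorm(47 * 3, 0, 0.01), 47)
  bfN <- bfFilter(Xnull, cfg)
  expect_true(all(bfN$bf10 < 1))
  expect_false(any(bfN$retain))

  # planted mean 0.3, sd 0.2, n = 47: retained in >= 95% of simulations
  hits <- vapply(1:100, function(r) {
    x <- matrix(rnorm(47, 0.3, 0.2), 47)
    bfFilter(x, cfg)$retain[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # strictness: an edge whose BF equals the threshold exactly is excluded
  x <- matrix(rnorm(30, 0.2, 0.3), 30)
  bf <- bfFilter(x, cfg)$bf10[1]
  cfgEq <- pipelineConfig(bfEdgeThreshold = bf)
  expect_false(bfFilter(x, cfgEq)$retain[1])
})

test_that("the cluster-overlap filter keeps only doubly-labeled endpoints", {
  parc <- toyParcels(4L, overlap = c("visual", "", "auditory", "manual"))
  edges <- dualconn:::upperPairs(4L)
  keep <- clusterOverlapFilter(edges, parc)
  # edges not touching region 2 survive
  expect_equal(keep, !(edges[, 1] == 2L | edges[, 2] == 2L))
  allLab <- toyParcels(4L, overlap = rep("vocal", 4))
  expect_true(all(clusterOverlapFilter(edges, allLab)))
  noLab <- toyParcels(4L)
  expect_false(any(clusterOverlapFilter(edges, noLab)))
})

test_that("partial Spearman matches its brute-force oracle and plain Spearman", {
  set.seed(72)
  # constant covariates reduce to the plain Spearman correlation
  x <- rnorm(20); y <- x + rnorm(20)
  Z <- matrix(5, 20, 2)
  ps <- partialSpearman(x, y, Z)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)

  # monotone relation: rho approaches 1 as n grows
  xb <- rnorm(400); yb <- exp(xb)
  Zb <- cbind(rnorm(400), rnorm(400))
  expect_gt(partialSpearman(xb, yb, Zb)$rho, 0.98)

  # n = 8 worked case against an explicit lm-based residualization oracle
  x8 <- c(2.1, -0.3, 1.7, 0.4, -1.2, 0.9, 2.8, -0.6)
  y8 <- c(1.0, 0.2, 2.5, -0.7, -1.5, 1.1, 0.3, -0.2)
  Z8 <- cbind(c(22, 25, 19, 30, 27, 21, 24, 28), c(0, 1, 0, 1, 1, 0, 0, 1))
  ps8 <- partialSpearman(x8, y8, Z8)
  rx <- rank(x8); ry <- rank(y8); rz <- apply(Z8, 2, rank)
  ex <- residuals(lm(rx ~ rz)); ey <- residuals(lm(ry ~ rz))
  expect_equal(ps8$rho, cor(ex, ey), tolerance = 1e-12)
  expect_equal(ps8$df, 8L - 2L - 2L)
  expect_error(partialSpearman(rep(1, 8), y8, Z8), "constant")
})

test_that("stability selection is deterministic under a fixed seed", {
  set.seed(73)
  n <- 24L; R <- 10L
  X <- matrix(rnorm(n * 45, 0, 0.1), n)
  y <- rnorm(n)
  X[, 7] <- 0.3 + 0.15 * scale(y) + rnorm(n, 0, 0.05)   # strong planted edge
  panel <- panelFromMatrix(X, R)
  beh <- behaviorTable(y, seed = 74)
  parc <- toyParcels(R, overlap = rep("visual", R))
  cfg <- pipelineConfig(nPermutations = 500L, rngSeed = 99L)
  res1 <- looStabilitySelection(panel, beh, parc, cfg)
  res2 <- looStabilitySelection(panel, beh, parc, cfg)
  expect_identical(res1@edges, res2@edges)
  expect_identical(res1@nullPercentiles, res2@nullPercentiles)
  expect_true(7L %in% selectedEdges(res1)$edge)

  # a different seed gives a different null band but the same statistics
  res3 <- looStabilitySelection(panel, beh, parc,
                                pipelineConfig(nPermutations = 500L,
                                               rngSeed = 100L))
  expect_equal(res3@edges$rho, res1@edges$rho)
  expect_false(identical(res3@nullPercentiles, res1@nullPercentiles))
})

test_that("subject order does not affect the deterministic selection statistics", {
  set.seed(75)
  n <- 20L; R <- 8L
  X <- matrix(rnorm(n * 28, 0, 0.1), n)
  y <- rnorm(n)
  X[, 3] <- 0.25 + 0.12 * scale(y) + rnorm(n, 0, 0.04)
  beh <- behaviorTable(y, seed = 76)
  parc <- toyParcels(R, overlap = rep("manual", R))
  cfg <- pipelineConfig(nPermutations = 200L, rngSeed = 7L)
  res <- looStabilitySelection(panelFromMatrix(X, R), beh, parc, cfg)

  perm <- sample(n)
  Xp <- X[perm, , drop = FALSE]
  panelP <- new("EdgeDifferencePanel", values = Xp,
                edges = dualconn:::upperPairs(R),
                subjectIds = sprintf("s%03d", perm))
  resP <- looStabilitySelection(panelP, beh, parc, cfg)
  expect_equal(resP@edges$edge, res@edges$edge)
  expect_equal(resP@edges$bf10, res@edges$bf10, tolerance = 1e-12)
  expect_equal(resP@edges$rho, res@edges$rho, tolerance = 1e-12)
  expect_equal(sort(resP@looRhos[, 1]), sort(res@looRhos[, 1]),
               tolerance = 1e-12)
})

test_that("negating the panel negates every rho", {
  set.seed(77)
  n <- 20L
  X <- matrix(rnorm(n * 10, 0.3, 0.1), n)
  y <- rnorm(n)
  Z <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  for (e in 1:10) {
    a <- partialSpearman(X[, e], y, Z)
    b <- partialSpearman(-X[, e], y, Z)
    expect_equal(b$rho, -a$rho, tolerance = 1e-12)
  }
})

test_that("an unlabeled parcellation yields zero candidates gracefully", {
  set.seed(78)
  X <- matrix(rnorm(15 * 6, 0.5, 0.1), 15)   # all edges pass the BF filter
  panel <- panelFromMatrix(X, 4L)
  beh <- behaviorTable(rnorm(15), seed = 79)
  res <- looStabilitySelection(panel, beh, toyParcels(4L),
                               pipelineConfig(nPermutations = 50L))
  expect_equal(nrow(res@edges), 0L)
  expect_equal(res@counts[["pass_overlap"]], 0L)
  expect_equal(nrow(selectedEdges(res)), 0L)
  # empty report round-trips as a header-only table
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSelectionReport(res, path)
  expect_equal(nrow(readSelectionReport(path)), 0L)
})

test_that("reports carry planted endpoints, direction, and round-trip", {
  set.seed(80)
  n <- 30L; R <- 6L
  X <- matrix(rnorm(n * 15, 0, 0.08), n)
  y <- rnorm(n)
  X[, 5] <- 0.3 + 0.15 * scale(y) + rnorm(n, 0, 0.04)
  panel <- panelFromMatrix(X, R)
  parc <- toyParcels(R, overlap = rep(c("visual", "auditory"), 3))
  res <- looStabilitySelection(panel, behaviorTable(y, seed = 81), parc,
                               pipelineConfig(nPermutations = 300L,
                                              rngSeed = 3L))
  rep5 <- reportSelection(res)
  row <- rep5[rep5$edge == 5L, ]
  expect_equal(nrow(row), 1L)
  expect_gt(row$rho, 0)                      # matches planted positive coupling
  expect_equal(row$direction, "incompatible>compatible")
  expect_equal(row$label_i, regionLabels(parc)[row$i])

  path <- withr::local_tempfile(fileext = ".tsv")
  writeSelectionReport(res, path)
  back <- readSelectionReport(path)
  expect_equal(back$rho, rep5$rho, tolerance = 1e-12)
  expect_equal(back$selected, rep5$selected)
})

test_that("single-fold null exceedance stays near its nominal level", {
  # under exchangeable behavior the probability that one fold's rho exits
  # the 5%/95% band is at most ~10%; the all-folds conjunction is far rarer
  set.seed(82)
  n <- 24L; R <- 6L
  nRep <- 60L
  exits <- 0L; folds <- 0L; allOut <- 0L
  for (r in seq_len(nRep)) {
    X <- matrix(rnorm(n * 15, 0.4, 0.1), n)   # passes BF, null behavior
    panel <- panelFromMatrix(X, R)
    beh <- behaviorTable(rnorm(n), seed = 8200 + r)
    parc <- toyParcels(R, overlap = rep("vocal", R))
    cfg <- pipelineConfig(nPermutations = 200L, rngSeed = 8300L + r,
                          alphaBehavior = 1)   # keep all candidates
    res <- looStabilitySelection(panel, beh, parc, cfg)
    lo <- matrix(res@nullPercentiles[, 1], n, nrow(res@edges), byrow = TRUE)
    hi <- matrix(res@nullPercentiles[, 2], n, nrow(res@edges), byrow = TRUE)
    out <- res@looRhos < lo | res@looRhos > hi
    exits <- exits + sum(out)
    folds <- folds + length(out)
    allOut <- allOut + sum(colSums(out) == n)
  }
  rate <- exits / folds
  expect_lt(rate, 0.135)          # 10% nominal plus Monte-Carlo slack
  expect_lt(allOut / (folds / n), rate)   # conjunction strictly rarer
})
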