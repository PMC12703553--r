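#' EdgeDifferencePanel: subjects x edges condition differences
#'
#' Fisher-z difference (incompatible minus compatible dual task) for every
#' upper-triangle edge, one row per subject entering the dual-task analysis.
#' Column order is fixed lexicographic over (i, j), i < j.
#'
#' @slot values subjects x edges numeric matrix.
#' @slot edges two-column integer matrix mapping columns to (i, j).
#' @slot subjectIds row identifiers.
#' @export
setClass("EdgeDifferencePanel", representation(
  values = "matrix", edges = "matrix", subjectIds = "character"))

#' @rdname EdgeDifferencePanel
#' @param object an \code{EdgeDifferencePanel}.
#' @export
setMethod("show", "EdgeDifferencePanel", function(object) {
  cat(sprintf("EdgeDifferencePanel: %d subjects x %d edges (%d missing values)\n",
              nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

#' Build the edge-wise condition-difference panel
#'
#' @param fcPairs named list (one entry per subject), each a list with
#'   elements \code{incompatible} and \code{compatible} holding the
#'   subject's two dual-task \linkS4class{FCMatrix} objects. Subjects
#'   missing a condition are dropped with a log entry.
#' @return an \linkS4class{EdgeDifferencePanel}.
#' @export
buildDifferencePanel <- function(fcPairs) {
  ok <- vapply(fcPairs, function(p)
    is(p$incompatible, "FCMatrix") && is(p$compatible, "FCMatrix"), logical(1))
  if (any(!ok))
    fcLog("buildDifferencePanel: dropping %d subject(s) missing a condition",
          sum(!ok))
  fcPairs <- fcPairs[ok]
  if (!length(fcPairs)) stop("no subject has both dual-task conditions")
  R <- nRegions(fcPairs[[1]]$incompatible)
  pairs <- upperPairs(R)
  vals <- t(vapply(fcPairs, function(p) {
    if (nRegions(p$incompatible) != R) stop("mixed dimensions across subjects")
    (fcValues(p$incompatible) - fcValues(p$compatible))[pairs]
  }, numeric(nrow(pairs))))
  new("EdgeDifferencePanel", values = vals, edges = pairs,
      subjectIds = names(fcPairs))
}

# per-column one-sample t statistics (pairwise-complete)
.columnT <- function(X) {
  n <- colSums(!is.na(X))
  m <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2L, function(col) stats::var(col, na.rm = TRUE))
  t <- ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * Inf))
  list(t = t, n = n)
}

#' Bayes-factor filter over a difference panel
#'
#' One-sample JZS Bayes factor of each edge's difference column against
#' zero; edges are retained when BF10 strictly exceeds the threshold
#' ("above 3" excludes exactly 3).
#'
#' @param panel an \linkS4class{EdgeDifferencePanel} (or bare matrix) with
#'   at least 3 subjects.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return list: \code{bf10} per edge, logical \code{retain}.
#' @export
bfFilter <- function(panel, cfg = pipelineConfig()) {
  X <- if (is(panel, "EdgeDifferencePanel")) panel@values else panel
  if (nrow(X) < 3L) stop("need at least 3 subjects")
  ct <- .columnT(X)
  bf <- rep(NA_real_, ncol(X))
  for (nn in unique(ct$n[ct$n >= 3L]))
    bf[ct$n == nn] <- jzsBF(ct$t[ct$n == nn], nn)
  list(bf10 = bf, retain = !is.na(bf) & bf > cfg@bfEdgeThreshold)
}

#' Task-cluster overlap filter
#'
#' Retains edges whose both endpoints carry a nonempty task-cluster overlap
#' label from the localizer analysis.
#'
#' @param edges two-column (i, j) index matrix.
#' @param parcels a \linkS4class{ParcelTable}.
#' @return logical vector over the edge rows.
#' @export
clusterOverlapFilter <- function(edges, parcels) {
  ov <- hasClusterOverlap(parcels)
  ov[edges[, 1]] & ov[edges[, 2]]
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y, and each covariate (average ranks for ties),
#' residualizes the ranked x and y on the ranked covariates plus an
#' intercept by least squares, and correlates the residuals. The p value
#' uses the t approximation with df = n - 2 - (number of covariates).
#' Constant covariates drop out, reducing to the plain Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame (n rows) or \code{NULL}.
#' @return list: \code{rho}, \code{p}, \code{df}, \code{n}.
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  Z <- if (is.null(covariates)) matrix(nrow = length(x), ncol = 0)
       else as.matrix(covariates)
  ok <- is.finite(x) & is.finite(y) & (ncol(Z) == 0 | rowSums(!is.finite(Z)) == 0)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n < k + 3L) stop("need n >= number of covariates + 3")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("constant x or y after ranking")
  rZ <- apply(Z, 2L, rank)
  qrD <- qr(cbind(1, rZ))
  ex <- qr.resid(qrD, rx)
  ey <- qr.resid(qrD, ry)
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  df <- n - 2L - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

# rank + residualize the columns of X on ranked covariates; returns the
# centered residual matrix and its column norms
.rankResidualize <- function(X, Z) {
  rX <- apply(X, 2L, rank)
  qrD <- qr(cbind(1, if (ncol(Z)) apply(Z, 2L, rank) else NULL))
  E <- qr.resid(qrD, rX)
  list(E = E, norms = sqrt(colSums(E^2)), qrD = qrD)
}

#' EdgeSelectionResult: output of the stability selection
#'
#' @slot edges per-candidate \code{data.frame}: endpoints, labels, cluster
#'   labels, Bayes factor, partial rho with uncorrected p, the null band,
#'   fold-wise rho extremes, and the final \code{selected} flag.
#' @slot looRhos folds x candidates matrix of leave-one-out rho values.
#' @slot nullPercentiles candidates x 2 matrix of the null band.
#' @slot counts integer vector tracing the funnel: edges, past the BF
#'   filter, past the overlap filter, candidates after the p screen.
#' @slot n subjects entering; \code{nPermutations} used; \code{seed} used.
#' @export
setClass("EdgeSelectionResult", representation(
  edges = "data.frame", looRhos = "matrix", nullPercentiles = "matrix",
  counts = "integer", n = "integer", nPermutations = "integer",
  seed = "integer"))

#' @describeIn EdgeSelectionResult the selected edges only.
#' @param x,object an \code{EdgeSelectionResult}.
#' @export
setGeneric("selectedEdges", function(x) standardGeneric("selectedEdges"))

#' @rdname EdgeSelectionResult
#' @export
setMethod("selectedEdges", "EdgeSelectionResult", function(x)
  x@edges[x@edges$selected, , drop = FALSE])

#' @rdname EdgeSelectionResult
#' @export
setMethod("show", "EdgeSelectionResult", function(object) {
  cat(sprintf(paste0("EdgeSelectionResult: %d subjects; funnel %d edges -> ",
                     "%d past BF filter -> %d past overlap -> %d candidates ",
                     "-> %d selected\n"),
              object@n, object@counts[["edges"]], object@counts[["pass_bf"]],
              object@counts[["pass_overlap"]], object@counts[["candidates"]],
              sum(object@edges$selected)))
})

#' Leave-one-out stability selection of brain-behavior edges
#'
#' The full post hoc selection pipeline: (1) one-sample Bayes-factor filter
#' (BF10 > threshold) on the condition-difference panel; (2) restriction to
#' edges whose both endpoints overlap a task cluster; (3) covariate-adjusted
#' partial Spearman correlation of each surviving edge with the behavioral
#' difference score, screened at the uncorrected \code{alphaBehavior} level;
#' (4) per candidate edge, a permutation null of \code{nPermutations}
#' replicates, each dropping one random subject and permuting the behavior
#' vector before re-correlating (filters are not re-applied inside the
#' null); and (5) a leave-one-out pass that re-runs the filters and the
#' correlation on every n-1 subset. An edge is selected iff it survives
#' both filters on every fold and its fold rho values all fall below the
#' null 5\% percentile or all above the 95\% percentile (empirical type-7
#' quantiles).
#'
#' Randomness (null subject drops and permutations) is governed by
#' \code{cfg@rngSeed} through a stage-specific child seed, so results are
#' reproducible for a fixed config.
#'
#' @param panel an \linkS4class{EdgeDifferencePanel}.
#' @param behavior \code{data.frame} with \code{subject_id}, the behavioral
#'   difference score \code{bis_diff}, and covariate columns (any of
#'   \code{age}, \code{gender}, \code{mean_fd} present are used), aligned by
#'   subject id to the panel.
#' @param parcels a \linkS4class{ParcelTable}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return an \linkS4class{EdgeSelectionResult}.
#' @export
looStabilitySelection <- function(panel, behavior, parcels,
                                  cfg = pipelineConfig()) {
  idx <- match(panel@subjectIds, behavior$subject_id)
  if (anyNA(idx)) {
    fcLog("looStabilitySelection: dropping %d subject(s) without behavior",
          sum(is.na(idx)))
  }
  keep <- which(!is.na(idx))
  X <- panel@values[keep, , drop = FALSE]
  beh <- behavior[idx[keep], , drop = FALSE]
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 subjects")
  covNames <- intersect(c("age", "gender", "mean_fd"), names(beh))
  Z <- as.matrix(beh[covNames])
  y <- beh$bis_diff
  edges <- panel@edges

  # full-sample funnel
  bf <- bfFilter(X, cfg)
  ovOK <- clusterOverlapFilter(edges, parcels)
  candPool <- which(bf$retain & ovOK)
  candPool <- candPool[colSums(is.na(X[, candPool, drop = FALSE])) == 0]
  ps <- lapply(candPool, function(e) partialSpearman(X[, e], y, Z))
  rho <- vapply(ps, `[[`, numeric(1), "rho")
  pval <- vapply(ps, `[[`, numeric(1), "p")
  cand <- candPool[pval < cfg@alphaBehavior]
  counts <- c(edges = ncol(X), pass_bf = sum(bf$retain, na.rm = TRUE),
              pass_overlap = length(candPool), candidates = length(cand))
  fcLog("looStabilitySelection: funnel %s",
        paste(names(counts), counts, sep = "=", collapse = ", "))
  seed <- childSeed(cfg@rngSeed, "edge_selection_null")

  emptyResult <- function() new("EdgeSelectionResult",
    edges = data.frame(edge = integer(0), i = integer(0), j = integer(0),
                       bf10 = numeric(0), rho = numeric(0),
                       p_uncorrected = numeric(0), null_lo = numeric(0),
                       null_hi = numeric(0), min_loo_rho = numeric(0),
                       max_loo_rho = numeric(0), folds_survived = integer(0),
                       selected = logical(0)),
    looRhos = matrix(numeric(0), n, 0), nullPercentiles = matrix(numeric(0), 0, 2),
    counts = setNames(as.integer(counts), names(counts)), n = as.integer(n),
    nPermutations = cfg@nPermutations, seed = seed)
  if (!length(cand)) return(emptyResult())

  rhoCand <- rho[match(cand, candPool)]
  pCand <- pval[match(cand, candPool)]
  XC <- X[, cand, drop = FALSE]

  # precompute, for each dropped subject, the ranked/residualized candidate
  # columns of the n-1 subset (shared by the null and the LOO pass)
  drops <- lapply(seq_len(n), function(d)
    .rankResidualize(XC[-d, , drop = FALSE], Z[-d, , drop = FALSE]))

  # permutation null: drop one random subject, permute behavior, correlate
  nullRho <- withSeed(seed, {
    out <- matrix(NA_real_, cfg@nPermutations, length(cand))
    for (b in seq_len(cfg@nPermutations)) {
      d <- sample.int(n, 1L)
      yp <- y[-d][sample.int(n - 1L)]
      ry <- rank(yp)
      ey <- qr.resid(drops[[d]]$qrD, ry)
      out[b, ] <- as.numeric(crossprod(drops[[d]]$E, ey)) /
        (drops[[d]]$norms * sqrt(sum(ey^2)))
    }
    out
  })
  band <- t(apply(nullRho, 2L, quantile,
                  probs = cfg@percentileBounds, type = 7, names = FALSE))

  # leave-one-out pass: filters recomputed on each n-1 subset, then rho
  looRho <- matrix(NA_real_, n, length(cand))
  foldOK <- matrix(FALSE, n, length(cand))
  S1 <- colSums(XC); S2 <- colSums(XC^2)
  for (f in seq_len(n)) {
    m <- (S1 - XC[f, ]) / (n - 1)
    v <- pmax((S2 - XC[f, ]^2 - (n - 1) * m^2) / (n - 2), 0)
    tf <- ifelse(v > 0, m / sqrt(v / (n - 1)), ifelse(m == 0, 0, sign(m) * Inf))
    foldOK[f, ] <- jzsBF(tf, n - 1L) > cfg@bfEdgeThreshold  # overlap is fold-invariant
    ry <- rank(y[-f])
    ey <- qr.resid(drops[[f]]$qrD, ry)
    looRho[f, ] <- as.numeric(crossprod(drops[[f]]$E, ey)) /
      (drops[[f]]$norms * sqrt(sum(ey^2)))
  }
  allBelow <- colSums(looRho < matrix(band[, 1], n, length(cand),
                                      byrow = TRUE)) == n
  allAbove <- colSums(looRho > matrix(band[, 2], n, length(cand),
                                      byrow = TRUE)) == n
  selected <- colSums(foldOK) == n & (allBelow | allAbove)

  labs <- regionLabels(parcels)
  ovStr <- vapply(clusterOverlap(parcels), paste, character(1), collapse = ",")
  edf <- data.frame(
    edge = cand, i = edges[cand, 1], j = edges[cand, 2],
    label_i = labs[edges[cand, 1]], label_j = labs[edges[cand, 2]],
    cluster_i = ovStr[edges[cand, 1]], cluster_j = ovStr[edges[cand, 2]],
    mean_fc_difference = colMeans(XC),
    bf10 = bf$bf10[cand], rho = rhoCand, p_uncorrected = pCand,
    null_lo = band[, 1], null_hi = band[, 2],
    min_loo_rho = apply(looRho, 2L, min), max_loo_rho = apply(looRho, 2L, max),
    folds_survived = colSums(foldOK), selected = selected)
  rownames(edf) <- NULL
  new("EdgeSelectionResult", edges = edf, looRhos = looRho,
      nullPercentiles = band, counts = setNames(as.integer(counts), names(counts)), n = as.integer(n),
      nPermutations = cfg@nPermutations, seed = seed)
}

#' Tabular report of an edge selection
#'
#' One row per candidate edge with endpoint labels and cluster labels, the
#' direction of the connectivity difference, the partial rho, fold-wise rho
#' extremes, and the null band. The behavioral difference score is the
#' dual-task BIS difference (incompatible minus compatible; positive rho
#' means a larger incompatible connectivity excess goes with relatively
#' better incompatible performance).
#'
#' @param result an \linkS4class{EdgeSelectionResult}.
#' @param selectedOnly report only selected edges (default all candidates).
#' @return a \code{data.frame}.
#' @export
reportSelection <- function(result, selectedOnly = FALSE) {
  edf <- if (selectedOnly) selectedEdges(result) else result@edges
  if (!nrow(edf)) {
    fcLog("reportSelection: empty selection (n=%d, %d permutations, seed %d)",
          result@n, result@nPermutations, result@seed)
    return(edf)
  }
  edf$direction <- ifelse(edf$mean_fc_difference > 0,
                          "incompatible>compatible",
                          "compatible>incompatible")
  edf
}

#' Write / read a selection report
#'
#' @param result an \linkS4class{EdgeSelectionResult}.
#' @param path TSV path.
#' @return \code{path} invisibly; \code{readSelectionReport} returns the
#'   \code{data.frame}.
#' @export
writeSelectionReport <- function(result, path) {
  write.table(reportSelection(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSelectionReport
#' @export
readSelectionReport <- function(path) {
  tb <- read.delim(path, sep = "\t")
  if (nrow(tb)) tb$selected <- as.logical(tb$selected)
  tb
}
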