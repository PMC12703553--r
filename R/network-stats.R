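#' Edge subsets from a parcellation
#'
#' Builds the canonical edge groupings used by the network-level analyses:
#' the whole-brain upper triangle, one \code{within:<network>} subset per
#' network (edges whose endpoints share that network), and one
#' \code{between:<network>} subset per network (edges with exactly one
#' endpoint in it). Every edge belongs to exactly one within subset or to
#' exactly two between subsets. Pairs are in fixed lexicographic (i, j)
#' order with i < j.
#'
#' @param parcels a \linkS4class{ParcelTable}.
#' @return named list of two-column integer matrices (\code{i}, \code{j}).
#' @export
edgeSubsets <- function(parcels) {
  nets <- networks(parcels)
  R <- nRegions(parcels)
  pairs <- upperPairs(R)
  ni <- nets[pairs[, 1]]
  nj <- nets[pairs[, 2]]
  out <- list(whole = pairs)
  for (nw in intersect(.networks7, unique(nets))) {
    out[[paste0("within:", nw)]] <- pairs[ni == nw & nj == nw, , drop = FALSE]
    out[[paste0("between:", nw)]] <- pairs[xor(ni == nw, nj == nw), , drop = FALSE]
  }
  out
}

#' Extract an edge vector from an FC matrix
#'
#' @param fc an \linkS4class{FCMatrix}.
#' @param subset a two-column (i, j) index matrix as produced by
#'   \code{\link{edgeSubsets}}.
#' @return numeric vector of Fisher-z values in the subset's fixed order
#'   (missing edges are \code{NA}; distances drop them pairwise).
#' @export
edgeVector <- function(fc, subset) {
  if (!nrow(subset)) stop("empty edge subset")
  if (max(subset) > nRegions(fc)) stop("subset indices exceed matrix size")
  fcValues(fc)[subset]
}

# drop positions missing in either vector; error if fewer than `min` remain
.pairwiseComplete <- function(a, b, min = 1L) {
  if (length(a) != length(b)) stop("edge vectors differ in length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min) stop("fewer than ", min, " usable edges after missing-edge removal")
  list(a = a[ok], b = b[ok], n = sum(ok))
}

#' Cosine distance between two edge vectors
#'
#' \eqn{d_{cos}(a,b) = 1 - \sum_i a_i b_i / (\|a\| \|b\|)}: 0 when the
#' vectors are proportional, 1 when orthogonal, 2 when antipodal. Scale
#' invariant, so it measures pattern dissimilarity regardless of overall
#' connectivity strength.
#'
#' @param a,b numeric vectors of equal length with nonzero norm
#'   (missing positions are dropped pairwise).
#' @return scalar in [0, 2].
#' @export
cosineDistance <- function(a, b) {
  pc <- .pairwiseComplete(a, b)
  na <- sqrt(sum(pc$a^2)); nb <- sqrt(sum(pc$b^2))
  if (na == 0 || nb == 0) stop("zero-norm input to cosineDistance")
  1 - sum(pc$a * pc$b) / (na * nb)
}

#' Robustness-variant dissimilarity/similarity measures
#'
#' Alternatives to the cosine distance used to check that conclusions do not
#' hinge on the choice of dissimilarity: the Euclidean distance
#' \eqn{\|a-b\|} and the Pearson similarity (sample correlation of the two
#' vectors).
#'
#' @param a,b numeric vectors of equal length.
#' @param which \code{"euclidean"} or \code{"pearson_similarity"}.
#' @return scalar.
#' @export
distanceVariants <- function(a, b, which = c("euclidean", "pearson_similarity")) {
  which <- match.arg(which)
  pc <- .pairwiseComplete(a, b, min = 2L)
  if (which == "euclidean") return(sqrt(sum((pc$a - pc$b)^2)))
  if (sd(pc$a) == 0 || sd(pc$b) == 0)
    stop("zero variance input to pearson_similarity")
  cor(pc$a, pc$b)
}

#' Mean (absolute) network connectivity
#'
#' Average of the absolute (default) or signed Fisher-z values over an edge
#' subset; the within/between-network strength statistic compared between
#' conditions.
#'
#' @param fc an \linkS4class{FCMatrix}.
#' @param subset two-column (i, j) index matrix.
#' @param absolute average |z| (default) or signed z.
#' @return scalar.
#' @export
meanNetworkFC <- function(fc, subset, absolute = TRUE) {
  v <- edgeVector(fc, subset)
  v <- v[is.finite(v)]
  if (!length(v)) stop("all edges missing in subset")
  if (absolute) mean(abs(v)) else mean(v)
}

# signed Fisher-z matrix -> nonnegative weight matrix in [0, 1]
.graphWeights <- function(fc, mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  W <- fcValues(fc)
  W[!is.finite(W)] <- 0
  diag(W) <- 0
  W <- if (mode == "absolute") abs(W) else pmax(W, 0)
  mx <- max(W)
  if (mx == 0) stop("total weight 0: graph has no edges")
  W / mx
}

#' Weighted-graph modularity of a given partition
#'
#' Newman's weighted modularity
#' \eqn{Q = \frac{1}{2m}\sum_{ij}(w_{ij} - k_i k_j / 2m)\,\delta(c_i,c_j)},
#' evaluated for an a-priori community assignment (by default the seven-network
#' parcel labels rather than data-driven communities). Signed Fisher-z edges
#' become weights via \code{graphWeightMode}: magnitude (default) or
#' positive-part, normalized by the matrix maximum to [0, 1].
#'
#' @param fc an \linkS4class{FCMatrix}.
#' @param partition community label per region (any atomic vector), e.g.
#'   \code{networks(parcels)}.
#' @param cfg a \linkS4class{PipelineConfig} (provides \code{graphWeightMode}).
#' @return scalar Q.
#' @export
modularityQ <- function(fc, partition, cfg = pipelineConfig()) {
  W <- .graphWeights(fc, cfg@graphWeightMode)
  stopifnot(length(partition) == nrow(W))
  k <- rowSums(W)
  m2 <- sum(W)
  same <- outer(partition, partition, `==`)
  sum((W - outer(k, k) / m2) * same) / m2
}

#' Weighted global efficiency
#'
#' Mean over node pairs of the inverse shortest-path length, where a path's
#' length sums the reciprocals of its edge weights (strong connections are
#' short). Disconnected pairs contribute 0. Weights come from the same
#' mapping as \code{\link{modularityQ}}, so the complete unit-weight graph
#' attains the maximum of 1.
#'
#' @param fc an \linkS4class{FCMatrix} with at least 2 regions.
#' @param cfg a \linkS4class{PipelineConfig} (provides \code{graphWeightMode}).
#' @return scalar in [0, 1].
#' @export
globalEfficiency <- function(fc, cfg = pipelineConfig()) {
  W <- .graphWeights(fc, cfg@graphWeightMode)
  R <- nrow(W)
  if (R < 2L) stop("need at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (R * (R - 1))
}

#' Dissimilarity between two FC matrices per edge subset
#'
#' Computes one dissimilarity per subset between two connectivity matrices
#' of the same subject: used both for the pairing comparison within a task
#' type (compatible vs incompatible) and for the single-vs-dual comparison
#' of averaged matrices. Only edges observed in both inputs enter each
#' distance; the usable edge count is reported.
#'
#' @param fcA,fcB \linkS4class{FCMatrix} objects of equal dimension.
#' @param subsets named list of edge-index matrices
#'   (\code{\link{edgeSubsets}}).
#' @param statistic \code{"cosine_distance"}, \code{"euclidean_distance"} or
#'   \code{"pearson_similarity"}.
#' @return \code{data.frame}: \code{subject_id}, \code{subset},
#'   \code{statistic}, \code{value}, \code{n_edges}.
#' @export
pairingDissimilarity <- function(fcA, fcB, subsets,
                                 statistic = c("cosine_distance",
                                               "euclidean_distance",
                                               "pearson_similarity")) {
  statistic <- match.arg(statistic)
  if (nRegions(fcA) != nRegions(fcB)) stop("matrices differ in dimension")
  rows <- lapply(names(subsets), function(nm) {
    a <- edgeVector(fcA, subsets[[nm]])
    b <- edgeVector(fcB, subsets[[nm]])
    pc <- .pairwiseComplete(a, b, min = 2L)
    val <- switch(statistic,
                  cosine_distance = cosineDistance(a, b),
                  euclidean_distance = distanceVariants(a, b, "euclidean"),
                  pearson_similarity = distanceVariants(a, b, "pearson_similarity"))
    data.frame(subject_id = fcA@subjectId, subset = nm, statistic = statistic,
               value = val, n_edges = pc$n)
  })
  do.call(rbind, rows)
}
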