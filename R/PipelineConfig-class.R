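#' PipelineConfig: run-wide analysis configuration
#'
#' Holds every tunable threshold of the analysis pipeline. Defaults reproduce
#' the study conditions the package emulates: runs are kept only when mean
#' framewise displacement is below 0.2 mm, fewer than 20\% of frames exceed
#' 0.25 mm, and no frame exceeds 5 mm; edges pass the evidence filter when
#' the one-sample Bayes factor exceeds 3; the permutation null uses 10,000
#' replicates and a 5\%/95\% percentile band.
#'
#' @slot fdMeanThreshold mm; run-level mean framewise displacement bound (0.2).
#' @slot spikeFdThreshold mm; per-frame displacement counted as a spike (0.25).
#' @slot spikeFractionMax proportion of spike frames tolerated (0.20).
#' @slot spikeHardMax mm; any frame above this invalidates the run (5.0).
#' @slot bfEdgeThreshold Bayes-factor filter threshold, strict (3).
#' @slot nPermutations permutation-null replicates (10000).
#' @slot percentileBounds lower/upper percentile of the null band (0.05, 0.95).
#' @slot alphaBehavior uncorrected p screen for brain-behavior edges (0.05).
#' @slot rngSeed integer global seed; per-stage seeds derive via \code{\link{childSeed}}.
#' @slot fisherClip correlations are clipped to this magnitude before arctanh.
#' @slot firLags number of post-onset lags in the task-evoked FIR basis (8).
#' @slot expandFd logical; give framewise displacement the full 4-term
#'   confound expansion (default) or enter it raw.
#' @slot dualCongruentScope \code{"across"} (default) or \code{"within"}:
#'   whether the 30\% congruent-trial error criterion for dual-task runs is
#'   averaged across a subject's two dual runs or applied per run.
#' @slot graphWeightMode \code{"absolute"} (default) or \code{"positive"}:
#'   how signed Fisher-z edges become nonnegative graph weights.
#' @export
setClass("PipelineConfig", representation(
  fdMeanThreshold = "numeric", spikeFdThreshold = "numeric",
  spikeFractionMax = "numeric", spikeHardMax = "numeric",
  bfEdgeThreshold = "numeric", nPermutations = "integer",
  percentileBounds = "numeric", alphaBehavior = "numeric",
  rngSeed = "integer", fisherClip = "numeric", firLags = "integer",
  expandFd = "logical", dualCongruentScope = "character",
  graphWeightMode = "character"))

setValidity("PipelineConfig", function(object) {
  thr <- c(object@fdMeanThreshold, object@spikeFdThreshold,
           object@spikeFractionMax, object@spikeHardMax,
           object@bfEdgeThreshold, object@alphaBehavior, object@fisherClip)
  if (any(!is.finite(thr)) || any(thr <= 0)) return("thresholds must be strictly positive")
  pb <- object@percentileBounds
  if (length(pb) != 2L || any(pb <= 0) || any(pb >= 1) || pb[1] >= pb[2])
    return("percentileBounds must be ordered and within (0,1)")
  if (object@nPermutations < 1L) return("nPermutations must be positive")
  if (object@fisherClip >= 1) return("fisherClip must be below 1")
  if (!object@dualCongruentScope %in% c("across", "within"))
    return("dualCongruentScope must be 'across' or 'within'")
  if (!object@graphWeightMode %in% c("absolute", "positive"))
    return("graphWeightMode must be 'absolute' or 'positive'")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param fdMeanThreshold,spikeFdThreshold,spikeFractionMax,spikeHardMax
#'   motion-screening thresholds (mm, mm, proportion, mm).
#' @param bfEdgeThreshold,nPermutations,percentileBounds,alphaBehavior
#'   edge-selection parameters.
#' @param rngSeed,fisherClip,firLags,expandFd,dualCongruentScope,graphWeightMode
#'   see \linkS4class{PipelineConfig}.
#' @return a validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(fdMeanThreshold = 0.2, spikeFdThreshold = 0.25,
                           spikeFractionMax = 0.20, spikeHardMax = 5.0,
                           bfEdgeThreshold = 3.0, nPermutations = 10000L,
                           percentileBounds = c(0.05, 0.95),
                           alphaBehavior = 0.05, rngSeed = 1L,
                           fisherClip = 1 - 1e-7, firLags = 8L,
                           expandFd = TRUE, dualCongruentScope = "across",
                           graphWeightMode = "absolute") {
  new("PipelineConfig",
      fdMeanThreshold = fdMeanThreshold, spikeFdThreshold = spikeFdThreshold,
      spikeFractionMax = spikeFractionMax, spikeHardMax = spikeHardMax,
      bfEdgeThreshold = bfEdgeThreshold, nPermutations = as.integer(nPermutations),
      percentileBounds = percentileBounds, alphaBehavior = alphaBehavior,
      rngSeed = as.integer(rngSeed), fisherClip = fisherClip,
      firLags = as.integer(firLags), expandFd = expandFd,
      dualCongruentScope = dualCongruentScope, graphWeightMode = graphWeightMode)
}

#' @rdname pipelineConfig
#' @param object a \code{PipelineConfig}.
#' @export
setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  motion: mean FD < %.3g mm, spikes (> %.3g mm) < %.0f%%, hard max %.3g mm\n",
              object@fdMeanThreshold, object@spikeFdThreshold,
              100 * object@spikeFractionMax, object@spikeHardMax))
  cat(sprintf("  edge filter: BF10 > %.3g; null: %d permutations, band (%.2g, %.2g)\n",
              object@bfEdgeThreshold, object@nPermutations,
              object@percentileBounds[1], object@percentileBounds[2]))
  cat(sprintf("  behavior screen alpha %.3g; seed %d\n",
              object@alphaBehavior, object@rngSeed))
})

.configKeys <- c(
  fd_mean_threshold = "fdMeanThreshold", spike_fd_threshold = "spikeFdThreshold",
  spike_fraction_max = "spikeFractionMax", spike_hard_max = "spikeHardMax",
  bf_edge_threshold = "bfEdgeThreshold", n_permutations = "nPermutations",
  percentile_bounds = "percentileBounds", alpha_behavior = "alphaBehavior",
  rng_seed = "rngSeed", fisher_clip = "fisherClip", fir_lags = "firLags",
  expand_fd = "expandFd", dual_congruent_scope = "dualCongruentScope",
  graph_weight_mode = "graphWeightMode")

#' Load a pipeline configuration from a key=value file
#'
#' Parses a plain-text file of \code{key=value} lines (\code{#} comments and
#' blank lines ignored). Missing keys take the documented defaults; unknown
#' keys and unparseable values are errors. The populated configuration is
#' echoed to the log.
#'
#' @param path path to the config file.
#' @return a validated \linkS4class{PipelineConfig}.
#' @export
loadConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("unparseable config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(.configKeys)) stop("unknown config key: ", key)
    slot <- .configKeys[[key]]
    parsed <- suppressWarnings(switch(slot,
      dualCongruentScope = , graphWeightMode = val,
      expandFd = as.logical(val),
      percentileBounds = as.numeric(strsplit(val, ",")[[1]]),
      nPermutations = , firLags = , rngSeed = as.integer(val),
      as.numeric(val)))
    if (anyNA(parsed)) stop("unparseable value for ", key, ": ", val)
    args[[slot]] <- parsed
  }
  cfg <- do.call(pipelineConfig, args)
  fcLog("loadConfig: %s (%d overrides); fd_mean_threshold=%g, n_permutations=%d",
        path, length(args), cfg@fdMeanThreshold, cfg@nPermutations)
  cfg
}
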