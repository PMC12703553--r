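#' RunTimeSeries: one run of parcellated BOLD data
#'
#' Regions-by-timepoints signal for a single run together with its
#' fMRIPrep-style confound columns and (optionally) task event onsets used
#' for task-evoked regression.
#'
#' @slot data regions x timepoints numeric matrix (arbitrary signal units).
#' @slot confounds data.frame with one row per timepoint and columns
#'   \code{global_signal}, \code{csf}, \code{white_matter},
#'   \code{trans_x/y/z}, \code{rot_x/y/z}, \code{framewise_displacement}.
#' @slot events data.frame with columns \code{label}, \code{onset_frame}
#'   (1-based), \code{duration_frames}; zero rows when no task model applies.
#' @slot subjectId,condition,runId identifiers.
#' @export
setClass("RunTimeSeries", representation(
  data = "matrix", confounds = "data.frame", events = "data.frame",
  subjectId = "character", condition = "character", runId = "character"))

.confoundCols <- c("global_signal", "csf", "white_matter",
                   "trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z", "framewise_displacement")

setValidity("RunTimeSeries", function(object) {
  Tn <- ncol(object@data)
  if (nrow(object@confounds) && nrow(object@confounds) != Tn)
    return("confound rows must equal timepoint count")
  fd <- object@confounds$framewise_displacement
  if (!is.null(fd) && any(fd < 0, na.rm = TRUE))
    return("framewise displacement must be nonnegative")
  TRUE
})

#' Construct a RunTimeSeries
#'
#' @param data regions x timepoints matrix.
#' @param confounds confound data.frame (may be zero-row).
#' @param events event data.frame (may be zero-row).
#' @param subjectId,condition,runId identifiers.
#' @return a \linkS4class{RunTimeSeries}.
#' @export
runTimeSeries <- function(data, confounds = data.frame(), events = .emptyEvents(),
                          subjectId = "sub", condition = "cond", runId = "run") {
  new("RunTimeSeries", data = data, confounds = confounds, events = events,
      subjectId = subjectId, condition = condition, runId = runId)
}

.emptyEvents <- function()
  data.frame(label = character(0), onset_frame = integer(0),
             duration_frames = integer(0))

#' @rdname runTimeSeries
#' @param object a \code{RunTimeSeries}.
#' @export
setMethod("show", "RunTimeSeries", function(object) {
  cat(sprintf("RunTimeSeries %s/%s/%s: %d regions x %d frames, %d confounds, %d events\n",
              object@subjectId, object@condition, object@runId,
              nrow(object@data), ncol(object@data),
              ncol(object@confounds), nrow(object@events)))
})

#' FCMatrix: one subject-by-condition functional connectivity matrix
#'
#' Symmetric matrix of Fisher z-transformed Pearson correlations between all
#' region pairs. The diagonal is undefined and stored as 0; it is masked out
#' of every downstream statistic. Edges touching a zero-variance region are
#' stored as \code{NA} and propagate as missing (pairwise-complete handling).
#'
#' @slot values R x R symmetric numeric matrix of Fisher-z correlations.
#' @slot subjectId,condition identifiers.
#' @slot nRunsAveraged number of runs averaged into this matrix.
#' @slot flaggedRegions integer indices of zero-variance regions whose edges
#'   are masked.
#' @export
setClass("FCMatrix", representation(
  values = "matrix", subjectId = "character", condition = "character",
  nRunsAveraged = "integer", flaggedRegions = "integer"))

setValidity("FCMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (max(abs(v - t(v)), na.rm = TRUE) > 1e-12) return("values must be symmetric")
  TRUE
})

#' @describeIn FCMatrix the Fisher-z value matrix.
#' @param x,object an \code{FCMatrix}.
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))

#' @rdname FCMatrix
#' @export
setMethod("fcValues", "FCMatrix", function(x) x@values)

#' @rdname FCMatrix
#' @export
setMethod("nRegions", "FCMatrix", function(x) nrow(x@values))

#' @rdname FCMatrix
#' @export
setMethod("show", "FCMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("FCMatrix %s/%s: %d regions, %d run(s) averaged\n",
              object@subjectId, object@condition, nRegions(object),
              object@nRunsAveraged))
  cat(sprintf("  edges: mean z %.3f (range %.3f..%.3f), %d missing\n",
              mean(off, na.rm = TRUE), suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)), sum(is.na(off))))
})

#' Motion screening of a run
#'
#' A run passes iff its mean framewise displacement is below
#' \code{fdMeanThreshold}, the fraction of frames with FD above
#' \code{spikeFdThreshold} is below \code{spikeFractionMax}, and no frame
#' exceeds \code{spikeHardMax} (inclusive bound: "no spikes above").
#'
#' @param run a \linkS4class{RunTimeSeries} whose confounds include
#'   \code{framewise_displacement}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return a one-row \code{data.frame}: \code{mean_fd}, \code{spike_fraction},
#'   \code{max_fd}, \code{pass}.
#' @export
screenRunMotion <- function(run, cfg = pipelineConfig()) {
  fd <- run@confounds$framewise_displacement
  if (is.null(fd)) stop("confounds lack a framewise_displacement column")
  out <- data.frame(
    subject_id = run@subjectId, condition = run@condition, run_id = run@runId,
    mean_fd = mean(fd), spike_fraction = mean(fd > cfg@spikeFdThreshold),
    max_fd = max(fd))
  out$pass <- out$mean_fd < cfg@fdMeanThreshold &
    out$spike_fraction < cfg@spikeFractionMax &
    out$max_fd <= cfg@spikeHardMax
  fcLog("screenRunMotion: %s/%s/%s mean_fd=%.3f spikes=%.2f max=%.2f pass=%s",
        run@subjectId, run@condition, run@runId, out$mean_fd,
        out$spike_fraction, out$max_fd, out$pass)
  out
}

# 4-term Satterthwaite-style expansion of one confound column:
# value, backward-difference derivative (first frame 0), square, squared derivative
.expandConfound <- function(v) {
  d <- c(0, diff(v))
  cbind(v, d, v^2, d^2)
}

# OLS residuals of each row of `data` (regions x T) on design X (T x p),
# dropping collinear columns (with a warning) when the design is rank deficient.
.residualize <- function(data, X, what = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf("rank-deficient %s: dropping %d collinear column(s)",
                    what, ncol(X) - qrX$rank))
    keep <- qrX$pivot[seq_len(qrX$rank)]
    qrX <- qr(X[, keep, drop = FALSE])
  }
  t(qr.resid(qrX, t(data)))
}

#' Nuisance regression
#'
#' Replaces each region's time series by its residual from an ordinary
#' least-squares fit on an intercept plus, for each confound column, the raw
#' value with three derived terms: temporal derivative (backward difference,
#' first frame 0), square, and squared derivative. Framewise displacement
#' receives the full expansion by default (\code{expandFd}); set
#' \code{expandFd = FALSE} in the config to enter it raw. Residuals are exactly
#' orthogonal to every retained design column, so the operation is a
#' projection (idempotent).
#'
#' @param run a screened \linkS4class{RunTimeSeries}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{RunTimeSeries} with residual data.
#' @export
nuisanceRegress <- function(run, cfg = pipelineConfig()) {
  cf <- run@confounds
  miss <- setdiff(.confoundCols, names(cf))
  if (length(miss)) stop("confounds missing columns: ", paste(miss, collapse = ", "))
  blocks <- lapply(.confoundCols, function(nm) {
    v <- cf[[nm]]
    if (nm == "framewise_displacement" && !cfg@expandFd) cbind(v)
    else .expandConfound(v)
  })
  X <- cbind(1, do.call(cbind, blocks))
  run@data <- .residualize(run@data, X, "nuisance design")
  fcLog("nuisanceRegress: %s/%s/%s design %d columns", run@subjectId,
        run@condition, run@runId, ncol(X))
  run
}

#' Task-evoked activity regression (FIR basis)
#'
#' Removes the mean task-evoked response from each region with a finite
#' impulse response basis: one indicator regressor per condition label and
#' post-onset lag \code{0..firLags-1}, each event contributing its boxcar of
#' \code{duration_frames} shifted by the lag. This takes out activity locked
#' to event timing without constraining the shape of the response, leaving
#' the background inter-region covariance of interest intact.
#'
#' @param run a \linkS4class{RunTimeSeries} with events.
#' @param cfg a \linkS4class{PipelineConfig} (provides \code{firLags}).
#' @return a \linkS4class{RunTimeSeries} with the task-evoked mean removed.
#'   When the run carries no events the data are returned unchanged with a
#'   warning.
#' @export
taskRegress <- function(run, cfg = pipelineConfig()) {
  ev <- run@events
  if (!nrow(ev)) {
    warning("no events: task regression is the identity for this run")
    return(run)
  }
  Tn <- ncol(run@data)
  K <- cfg@firLags
  if (K > Tn / 5) stop("FIR order exceeds timepoints/5")
  labs <- unique(ev$label)
  cols <- list()
  for (lb in labs) {
    sub <- ev[ev$label == lb, , drop = FALSE]
    for (k in seq_len(K) - 1L) {
      v <- numeric(Tn)
      for (r in seq_len(nrow(sub))) {
        fr <- (sub$onset_frame[r] + k):(sub$onset_frame[r] + k +
                                          max(sub$duration_frames[r], 1L) - 1L)
        fr <- fr[fr >= 1L & fr <= Tn]
        v[fr] <- 1
      }
      cols[[paste(lb, k, sep = "_lag")]] <- v
    }
  }
  X <- cbind(1, do.call(cbind, cols))
  run@data <- .residualize(run@data, X, "FIR task design")
  fcLog("taskRegress: %s/%s/%s %d labels x %d lags", run@subjectId,
        run@condition, run@runId, length(labs), K)
  run
}

#' Compute a Fisher-z functional connectivity matrix from one run
#'
#' Pearson correlations between all region pairs, clipped to
#' \code{fisherClip} in magnitude and arctanh-transformed. Zero-variance
#' regions are flagged and their edges stored as \code{NA}, never as silent
#' zeros; correlations of exactly +/-1 are clipped and flagged rather than
#' producing infinities.
#'
#' @param run a \linkS4class{RunTimeSeries} with at least 3 timepoints.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return an \linkS4class{FCMatrix}.
#' @export
computeFC <- function(run, cfg = pipelineConfig()) {
  if (ncol(run@data) < 3L) stop("need at least 3 timepoints")
  sds <- apply(run@data, 1L, sd)
  flagged <- which(sds == 0)
  r <- suppressWarnings(cor(t(run@data)))
  if (length(flagged)) {
    r[flagged, ] <- NA_real_
    r[, flagged] <- NA_real_
    fcLog("computeFC: %d zero-variance region(s) masked", length(flagged))
  }
  clipped <- abs(r) > cfg@fisherClip & upper.tri(r)
  if (any(clipped, na.rm = TRUE))
    fcLog("computeFC: %d edge(s) clipped at |r|=%.8f",
          sum(clipped, na.rm = TRUE), cfg@fisherClip)
  r <- pmin(pmax(r, -cfg@fisherClip), cfg@fisherClip)
  z <- atanh(r)
  diag(z) <- 0
  new("FCMatrix", values = z, subjectId = run@subjectId,
      condition = run@condition, nRunsAveraged = 1L,
      flaggedRegions = as.integer(flagged))
}

#' Average functional connectivity matrices in Fisher-z space
#'
#' Element-wise mean of the Fisher-z values; used to pool runs of the same
#' condition and to average the two component single tasks of a modality
#' pairing. Missing (masked) edges propagate as missing.
#'
#' @param matrices list of \linkS4class{FCMatrix} with identical dimensions.
#' @param condition condition label of the result; defaults to the first
#'   input's label.
#' @return an \linkS4class{FCMatrix} with \code{nRunsAveraged} set to the
#'   total number of runs pooled.
#' @export
averageFC <- function(matrices, condition = NULL) {
  stopifnot(length(matrices) >= 1L)
  Rs <- vapply(matrices, nRegions, integer(1))
  if (length(unique(Rs)) != 1L) stop("mixed dimensions")
  vals <- Reduce(`+`, lapply(matrices, fcValues)) / length(matrices)
  new("FCMatrix", values = vals,
      subjectId = matrices[[1]]@subjectId,
      condition = if (is.null(condition)) matrices[[1]]@condition else condition,
      nRunsAveraged = sum(vapply(matrices, function(m) m@nRunsAveraged, integer(1))),
      flaggedRegions = sort(unique(unlist(lapply(matrices,
                                                 function(m) m@flaggedRegions)))))
}
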