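#' Synthetic parcellation metadata
#'
#' Builds a parcel table with regions split evenly between hemispheres,
#' assigned to the seven canonical networks in contiguous blocks, and with a
#' deterministic subset of regions flagged as overlapping univariate task
#' clusters (labels cycle through visual, auditory, manual, vocal,
#' dual-frontal).
#'
#' @param nRegions number of regions (>= 14 for network-level statistics).
#' @param overlapFraction fraction of regions flagged with a task-cluster
#'   label.
#' @return a \linkS4class{ParcelTable}.
#' @export
syntheticParcelTable <- function(nRegions = 200L, overlapFraction = 0.4) {
  nets <- rep(.networks7, length.out = nRegions)
  nets <- sort(factor(nets, levels = .networks7))
  hemi <- rep(c("left", "right"), length.out = nRegions)
  nOv <- round(overlapFraction * nRegions)
  ov <- rep("", nRegions)
  if (nOv > 0) {
    # spread flagged regions evenly across the table so every network
    # contributes candidate regions
    idx <- unique(round(seq(1, nRegions, length.out = nOv)))
    ov[idx] <- rep(.clusterLabels, length.out = length(idx))
  }
  ParcelTable(data.frame(
    region_id = seq_len(nRegions),
    region_label = sprintf("%s_%s_%03d", substr(hemi, 1, 1),
                           as.character(nets), seq_len(nRegions)),
    hemisphere = hemi, network = as.character(nets), cluster_overlap = ov))
}

.allConditions <- c("VM", "AV", "VV", "AM", "dual-compatible", "dual-incompatible")
.singleTasks <- c("VM", "AV", "VV", "AM")
.pairingOf <- c(VM = "compatible", AV = "compatible",
                VV = "incompatible", AM = "incompatible",
                `dual-compatible` = "compatible",
                `dual-incompatible` = "incompatible")

.defaultBehaviorParams <- function() data.frame(
  condition = .allConditions,
  rt_mean = c(508.07, 508.07, 470.59, 470.59, 751.92, 868.59),
  rt_sd = c(241.14, 241.14, 170.65, 170.65, 193.98, 229.92),
  error_rate = c(0.0275, 0.0275, 0.0247, 0.0247, 0.1723, 0.3431))

#' SimulationConfig: parameters of the synthetic cohort
#'
#' Defines the study design the generator emulates: a cohort of subjects,
#' each with one run per dual-task modality pairing and two runs per
#' single-task condition, region-wise time series whose correlation
#' structure has seven-community block structure, condition-specific offsets
#' on designated edges, an optional subject-level latent coupling between an
#' edge's connectivity difference and the behavioral difference score,
#' log-normal motion traces, and condition-dependent reaction times and
#' error rates matching the dual-task literature.
#'
#' @slot nSubjects number of subjects.
#' @slot parcels \linkS4class{ParcelTable} giving region count and networks.
#' @slot nTimepoints named integer: frames per run per condition.
#' @slot runsPerCondition named integer: runs per condition; only listed
#'   conditions are generated.
#' @slot baseWithinR,baseBetweenR block correlations of the target matrix.
#' @slot effectEdges \code{data.frame(i, j, condition, delta_r)}: fixed
#'   correlation offsets planted on designated edges in one condition.
#' @slot couplingEdges \code{data.frame(i, j, coupling_r)}: edges whose
#'   incompatible-minus-compatible connectivity difference is coupled, at the
#'   given correlation, to the subject's behavioral difference score.
#' @slot edgeLatentSd SD (correlation units) of the subject-level latent
#'   contribution on coupling edges.
#' @slot behaviorParams \code{data.frame(condition, rt_mean, rt_sd,
#'   error_rate)} (ms / proportions).
#' @slot trialsPerDualRun,trialsPerSingleRun trials per run.
#' @slot omissionShare fraction of errors that are omissions.
#' @slot rtCouplingScale,errCouplingScale how strongly the behavioral latent
#'   shifts a subject's incompatible dual-task RT mean (ms per latent SD)
#'   and error rate.
#' @slot subjectRtSd between-subject SD of a global RT offset (ms).
#' @slot fdMedian,fdSubjectSdLog,fdFrameSdLog log-normal motion model:
#'   cohort median framewise displacement (mm), between-subject log SD,
#'   within-run frame-to-frame log SD.
#' @slot confoundLeakWeight weight with which the global-signal confound
#'   leaks into every region's series (0 = clean).
#' @slot seed integer; all generator output is a pure function of the
#'   config including this seed.
#' @export
setClass("SimulationConfig", representation(
  nSubjects = "integer", parcels = "ParcelTable", nTimepoints = "integer",
  runsPerCondition = "integer", baseWithinR = "numeric",
  baseBetweenR = "numeric", effectEdges = "data.frame",
  couplingEdges = "data.frame", edgeLatentSd = "numeric",
  behaviorParams = "data.frame", trialsPerDualRun = "integer",
  trialsPerSingleRun = "integer", omissionShare = "numeric",
  rtCouplingScale = "numeric", errCouplingScale = "numeric",
  subjectRtSd = "numeric", fdMedian = "numeric", fdSubjectSdLog = "numeric",
  fdFrameSdLog = "numeric", confoundLeakWeight = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be positive")
  if (abs(object@baseWithinR) >= 1 || abs(object@baseBetweenR) >= 1)
    return("base correlations must lie in (-1, 1)")
  bad <- setdiff(names(object@runsPerCondition), .allConditions)
  if (length(bad)) return(paste("unknown condition:", paste(bad, collapse = ", ")))
  if (nrow(object@effectEdges)) {
    if (any(abs(object@baseWithinR + object@effectEdges$delta_r) >= 1) &&
        any(abs(object@baseBetweenR + object@effectEdges$delta_r) >= 1))
      return("base r + delta_r must stay inside (-1, 1)")
    if (!all(object@effectEdges$condition %in% .allConditions))
      return("effectEdges condition must be a known condition")
  }
  if (nrow(object@couplingEdges) &&
      any(abs(object@couplingEdges$coupling_r) >= 1))
    return("coupling_r must lie in (-1, 1)")
  er <- object@behaviorParams$error_rate
  if (any(er < 0 | er > 1)) return("error rates must lie in [0, 1]")
  TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults reproduce the emulated study design: 47 subjects, a 200-region
#' seven-network parcellation, one 139-frame run per dual-task pairing and
#' two 183-frame runs per single task, within/between-network base
#' correlations of 0.3/0.1, and reaction-time/error marginals matching the
#' dual-task modality-compatibility literature (dual 752/869 ms and
#' 17.2\%/34.3\% errors for compatible/incompatible; singles 508/471 ms and
#' 2.8\%/2.5\%).
#'
#' @param nSubjects,parcels,nTimepoints,runsPerCondition,baseWithinR,baseBetweenR
#'   see \linkS4class{SimulationConfig}.
#' @param effectEdges,couplingEdges,edgeLatentSd,behaviorParams planted effects.
#' @param trialsPerDualRun,trialsPerSingleRun,omissionShare trial counts.
#' @param rtCouplingScale,errCouplingScale,subjectRtSd behavioral model.
#' @param fdMedian,fdSubjectSdLog,fdFrameSdLog,confoundLeakWeight nuisance model.
#' @param seed integer seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(
    nSubjects = 47L, parcels = syntheticParcelTable(200L),
    nTimepoints = c(VM = 183L, AV = 183L, VV = 183L, AM = 183L,
                    `dual-compatible` = 139L, `dual-incompatible` = 139L),
    runsPerCondition = c(VM = 2L, AV = 2L, VV = 2L, AM = 2L,
                         `dual-compatible` = 1L, `dual-incompatible` = 1L),
    baseWithinR = 0.3, baseBetweenR = 0.1,
    effectEdges = data.frame(i = integer(0), j = integer(0),
                             condition = character(0), delta_r = numeric(0)),
    couplingEdges = data.frame(i = integer(0), j = integer(0),
                               coupling_r = numeric(0)),
    edgeLatentSd = 0.12, behaviorParams = .defaultBehaviorParams(),
    trialsPerDualRun = 128L, trialsPerSingleRun = 32L, omissionShare = 0.15,
    rtCouplingScale = 60, errCouplingScale = 0.06, subjectRtSd = 40,
    fdMedian = 0.08, fdSubjectSdLog = 0.35, fdFrameSdLog = 0.4,
    confoundLeakWeight = 0, seed = 1L) {
  if (length(nTimepoints) == 1L && is.null(names(nTimepoints)))
    nTimepoints <- setNames(rep(as.integer(nTimepoints),
                                length(runsPerCondition)),
                            names(runsPerCondition))
  new("SimulationConfig", nSubjects = as.integer(nSubjects), parcels = parcels,
      nTimepoints = setNames(as.integer(nTimepoints), names(nTimepoints)),
      runsPerCondition = setNames(as.integer(runsPerCondition),
                                  names(runsPerCondition)),
      baseWithinR = baseWithinR, baseBetweenR = baseBetweenR,
      effectEdges = effectEdges, couplingEdges = couplingEdges,
      edgeLatentSd = edgeLatentSd, behaviorParams = behaviorParams,
      trialsPerDualRun = as.integer(trialsPerDualRun),
      trialsPerSingleRun = as.integer(trialsPerSingleRun),
      omissionShare = omissionShare, rtCouplingScale = rtCouplingScale,
      errCouplingScale = errCouplingScale, subjectRtSd = subjectRtSd,
      fdMedian = fdMedian, fdSubjectSdLog = fdSubjectSdLog,
      fdFrameSdLog = fdFrameSdLog, confoundLeakWeight = confoundLeakWeight,
      seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @param object a \code{SimulationConfig}.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d subjects, %d regions, conditions %s\n",
              object@nSubjects, nRegions(object@parcels),
              paste(names(object@runsPerCondition), collapse = ", ")))
  cat(sprintf("  base r within %.2f / between %.2f; %d effect edge(s), %d coupling edge(s); seed %d\n",
              object@baseWithinR, object@baseBetweenR,
              nrow(object@effectEdges), nrow(object@couplingEdges),
              object@seed))
})

.subjectIds <- function(cfg) sprintf("sub%03d", seq_len(cfg@nSubjects))

#' Subject-level latent scores of a simulation config
#'
#' Deterministic in the config seed. One standard-normal behavioral latent
#' per subject; each coupling edge mixes that latent with independent noise
#' so the correlation between the edge's planted connectivity delta and the
#' behavioral difference score equals its \code{coupling_r}.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return list: \code{behavior} (length-n vector) and \code{edges}
#'   (n x nrow(couplingEdges) matrix of edge latents).
#' @export
subjectLatents <- function(cfg) {
  withSeed(childSeed(cfg@seed, "latents"), {
    b <- rnorm(cfg@nSubjects)
    ne <- nrow(cfg@couplingEdges)
    E <- matrix(0, cfg@nSubjects, max(ne, 0L))
    for (e in seq_len(ne)) {
      r <- cfg@couplingEdges$coupling_r[e]
      E[, e] <- r * b + sqrt(1 - r^2) * rnorm(cfg@nSubjects)
    }
    list(behavior = b, edges = E)
  })
}

# block-structured target correlation matrix for one subject x condition
.targetCorrelation <- function(cfg, subjectIndex, condition, latents) {
  nets <- networks(cfg@parcels)
  R <- nRegions(cfg@parcels)
  Sig <- matrix(cfg@baseBetweenR, R, R)
  same <- outer(nets, nets, `==`)
  Sig[same] <- cfg@baseWithinR
  ee <- cfg@effectEdges
  for (k in seq_len(nrow(ee))) if (ee$condition[k] == condition) {
    Sig[ee$i[k], ee$j[k]] <- Sig[ee$i[k], ee$j[k]] + ee$delta_r[k]
    Sig[ee$j[k], ee$i[k]] <- Sig[ee$i[k], ee$j[k]]
  }
  ce <- cfg@couplingEdges
  if (nrow(ce) && condition == "dual-incompatible") {
    for (e in seq_len(nrow(ce))) {
      d <- cfg@edgeLatentSd * latents$edges[subjectIndex, e]
      Sig[ce$i[e], ce$j[e]] <- Sig[ce$i[e], ce$j[e]] + d
      Sig[ce$j[e], ce$i[e]] <- Sig[ce$i[e], ce$j[e]]
    }
  }
  Sig <- pmin(pmax(Sig, -0.97), 0.97)
  diag(Sig) <- 1
  Sig
}

# eigenvalue clipping at 1e-8 followed by diagonal re-normalization
.nearestPD <- function(Sig) {
  e <- eigen(Sig, symmetric = TRUE)
  if (min(e$values) >= 1e-8) return(Sig)
  fcLog("nearestPD repair applied (min eigenvalue %.3g)", min(e$values))
  v <- pmax(e$values, 1e-8)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

#' Simulate one run of parcellated time series
#'
#' Draws a zero-mean Gaussian process with the subject- and
#' condition-specific target correlation (white noise multiplied by the
#' Cholesky factor; the downstream analysis consumes only second-order
#' structure, so no hemodynamic model is imposed). Confound columns and a
#' log-normal framewise-displacement trace are attached; when
#' \code{confoundLeakWeight > 0} the global-signal column leaks into every
#' region.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param subject subject index (1-based) or id string.
#' @param condition one of the configured conditions.
#' @param run run number within the condition.
#' @return a \linkS4class{RunTimeSeries}.
#' @export
simulateTimeseries <- function(cfg, subject, condition, run = 1L) {
  if (is.character(subject)) subject <- match(subject, .subjectIds(cfg))
  stopifnot(!is.na(subject), condition %in% names(cfg@runsPerCondition))
  latents <- subjectLatents(cfg)
  Sig <- .nearestPD(.targetCorrelation(cfg, subject, condition, latents))
  Tn <- cfg@nTimepoints[[condition]]
  R <- nRegions(cfg@parcels)
  withSeed(childSeed(cfg@seed, paste("ts", subject, condition, run)), {
    L <- t(chol(Sig))
    data <- L %*% matrix(rnorm(R * Tn), R, Tn)
    conf <- data.frame(
      global_signal = rnorm(Tn), csf = rnorm(Tn), white_matter = rnorm(Tn),
      trans_x = rnorm(Tn, 0, 0.05), trans_y = rnorm(Tn, 0, 0.05),
      trans_z = rnorm(Tn, 0, 0.05), rot_x = rnorm(Tn, 0, 0.05),
      rot_y = rnorm(Tn, 0, 0.05), rot_z = rnorm(Tn, 0, 0.05))
    subjMedian <- withSeed(childSeed(cfg@seed, paste("motion", subject)),
                           cfg@fdMedian * exp(rnorm(1, 0, cfg@fdSubjectSdLog)))
    fd <- subjMedian * exp(rnorm(Tn, 0, cfg@fdFrameSdLog))
    fd[1] <- 0
    conf$framewise_displacement <- fd
    if (cfg@confoundLeakWeight != 0)
      data <- data + cfg@confoundLeakWeight *
        matrix(conf$global_signal, R, Tn, byrow = TRUE)
    runTimeSeries(data, conf, subjectId = .subjectIds(cfg)[subject],
                  condition = condition, runId = sprintf("run%02d", run))
  })
}

# truncated normal with lower bound, via inverse-CDF sampling
.rtruncnorm <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  qnorm(runif(n, plo, 1), mean, sd)
}

#' Simulate the cohort's trial table
#'
#' Per-trial reaction times (truncated normal, >= 150 ms) and correctness
#' (Bernoulli, omissions forming a fixed share of errors) for every
#' configured condition and run. When coupling edges are configured, each
#' subject's behavioral latent shifts the incompatible dual-task RT mean and
#' error rate, so the dual-task BIS difference correlates with the planted
#' connectivity differences.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return trial \code{data.frame} (see \code{\link{readTrialTable}}).
#' @export
simulateBehavior <- function(cfg) {
  bp <- cfg@behaviorParams
  need <- names(cfg@runsPerCondition)
  miss <- setdiff(need, bp$condition)
  if (length(miss)) stop("behaviorParams missing conditions: ",
                         paste(miss, collapse = ", "))
  latents <- subjectLatents(cfg)
  coupled <- nrow(cfg@couplingEdges) > 0
  ids <- .subjectIds(cfg)
  withSeed(childSeed(cfg@seed, "behavior"), {
    rtOffset <- rnorm(cfg@nSubjects, 0, cfg@subjectRtSd)
    rows <- list()
    for (s in seq_len(cfg@nSubjects)) {
      for (cond in need) {
        p <- bp[bp$condition == cond, ]
        isDual <- startsWith(cond, "dual")
        nTr <- if (isDual) cfg@trialsPerDualRun else cfg@trialsPerSingleRun
        mu <- p$rt_mean + rtOffset[s]
        err <- p$error_rate
        if (coupled && cond == "dual-incompatible") {
          mu <- mu - cfg@rtCouplingScale * latents$behavior[s]
          err <- min(max(err - cfg@errCouplingScale * latents$behavior[s],
                         0.01), 0.95)
        }
        for (r in seq_len(cfg@runsPerCondition[[cond]])) {
          rt <- .rtruncnorm(nTr, mu, p$rt_sd, 150)
          correct <- runif(nTr) > err
          omit <- !correct & runif(nTr) < cfg@omissionShare
          rt[omit] <- NA_real_
          expMod <- if (isDual) "both" else unname(.expectedModality[cond])
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = ids[s],
            run_id = sprintf("%s_run%02d", cond, r),
            block_id = paste0("block", rep(seq_len(max(1L, nTr %/% 16L)),
                                           each = 16L, length.out = nTr)),
            task_type = if (isDual) "dual" else "single",
            pairing = unname(.pairingOf[cond]),
            component_task = if (isDual)
              if (cond == "dual-compatible") "VM+AV" else "VV+AM" else cond,
            congruency = if (isDual)
              sample(c("congruent", "incongruent"), nTr, replace = TRUE)
              else NA_character_,
            response_modality = ifelse(omit, "none", expMod),
            rt = rt, correct = correct,
            difficulty = if (isDual) NA_character_ else
              rep(c("easy", "difficult"), length.out = nTr))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' SyntheticCohort: a fully simulated data set with ground truth
#'
#' @slot runs named list of \linkS4class{RunTimeSeries}; keys
#'   \code{"<subject>|<condition>|<run>"}.
#' @slot trials trial \code{data.frame}.
#' @slot covariates covariate \code{data.frame} (age, gender, mean FD over
#'   dual runs, valid single-run count).
#' @slot parcels the \linkS4class{ParcelTable} used.
#' @slot truth list with \code{subjects} (per-subject behavioral latents and
#'   difference scores) and \code{edges} (planted edges with per-subject
#'   realized deltas).
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("SyntheticCohort", representation(
  runs = "list", trials = "data.frame", covariates = "data.frame",
  parcels = "ParcelTable", truth = "list", config = "SimulationConfig"))

#' @rdname SyntheticCohort
#' @param object a \code{SyntheticCohort}.
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects, %d runs, %d trials, %d regions\n",
              object@config@nSubjects, length(object@runs),
              nrow(object@trials), nRegions(object@parcels)))
})

.runKey <- function(subject, condition, run)
  paste(subject, condition, sprintf("run%02d", run), sep = "|")

#' @describeIn SyntheticCohort fetch one run's time series.
#' @param cohort a \code{SyntheticCohort}.
#' @param subject subject id string.
#' @param condition condition name.
#' @param run run number.
#' @export
getRun <- function(cohort, subject, condition, run = 1L)
  cohort@runs[[.runKey(subject, condition, run)]]

#' Simulate a full synthetic cohort
#'
#' Generates every configured run's time series, the trial table, subject
#' covariates (age, gender, dual-run mean framewise displacement, valid
#' single-run count after motion screening), and the ground-truth record
#' needed to score recovery. All outputs are pure functions of the config,
#' including its seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param screenCfg \linkS4class{PipelineConfig} used for the valid-run
#'   counts recorded in the covariates.
#' @return a \linkS4class{SyntheticCohort}.
#' @export
simulateCohort <- function(cfg, screenCfg = pipelineConfig()) {
  latents <- subjectLatents(cfg)
  ids <- .subjectIds(cfg)
  runs <- list()
  for (s in seq_len(cfg@nSubjects))
    for (cond in names(cfg@runsPerCondition))
      for (r in seq_len(cfg@runsPerCondition[[cond]]))
        runs[[.runKey(ids[s], cond, r)]] <- simulateTimeseries(cfg, s, cond, r)
  trials <- simulateBehavior(cfg)
  demo <- withSeed(childSeed(cfg@seed, "covariates"), data.frame(
    subject_id = ids,
    age = round(runif(cfg@nSubjects, 18, 30)),
    gender = rbinom(cfg@nSubjects, 1L, 0.5)))
  dualConds <- grep("^dual", names(cfg@runsPerCondition), value = TRUE)
  singleConds <- intersect(names(cfg@runsPerCondition), .singleTasks)
  demo$mean_fd <- vapply(ids, function(id) {
    fds <- unlist(lapply(dualConds, function(cond)
      lapply(seq_len(cfg@runsPerCondition[[cond]]), function(r)
        getRunFd(runs, id, cond, r))))
    if (length(fds)) mean(fds) else NA_real_
  }, numeric(1))
  demo$n_valid_single_runs <- vapply(ids, function(id) {
    sum(unlist(lapply(singleConds, function(cond)
      vapply(seq_len(cfg@runsPerCondition[[cond]]), function(r)
        screenRunMotion(runs[[.runKey(id, cond, r)]], screenCfg)$pass,
        logical(1)))))
  }, integer(1))
  # ground truth: per-subject realized planted deltas and behavioral scores
  ce <- cfg@couplingEdges
  edgeDeltas <- if (nrow(ce))
    cfg@edgeLatentSd * latents$edges else matrix(0, cfg@nSubjects, 0)
  subjects <- data.frame(subject_id = ids, behavior_latent = latents$behavior,
                         behavior_diff = latents$behavior)
  if (nrow(ce))
    for (e in seq_len(nrow(ce)))
      subjects[[sprintf("delta_edge_%d_%d", ce$i[e], ce$j[e])]] <- edgeDeltas[, e]
  edges <- rbind(
    if (nrow(cfg@effectEdges))
      data.frame(i = cfg@effectEdges$i, j = cfg@effectEdges$j,
                 condition = cfg@effectEdges$condition,
                 delta_r = cfg@effectEdges$delta_r, type = "effect"),
    if (nrow(ce))
      data.frame(i = ce$i, j = ce$j, condition = "dual-incompatible",
                 delta_r = ce$coupling_r, type = "coupling"))
  if (is.null(edges)) edges <- data.frame(i = integer(0), j = integer(0),
                                          condition = character(0),
                                          delta_r = numeric(0),
                                          type = character(0))
  new("SyntheticCohort", runs = runs, trials = trials, covariates = demo,
      parcels = cfg@parcels, truth = list(subjects = subjects, edges = edges),
      config = cfg)
}

getRunFd <- function(runs, id, cond, r)
  mean(runs[[.runKey(id, cond, r)]]@confounds$framewise_displacement)

#' Write a synthetic cohort to a data directory
#'
#' Lays the cohort out exactly as the readers expect: one delimited matrix
#' per run under \code{timeseries/}, confounds under \code{confounds/},
#' \code{trials.tsv}, \code{covariates.tsv}, \code{parcels.tsv}, and a
#' \code{manifest.tsv}. Ground truth goes to a separate \code{truth/}
#' subdirectory so analysis code never reads it by accident.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return the manifest \code{data.frame}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  for (d in file.path(dir, c("timeseries", "confounds", "truth")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (key in names(cohort@runs)) {
    run <- cohort@runs[[key]]
    stem <- gsub("[|]", "_", key)
    writeMatrixFile(run@data, file.path(dir, "timeseries", paste0(stem, ".tsv")))
    writeTable17(run@confounds, file.path(dir, "confounds", paste0(stem, ".tsv")))
    manifest[[length(manifest) + 1L]] <- data.frame(
      subject_id = run@subjectId, condition = run@condition,
      run_id = run@runId, n_regions = nrow(run@data),
      n_timepoints = ncol(run@data), file = paste0(stem, ".tsv"))
  }
  manifest <- do.call(rbind, manifest)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeTrialTable(cohort@trials, file.path(dir, "trials.tsv"))
  writeCovariateTable(cohort@covariates, file.path(dir, "covariates.tsv"))
  writeParcelTable(cohort@parcels, file.path(dir, "parcels.tsv"))
  writeTable17(cohort@truth$subjects, file.path(dir, "truth", "subjects.tsv"))
  writeTable17(cohort@truth$edges, file.path(dir, "truth", "edges.tsv"))
  fcLog("writeCohort: %d runs written to %s", nrow(manifest), dir)
  invisible(manifest)
}

#' Read a cohort data directory back into memory
#'
#' Inverse of \code{\link{writeCohort}} for the analysis inputs (time
#' series, confounds, trials, covariates, parcels); ground truth is reloaded
#' when present.
#'
#' @param dir cohort directory.
#' @return a list with \code{runs}, \code{trials}, \code{covariates},
#'   \code{parcels}, and (if present) \code{truth}.
#' @export
readCohortDir <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"), sep = "\t")
  runs <- list()
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    data <- readMatrixFile(file.path(dir, "timeseries", m$file))
    conf <- read.delim(file.path(dir, "confounds", m$file), sep = "\t")
    run <- runTimeSeries(data, conf, subjectId = m$subject_id,
                         condition = m$condition, runId = m$run_id)
    runs[[paste(m$subject_id, m$condition, m$run_id, sep = "|")]] <- run
  }
  out <- list(runs = runs,
              trials = readTrialTable(file.path(dir, "trials.tsv")),
              covariates = readCovariateTable(file.path(dir, "covariates.tsv")),
              parcels = readParcelTable(file.path(dir, "parcels.tsv")))
  tf <- file.path(dir, "truth", "subjects.tsv")
  if (file.exists(tf))
    out$truth <- list(subjects = read.delim(tf, sep = "\t"),
                      edges = read.delim(file.path(dir, "truth", "edges.tsv"),
                                         sep = "\t"))
  out
}
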