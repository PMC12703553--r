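#' Expected response modality per component task
#' @keywords internal
.expectedModality <- c(VM = "manual", AV = "vocal", VV = "vocal", AM = "manual")

#' Apply run-level behavioral exclusion rules
#'
#' Flags invalid runs and excluded participants by three rules, each applied
#' per run:
#' \itemize{
#'   \item wrong response modality on more than five trials in any block of
#'     the run (e.g., a vocal response in a visual-manual block);
#'   \item more than 30\% errors (omissions count as errors) in a single-task
#'     or localizer run;
#'   \item for dual-task runs, more than 30\% errors on congruent trials
#'     (both stimuli requiring the same response side), by default averaged
#'     across the subject's two dual runs (\code{dualCongruentScope =
#'     "across"}); set \code{"within"} to judge each dual run on its own.
#' }
#' A participant is excluded when at least one dual-task run, more than one
#' localizer run, or more than three single-task runs are invalid.
#'
#' @param trials trial \code{data.frame} (see \code{\link{readTrialTable}};
#'   a \code{task_type} of \code{"localizer"} is screened with the
#'   single-task error rule).
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param errorMax error-rate bound applied by the run rules (0.30).
#' @param wrongModalityMax wrong-modality trials tolerated per block (5).
#' @return list with \code{trials} (rows from valid runs of retained
#'   subjects), \code{report} (one row per run x rule with the measured
#'   value and flag), and \code{excluded_subjects}.
#' @export
applyExclusionCriteria <- function(trials, cfg = pipelineConfig(),
                                   errorMax = 0.30, wrongModalityMax = 5L) {
  runs <- unique(trials[c("subject_id", "task_type", "run_id")])
  rownames(runs) <- NULL
  rep_rows <- list()
  flagRun <- function(sub, tt, run, rule, value, flagged)
    data.frame(subject_id = sub, task_type = tt, run_id = run,
               rule = rule, value = value, flagged = flagged)

  for (k in seq_len(nrow(runs))) {
    sub <- runs$subject_id[k]; tt <- runs$task_type[k]; run <- runs$run_id[k]
    tr <- trials[trials$subject_id == sub & trials$run_id == run &
                   trials$task_type == tt, , drop = FALSE]
    # wrong-modality rule, per block within the run
    wrong <- tr$response_modality != "none" & !is.na(tr$response_modality)
    if (tt == "dual") {
      wrong <- wrong & tr$response_modality != "both"
    } else {
      exp_mod <- .expectedModality[tr$component_task]
      wrong <- wrong & tr$response_modality != exp_mod
    }
    per_block <- tapply(wrong, tr$block_id, sum)
    wm <- max(c(per_block, 0), na.rm = TRUE)
    rep_rows[[length(rep_rows) + 1L]] <-
      flagRun(sub, tt, run, "wrong_modality", wm, wm > wrongModalityMax)
    # error-rate rule
    if (tt %in% c("single", "localizer")) {
      er <- mean(!tr$correct)
      rep_rows[[length(rep_rows) + 1L]] <-
        flagRun(sub, tt, run, "error_rate", er, er > errorMax)
    } else {
      cong <- tr[tr$congruency %in% "congruent", , drop = FALSE]
      if (cfg@dualCongruentScope == "across") {
        both <- trials[trials$subject_id == sub & trials$task_type == "dual" &
                         trials$congruency %in% "congruent", , drop = FALSE]
        er <- if (nrow(both)) mean(!both$correct) else NA_real_
      } else {
        er <- if (nrow(cong)) mean(!cong$correct) else NA_real_
      }
      rep_rows[[length(rep_rows) + 1L]] <-
        flagRun(sub, tt, run, "congruent_error_rate", er,
                isTRUE(er > errorMax))
    }
  }
  report <- do.call(rbind, rep_rows)
  runFlag <- stats::aggregate(flagged ~ subject_id + task_type + run_id,
                              report, any)
  excl <- character(0)
  for (sub in unique(runFlag$subject_id)) {
    rf <- runFlag[runFlag$subject_id == sub, ]
    nbad <- function(tt) sum(rf$flagged[rf$task_type == tt])
    if (nbad("dual") >= 1L || nbad("localizer") > 1L || nbad("single") > 3L)
      excl <- c(excl, sub)
  }
  bad <- runFlag[runFlag$flagged, c("subject_id", "run_id", "task_type")]
  keep <- !(trials$subject_id %in% excl) &
    !(paste(trials$subject_id, trials$run_id, trials$task_type) %in%
        paste(bad$subject_id, bad$run_id, bad$task_type))
  fcLog("applyExclusionCriteria: %d/%d runs flagged, %d subject(s) excluded",
        sum(runFlag$flagged), nrow(runFlag), length(excl))
  list(trials = trials[keep, , drop = FALSE], report = report,
       excluded_subjects = excl)
}

#' BISResult: integrated behavioral performance scores
#'
#' @slot cells \code{data.frame}, one row per subject x task type x pairing:
#'   \code{mean_rt} (ms, correct trials only), \code{accuracy} (proportion,
#'   omissions counted as errors), and \code{bis} (z units).
#' @slot costs \code{data.frame}, one row per subject x pairing:
#'   \code{dual_task_cost = bis_single - bis_dual} (positive = worse
#'   dual-task performance); \code{NA} when either cell is missing.
#' @export
setClass("BISResult", representation(cells = "data.frame", costs = "data.frame"))

#' @describeIn BISResult per-cell scores.
#' @param x,object a \code{BISResult}.
#' @export
setGeneric("bisCells", function(x) standardGeneric("bisCells"))

#' @rdname BISResult
#' @export
setMethod("bisCells", "BISResult", function(x) x@cells)

#' @describeIn BISResult per-subject dual-task costs.
#' @export
setGeneric("dualTaskCosts", function(x) standardGeneric("dualTaskCosts"))

#' @rdname BISResult
#' @export
setMethod("dualTaskCosts", "BISResult", function(x) x@costs)

#' @rdname BISResult
#' @export
setMethod("show", "BISResult", function(object) {
  cat(sprintf("BISResult: %d cells, %d subjects\n", nrow(object@cells),
              length(unique(object@cells$subject_id))))
  ok <- !is.na(object@costs$dual_task_cost)
  if (any(ok)) {
    m <- tapply(object@costs$dual_task_cost[ok], object@costs$pairing[ok], mean)
    cat("  mean dual-task cost:",
        paste(sprintf("%s %.3f", names(m), m), collapse = ", "), "\n")
  }
})

.zscore <- function(v) {
  s <- sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    fcLog("computeBIS: zero-variance standardization pool; z set to 0")
    return(rep(0, length(v)))
  }
  (v - mean(v, na.rm = TRUE)) / s
}

#' Balanced integration score (BIS) and dual-task costs
#'
#' Integrates speed and accuracy into one score per subject x task type x
#' pairing cell: \code{bis = z(accuracy) - z(mean RT)}, with z
#' standardization over the pooled set of all cells (so the score is
#' invariant to affine rescaling of RT or accuracy units, and larger values
#' mean better performance). Mean RT uses correct-response trials only;
#' accuracy counts omissions as errors. Single-task cells use easy blocks
#' only and average the two component tasks of each pairing. The dual-task
#' cost is \code{bis_single - bis_dual}, positive when dual-task performance
#' is worse.
#'
#' @param trials trial \code{data.frame}, already filtered by
#'   \code{\link{applyExclusionCriteria}}.
#' @return a \linkS4class{BISResult}.
#' @export
computeBIS <- function(trials) {
  tr <- trials[trials$task_type %in% c("single", "dual"), , drop = FALSE]
  tr <- tr[!(tr$task_type == "single" & !(tr$difficulty %in% "easy")), ,
           drop = FALSE]
  cellStats <- function(d) {
    rts <- d$rt[d$correct & !is.na(d$rt)]
    data.frame(mean_rt = if (length(rts)) mean(rts) else NA_real_,
               accuracy = mean(d$correct), n_trials = nrow(d))
  }
  # dual: directly per subject x pairing; single: per component task first,
  # then average the pairing's two components
  parts <- list()
  dual <- tr[tr$task_type == "dual", , drop = FALSE]
  if (nrow(dual)) {
    sp <- split(dual, list(dual$subject_id, dual$pairing), drop = TRUE)
    parts$dual <- do.call(rbind, lapply(sp, function(d)
      cbind(data.frame(subject_id = d$subject_id[1], task_type = "dual",
                       pairing = d$pairing[1]), cellStats(d))))
  }
  single <- tr[tr$task_type == "single", , drop = FALSE]
  if (nrow(single)) {
    sp <- split(single, list(single$subject_id, single$component_task),
                drop = TRUE)
    comp <- do.call(rbind, lapply(sp, function(d)
      cbind(data.frame(subject_id = d$subject_id[1],
                       pairing = d$pairing[1],
                       component_task = d$component_task[1]), cellStats(d))))
    sp2 <- split(comp, list(comp$subject_id, comp$pairing), drop = TRUE)
    parts$single <- do.call(rbind, lapply(sp2, function(d)
      data.frame(subject_id = d$subject_id[1], task_type = "single",
                 pairing = d$pairing[1], mean_rt = mean(d$mean_rt),
                 accuracy = mean(d$accuracy), n_trials = sum(d$n_trials))))
  }
  cells <- do.call(rbind, parts)
  rownames(cells) <- NULL
  cells$bis <- .zscore(cells$accuracy) - .zscore(cells$mean_rt)
  pairings <- unique(cells$pairing)
  subs <- unique(cells$subject_id)
  grid <- expand.grid(subject_id = subs, pairing = pairings,
                      stringsAsFactors = FALSE)
  getBis <- function(sub, tt, pr) {
    v <- cells$bis[cells$subject_id == sub & cells$task_type == tt &
                     cells$pairing == pr]
    if (length(v) == 1L && !is.na(v)) v else NA_real_
  }
  grid$dual_task_cost <- mapply(function(sub, pr)
    getBis(sub, "single", pr) - getBis(sub, "dual", pr),
    grid$subject_id, grid$pairing)
  if (anyNA(grid$dual_task_cost))
    fcLog("computeBIS: %d subject x pairing cost(s) undefined (missing cell)",
          sum(is.na(grid$dual_task_cost)))
  new("BISResult", cells = cells, costs = grid)
}

#' Behavioral modality-compatibility contrast
#'
#' Paired comparison of dual-task costs between the two modality pairings
#' (compatible minus incompatible, so the t statistic is negative when the
#' incompatible pairing carries the larger cost), with a JZS Bayes factor.
#'
#' @param bis a \linkS4class{BISResult} with costs for both pairings.
#' @return a \code{\link{TestResult}}.
#' @export
behavioralContrast <- function(bis) {
  costs <- dualTaskCosts(bis)
  wide <- merge(costs[costs$pairing == "compatible",
                      c("subject_id", "dual_task_cost")],
                costs[costs$pairing == "incompatible",
                      c("subject_id", "dual_task_cost")],
                by = "subject_id", suffixes = c("_comp", "_incomp"))
  wide <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3L) stop("fewer than 3 subjects with both costs defined")
  pairedTtest(wide$dual_task_cost_comp, wide$dual_task_cost_incomp)
}

#' Per-subject dual-task BIS difference
#'
#' The behavioral difference score used by the edge-level brain-behavior
#' analysis: dual-task BIS for the incompatible pairing minus dual-task BIS
#' for the compatible pairing (positive = relatively better incompatible
#' performance).
#'
#' @param bis a \linkS4class{BISResult}.
#' @return \code{data.frame}: \code{subject_id}, \code{bis_diff}.
#' @export
dualBISDifference <- function(bis) {
  cells <- bisCells(bis)
  d <- cells[cells$task_type == "dual", , drop = FALSE]
  wide <- merge(d[d$pairing == "incompatible", c("subject_id", "bis")],
                d[d$pairing == "compatible", c("subject_id", "bis")],
                by = "subject_id", suffixes = c("_incomp", "_comp"))
  data.frame(subject_id = wide$subject_id,
             bis_diff = wide$bis_incomp - wide$bis_comp)
}
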