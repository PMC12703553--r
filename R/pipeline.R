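#' Per-subject dual-task FC matrices from a cohort
#'
#' For every subject and dual-task condition: screen runs for motion, apply
#' nuisance regression (and task-evoked FIR regression when the run carries
#' events), compute the Fisher-z FC per run, and average runs. Subjects
#' lacking a passing run in either condition are dropped.
#'
#' @param cohort a \linkS4class{SyntheticCohort} (or any list-alike with
#'   \code{runs} keyed \code{subject|condition|runNN}).
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param regress apply nuisance regression (default TRUE).
#' @return list: \code{fcPairs} (per-subject lists with
#'   \code{incompatible}/\code{compatible} \linkS4class{FCMatrix}) and
#'   \code{qc} (motion-screening table).
#' @export
cohortDualFC <- function(cohort, cfg = pipelineConfig(), regress = TRUE) {
  runs <- if (is.list(cohort)) cohort$runs else cohort@runs
  qc <- list()
  fcPairs <- list()
  conds <- c(incompatible = "dual-incompatible", compatible = "dual-compatible")
  subjects <- unique(vapply(strsplit(names(runs), "|", fixed = TRUE),
                            `[[`, character(1), 1L))
  for (sub in subjects) {
    pair <- list()
    for (nm in names(conds)) {
      keys <- grep(paste0("^", sub, "\\|", conds[[nm]], "\\|"), names(runs),
                   value = TRUE)
      mats <- list()
      for (key in keys) {
        run <- runs[[key]]
        ms <- screenRunMotion(run, cfg)
        qc[[length(qc) + 1L]] <- ms
        if (!ms$pass) next
        if (regress) {
          run <- nuisanceRegress(run, cfg)
          if (nrow(run@events)) run <- taskRegress(run, cfg)
        }
        mats[[length(mats) + 1L]] <- computeFC(run, cfg)
      }
      if (length(mats)) pair[[nm]] <- averageFC(mats)
    }
    if (all(names(conds) %in% names(pair))) fcPairs[[sub]] <- pair
  }
  list(fcPairs = fcPairs, qc = do.call(rbind, qc))
}

#' End-to-end dual-task edge-selection analysis
#'
#' Runs the whole chain on a cohort: behavioral exclusion and BIS scoring,
#' per-subject dual-task FC construction with motion screening and nuisance
#' regression, the edge-wise condition-difference panel, and the
#' leave-one-out permutation-null stability selection of brain-behavior
#' edges.
#'
#' @param cohort a \linkS4class{SyntheticCohort}, or the list returned by
#'   \code{\link{readCohortDir}}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return list: \code{selection} (\linkS4class{EdgeSelectionResult}),
#'   \code{panel}, \code{behavior}, \code{bis}, \code{exclusion}, \code{qc}.
#' @export
runEdgeSelectionPipeline <- function(cohort, cfg = pipelineConfig()) {
  asList <- is.list(cohort)
  trials <- if (asList) cohort$trials else cohort@trials
  covariates <- if (asList) cohort$covariates else cohort@covariates
  parcels <- if (asList) cohort$parcels else cohort@parcels
  excl <- applyExclusionCriteria(trials, cfg)
  bis <- computeBIS(excl$trials)
  behavior <- merge(dualBISDifference(bis), covariates, by = "subject_id")
  fc <- cohortDualFC(if (asList) cohort else list(runs = cohort@runs), cfg)
  panel <- buildDifferencePanel(fc$fcPairs)
  selection <- looStabilitySelection(panel, behavior, parcels, cfg)
  list(selection = selection, panel = panel, behavior = behavior, bis = bis,
       exclusion = excl, qc = fc$qc)
}
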