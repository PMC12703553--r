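#' Read a delimited numeric matrix
#'
#' Reads a headerless rectangular grid of numbers (tab- or
#' whitespace-delimited). Ragged rows and non-numeric cells are errors.
#' Together with \code{\link{writeMatrixFile}} the round trip is
#' bit-identical: values are written with 17 significant digits, enough to
#' reproduce any double exactly.
#'
#' @param path path to the text file.
#' @return a numeric matrix.
#' @export
readMatrixFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  cells <- strsplit(trimws(lines), "[\t ]+")
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in matrix file: ", path)
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) stop("non-numeric cell in matrix file: ", path)
  m <- matrix(vals, nrow = length(lines), ncol = ncols[1], byrow = TRUE)
  fcLog("readMatrixFile: %s -> %d x %d", path, nrow(m), ncol(m))
  m
}

#' Write a numeric matrix as delimited text
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixFile <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  txt <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

# write a data.frame as TSV with numeric columns at 17 significant digits,
# so read.delim reproduces every double exactly
writeTable17 <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' Tab-separated, one row per subject, with columns \code{subject_id},
#' \code{age} (years), \code{gender} (pre-coded 0/1), \code{mean_fd} (mm),
#' and \code{n_valid_single_runs}.
#'
#' @param path TSV path.
#' @return a \code{data.frame}, one row per subject.
#' @export
readCovariateTable <- function(path) {
  tb <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("subject_id", "age", "gender", "mean_fd", "n_valid_single_runs")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("covariate table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tb$subject_id)) stop("duplicate subject_id in covariate table")
  fcLog("readCovariateTable: %s -> %d subjects", path, nrow(tb))
  tb
}

#' Write a covariate table
#'
#' @param covariates data.frame as returned by \code{\link{readCovariateTable}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCovariateTable <- function(covariates, path) {
  writeTable17(covariates, path)
}

#' Read a trial-level behavior table
#'
#' @param path TSV path with the columns documented in
#'   \code{\link{simulateBehavior}}.
#' @return a \code{data.frame} of trials.
#' @export
readTrialTable <- function(path) {
  tb <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = c("NA", ""))
  need <- c("subject_id", "run_id", "block_id", "task_type", "pairing",
            "component_task", "congruency", "response_modality", "rt",
            "correct", "difficulty")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("trial table missing columns: ",
                         paste(miss, collapse = ", "))
  tb$correct <- as.logical(tb$correct)
  tb
}

#' Write a trial-level behavior table
#'
#' @param trials trial \code{data.frame}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  writeTable17(trials, path)
}
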