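#' Canonical vocabulary for parcel metadata
#'
#' The seven canonical resting-state networks used to label parcels and the
#' task-cluster labels a localizer analysis can attach to a region.
#'
#' @name parcelVocabulary
#' @keywords internal
NULL

.networks7 <- c("visual", "somatomotor", "dorsal-attention",
                "ventral-attention", "limbic", "control", "default")
.clusterLabels <- c("visual", "auditory", "manual", "vocal", "dual-frontal")

#' ParcelTable: parcellation metadata
#'
#' Region-level metadata for a cortical parcellation: one row per region with
#' a unique contiguous id, a free-text label, a hemisphere, exactly one of the
#' seven canonical functional network labels, and a (possibly empty) set of
#' task-cluster overlap flags produced by a univariate localizer analysis.
#'
#' @slot table a \code{data.frame} with columns \code{region_id} (integer,
#'   1..R, contiguous), \code{region_label}, \code{hemisphere}
#'   (\code{left}/\code{right}), \code{network} (one of the seven canonical
#'   names), and \code{cluster_overlap} (comma-separated subset of
#'   \code{visual, auditory, manual, vocal, dual-frontal}; empty string when
#'   the region overlaps no task cluster).
#' @export
setClass("ParcelTable", representation(table = "data.frame"))

setValidity("ParcelTable", function(object) {
  tb <- object@table
  need <- c("region_id", "region_label", "hemisphere", "network", "cluster_overlap")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  if (anyDuplicated(tb$region_id)) return("duplicate region_id")
  R <- nrow(tb)
  if (!identical(sort(as.integer(tb$region_id)), seq_len(R)))
    return("region_id must be contiguous 1..R")
  if (!all(tb$hemisphere %in% c("left", "right")))
    return("hemisphere must be 'left' or 'right'")
  bad <- setdiff(unique(tb$network), .networks7)
  if (length(bad))
    return(paste("unknown network label(s):", paste(bad, collapse = ", ")))
  labs <- unlist(strsplit(tb$cluster_overlap[nzchar(tb$cluster_overlap)], ","),
                 use.names = FALSE)
  bad <- setdiff(trimws(labs), .clusterLabels)
  if (length(bad))
    return(paste("unknown cluster label(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a ParcelTable from a data.frame
#'
#' @param table data.frame with the columns documented in
#'   \linkS4class{ParcelTable}. \code{cluster_overlap} may be missing (all
#'   regions then carry no overlap flag).
#' @return a validated \linkS4class{ParcelTable}.
#' @export
ParcelTable <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$cluster_overlap)) table$cluster_overlap <- ""
  table$cluster_overlap[is.na(table$cluster_overlap)] <- ""
  table$region_id <- as.integer(table$region_id)
  table <- table[order(table$region_id), , drop = FALSE]
  rownames(table) <- NULL
  new("ParcelTable", table = table)
}

#' @describeIn ParcelTable number of regions R.
#' @param x,object a \code{ParcelTable}.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname ParcelTable
#' @export
setMethod("nRegions", "ParcelTable", function(x) nrow(x@table))

#' @describeIn ParcelTable network label per region (character vector, length R).
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' @rdname ParcelTable
#' @export
setMethod("networks", "ParcelTable", function(x) x@table$network)

#' @describeIn ParcelTable region labels (character vector, length R).
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname ParcelTable
#' @export
setMethod("regionLabels", "ParcelTable", function(x) x@table$region_label)

#' @describeIn ParcelTable list (length R) of task-cluster labels per region.
#' @export
setGeneric("clusterOverlap", function(x) standardGeneric("clusterOverlap"))

#' @rdname ParcelTable
#' @export
setMethod("clusterOverlap", "ParcelTable", function(x) {
  lapply(x@table$cluster_overlap, function(s)
    if (nzchar(s)) trimws(strsplit(s, ",")[[1]]) else character(0))
})

#' @describeIn ParcelTable logical vector: does the region overlap any task cluster?
#' @export
setGeneric("hasClusterOverlap", function(x) standardGeneric("hasClusterOverlap"))

#' @rdname ParcelTable
#' @export
setMethod("hasClusterOverlap", "ParcelTable", function(x)
  nzchar(x@table$cluster_overlap))

#' @rdname ParcelTable
#' @export
setMethod("show", "ParcelTable", function(object) {
  cat(sprintf("ParcelTable with %d regions across %d networks\n",
              nRegions(object), length(unique(networks(object)))))
  cat(sprintf("  task-cluster overlap: %d regions flagged\n",
              sum(hasClusterOverlap(object))))
})

#' Read a parcellation metadata table
#'
#' Reads a tab-separated parcel table with a header row and validates it:
#' region ids must be unique and contiguous, the network label must come from
#' the seven-name canonical vocabulary, and cluster-overlap flags must come
#' from the localizer label set.
#'
#' @param path path to a TSV file.
#' @return a \linkS4class{ParcelTable}.
#' @export
readParcelTable <- function(path) {
  tb <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  pt <- ParcelTable(tb)
  fcLog("readParcelTable: %s -> %d regions", path, nRegions(pt))
  pt
}

#' Write a parcellation metadata table
#'
#' @param parcels a \linkS4class{ParcelTable}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeParcelTable <- function(parcels, path) {
  stopifnot(is(parcels, "ParcelTable"))
  write.table(parcels@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
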