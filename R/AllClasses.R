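#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' Paired IgA+/IgA- fraction container
#'
#' An S4 class holding the subject-level join of an IgA-SEQ experiment: two
#' taxon-by-subject count matrices (assays \code{pos} and \code{neg}, one
#' column per subject, aligned on both axes) plus per-subject metadata
#' (\code{group}, \code{site}, \code{basdai}, optionally \code{sex},
#' \code{age}) in \code{colData}. Extends
#' \linkS4class{SummarizedExperiment}, so standard subsetting (\code{[}),
#' \code{dim}, \code{rownames} (taxa) and \code{colnames} (subjects) apply.
#'
#' @slot .. inherited from \linkS4class{SummarizedExperiment}.
#' @seealso [pairFractions()] which constructs this class from a count table
#'   and a sample manifest, [filterByDepth()], [prevalenceFilter()],
#'   [igaIndexMatrix()].
#' @export
setClass("PairedFractions", contains = "SummarizedExperiment")

.check_count_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    return(sprintf("assay '%s' must be a numeric matrix", what))
  if (anyNA(m)) return(sprintf("assay '%s' contains NA counts", what))
  if (any(m < 0)) return(sprintf("assay '%s' contains negative counts", what))
  if (any(m != round(m))) return(sprintf("assay '%s' contains non-integer counts", what))
  NULL
}

setValidity("PairedFractions", function(object) {
  msgs <- character(0)
  an <- assayNames(object)
  if (!identical(an, c("pos", "neg")))
    msgs <- c(msgs, "assays must be named 'pos' and 'neg' (in that order)")
  else {
    msgs <- c(msgs, .check_count_matrix(assay(object, "pos"), "pos"),
              .check_count_matrix(assay(object, "neg"), "neg"))
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msgs <- c(msgs, "taxon (row) and subject (column) names are required")
  else {
    if (anyDuplicated(rownames(object)))
      msgs <- c(msgs, "duplicated taxon ids")
    if (anyDuplicated(colnames(object)))
      msgs <- c(msgs, "duplicated subject ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PairedFractions object
#'
#' @param pos,neg Non-negative integer matrices (taxa x subjects) with
#'   identical dimnames: counts of each taxon in the IgA+ (\code{pos}) and
#'   IgA- (\code{neg}) fraction of each subject.
#' @param subjectData A data.frame or \linkS4class{DataFrame} of per-subject
#'   metadata, one row per subject in column order. Columns \code{group},
#'   \code{site} and \code{basdai} are filled with \code{NA} when absent.
#' @return A [PairedFractions-class] object.
#' @export
PairedFractions <- function(pos, neg, subjectData = NULL) {
  if (!identical(dimnames(pos), dimnames(neg)))
    stop("'pos' and 'neg' must share identical dimnames")
  if (is.null(subjectData))
    subjectData <- DataFrame(subject_id = colnames(pos))
  subjectData <- as(subjectData, "DataFrame")
  for (col in c("subject_id", "group", "site", "basdai")) {
    if (!col %in% colnames(subjectData))
      subjectData[[col]] <- if (col == "subject_id") colnames(pos) else NA
  }
  rownames(subjectData) <- colnames(pos)
  se <- SummarizedExperiment(
    assays = list(pos = as.matrix(pos), neg = as.matrix(neg)),
    colData = subjectData)
  new("PairedFractions", se)
}

#' @describeIn PairedFractions IgA+ fraction counts (taxa x subjects).
#' @param x A \code{PairedFractions} object.
#' @export
posCounts <- function(x) assay(x, "pos")

#' @describeIn PairedFractions IgA- fraction counts (taxa x subjects).
#' @export
negCounts <- function(x) assay(x, "neg")

#' @describeIn PairedFractions Per-subject metadata as a data.frame.
#' @export
subjectData <- function(x) as.data.frame(colData(x))

#' @describeIn PairedFractions Sequencing depth of each subject's fractions;
#'   a subjects x 2 matrix with columns \code{pos} and \code{neg}.
#' @export
fractionDepths <- function(x) {
  cbind(pos = colSums(posCounts(x)), neg = colSums(negCounts(x)))
}

setMethod("show", "PairedFractions", function(object) {
  cat(sprintf("PairedFractions: %d taxa x %d subjects\n",
              nrow(object), ncol(object)))
  cd <- colData(object)
  if ("group" %in% colnames(cd) && !all(is.na(cd$group))) {
    tb <- table(cd$group)
    cat("  groups: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if ("site" %in% colnames(cd) && !all(is.na(cd$site)))
    cat("  site:   ", paste(unique(stats::na.omit(cd$site)), collapse = ", "), "\n")
  dp <- fractionDepths(object)
  cat(sprintf("  depth:   pos %s-%s, neg %s-%s reads\n",
              min(dp[, "pos"]), max(dp[, "pos"]),
              min(dp[, "neg"]), max(dp[, "neg"])))
})
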