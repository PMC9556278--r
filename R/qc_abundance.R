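## Sample-retention rule, prevalence filtering, taxonomic aggregation and
## relative-abundance conversion.

#' Filter subjects by fraction sequencing depth
#'
#' Retains subjects whose IgA+ and IgA- fractions both reach
#' \code{min_reads}. The boundary is inclusive: exactly \code{min_reads}
#' reads in both fractions is retained. Default 7,500 reads.
#'
#' @param paired A [PairedFractions-class] object.
#' @param min_reads Minimum reads required in each fraction (>= 0).
#' @return The filtered [PairedFractions-class]; dropped subjects are
#'   reported via \code{message()}. Idempotent.
#' @export
filterByDepth <- function(paired, min_reads = 7500) {
  stopifnot(is(paired, "PairedFractions"), min_reads >= 0)
  dp <- fractionDepths(paired)
  keep <- dp[, "pos"] >= min_reads & dp[, "neg"] >= min_reads
  if (any(!keep))
    message("filterByDepth: removed subject(s) below ", min_reads,
            " reads in a fraction: ",
            paste(sprintf("%s (pos=%d, neg=%d)", rownames(dp)[!keep],
                          dp[!keep, "pos"], dp[!keep, "neg"]),
                  collapse = ", "))
  if (!any(keep))
    stop("filterByDepth removed all subjects (min_reads = ", min_reads, ")")
  paired[, keep]
}

#' Filter taxa by prevalence across subjects
#'
#' A taxon is retained iff it is detected (count > 0 in either fraction) in
#' at least \code{min_subjects} subjects. Default 3, a permissive floor that
#' avoids single-subject artifacts.
#'
#' @param paired A [PairedFractions-class] object.
#' @param min_subjects Minimum number of subjects with detection (>= 0).
#' @return The filtered [PairedFractions-class]. Idempotent.
#' @export
prevalenceFilter <- function(paired, min_subjects = 3) {
  stopifnot(is(paired, "PairedFractions"), min_subjects >= 0)
  detected <- (posCounts(paired) + negCounts(paired)) > 0
  keep <- rowSums(detected) >= min_subjects
  if (any(!keep))
    message("prevalenceFilter: removed ", sum(!keep),
            " taxa detected in fewer than ", min_subjects, " subjects")
  paired[keep, ]
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Aggregate a count table to a taxonomic rank
#'
#' Sums counts over taxa sharing the lineage down to \code{rank}. Taxa
#' unclassified at that rank are pooled into \code{"unclassified_<parent>"}
#' rows, where parent is the nearest classified higher rank. \code{rank =
#' "asv"} is the identity.
#'
#' @param counts Integer matrix (taxa x samples).
#' @param taxonomy Data.frame with column \code{taxon_id} and lineage columns
#'   \code{kingdom} ... \code{genus}; every row of \code{counts} must have an
#'   entry. Empty strings and NA mean unclassified at that rank.
#' @param rank One of kingdom, phylum, class, order, family, genus, asv.
#' @return An integer matrix aggregated to \code{rank}; total counts are
#'   conserved.
#' @export
aggregateTaxonomy <- function(counts, taxonomy, rank) {
  rank <- as.character(rank)
  if (!rank %in% c(.RANKS, "asv"))
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(c(.RANKS, "asv"), collapse = ", "))
  if (rank == "asv") return(counts)
  miss <- setdiff(rownames(counts), taxonomy$taxon_id)
  if (length(miss))
    stop("taxa missing from taxonomy: ", paste(miss, collapse = ", "))
  tax <- taxonomy[match(rownames(counts), taxonomy$taxon_id), , drop = FALSE]
  upto <- .RANKS[seq_len(match(rank, .RANKS))]
  lab <- vapply(seq_len(nrow(tax)), function(i) {
    lin <- as.character(unlist(tax[i, upto]))
    lin[is.na(lin)] <- ""
    at <- lin[length(lin)]
    if (!nzchar(at)) {
      parents <- lin[nzchar(lin)]
      parent <- if (length(parents)) parents[length(parents)] else "root"
      paste0("unclassified_", parent)
    } else at
  }, character(1))
  m <- rowsum(counts, group = lab, reorder = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Convert counts to relative abundance
#'
#' Adds \code{pseudocount} to every cell and normalizes each sample (column)
#' to sum to 1. The default pseudocount of 1 read keeps downstream log-ratio
#' statistics (the IgA index) defined in the presence of zeros.
#'
#' @param counts Numeric matrix (taxa x samples), non-negative.
#' @param pseudocount Reads added to every cell before normalization (>= 0).
#' @return Matrix of proportions; columns sum to 1; strictly positive when
#'   \code{pseudocount > 0}.
#' @export
relativeAbundance <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount >= 0, all(counts >= 0))
  m <- counts + pseudocount
  cs <- colSums(m)
  if (any(cs == 0))
    stop("zero-depth sample(s) with pseudocount 0: ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(m, 2, cs, "/")
}
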