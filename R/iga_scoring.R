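## The core statistic: the per-taxon IgA index on paired fraction relative
## abundances, enrichment/depletion calls within group, and between-group
## index comparison.

#' The IgA index
#'
#' For a taxon with relative abundance \code{p_pos} in the IgA+ fraction and
#' \code{p_neg} in the IgA- fraction,
#' \deqn{-\frac{\log p^{+} - \log p^{-}}{\log p^{+} + \log p^{-}}}
#' a log ratio bounded in [-1, 1] for proportions in (0, 1): since both logs
#' are negative, |log a - log b| <= |log a + log b|. Positive values mean the
#' taxon is preferentially IgA-coated (enriched in the IgA+ fraction); the
#' index is antisymmetric under swapping the fractions and invariant to the
#' logarithm base (the base cancels in the ratio).
#'
#' @param p_pos,p_neg Relative abundances strictly inside (0, 1); use a
#'   pseudocount upstream (see [relativeAbundance()]) to guarantee this.
#'   Vectorized; recycled to a common length.
#' @return Numeric vector of index values in [-1, 1].
#' @export
igaIndex <- function(p_pos, p_neg) {
  if (any(p_pos <= 0 | p_pos >= 1 | p_neg <= 0 | p_neg >= 1))
    stop("proportions must lie strictly in (0, 1); apply a pseudocount ",
         "(see relativeAbundance) before computing the IgA index")
  -(log(p_pos) - log(p_neg)) / (log(p_pos) + log(p_neg))
}

#' Per-taxon, per-subject IgA index matrix
#'
#' Applies [igaIndex()] elementwise to the per-fraction relative abundances
#' of a paired table (pseudocount applied per cell before normalization).
#' A taxon undetected in both fractions of a subject yields \code{NA}, not a
#' pseudocount-driven 0: double absence is no evidence about coating.
#'
#' @param paired A [PairedFractions-class] object (post-QC).
#' @param pseudocount Reads added per cell (default 1).
#' @return Numeric matrix (taxa x subjects) in [-1, 1] with \code{NA} for
#'   double-absent cells.
#' @export
igaIndexMatrix <- function(paired, pseudocount = 1) {
  stopifnot(is(paired, "PairedFractions"))
  pos <- posCounts(paired)
  neg <- negCounts(paired)
  pp <- relativeAbundance(pos, pseudocount)
  pn <- relativeAbundance(neg, pseudocount)
  idx <- igaIndex(pp, pn)
  idx[pos == 0 & neg == 0] <- NA_real_
  idx
}

#' Call IgA-enriched and IgA-depleted taxa within a group
#'
#' For each taxon, a two-sided one-sample Wilcoxon signed-rank test of the
#' group's per-subject index values against 0 (the natural paired-design
#' test: equivalent to a paired test on log fraction abundances), followed by
#' Benjamini-Hochberg correction across the taxa tested in the group. A
#' significant taxon is called \code{enriched} if its median index is > 0 and
#' \code{depleted} if < 0. Taxa with fewer than \code{min_n} non-missing
#' values are reported \code{untested} (below n = 5 the exact signed-rank
#' test cannot reach two-sided p < 0.05).
#'
#' @param idx Matrix from [igaIndexMatrix()].
#' @param groups Named vector mapping subject ids to group labels.
#' @param group The group to test (e.g. \code{"axSpA"}).
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @param min_n Minimum subjects with a non-missing index (default 5).
#' @return Data.frame with columns \code{taxon_id}, \code{group}, \code{n},
#'   \code{median_index}, \code{p}, \code{p_fdr}, \code{call} (enriched /
#'   depleted / ns / untested).
#' @export
callEnrichment <- function(idx, groups, group, fdr_threshold = 0.05, min_n = 5) {
  subs <- intersect(colnames(idx), names(groups)[groups == group])
  if (!length(subs)) stop("no subjects in group '", group, "'")
  res <- data.frame(taxon_id = rownames(idx), group = group,
                    n = NA_integer_, median_index = NA_real_,
                    p = NA_real_, p_fdr = NA_real_, call = "untested",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(idx))) {
    v <- idx[i, subs]
    v <- v[!is.na(v)]
    res$n[i] <- length(v)
    if (length(v) < min_n) next
    res$median_index[i] <- stats::median(v)
    res$p[i] <- suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
  }
  skipped <- sum(is.na(res$p))
  if (skipped)
    message("callEnrichment: ", skipped, " taxa untested (fewer than ",
            min_n, " subjects with an index value)")
  tested <- !is.na(res$p)
  res$p_fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  sig <- tested & res$p_fdr < fdr_threshold
  res$call[tested] <- "ns"
  res$call[sig & res$median_index > 0] <- "enriched"
  res$call[sig & res$median_index < 0] <- "depleted"
  res
}

#' Compare the IgA index between groups per taxon
#'
#' Two-sided Wilcoxon rank-sum test of per-subject index values between the
#' two groups, per taxon, with BH correction across taxa.
#'
#' @param idx Matrix from [igaIndexMatrix()].
#' @param groups Named vector mapping subject ids to exactly two group
#'   labels.
#' @param min_n Minimum non-missing subjects required in each group.
#' @return Data.frame with columns \code{taxon_id}, \code{group1},
#'   \code{group2}, \code{n1}, \code{n2}, \code{median1}, \code{median2},
#'   \code{statistic}, \code{p}, \code{p_fdr}.
#' @export
compareIndexBetweenGroups <- function(idx, groups, min_n = 5) {
  groups <- groups[intersect(colnames(idx), names(groups))]
  lev <- sort(unique(as.character(groups[!is.na(groups)])))
  if (length(lev) != 2)
    stop("need exactly two groups, got: ", paste(lev, collapse = ", "))
  s1 <- names(groups)[groups == lev[1]]
  s2 <- names(groups)[groups == lev[2]]
  res <- data.frame(taxon_id = rownames(idx), group1 = lev[1], group2 = lev[2],
                    n1 = NA_integer_, n2 = NA_integer_,
                    median1 = NA_real_, median2 = NA_real_,
                    statistic = NA_real_, p = NA_real_, p_fdr = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(idx))) {
    v1 <- idx[i, s1]; v1 <- v1[!is.na(v1)]
    v2 <- idx[i, s2]; v2 <- v2[!is.na(v2)]
    res$n1[i] <- length(v1); res$n2[i] <- length(v2)
    if (length(v1) < min_n || length(v2) < min_n) next
    res$median1[i] <- stats::median(v1)
    res$median2[i] <- stats::median(v2)
    wt <- suppressWarnings(stats::wilcox.test(v1, v2))
    res$statistic[i] <- unname(wt$statistic)
    res$p[i] <- wt$p.value
  }
  tested <- !is.na(res$p)
  res$p_fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res
}

#' Overlap of called taxa between two call sets
#'
#' Partition counts of the taxa carrying a given call (default
#' \code{"enriched"}) in two [callEnrichment()] results over the same taxon
#' universe, e.g. axSpA vs HC.
#'
#' @param calls_a,calls_b Data.frames from [callEnrichment()] with identical
#'   taxon universes.
#' @param call Which call to intersect: \code{"enriched"} or
#'   \code{"depleted"}.
#' @return Named integer vector \code{c(n_only_a, n_only_b, n_shared)}.
#' @export
sharedTaxaOverlap <- function(calls_a, calls_b, call = c("enriched", "depleted")) {
  call <- match.arg(call)
  if (!setequal(calls_a$taxon_id, calls_b$taxon_id))
    stop("call sets come from different taxon universes")
  a <- calls_a$taxon_id[calls_a$call == call]
  b <- calls_b$taxon_id[calls_b$call == call]
  c(n_only_a = length(setdiff(a, b)),
    n_only_b = length(setdiff(b, a)),
    n_shared = length(intersect(a, b)))
}
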