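## Correlation of per-taxon statistics (IgA index or relative abundance)
## with BASDAI disease activity.

#' Spearman correlation of a per-taxon statistic with BASDAI
#'
#' For each taxon, Spearman's rho between the per-subject statistic (IgA
#' index or relative abundance) and the BASDAI score, subjects with missing
#' BASDAI excluded. p-values come from the exact permutation distribution
#' when n <= 9 and tie-free, otherwise from the t approximation with
#' midranks for ties ([stats::cor.test()]); BH correction is applied across
#' the taxa tested. Taxa with a constant statistic or constant BASDAI are
#' skipped (rho undefined).
#'
#' @param values Numeric matrix (taxa x subjects), e.g. from
#'   [igaIndexMatrix()]; NAs allowed.
#' @param basdai Named numeric vector of BASDAI scores per subject (NA =
#'   missing).
#' @param min_n Minimum complete pairs per taxon (default 5).
#' @return Data.frame with columns \code{taxon_id}, \code{n}, \code{rho},
#'   \code{p}, \code{p_fdr}; untestable taxa carry NAs.
#' @export
correlateWithBasdai <- function(values, basdai, min_n = 5) {
  subs <- intersect(colnames(values), names(basdai))
  if (!length(subs)) stop("no subjects shared between values and basdai")
  res <- data.frame(taxon_id = rownames(values), n = NA_integer_,
                    rho = NA_real_, p = NA_real_, p_fdr = NA_real_,
                    stringsAsFactors = FALSE)
  skipped <- character(0)
  for (i in seq_len(nrow(values))) {
    x <- values[i, subs]
    y <- basdai[subs]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    res$n[i] <- length(x)
    if (length(x) < min_n) next
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      skipped <- c(skipped, res$taxon_id[i])
      next
    }
    exact <- length(x) <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = exact))
    res$rho[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  if (length(skipped))
    message("correlateWithBasdai: skipped taxa with a constant statistic ",
            "or constant BASDAI: ", paste(skipped, collapse = ", "))
  tested <- !is.na(res$p)
  res$p_fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res
}
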