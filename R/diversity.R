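## Community-level comparisons: alpha diversity (Observed richness, Shannon,
## Inverse Simpson), unweighted UniFrac, PCoA, PERMANOVA.

#' Per-sample alpha diversity
#'
#' Observed = number of taxa with count > 0; Shannon = -sum p_i ln p_i
#' (natural log) over detected taxa; Inverse Simpson = 1 / sum p_i^2.
#' Proportions are computed without a pseudocount.
#'
#' @param counts Matrix (taxa x samples); no sample may be all-zero.
#' @param metrics Subset of \code{c("observed", "shannon", "invsimpson")}.
#' @return Long data.frame with columns \code{sample_id}, \code{metric},
#'   \code{value}.
#' @export
alphaDiversity <- function(counts, metrics = c("observed", "shannon", "invsimpson")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (any(colSums(counts) == 0))
    stop("empty sample(s): ", paste(colnames(counts)[colSums(counts) == 0],
                                    collapse = ", "))
  comm <- t(counts)
  vals <- list(
    observed = vegan::specnumber(comm),
    shannon = vegan::diversity(comm, index = "shannon"),
    invsimpson = vegan::diversity(comm, index = "invsimpson"))
  do.call(rbind, lapply(metrics, function(m)
    data.frame(sample_id = colnames(counts), metric = m,
               value = unname(vals[[m]]), stringsAsFactors = FALSE)))
}

#' Compare alpha diversity between two groups
#'
#' Two-sided Wilcoxon rank-sum test per metric (exact when both groups have
#' <= 10 tie-free observations, normal approximation with tie and continuity
#' correction otherwise, as implemented in [stats::wilcox.test()]), with
#' Benjamini-Hochberg correction across the metrics of the comparison family.
#'
#' @param alpha Long data.frame from [alphaDiversity()].
#' @param grouping Named vector (names = sample ids) with exactly two groups.
#' @return Data.frame with columns \code{metric}, \code{statistic}, \code{p},
#'   \code{p_fdr}.
#' @export
compareAlpha <- function(alpha, grouping) {
  grouping <- grouping[!is.na(grouping)]
  lev <- sort(unique(as.character(grouping)))
  if (length(lev) != 2) stop("grouping must contain exactly two groups")
  res <- do.call(rbind, lapply(unique(alpha$metric), function(m) {
    sub <- alpha[alpha$metric == m, , drop = FALSE]
    g <- grouping[sub$sample_id]
    x <- sub$value[!is.na(g) & g == lev[1]]
    y <- sub$value[!is.na(g) & g == lev[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("group with < 2 samples for metric ", m)
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(metric = m, statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Unweighted UniFrac distances
#'
#' Fraction of branch length leading exclusively to taxa present in only one
#' of two samples: sum(b_i XOR) / sum(b_i OR) over branches, presence derived
#' from counts > 0. Computed with \code{picante::unifrac} on the rooted tree.
#'
#' Taxa present in the table but absent from the tree are an error unless
#' \code{prune = TRUE} (silent pruning changes distances); tree tips absent
#' from the table are pruned, which leaves pairwise distances unchanged.
#'
#' @param counts Matrix (taxa x samples).
#' @param tree Rooted [ape::phylo] with branch lengths, e.g. from
#'   [readTree()].
#' @param prune Drop table taxa that are not tree leaves (with a warning)
#'   instead of failing.
#' @return Symmetric distance matrix (samples x samples), values in [0, 1].
#' @export
unweightedUnifrac <- function(counts, tree, prune = FALSE) {
  miss <- setdiff(rownames(counts), tree$tip.label)
  if (length(miss)) {
    if (!prune)
      stop("taxa absent from the tree (set prune = TRUE to drop them): ",
           paste(miss, collapse = ", "))
    warning("unweightedUnifrac: pruning ", length(miss),
            " taxa absent from the tree")
    counts <- counts[setdiff(rownames(counts), miss), , drop = FALSE]
  }
  if (length(setdiff(tree$tip.label, rownames(counts))))
    tree <- ape::keep.tip(tree, rownames(counts))
  pres <- t((counts > 0) * 1)
  d <- as.matrix(picante::unifrac(pres, tree))
  d[colnames(counts), colnames(counts)]
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition
#' ([stats::cmdscale()]); coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are reported,
#' not corrected.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to return (default: all positive ones).
#' @return List of class \code{iga_pcoa}: \code{points} (samples x axes, only
#'   positive-eigenvalue axes), \code{eigenvalues} (all, decreasing),
#'   \code{prop_explained} (share of the positive eigenvalue sum).
#' @export
pcoaOrdination <- function(dm, n_axes = NULL) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be zero")
  n <- nrow(dm)
  k <- min(if (is.null(n_axes)) n - 1 else n_axes, n - 1)
  ## cmdscale warns when fewer than k eigenvalues are positive; we report
  ## the eigenvalue spectrum ourselves, so that warning is redundant
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig[1], 0) * 1e-9)
  keep <- intersect(seq_len(ncol(fit$points)), pos)
  pts <- fit$points[, keep, drop = FALSE]
  rownames(pts) <- rownames(dm)
  if (ncol(pts)) colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  pe <- if (length(pos)) eig / sum(eig[pos]) else rep(0, length(eig))
  structure(list(points = pts, eigenvalues = eig, prop_explained = pe),
            class = "iga_pcoa")
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from the partition of squared distances between and within groups
#' (Anderson 2001), with a permutation p-value
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). Runs
#' [vegan::adonis2()] with free permutation of sample labels under the given
#' seed.
#'
#' @param dm Symmetric distance matrix.
#' @param grouping Named vector (names = sample ids of \code{dm}) with >= 2
#'   groups of >= 2 samples each.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed (required for reproducibility).
#' @return List with \code{pseudo_F}, \code{R2}, \code{p_value},
#'   \code{n_permutations}, \code{seed}.
#' @export
permanovaTest <- function(dm, grouping, n_perm = 999, seed) {
  dm <- as.matrix(dm)
  if (missing(seed)) stop("seed is required")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (all(dm == 0)) stop("degenerate distance matrix: all distances are zero")
  g <- factor(grouping[rownames(dm)])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  df <- data.frame(group = g)
  res <- .with_seed(seed,
    vegan::adonis2(stats::as.dist(dm) ~ group, data = df,
                   permutations = n_perm))
  list(pseudo_F = res$F[1], R2 = res$R2[1], p_value = res$`Pr(>F)`[1],
       n_permutations = n_perm, seed = seed)
}
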