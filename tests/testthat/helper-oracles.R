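# Independent oracles used across the suite. These deliberately use naive
# enumeration / first-principles definitions, not the package's code paths.

# Brute-force unweighted UniFrac: per branch, XOR/OR of presence of any
# descendant tip, weighted by branch length.
oracle_unifrac <- function(tree, pres1, pres2) {
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], desc_tips))
  }
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc_tips(tree$edge[e, 2])]
    a <- any(pres1[tips])
    b <- any(pres2[tips])
    if (xor(a, b)) num <- num + tree$edge.length[e]
    if (a || b) den <- den + tree$edge.length[e]
  }
  if (den == 0) 0 else num / den
}

# Benjamini-Hochberg step-up from the definition: the adjusted value of p_i
# is min over all p_j >= p_i of n * p_j / #{k : p_k <= p_j}, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(pj) n * pj / sum(p <= pj), numeric(1))))
  }, numeric(1))
}

# Random tree with uniform branch lengths and taxon_* style labels.
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(n) runif(n, 0.1, 2))
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

# Minimal paired-fraction object from two matrices.
make_paired <- function(pos, neg, group = NULL, basdai = NA, sex = NULL) {
  n <- ncol(pos)
  if (is.null(rownames(pos))) {
    rownames(pos) <- rownames(neg) <- sprintf("t%02d", seq_len(nrow(pos)))
  }
  if (is.null(colnames(pos))) {
    colnames(pos) <- colnames(neg) <- sprintf("s%02d", seq_len(n))
  }
  if (is.null(group)) group <- rep(c("axSpA", "HC"), length.out = n)
  cd <- S4Vectors::DataFrame(subject_id = colnames(pos), group = group,
                             site = "fecal", basdai = rep_len(basdai, n))
  if (!is.null(sex)) cd$sex <- rep_len(sex, n)
  PairedFractions(pos, neg, cd)
}

# Random integer count matrix.
random_counts <- function(n_taxa, n_samples, seed, lambda = 20) {
  set.seed(seed)
  matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
         dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                         sprintf("s%02d", seq_len(n_samples))))
}
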