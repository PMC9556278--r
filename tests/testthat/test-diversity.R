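test_that("alpha diversity matches closed forms", {
  # uniform 4-taxon sample
  m <- matrix(c(5, 5, 5, 5), 4, dimnames = list(letters[1:4], "s1"))
  a <- alphaDiversity(m)
  val <- setNames(a$value, a$metric)
  expect_equal(unname(val["observed"]), 4)
  expect_equal(unname(val["shannon"]), log(4))
  expect_equal(unname(val["invsimpson"]), 4)

  # single-taxon sample
  m1 <- matrix(c(7, 0), 2, dimnames = list(c("a", "b"), "s1"))
  a1 <- alphaDiversity(m1)
  expect_equal(setNames(a1$value, a1$metric),
               c(observed = 1, shannon = 0, invsimpson = 1))

  # proportions (0.5, 0.25, 0.25) -> inverse Simpson 8/3
  m2 <- matrix(c(2, 1, 1), 3, dimnames = list(letters[1:3], "s1"))
  a2 <- alphaDiversity(m2, "invsimpson")
  expect_equal(a2$value, 8 / 3)

  expect_error(alphaDiversity(matrix(0, 2, 1,
                                     dimnames = list(c("a", "b"), "s1"))),
               "empty")
})

test_that("Shannon is maximized by the uniform profile at fixed richness", {
  set.seed(31)
  S <- 6
  unif <- matrix(rep(10, S), S, dimnames = list(paste0("t", 1:S), "u"))
  h_unif <- alphaDiversity(unif, "shannon")$value
  for (r in 1:25) {
    x <- matrix(rmultinom(1, 300, runif(S) + 0.05) + 1, S,
                dimnames = list(paste0("t", 1:S), "x"))
    expect_lte(alphaDiversity(x, "shannon")$value, h_unif + 1e-12)
  }
})

test_that("group comparison of alpha diversity uses exact rank-sum and BH", {
  a <- data.frame(sample_id = paste0("s", 1:10),
                  metric = "shannon",
                  value = c(1:5, 6:10))
  grouping <- setNames(rep(c("HC", "axSpA"), each = 5), paste0("s", 1:10))
  res <- compareAlpha(a, grouping)
  expect_equal(res$p, 2 / 252)  # complete separation, exact two-sided

  # identical groups: maximal p
  a$value <- rep(1:5, 2)
  expect_equal(compareAlpha(a, grouping)$p, 1)

  # BH across the metric family equals the step-up definition
  p <- c(0.01, 0.02, 0.03)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.03, 3))
  expect_equal(oracle_bh(p), rep(0.03, 3))
})

test_that("unweighted UniFrac hits closed-form cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  counts <- matrix(c(1, 1, 0, 0,
                     1, 1, 0, 0,
                     1, 0, 1, 0), 4, 3,
                   dimnames = list(c("A", "B", "C", "D"), c("s1", "s2", "s3")))
  d <- unweightedUnifrac(counts, tr)
  expect_equal(d["s1", "s2"], 0)            # identical presence profiles
  expect_equal(d["s1", "s3"], 0.6)          # shared: A + its cherry stem
  # star tree, disjoint sets -> 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  star <- suppressWarnings(phangorn::midpoint(star))
  cs <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("x", "y")))
  expect_equal(unweightedUnifrac(cs, star)["x", "y"], 1)
})

test_that("UniFrac equals the brute-force branch oracle and is a metric", {
  for (r in 1:20) {
    tr <- random_tree(8, seed = 400 + r)
    set.seed(500 + r)
    pres <- matrix(rbinom(8 * 3, 1, 0.5), 8, 3,
                   dimnames = list(tr$tip.label, c("s1", "s2", "s3")))
    pres[cbind(sample(8, 3), 1:3)] <- 1  # no empty sample
    d <- unweightedUnifrac(pres, tr)
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(d[i, j],
                   oracle_unifrac(tr, pres[, i] > 0, pres[, j] > 0),
                   tolerance = 1e-12)
    }
    # metric properties
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
  }
})

test_that("UniFrac enforces the tree/table taxon contract", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  counts <- matrix(1, 5, 2, dimnames = list(c("A", "B", "C", "D", "E"),
                                            c("s1", "s2")))
  expect_error(unweightedUnifrac(counts, tr), "E")
  expect_warning(d <- unweightedUnifrac(counts, tr, prune = TRUE), "pruning")
  expect_equal(dim(d), c(2L, 2L))
})

test_that("PCoA reconstructs Euclidean distances and handles degenerate input", {
  set.seed(77)
  X <- matrix(rnorm(8 * 3), 8)
  D <- as.matrix(dist(X))
  ord <- pcoaOrdination(D)
  expect_lt(max(abs(as.matrix(dist(ord$points)) - D)), 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))  # decreasing
  expect_equal(sum(ord$prop_explained[ord$eigenvalues > 0]), 1)

  z <- matrix(0, 4, 4)
  ordz <- pcoaOrdination(z)
  expect_equal(ncol(ordz$points), 0)
  expect_true(all(abs(ordz$eigenvalues) < 1e-12))

  bad <- D
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoaOrdination(bad), "symmetric")
})

test_that("PERMANOVA separates clusters, is seed-stable and relabel-invariant", {
  set.seed(12)
  X <- rbind(matrix(rnorm(5 * 2, 0), 5), matrix(rnorm(5 * 2, 8), 5))
  rownames(X) <- paste0("s", 1:10)
  D <- as.matrix(dist(X))
  g <- setNames(rep(c("a", "b"), each = 5), rownames(X))
  res <- permanovaTest(D, g, n_perm = 999, seed = 4)
  expect_lt(res$p_value, 0.02)  # near the minimal attainable p
  expect_gt(res$R2, 0.9)
  expect_equal(res, permanovaTest(D, g, n_perm = 999, seed = 4))

  # jointly permuting sample order and labels leaves F unchanged
  perm <- sample(10)
  res2 <- permanovaTest(D[perm, perm], g, n_perm = 999, seed = 4)
  expect_equal(res2$pseudo_F, res$pseudo_F)

  expect_error(permanovaTest(matrix(0, 4, 4,
                                    dimnames = list(paste0("s", 1:4),
                                                    paste0("s", 1:4))),
                             setNames(rep(c("a", "b"), 2), paste0("s", 1:4)),
                             seed = 1),
               "degenerate")
})
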