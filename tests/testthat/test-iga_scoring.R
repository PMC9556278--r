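test_that("the IgA index obeys its analytic identities", {
  # hand evaluation: -(ln .1 - ln .01)/(ln .1 + ln .01) = 1/3 exactly
  expect_equal(igaIndex(0.1, 0.01), 1 / 3)
  expect_equal(igaIndex(0.3, 0.3), 0)
  # antisymmetry
  expect_equal(igaIndex(0.2, 0.07), -igaIndex(0.07, 0.2))
  # bounded on a grid over (0,1)^2
  g <- seq(0.005, 0.995, length.out = 80)
  grid <- expand.grid(a = g, b = g)
  v <- igaIndex(grid$a, grid$b)
  expect_true(all(abs(v) <= 1))
  # log-base invariance: same formula in base 2 and 10
  for (base in c(2, 10)) {
    vb <- -(log(grid$a, base) - log(grid$b, base)) /
      (log(grid$a, base) + log(grid$b, base))
    expect_equal(vb, v)
  }
  expect_error(igaIndex(0, 0.5), "pseudocount")
  expect_error(igaIndex(0.5, 1), "pseudocount")
})

test_that("the index matrix vectorizes the scalar formula with NA for double absence", {
  pos <- random_counts(10, 6, seed = 13, lambda = 3)
  neg <- random_counts(10, 6, seed = 14, lambda = 3)
  pf <- make_paired(pos, neg)
  idx <- igaIndexMatrix(pf, pseudocount = 1)
  pp <- relativeAbundance(pos, 1)
  pn <- relativeAbundance(neg, 1)
  for (i in seq_len(10)) for (j in seq_len(6)) {
    expected <- if (pos[i, j] == 0 && neg[i, j] == 0) NA_real_
                else igaIndex(pp[i, j], pn[i, j])
    expect_equal(idx[i, j], expected)
  }
  # antisymmetric under fraction swap
  swapped <- igaIndexMatrix(make_paired(neg, pos), 1)
  expect_equal(swapped, -idx)
  # identical fractions at equal depths -> all zero (where defined)
  same <- igaIndexMatrix(make_paired(pos, pos), 1)
  expect_true(all(same[!is.na(same)] == 0))
})

test_that("enrichment calls use the exact signed-rank test and median sign", {
  # 8 subjects, all positive: exact two-sided p = 2/256
  idx <- matrix(seq(0.35, 0.45, length.out = 8), 1,
                dimnames = list("tA", paste0("s", 1:8)))
  groups <- setNames(rep("axSpA", 8), paste0("s", 1:8))
  res <- callEnrichment(idx, groups, "axSpA")
  expect_equal(res$p, 2 / 256)
  expect_identical(res$call, "enriched")

  # values symmetric around zero -> ns
  idx2 <- matrix(c(-4:-1, 1:4) / 10, 1, dimnames = list("tA", paste0("s", 1:8)))
  expect_identical(callEnrichment(idx2, groups, "axSpA")$call, "ns")

  # under min_n the taxon is untested, not ns
  idx3 <- matrix(c(0.4, 0.4, 0.4, NA, NA, NA, NA, NA), 1,
                 dimnames = list("tA", paste0("s", 1:8)))
  res3 <- suppressMessages(callEnrichment(idx3, groups, "axSpA"))
  expect_identical(res3$call, "untested")
  expect_true(is.na(res3$p))
})

test_that("planted coating effects are recovered within the affected group", {
  beta <- rep(0, 30)
  beta[c(3, 11, 19)] <- 1.5
  cfg <- simulationConfig(n_per_group = 20, n_taxa = 30, depth_mean = 30000,
                          beta = beta, seed = 71)
  co <- simulateCohort(cfg)
  pf <- suppressMessages(filterByDepth(pairFractions(co$counts, co$manifest)))
  idx <- igaIndexMatrix(pf)
  groups <- setNames(subjectData(pf)$group, colnames(pf))
  calls <- suppressMessages(callEnrichment(idx, groups, "axSpA"))
  planted <- sprintf("taxon_%03d", c(3, 11, 19))
  expect_true(all(calls$call[match(planted, calls$taxon_id)] == "enriched"))
  # no spurious *enriched* call (closure pushes null taxa the other way)
  expect_lte(sum(calls$call == "enriched" & !calls$taxon_id %in% planted), 1)
})

test_that("between-group comparison is label-symmetric and finds group effects", {
  set.seed(55)
  idx <- matrix(rnorm(5 * 12, 0, 0.1), 5, 12,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:12)))
  groups <- setNames(rep(c("axSpA", "HC"), each = 6), paste0("s", 1:12))
  idx[2, groups == "axSpA"] <- idx[2, groups == "axSpA"] + 1
  res <- compareIndexBetweenGroups(idx, groups)
  expect_equal(res$p[2], min(res$p))
  expect_lt(res$p_fdr[2], 0.05)

  # swapping group labels leaves two-sided p unchanged
  flipped <- setNames(ifelse(groups == "axSpA", "HC", "axSpA"), names(groups))
  expect_equal(compareIndexBetweenGroups(idx, flipped)$p, res$p)

  # identical distributions: p near 1
  same <- matrix(rep(c(1:6 / 10, 1:6 / 10), each = 1), 1, 12, byrow = TRUE,
                 dimnames = list("t1", paste0("s", 1:12)))
  expect_gte(compareIndexBetweenGroups(same, groups)$p, 0.9)

  expect_error(compareIndexBetweenGroups(idx, setNames(rep("axSpA", 12),
                                                       paste0("s", 1:12))),
               "two groups")
})

test_that("overlap counts match brute-force set arithmetic", {
  mk <- function(taxa, enriched) data.frame(
    taxon_id = taxa, call = ifelse(taxa %in% enriched, "enriched", "ns"))
  u <- paste0("t", 1:10)
  a <- mk(u, c("t1", "t2", "t3"))
  b <- mk(u, "t2")
  expect_equal(sharedTaxaOverlap(a, b),
               c(n_only_a = 2, n_only_b = 0, n_shared = 1))
  expect_equal(sharedTaxaOverlap(mk(u, c("t1", "t2")), mk(u, c("t3", "t4")))[["n_shared"]], 0)
  expect_error(sharedTaxaOverlap(a, mk(paste0("x", 1:10), "x1")), "universe")

  set.seed(9)
  for (r in 1:10) {
    ea <- sample(u, sample(0:10, 1))
    eb <- sample(u, sample(0:10, 1))
    got <- sharedTaxaOverlap(mk(u, ea), mk(u, eb))
    expect_equal(unname(got), c(length(setdiff(ea, eb)),
                                length(setdiff(eb, ea)),
                                length(intersect(ea, eb))))
  }
})
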