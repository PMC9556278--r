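test_that("class-level Kruskal-Wallis screens features and matches rank-sum", {
  set.seed(26)
  X <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:12)))
  lab <- factor(rep(c("a", "b"), each = 6))
  X[1, lab == "a"] <- X[1, lab == "a"] + 10  # fully separated
  res <- classTest(X, lab)
  expect_lt(res$kw_p[1], 0.05)
  expect_true(res$keep[1])

  # identical class distributions -> high p, eliminated
  Xc <- matrix(rep(1:6 / 10, 2), 1, 12,
               dimnames = list("f1", paste0("s", 1:12)))
  resc <- classTest(Xc, lab)
  expect_gt(resc$kw_p, 0.9)
  expect_false(resc$keep)

  # with 2 tie-free classes KW equals the two-sided normal-approximation
  # rank-sum test without continuity correction
  for (r in 1:10) {
    x <- rnorm(12)
    p_kw <- kruskal.test(x, lab)$p.value
    p_w <- wilcox.test(x[lab == "a"], x[lab == "b"], exact = FALSE,
                       correct = FALSE)$p.value
    expect_equal(p_kw, p_w, tolerance = 1e-10)
  }

  expect_error(classTest(X, factor(c("a", rep("b", 11)))), ">= 2 samples")
})

test_that("subclass consistency rejects sex-reversed effects", {
  set.seed(27)
  n <- 10  # per class, 5 male / 5 female
  lab <- factor(rep(c("a", "b"), each = n))
  sex <- rep(rep(c("m", "f"), each = 5), 2)
  X <- matrix(rnorm(2 * 2 * n, 10, 0.3), 2, 2 * n,
              dimnames = list(c("consistent", "reversed"),
                              paste0("s", 1:(2 * n))))
  # consistent: up in class a for both sexes
  X["consistent", lab == "a"] <- X["consistent", lab == "a"] + 5
  # reversed: up in class-a males, down in class-a females
  X["reversed", lab == "a" & sex == "m"] <-
    X["reversed", lab == "a" & sex == "m"] + 5
  X["reversed", lab == "a" & sex == "f"] <-
    X["reversed", lab == "a" & sex == "f"] - 5
  pass <- subclassTest(X, lab, sex)
  expect_true(pass[["consistent"]])
  expect_false(pass[["reversed"]])

  # no subclass labels: trivially passes with a warning
  expect_warning(pass2 <- subclassTest(X, lab, NULL), "passes all")
  expect_true(all(pass2))
  expect_warning(pass3 <- subclassTest(X, lab, rep("m", 2 * n)), "passes all")
  expect_true(all(pass3))
})

test_that("LDA effect size ranks a strong feature first and is deterministic", {
  set.seed(28)
  lab <- factor(rep(c("a", "b"), each = 10))
  X <- matrix(rlnorm(20 * 20, log(50), 0.2), 20, 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:20)))
  X[4, lab == "a"] <- X[4, lab == "a"] * 100  # 100-fold class difference
  res <- ldaEffectSize(X, lab, seed = 5)
  expect_identical(res$feature_id[which.max(abs(res$lda_score))], "f4")
  expect_gte(abs(res$lda_score[4]), 2)
  expect_identical(res$enriched_class[4], "a")
  expect_identical(res, ldaEffectSize(X, lab, seed = 5))

  # sign always matches the raw class-mean difference (on the 1e6 scale)
  Xs <- sweep(X, 2, colSums(X), "/") * 1e6
  d <- rowMeans(Xs[, lab == "a"]) - rowMeans(Xs[, lab == "b"])
  expect_true(all(sign(res$lda_score) == sign(d)))
})

test_that("the discriminant direction agrees with classical LDA when well-posed", {
  skip_if_not_installed("MASS")
  set.seed(29)
  lab <- factor(rep(c("a", "b"), each = 30))
  X <- matrix(rnorm(4 * 60), 4, 60)
  X[1, lab == "a"] <- X[1, lab == "a"] + 2
  w_pkg <- igaseqr:::.lda_direction(X, lab)$w
  w_mass <- as.numeric(MASS::lda(t(X), lab)$scaling)
  w_mass <- w_mass / sqrt(sum(w_mass^2))
  # same axis up to sign
  expect_gt(abs(sum(w_pkg * w_mass)), 0.999)
})

test_that("the cascade recovers planted features and orders by effect size", {
  ft <- simulateFeatureTable(planted = 5:7, seed = 3)
  res <- runCascade(ft$features, ft$labels, ft$subclass, seed = 3)
  sig <- res$feature_id[res$significant]
  expect_true(all(c("feat_005", "feat_006", "feat_007") %in% sig))
  expect_lte(length(setdiff(sig, c("feat_005", "feat_006", "feat_007"))), 1)
  # ranking order: decreasing |lda_score|, NAs last
  sc <- abs(res$lda_score)
  expect_true(all(diff(sc[!is.na(sc)]) <= 1e-12))
  expect_true(all(is.na(res$lda_score[res$kw_p >= 0.05])))

  # empty survivor set is a clean empty result
  set.seed(30)
  Xn <- matrix(rep(rlnorm(10, log(100), 1), 12) *
                 rlnorm(120, 0, 0.01), 10, 12,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:12)))
  lab <- factor(rep(c("a", "b"), each = 6))
  resn <- suppressWarnings(runCascade(Xn, lab, alpha_class = 1e-6))
  expect_false(any(resn$significant))
  expect_true(all(is.na(resn$lda_score)))
})

test_that("shrinking alpha_class never enlarges the significant set", {
  ft <- simulateFeatureTable(planted = c(4, 9), seed = 12)
  sets <- lapply(c(0.1, 0.05, 0.01), function(a)
    with(runCascade(ft$features, ft$labels, ft$subclass,
                    alpha_class = a, seed = 2),
         feature_id[significant]))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("overlap of significant features matches set arithmetic", {
  mk <- function(sig) data.frame(feature_id = paste0("f", 1:8),
                                 significant = paste0("f", 1:8) %in% sig)
  expect_equal(overlapSignificant(mk(c("f1", "f2")), mk(c("f2", "f3", "f4"))),
               c(n_only_a = 1, n_only_b = 2, n_shared = 1))
  expect_equal(unname(overlapSignificant(mk("f1"), mk("f1"))), c(0, 0, 1))
  expect_error(overlapSignificant(
    mk("f1"), data.frame(feature_id = paste0("g", 1:8), significant = FALSE)),
    "universe")
})
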