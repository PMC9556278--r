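## Three-step biomarker cascade (LEfSe-style): class-level Kruskal-Wallis,
## subclass-level Wilcoxon consistency, and an LDA effect size with
## ridge-regularized within-class scatter. Applies to any feature x sample
## abundance table (taxa, KO, MetaCyc pathways).

#' Class-level Kruskal-Wallis screen
#'
#' Kruskal-Wallis rank-sum test of each feature across the classes; features
#' with p >= \code{alpha_class} are eliminated from the rest of the cascade.
#'
#' @param features Numeric matrix (features x samples).
#' @param labels Factor (or coercible) of class labels, >= 2 classes with
#'   >= 2 samples each.
#' @param alpha_class Elimination threshold (default 0.05).
#' @return Data.frame with columns \code{feature_id}, \code{kw_p},
#'   \code{keep}.
#' @export
classTest <- function(features, labels, alpha_class = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  kw <- apply(features, 1, function(x) stats::kruskal.test(x, labels)$p.value)
  data.frame(feature_id = rownames(features), kw_p = unname(kw),
             keep = unname(kw) < alpha_class, stringsAsFactors = FALSE)
}

#' Subclass-level Wilcoxon consistency check
#'
#' For each feature, the class-level difference must replicate within every
#' comparable subclass stratum (e.g. within males and within females): a
#' two-sided rank-sum test between the two classes restricted to the stratum
#' must meet \code{alpha_sub} and agree in direction (sign of the median
#' difference) with the class-level difference. Strata with fewer than 2
#' samples on either side are skipped; with no subclass labels (or a single
#' level) the step passes trivially with a warning.
#'
#' @param features Numeric matrix (features x samples).
#' @param labels Two-class factor.
#' @param subclass Vector of subclass labels per sample, or NULL.
#' @param alpha_sub Per-stratum threshold (default 0.05).
#' @return Logical vector per feature (TRUE = passes).
#' @export
subclassTest <- function(features, labels, subclass = NULL, alpha_sub = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("subclass step expects exactly 2 classes")
  pass <- rep(TRUE, nrow(features))
  names(pass) <- rownames(features)
  if (is.null(subclass) || length(unique(subclass)) < 2) {
    warning("no (or constant) subclass labels: subclass step passes all features")
    return(pass)
  }
  lv <- levels(labels)
  strata <- intersect(unique(subclass[labels == lv[1]]),
                      unique(subclass[labels == lv[2]]))
  for (i in seq_len(nrow(features))) {
    x <- features[i, ]
    dir_class <- sign(stats::median(x[labels == lv[1]]) -
                        stats::median(x[labels == lv[2]]))
    n_used <- 0L
    for (s in strata) {
      x1 <- x[labels == lv[1] & subclass == s]
      x2 <- x[labels == lv[2] & subclass == s]
      if (length(x1) < 2 || length(x2) < 2) next
      n_used <- n_used + 1L
      p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
      d <- sign(stats::median(x1) - stats::median(x2))
      if (!(p < alpha_sub && d == dir_class)) {
        pass[i] <- FALSE
        break
      }
    }
  }
  pass
}

## discriminant direction with ridge-regularized pooled within-class scatter;
## lambda = 1e-6 * trace(Sw)/p survives p >> n feature tables (KO matrices)
.lda_direction <- function(X, labels, ridge = 1e-6) {
  lv <- levels(labels)
  m1 <- rowMeans(X[, labels == lv[1], drop = FALSE])
  m2 <- rowMeans(X[, labels == lv[2], drop = FALSE])
  Xc <- X
  Xc[, labels == lv[1]] <- X[, labels == lv[1]] - m1
  Xc[, labels == lv[2]] <- X[, labels == lv[2]] - m2
  Sw <- tcrossprod(Xc) / max(1, ncol(X) - 2)
  p <- nrow(X)
  lam <- ridge * sum(diag(Sw)) / p
  if (lam <= 0) lam <- ridge
  w <- tryCatch(solve(Sw + diag(lam, p), m1 - m2),
                error = function(e) solve(Sw + diag(lam * 1e6, p), m1 - m2))
  nw <- sqrt(sum(w^2))
  if (nw > 0) w <- w / nw
  list(w = w, m1 = m1, m2 = m2)
}

#' LDA effect size of class-discriminating features
#'
#' Features are scaled to a per-sample sum of 1e6 (as in LEfSe). Over
#' \code{n_boot} subsamples of fraction \code{subsample_frac} per class, a
#' two-class linear discriminant is fit with ridge-regularized within-class
#' scatter; per feature and bootstrap the effect is
#' log10(1 + |Delta|), where Delta averages the feature's share of the
#' class-mean separation along the discriminant axis and the raw class-mean
#' difference. Scores are the bootstrap mean, signed by the enriched class
#' (positive = higher in the first class level). Deterministic given
#' \code{seed}.
#'
#' @param features Numeric matrix (features x samples).
#' @param labels Two-class factor.
#' @param n_boot Bootstrap subsamples (default 30).
#' @param subsample_frac Fraction of each class per subsample (default 2/3).
#' @param seed Integer seed.
#' @param scale Scale samples to a sum of 1e6 before fitting (default TRUE).
#'   Set FALSE when the table was already normalized over the full feature
#'   universe, e.g. when scoring a survivor subset inside [runCascade()].
#' @return Data.frame with columns \code{feature_id}, \code{lda_score}
#'   (log10 scale, signed), \code{enriched_class}.
#' @export
ldaEffectSize <- function(features, labels, n_boot = 30,
                          subsample_frac = 2/3, seed = 1, scale = TRUE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("LDA effect size expects exactly 2 classes")
  X <- if (scale) sweep(features, 2, colSums(features), "/") * 1e6 else features
  lv <- levels(labels)
  p <- nrow(X)
  .with_seed(seed, {
    acc <- matrix(0, p, n_boot)
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(lv, function(l) {
        ii <- which(labels == l)
        sample(ii, max(2, floor(length(ii) * subsample_frac)))
      }))
      fit <- .lda_direction(X[, take, drop = FALSE], droplevels(labels[take]))
      dproj <- sum(fit$w * (fit$m1 - fit$m2))
      delta <- (fit$w * dproj + (fit$m1 - fit$m2)) / 2
      acc[, b] <- log10(1 + abs(delta))
    }
    m1 <- rowMeans(X[, labels == lv[1], drop = FALSE])
    m2 <- rowMeans(X[, labels == lv[2], drop = FALSE])
    score <- rowMeans(acc) * ifelse(m1 >= m2, 1, -1)
    data.frame(feature_id = rownames(features), lda_score = score,
               enriched_class = ifelse(m1 >= m2, lv[1], lv[2]),
               stringsAsFactors = FALSE)
  })
}

#' Run the three-step discriminant cascade
#'
#' Composition of [classTest()], [subclassTest()] and [ldaEffectSize()]: a
#' feature is significant iff its Kruskal-Wallis p < \code{alpha_class}, it
#' passes the subclass consistency check, and |LDA score| >=
#' \code{lda_threshold}. The LDA is fit on the class-test survivors only;
#' eliminated features carry \code{NA} scores. The result is ordered by
#' decreasing |LDA score| (the ranking order).
#'
#' @inheritParams ldaEffectSize
#' @param subclass Optional subclass labels (see [subclassTest()]).
#' @param alpha_class,alpha_sub,lda_threshold Cascade thresholds; LEfSe
#'   defaults 0.05 / 0.05 / 2.0. The relaxed exploratory preset uses
#'   \code{alpha_class = 0.1}.
#' @return Data.frame with columns \code{feature_id}, \code{kw_p},
#'   \code{subclass_pass}, \code{lda_score}, \code{enriched_class},
#'   \code{significant}.
#' @export
runCascade <- function(features, labels, subclass = NULL,
                       alpha_class = 0.05, alpha_sub = 0.05,
                       lda_threshold = 2, n_boot = 30,
                       subsample_frac = 2/3, seed = 1) {
  ## rank tests see the features as supplied; the 1e6 per-sample scaling is
  ## part of the LDA stage and uses the full feature universe as its basis
  ## (normalizing within a survivor subset would distort effect directions)
  scaled <- sweep(features, 2, colSums(features), "/") * 1e6
  ct <- classTest(features, labels, alpha_class)
  res <- data.frame(feature_id = ct$feature_id, kw_p = ct$kw_p,
                    subclass_pass = NA, lda_score = NA_real_,
                    enriched_class = NA_character_, significant = FALSE,
                    stringsAsFactors = FALSE)
  surv <- which(ct$keep)
  if (length(surv)) {
    sp <- subclassTest(features[surv, , drop = FALSE], labels, subclass,
                       alpha_sub)
    res$subclass_pass[surv] <- sp
    surv2 <- surv[sp]
    if (length(surv2)) {
      ld <- ldaEffectSize(scaled[surv2, , drop = FALSE], labels,
                          n_boot, subsample_frac, seed, scale = FALSE)
      res$lda_score[surv2] <- ld$lda_score
      res$enriched_class[surv2] <- ld$enriched_class
      res$significant[surv2] <- abs(ld$lda_score) >= lda_threshold
    }
  }
  res[order(-abs(res$lda_score), res$feature_id, na.last = TRUE), ]
}

#' Overlap of significant features between two cascade results
#'
#' Partition counts of the significant feature sets of two [runCascade()]
#' results over the same feature universe (e.g. the IgA+ and IgA- fraction
#' analyses).
#'
#' @param results_a,results_b Data.frames from [runCascade()].
#' @return Named integer vector \code{c(n_only_a, n_only_b, n_shared)}.
#' @export
overlapSignificant <- function(results_a, results_b) {
  if (!setequal(results_a$feature_id, results_b$feature_id))
    stop("results come from different feature universes")
  a <- results_a$feature_id[results_a$significant]
  b <- results_b$feature_id[results_b$significant]
  c(n_only_a = length(setdiff(a, b)),
    n_only_b = length(setdiff(b, a)),
    n_shared = length(intersect(a, b)))
}
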