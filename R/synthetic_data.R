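## Generative model for paired IgA+/IgA- cohorts. Per subject s:
##   pi_s ~ Dirichlet(alpha_base)                       (community composition)
##   theta_{s,t} = logistic(mu_t + beta_t * 1[axSpA] + eps_{s,t}),
##                 eps ~ N(0, sigma_subject^2)          (coating probability)
##   IgA+ composition ~ pi_s * theta_s (renormalized), IgA- ~ pi_s * (1-theta_s)
##   counts ~ Multinomial(depth), depth ~ NB(depth_mean, dispersion)
##   BASDAI_s = clip(b0 + b1 * logit(theta_{s, basdai_taxon}) + N(0, sigma_b), 0, 10)
## The sort is modelled compositionally (16S observes composition, not load).

.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
  set.seed(seed)
  force(code)
}

#' Configuration for the paired-fraction cohort simulator
#'
#' Defaults describe a small single-site IgA-SEQ cohort: 15 subjects per
#' group, 50 taxa with a heavy-tailed Dirichlet community, sequencing depth
#' negative-binomial around 30,000 reads, a baseline IgA-coating probability
#' of 0.1 (roughly the 5-10\% coated fraction reported for gut communities),
#' and subject-level coating noise of 0.5 logits.
#'
#' @param n_per_group Subjects per group (axSpA, HC); >= 2.
#' @param n_taxa Number of taxa.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model per
#'   fraction sample (mean reads; dispersion as in \code{size = 1/dispersion}).
#' @param alpha_base Strictly positive Dirichlet concentration vector of
#'   length \code{n_taxa}; default a geometric series from 10 to 0.1 (uneven,
#'   long-tailed community).
#' @param mu Baseline coating logit per taxon (scalar recycled).
#' @param beta Group (axSpA) effect on the coating logit per taxon (scalar
#'   recycled); 0 for null taxa.
#' @param sigma_subject SD of subject-level coating noise, logits.
#' @param basdai_taxon Index of the taxon whose coating drives BASDAI, or
#'   \code{NA} for no coupling (BASDAI is then taxon-independent noise around
#'   group-typical scores, 3.5 for axSpA and 0.8 for HC).
#' @param b0,b1,sigma_b BASDAI linear model: intercept, slope on the coating
#'   logit, residual SD. Scores are clipped to [0, 10]. The default intercept
#'   6.8 places the mean score at ~3.5 (a typical active-disease cohort mean)
#'   under the default coating baseline, keeping floor-clipping rare.
#' @param carry_over Fraction of each sorted aliquot contaminated by the
#'   other fraction (sort impurity); default 0.
#' @param site Site label written into the manifest.
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return A validated config (list of class \code{iga_sim_config}).
#' @export
simulationConfig <- function(n_per_group = 15, n_taxa = 50,
                             depth_mean = 30000, depth_dispersion = 0.3,
                             alpha_base = NULL,
                             mu = stats::qlogis(0.1), beta = 0,
                             sigma_subject = 0.5,
                             basdai_taxon = NA, b0 = 6.8, b1 = 1.5, sigma_b = 1,
                             carry_over = 0, site = "fecal", seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (is.null(alpha_base))
    alpha_base <- exp(seq(log(10), log(0.1), length.out = n_taxa))
  if (length(alpha_base) != n_taxa)
    stop("alpha_base must have length n_taxa")
  if (any(alpha_base <= 0))
    stop("degenerate config: alpha_base must be strictly positive")
  mu <- rep_len(mu, n_taxa)
  beta <- rep_len(beta, n_taxa)
  if (sigma_subject < 0 || sigma_b < 0) stop("standard deviations must be >= 0")
  if (carry_over < 0 || carry_over >= 0.5)
    stop("carry_over must lie in [0, 0.5)")
  if (!is.na(basdai_taxon) &&
      (basdai_taxon < 1 || basdai_taxon > n_taxa))
    stop("basdai_taxon out of range")
  structure(list(n_per_group = n_per_group, n_taxa = n_taxa,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 alpha_base = alpha_base, mu = mu, beta = beta,
                 sigma_subject = sigma_subject, basdai_taxon = basdai_taxon,
                 b0 = b0, b1 = b1, sigma_b = sigma_b,
                 carry_over = carry_over, site = site, seed = as.integer(seed)),
            class = "iga_sim_config")
}

#' Simulate a paired IgA+/IgA- cohort
#'
#' Draws a synthetic two-group cohort under the generative model described in
#' [simulationConfig()] and returns the raw observables (count table and
#' manifest) together with the latent ground truth used to generate them.
#'
#' @param config From [simulationConfig()].
#' @return A list with elements \code{counts} (integer matrix, taxa x
#'   samples; two fraction samples per subject), \code{manifest} (data.frame
#'   in [readManifest()] layout, including alternating \code{sex} labels),
#'   and \code{truth} (class \code{iga_truth}: latent compositions \code{pi},
#'   coating probabilities \code{theta}, per-taxon \code{beta} and enrichment
#'   \code{direction}, the BASDAI coupling, and the config echo).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "iga_sim_config"))
  .with_seed(config$seed, {
    n <- 2L * config$n_per_group
    nt <- config$n_taxa
    group <- rep(c("axSpA", "HC"), each = config$n_per_group)
    subj <- sprintf("%s%02d", ifelse(group == "axSpA", "A", "H"),
                    c(seq_len(config$n_per_group), seq_len(config$n_per_group)))
    sex <- rep_len(c("F", "M"), n)
    taxa <- sprintf("taxon_%03d", seq_len(nt))
    pi_m <- theta <- matrix(NA_real_, nt, n, dimnames = list(taxa, subj))
    pos <- neg <- matrix(0L, nt, n, dimnames = list(taxa, subj))
    co <- config$carry_over
    for (s in seq_len(n)) {
      g <- as.numeric(group[s] == "axSpA")
      pi_s <- stats::rgamma(nt, shape = config$alpha_base)
      pi_s <- pi_s / sum(pi_s)
      th <- stats::plogis(config$mu + config$beta * g +
                            stats::rnorm(nt, 0, config$sigma_subject))
      pi_m[, s] <- pi_s
      theta[, s] <- th
      w_pos <- pi_s * (th * (1 - co) + (1 - th) * co)
      w_neg <- pi_s * ((1 - th) * (1 - co) + th * co)
      d_pos <- max(1, stats::rnbinom(1, mu = config$depth_mean,
                                     size = 1 / config$depth_dispersion))
      d_neg <- max(1, stats::rnbinom(1, mu = config$depth_mean,
                                     size = 1 / config$depth_dispersion))
      pos[, s] <- stats::rmultinom(1, d_pos, w_pos)
      neg[, s] <- stats::rmultinom(1, d_neg, w_neg)
    }
    if (is.na(config$basdai_taxon)) {
      ## no coupling: noise around group-typical scores (axSpA ~3.5, HC ~0.8),
      ## independent of every taxon
      basdai <- pmin(10, pmax(0, ifelse(group == "axSpA", 3.5, 0.8) +
                                  stats::rnorm(n, 0, config$sigma_b)))
    } else {
      basdai <- pmin(10, pmax(0, config$b0 +
        config$b1 * stats::qlogis(theta[config$basdai_taxon, ]) +
        stats::rnorm(n, 0, config$sigma_b)))
    }
    counts <- cbind(pos, neg)
    colnames(counts) <- c(paste0(subj, "_pos"), paste0(subj, "_neg"))
    manifest <- data.frame(
      sample_id = colnames(counts),
      subject_id = rep(subj, 2),
      site = config$site,
      fraction = rep(c("pos", "neg"), each = n),
      group = rep(group, 2),
      basdai = round(rep(basdai, 2), 3),
      sex = rep(sex, 2),
      stringsAsFactors = FALSE)
    truth <- structure(list(
      pi = pi_m, theta = theta, beta = config$beta,
      direction = sign(config$beta),
      basdai_taxon = config$basdai_taxon,
      b0 = config$b0, b1 = config$b1, sigma_b = config$sigma_b,
      config = config), class = "iga_truth")
    list(counts = counts, manifest = manifest, truth = truth)
  })
}

#' Simulate a cohort with no coating effects
#'
#' Convenience wrapper around [simulateCohort()] with every group effect and
#' the BASDAI coupling switched off; the truth records all taxa as null.
#' Used as the type-I error harness.
#'
#' @inheritParams simulateCohort
#' @export
nullCohort <- function(config) {
  stopifnot(inherits(config, "iga_sim_config"))
  config$beta <- rep(0, config$n_taxa)
  config$basdai_taxon <- NA
  simulateCohort(config)
}

#' Simulate a predicted-function feature table
#'
#' Generates a KO/pathway-like feature-by-sample abundance table for two
#' classes with optional planted fold changes, used to exercise the
#' discriminant cascade. Baseline feature abundances are heavy-tailed
#' lognormal (most features rare, a few dominant, as in real predicted
#' metagenome tables); within-class replicate noise is lognormal with
#' \code{noise_sdlog} on the log scale (~25\% CV by default).
#'
#' @param n_features,n_per_class Table dimensions.
#' @param planted Integer indices of features shifted up in the first class.
#' @param fold Fold change applied to planted features.
#' @param base_meanlog,base_sdlog Lognormal baseline abundance parameters.
#' @param noise_sdlog Within-class lognormal noise SD (log scale).
#' @param classes Two class labels, first one carries the planted effect.
#' @param seed Integer seed.
#' @return List with \code{features} (matrix, features x samples),
#'   \code{labels} (factor), \code{subclass} (alternating sex labels) and
#'   \code{planted} (the indices).
#' @export
simulateFeatureTable <- function(n_features = 40, n_per_class = 15,
                                 planted = integer(0), fold = 2,
                                 base_meanlog = log(100), base_sdlog = 2,
                                 noise_sdlog = 0.25,
                                 classes = c("axSpA", "HC"), seed = 1) {
  stopifnot(length(classes) == 2, all(planted %in% seq_len(n_features)))
  .with_seed(seed, {
    n <- 2L * n_per_class
    ## sorted so feature index = abundance rank (1 = most abundant); lets
    ## callers plant effects at a chosen abundance tier deterministically
    base <- sort(stats::rlnorm(n_features, base_meanlog, base_sdlog),
                 decreasing = TRUE)
    labels <- factor(rep(classes, each = n_per_class), levels = classes)
    mu <- matrix(base, n_features, n)
    if (length(planted))
      mu[planted, labels == classes[1]] <-
        mu[planted, labels == classes[1]] * fold
    X <- matrix(stats::rlnorm(n_features * n, log(mu), noise_sdlog),
                n_features, n,
                dimnames = list(sprintf("feat_%03d", seq_len(n_features)),
                                sprintf("s%02d", seq_len(n))))
    list(features = X, labels = labels,
         subclass = rep_len(c("F", "M"), n), planted = planted)
  })
}
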