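## Orchestration: one run = one site, fixed stage order
## QC -> diversity -> IgA scoring -> correlation -> discriminant,
## all stochastic stages seeded deterministically from the run seed, all
## outputs written once as TSV into the run directory.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' @param counts,manifest Paths to the count table and manifest TSVs.
#' @param tree Optional path to a rooted newick tree; without it the
#'   UniFrac/PCoA/PERMANOVA stage is skipped (logged).
#' @param function_table Optional path to a predicted-function feature table
#'   (features x samples TSV, e.g. PICRUSt2 KO output) run through the
#'   discriminant cascade in addition to the taxa.
#' @param site Site analyzed in this run (one run = one site).
#' @param min_reads Depth filter, reads per fraction (default 7500).
#' @param pseudocount Pseudocount for relative abundances (default 1).
#' @param min_subjects Prevalence filter (default 3).
#' @param fdr_threshold BH threshold for calls (default 0.05).
#' @param lefse_preset \code{"strict"} (class alpha 0.05) or
#'   \code{"relaxed"} (class alpha 0.1) cascade preset.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param prune_tree Drop table taxa missing from the tree instead of
#'   failing (see [unweightedUnifrac()]).
#' @param seed Integer seed (required); every stochastic stage derives its
#'   seed from it.
#' @param outdir Output directory (created; must be empty or absent).
#' @return Validated config of class \code{iga_run_config}.
#' @export
runConfig <- function(counts, manifest, tree = NULL, function_table = NULL,
                      site = "fecal", min_reads = 7500, pseudocount = 1,
                      min_subjects = 3, fdr_threshold = 0.05,
                      lefse_preset = c("strict", "relaxed"), n_perm = 999,
                      prune_tree = FALSE, seed, outdir) {
  if (missing(seed)) stop("seed is required")
  if (missing(outdir)) stop("outdir is required")
  lefse_preset <- match.arg(lefse_preset)
  for (p in c(counts, manifest, tree, function_table))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]")
  structure(list(counts = counts, manifest = manifest, tree = tree,
                 function_table = function_table, site = site,
                 min_reads = min_reads, pseudocount = pseudocount,
                 min_subjects = min_subjects, fdr_threshold = fdr_threshold,
                 lefse_preset = lefse_preset, n_perm = n_perm,
                 prune_tree = prune_tree, seed = as.integer(seed),
                 outdir = outdir), class = "iga_run_config")
}

#' Run the full IgA-SEQ analysis for one site
#'
#' Executes the stages in fixed order, writing each stage's tables to
#' \code{config$outdir}. A stage failure writes a \code{FAILED} marker naming
#' the stage, leaves completed outputs intact, and raises an error. Runs are
#' deterministic given (inputs, config, seed): outputs carry no timestamps.
#'
#' @param config From [runConfig()].
#' @return The run report (data.frame of key/value rows), invisibly; also
#'   written as \code{report.tsv}.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "iga_run_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  note <- function(key, value) report[[key]] <<- as.character(value)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(name, file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  note("package_version", as.character(utils::packageVersion("igaseqr")))
  note("seed", config$seed)
  note("site", config$site)

  counts <- stage("read_inputs", readCountTable(config$counts))
  manifest <- stage("read_inputs", readManifest(config$manifest))
  tree <- if (!is.null(config$tree)) stage("read_inputs", readTree(config$tree))
  note("input_taxa", nrow(counts))
  note("input_samples", ncol(counts))

  paired <- stage("pair_fractions",
                  pairFractions(counts, manifest, config$site))
  note("paired_subjects", ncol(paired))
  qc_rows <- function(entity, ids, reason)
    data.frame(entity = rep(entity, length(ids)), id = ids,
               reason = rep(reason, length(ids)), stringsAsFactors = FALSE)
  paired <- stage("filter_by_depth", {
    before <- colnames(paired)
    pf <- filterByDepth(paired, config$min_reads)
    qc <- qc_rows("subject", setdiff(before, colnames(pf)),
                  paste0("fraction depth < ", config$min_reads))
    taxa_before <- rownames(pf)
    pf2 <- prevalenceFilter(pf, config$min_subjects)
    qc <- rbind(qc, qc_rows("taxon", setdiff(taxa_before, rownames(pf2)),
                            paste0("detected in < ", config$min_subjects,
                                   " subjects")))
    .write_tsv(qc, file.path(out, "qc_log.tsv"))
    pf2
  })
  note("qc_subjects", ncol(paired))
  note("qc_taxa", nrow(paired))
  groups <- stats::setNames(subjectData(paired)$group, colnames(paired))

  stage("diversity", {
    frac_counts <- list(pos = posCounts(paired), neg = negCounts(paired))
    alpha_all <- do.call(rbind, lapply(names(frac_counts), function(f) {
      a <- alphaDiversity(frac_counts[[f]])
      a$fraction <- f
      a
    }))
    .write_tsv(alpha_all, file.path(out, "alpha_diversity.tsv"))
    tests <- do.call(rbind, lapply(names(frac_counts), function(f) {
      tt <- compareAlpha(alpha_all[alpha_all$fraction == f, ], groups)
      tt$fraction <- f
      tt
    }))
    .write_tsv(tests, file.path(out, "alpha_tests.tsv"))
    if (!is.null(tree)) {
      perm <- do.call(rbind, lapply(names(frac_counts), function(f) {
        dm <- unweightedUnifrac(frac_counts[[f]], tree, prune = config$prune_tree)
        .write_tsv(data.frame(sample_id = rownames(dm), dm,
                              check.names = FALSE),
                   file.path(out, paste0("unifrac_", f, ".tsv")))
        ord <- pcoaOrdination(dm)
        .write_tsv(data.frame(sample_id = rownames(ord$points),
                              ord$points, check.names = FALSE),
                   file.path(out, paste0("pcoa_", f, ".tsv")))
        pv <- permanovaTest(dm, groups, config$n_perm,
                            seed = config$seed + 11L)
        data.frame(fraction = f, pseudo_F = pv$pseudo_F, R2 = pv$R2,
                   p = pv$p_value, n_perm = pv$n_permutations)
      }))
      .write_tsv(perm, file.path(out, "permanova.tsv"))
    } else message("runFullAnalysis: no tree supplied; skipping UniFrac/PCoA/PERMANOVA")
  })

  idx <- stage("iga_scoring", {
    idx <- igaIndexMatrix(paired, config$pseudocount)
    .write_tsv(data.frame(taxon_id = rownames(idx), idx, check.names = FALSE),
               file.path(out, "iga_index.tsv"))
    calls <- lapply(c("axSpA", "HC"), function(g)
      callEnrichment(idx, groups, g, config$fdr_threshold))
    names(calls) <- c("axSpA", "HC")
    .write_tsv(rbind(calls$axSpA, calls$HC),
               file.path(out, "enrichment_calls.tsv"))
    ov <- rbind(
      data.frame(call = "enriched",
                 t(sharedTaxaOverlap(calls$axSpA, calls$HC, "enriched"))),
      data.frame(call = "depleted",
                 t(sharedTaxaOverlap(calls$axSpA, calls$HC, "depleted"))))
    .write_tsv(ov, file.path(out, "enrichment_overlap.tsv"))
    .write_tsv(compareIndexBetweenGroups(idx, groups),
               file.path(out, "group_comparison.tsv"))
    note("enriched_axSpA", sum(calls$axSpA$call == "enriched"))
    note("enriched_HC", sum(calls$HC$call == "enriched"))
    idx
  })

  stage("correlation", {
    basdai <- stats::setNames(subjectData(paired)$basdai, colnames(paired))
    if (any(!is.na(basdai))) {
      relab <- relativeAbundance(posCounts(paired) + negCounts(paired),
                                 config$pseudocount)
      cors <- rbind(
        cbind(statistic_type = "iga_index",
              correlateWithBasdai(idx, basdai)),
        cbind(statistic_type = "relative_abundance",
              correlateWithBasdai(relab, basdai)))
      .write_tsv(cors, file.path(out, "basdai_correlation.tsv"))
    } else message("runFullAnalysis: no BASDAI scores; skipping correlation")
  })

  stage("discriminant", {
    alpha_class <- if (config$lefse_preset == "relaxed") 0.1 else 0.05
    sd_ <- subjectData(paired)
    subclass <- if ("sex" %in% colnames(sd_) && !all(is.na(sd_$sex)))
      sd_$sex
    run_one <- function(mat, tag, seed_off) {
      res <- runCascade(mat, factor(groups, levels = c("axSpA", "HC")),
                        subclass = subclass, alpha_class = alpha_class,
                        seed = config$seed + seed_off)
      .write_tsv(res, file.path(out, paste0("discriminant_", tag, ".tsv")))
      res
    }
    res_pos <- run_one(relativeAbundance(posCounts(paired),
                                         config$pseudocount) * 1e6,
                       "pos", 21L)
    res_neg <- run_one(relativeAbundance(negCounts(paired),
                                         config$pseudocount) * 1e6,
                       "neg", 22L)
    .write_tsv(data.frame(t(overlapSignificant(res_pos, res_neg))),
               file.path(out, "discriminant_overlap.tsv"))
    note("discriminant_sig_pos", sum(res_pos$significant))
    note("discriminant_sig_neg", sum(res_neg$significant))
    if (!is.null(config$function_table)) {
      fx <- readCountTable(config$function_table)
      sd2 <- subjectData(paired)
      ## function tables are per fraction sample; restrict to retained
      ## subjects' pos samples when ids match, else use as supplied
      keep <- intersect(colnames(fx), paste0(colnames(paired), "_pos"))
      if (length(keep) >= 4) {
        fx <- fx[, keep, drop = FALSE]
        glab <- groups[sub("_pos$", "", keep)]
        res_fx <- runCascade(fx + 0, factor(glab, levels = c("axSpA", "HC")),
                             subclass = NULL, alpha_class = alpha_class,
                             seed = config$seed + 23L)
        .write_tsv(res_fx, file.path(out, "discriminant_function.tsv"))
      }
    }
  })

  rep_df <- data.frame(key = names(report), value = unlist(report),
                       stringsAsFactors = FALSE, row.names = NULL)
  .write_tsv(rep_df, file.path(out, "report.tsv"))
  invisible(rep_df)
}

.EXPECTED_STAGE_FILES <- c(
  qc = "qc_log.tsv", diversity = "alpha_diversity.tsv",
  iga_scoring = "iga_index.tsv", enrichment = "enrichment_calls.tsv",
  report = "report.tsv")

#' Consolidate a run directory into a report
#'
#' Re-reads the TSVs a completed (or partial) [runFullAnalysis()] run
#' emitted, recounts their rows, and flags missing stages; every number is
#' recomputable from the files themselves.
#'
#' @param run_dir Path to the run directory.
#' @return Data.frame of key/value rows (file row counts, missing-stage
#'   flags, and the original report when present).
#' @export
generateReport <- function(run_dir) {
  if (!dir.exists(run_dir) || !length(list.files(run_dir)))
    stop("run directory is missing or empty: ", run_dir)
  files <- list.files(run_dir, pattern = "\\.tsv$")
  rows <- vapply(files, function(f)
    nrow(utils::read.delim(file.path(run_dir, f))), integer(1))
  rep <- data.frame(key = character(0), value = character(0),
                    stringsAsFactors = FALSE)
  if (length(files))
    rep <- data.frame(key = paste0("rows_", files), value = as.character(rows),
                      stringsAsFactors = FALSE)
  missing <- .EXPECTED_STAGE_FILES[!(.EXPECTED_STAGE_FILES %in% files)]
  if (length(missing))
    rep <- rbind(rep, data.frame(key = paste0("missing_stage_", names(missing)),
                                 value = missing, stringsAsFactors = FALSE))
  if (file.exists(file.path(run_dir, "FAILED")))
    rep <- rbind(rep, data.frame(
      key = "failed_stage",
      value = readLines(file.path(run_dir, "FAILED"))[1],
      stringsAsFactors = FALSE))
  if ("report.tsv" %in% files) {
    orig <- utils::read.delim(file.path(run_dir, "report.tsv"),
                              colClasses = "character")
    rep <- rbind(rep, orig)
  }
  rownames(rep) <- NULL
  rep
}
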