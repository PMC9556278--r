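# Writes a small synthetic cohort to disk in the pipeline's input formats.
write_cohort_inputs <- function(dir, n_per_group = 8, n_taxa = 24, seed = 202) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta <- rep(0, n_taxa)
  beta[c(2, 7)] <- 1.5
  cfg <- simulationConfig(n_per_group = n_per_group, n_taxa = n_taxa,
                          depth_mean = 12000, beta = beta, basdai_taxon = 2,
                          seed = seed)
  co <- simulateCohort(cfg)
  writeCountTable(co$counts, file.path(dir, "counts.tsv"))
  writeManifest(co$manifest, file.path(dir, "manifest.tsv"))
  set.seed(seed)
  tr <- ape::rcoal(n_taxa, tip.label = rownames(co$counts))
  ape::write.tree(tr, file.path(dir, "tree.nwk"))
  dir
}

run_quiet <- function(cfg) {
  suppressWarnings(suppressMessages(runFullAnalysis(cfg)))
}
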