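#!/usr/bin/env Rscript
# End-to-end orchestrated run: design -> simulate -> synthetic tables ->
# preprocessing -> epistasis -> outcome classification -> report, through
# run_workflow(), with every output hashed into a manifest. Demonstrates
# that a rerun with the same configuration reproduces the hashes.

suppressPackageStartupMessages(library(envcomplexity))

cfg <- list(
  resources = list(names = sprintf("cs%d", 1:8), rank_scores = 1:8),
  ensemble = list(S = 13, theta = 0.5, n_replicates = 2,
                  byproduct_counts = c(1, 5)),
  synth = list(planted_EY = list("4-1" = -0.15)),
  out_dir = "results/workflow_run", seed = 20260925)

stages <- c("design", "simulate", "synth", "preprocess", "epistasis",
            "classify", "cluster", "report")
mf <- run_workflow(cfg, stages)
cat("\nmanifest files:\n")
for (f in names(mf$files)) cat(sprintf("  %-22s %s\n", f, mf$files[[f]]$md5))

cat("\nreport:\n")
writeLines(readLines(file.path(cfg$out_dir, "report.txt")))

# determinism: the same configuration in a fresh directory gives identical
# content hashes for every table
cfg2 <- cfg; cfg2$out_dir <- "results/workflow_rerun"
mf2 <- run_workflow(cfg2, stages)
same <- all(vapply(names(mf$files), function(f)
  identical(mf$files[[f]]$md5, mf2$files[[f]]$md5), logical(1)))
cat("\nrerun reproduces every file hash:", same, "\n")
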