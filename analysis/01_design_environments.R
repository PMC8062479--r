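#!/usr/bin/env Rscript
# Build the two combinatorial environment designs used throughout:
#   - the hierarchical 63-environment scheme over 32 carbon sources
#     (rank-extreme pairing, equal total carbon at every complexity level)
#   - the all-subsets 31-environment scheme over 5 carbon sources
# and write their serializations under results/design/.

suppressPackageStartupMessages(library(envcomplexity))

dir.create("results/design", showWarnings = FALSE, recursive = TRUE)

# rank scores stand in for monoculture growth yields; they only fix the
# pairing order, not any simulated quantity
res32 <- resource_set(sprintf("cs%02d", 1:32), rank_scores = 1:32)
sch32 <- build_hierarchical_scheme(res32, total_carbon = 1.5)
validate_scheme(sch32)
print(sch32)
write_scheme(sch32, "results/design/scheme32.tsv")

res5 <- resource_set(c("glucose", "pyruvate", "glcnac", "proline",
                       "threonine"), rank_scores = c(5, 4, 3, 2, 1))
sch5 <- build_full_subset_scheme(res5, total_carbon = 1.5)
validate_scheme(sch5)
print(sch5)
write_scheme(sch5, "results/design/scheme5.tsv")

cat(sprintf("\nhierarchical scheme: %d environments, %d epistasis edges\n",
            nrow(sch32$environments), nrow(sch32$edges)))
cat(sprintf("all-subsets scheme:  %d environments, %d epistasis edges\n",
            nrow(sch5$environments), nrow(sch5$edges)))
cat("every environment carries 1.5 carbon units:",
    all(abs(vapply(c(sch32$concentrations, sch5$concentrations), sum,
                   numeric(1)) - 1.5) < 1e-12), "\n")
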