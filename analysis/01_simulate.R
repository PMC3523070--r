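#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the synthetic JIA cohort the rest of the workflow analyzes:
# 71 samples (22 SJIA flare, 24 SJIA quiescence, 17 POLY flare, 8 POLY
# quiescence) over a 181-gene panel with 4 housekeeping genes, 75
# low-variation genes, and planted ESR-linear, joint-count-linear and
# flare-shift effects with recorded truth. Also writes a gene-set
# collection with known enriched and background sets.

library(jiaassoc)

config <- run_config(rng_seed = 20260922L)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

design <- simulation_design(seed = derive_seed(config$rng_seed, "simulate"))
cohort <- generate_cohort(design)
paths <- write_cohort(cohort, "results/data")
write_config(config, "results/data/config.yaml")

sets <- generate_gene_sets(cohort, n_sets = 50, enriched_fraction = 0.3,
                           seed = derive_seed(config$rng_seed, "gene_sets"))
write_gmt(sets, "results/data/sets.gmt")

print(cohort)
cat(sprintf("wrote cohort (%s) and %d gene sets\n",
            paste(basename(paths), collapse = ", "), length(sets)))
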