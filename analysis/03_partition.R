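#!/usr/bin/env Rscript
# Stage 3: clinical scoring and sample partitions.
#
# Applies the flare/quiescence scoring rules (systemic score 0-3,
# arthritis scores A-D / 0-3), the ESR < 20 flare partition (F1/F2) and
# the SAF/AF subgrouping of SJIA flares, and writes the grouping table
# every later stage consumes.

library(jiaassoc)

config <- read_config("results/data/config.yaml")
clinical <- read_clinical("results/data/clinical.tsv")

grouping <- sample_grouping(clinical, config)
write_grouping(grouping, "results/grouping.tsv")

cat("samples by disease and state:\n")
print(table(grouping$disease, grouping$state))
cat("\nESR partition (flares split at", config$esr_partition_cutoff, "mm/h):\n")
print(table(grouping$esr_partition))
cat("\nSJIA flare subgroups:\n")
print(table(grouping$saf_af[grouping$disease == "SJIA" & grouping$state == "F"]))
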