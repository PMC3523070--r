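#!/usr/bin/env Rscript
# Stage 5: pathway enrichment and profile comparison.
#
# Scores the gene-set collection for over-representation of each
# condition's combined gene list (hypergeometric upper tail against the
# 181-gene panel), annotates per-pathway expression direction, then
# compares condition profiles: SJIA ESR vs SJIA JC and SJIA ESR vs POLY
# ESR. Each comparison gets a 500-permutation null of absolute -log10 P
# differences, 20/50/80 percentile curves and a differentiating-pathway
# report thresholded at the 95th percentile of the pooled per-pathway
# 80th-percentile null.

library(jiaassoc)

config <- read_config("results/data/config.yaml")
expression <- read_expression("results/data/expression.tsv",
                              c("EEF1A1", "PPP1CC", "RPL12", "RPL41"))
sets <- read_gmt("results/data/sets.gmt")
universe <- rownames(expression$values)

scores <- list()
for (key in c("SJIA_ESR", "SJIA_JC", "POLY_ESR", "POLY_JC")) {
  f <- sprintf("results/genes_%s.tsv", key)
  if (!file.exists(f)) next
  genes <- read.delim(f)
  if (!nrow(genes)) {
    cat(sprintf("%s: empty gene list, no enrichment\n", key))
    next
  }
  sc <- score_condition(genes, sets, universe, key, config$direction_threshold)
  scores[[key]] <- sc
  write_pathway_scores(sc, sprintf("results/pathways_%s.tsv", key))
  cat(sprintf("%s: %d pathways scored, top -log10 p = %.2f\n", key, nrow(sc),
              max(sc$neglog10p)))
}

for (pair in list(c("SJIA_ESR", "SJIA_JC"), c("SJIA_ESR", "POLY_ESR"))) {
  if (!all(pair %in% names(scores))) {
    cat(sprintf("comparison %s vs %s skipped (missing profile)\n",
                pair[1], pair[2]))
    next
  }
  key <- paste0(pair[1], "_vs_", pair[2])
  res <- compare_conditions(scores[[pair[1]]], scores[[pair[2]]], config,
                            seed = derive_seed(config$rng_seed, key))
  write_comparison(res,
                   sprintf("results/comparison_%s.tsv", key),
                   sprintf("results/null_percentiles_%s.tsv", key),
                   sprintf("results/density_curves_%s.tsv", key))
  print(res)
}
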