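#' Pipeline run configuration
#'
#' Central knobs of the association pipeline with their defaults: 100 label
#' permutations for the per-gene null, 500 pathway-profile simulations,
#' lFDR selection gate 0.05, ESR flare partition at 20 mm/h, raw-p subgroup
#' gate 0.05, and the 20/50/80 null percentiles summarised per pathway.
#'
#' @param n_permutations_gene permutations for the gene-level null (>= 1).
#' @param n_simulations_pathway pathway-profile permutations (>= 1).
#' @param lfdr_cutoff local-FDR selection gate, in (0, 1].
#' @param esr_partition_cutoff ESR (mm/h) splitting flare samples into
#'   F1 (< cutoff) and F2 (>= cutoff).
#' @param subgroup_p_cutoff raw two-sided p gate for SAF/AF subgroup
#'   correlations, in (0, 1].
#' @param rng_seed global integer seed; stage seeds are derived from it.
#' @param percentiles strictly increasing percentiles in (0, 100) summarising
#'   the pathway permutation null.
#' @param sjia_flare_rule `"jc5"` (flare if systemic score >= 1 or
#'   joint count >= 5) or `"literal_b"` (>= 1 active joint qualifies).
#' @param pathway_threshold_mode `"global"` (one threshold: a percentile of
#'   the pooled per-pathway 80th-percentile null values) or `"per_pathway"`
#'   (each pathway compared to its own 80th-percentile null).
#' @param pathway_threshold_percentile percentile used in global mode.
#' @param direction_threshold fraction of overlap genes that must share a
#'   direction before a pathway is labelled higher/lower (default 2/3).
#' @return a list of class `run_config`.
#' @export
run_config <- function(n_permutations_gene = 100L,
                       n_simulations_pathway = 500L,
                       lfdr_cutoff = 0.05,
                       esr_partition_cutoff = 20,
                       subgroup_p_cutoff = 0.05,
                       rng_seed = 1L,
                       percentiles = c(20, 50, 80),
                       sjia_flare_rule = c("jc5", "literal_b"),
                       pathway_threshold_mode = c("global", "per_pathway"),
                       pathway_threshold_percentile = 95,
                       direction_threshold = 2 / 3) {
  sjia_flare_rule <- match.arg(sjia_flare_rule)
  pathway_threshold_mode <- match.arg(pathway_threshold_mode)
  stopifnot(
    n_permutations_gene >= 1, n_simulations_pathway >= 1,
    lfdr_cutoff > 0, lfdr_cutoff <= 1,
    subgroup_p_cutoff > 0, subgroup_p_cutoff <= 1,
    all(percentiles > 0), all(percentiles < 100),
    all(diff(percentiles) > 0),
    pathway_threshold_percentile > 0, pathway_threshold_percentile <= 100,
    direction_threshold >= 0.5, direction_threshold <= 1
  )
  structure(list(
    n_permutations_gene = as.integer(n_permutations_gene),
    n_simulations_pathway = as.integer(n_simulations_pathway),
    lfdr_cutoff = lfdr_cutoff,
    esr_partition_cutoff = esr_partition_cutoff,
    subgroup_p_cutoff = subgroup_p_cutoff,
    rng_seed = as.integer(rng_seed),
    percentiles = as.numeric(percentiles),
    sjia_flare_rule = sjia_flare_rule,
    pathway_threshold_mode = pathway_threshold_mode,
    pathway_threshold_percentile = pathway_threshold_percentile,
    direction_threshold = direction_threshold
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
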