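#' Run the full association pipeline
#'
#' Executes the stages in order — (simulate or load) -> partition ->
#' associate (ESR and joint count, per disease cohort) -> enrich ->
#' compare -> subgroup — writing every stage output under `out_dir` and
#' returning a manifest. Inputs are either file paths or a synthetic
#' cohort simulated in place (`simulate = TRUE`). Stage failures abort
#' with the stage name and cause; per-cohort analyses that are degenerate
#' on the supplied data (e.g. no quiescent POLY variation) are skipped and
#' logged rather than aborting the run. All randomness derives from
#' `config$rng_seed` via stage-keyed seeds, so identical inputs and seed
#' give identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param simulate simulate a default cohort instead of reading inputs.
#' @param design [simulation_design()] used when `simulate = TRUE`
#'   (its seed is replaced by a derived stage seed).
#' @param expression_path,clinical_path,gmt_path input files when
#'   `simulate = FALSE` (expression must be housekeeping-normalized).
#' @param housekeeping_ids housekeeping gene ids for [read_expression()].
#' @param gene_sets optional `gene_set_collection` (overrides `gmt_path`;
#'   when simulating and neither is given, sets are simulated too).
#' @param stages stages to run after data loading; subset of
#'   `c("partition", "associate", "enrich", "compare", "subgroup")`.
#' @return list of class `run_manifest`: config snapshot, input digests,
#'   seed, per-stage output paths, counts summary and log. Also written as
#'   JSON to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, simulate = FALSE,
                         design = NULL, expression_path = NULL,
                         clinical_path = NULL, gmt_path = NULL,
                         housekeeping_ids = NULL, gene_sets = NULL,
                         stages = c("partition", "associate", "enrich",
                                    "compare", "subgroup")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  env$outputs <- character()
  env$counts <- list()
  env$log <- character()
  say <- function(fmt, ...) env$log <- c(env$log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_with("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  digests <- character()
  if (simulate) {
    cohort <- stage("simulate", {
      design <- design %||% simulation_design()
      design$seed <- derive_seed(config$rng_seed, "simulate")
      generate_cohort(design)
    })
    paths <- write_cohort(cohort, file.path(out_dir, "data"))
    env$outputs[names(paths)] <- paths
    expression <- cohort$expression
    clinical <- cohort$clinical
    say("simulated cohort: %d samples, %d genes", nrow(clinical),
        nrow(expression$values))
    if (is.null(gene_sets) && is.null(gmt_path)) {
      gene_sets <- generate_gene_sets(
        cohort, n_sets = 50L, enriched_fraction = 0.3,
        seed = derive_seed(config$rng_seed, "gene_sets"))
      gmt_out <- file.path(out_dir, "data", "sets.gmt")
      write_gmt(gene_sets, gmt_out)
      env$outputs["gene_sets"] <- gmt_out
    }
  } else {
    stage("load", {
      if (is.null(expression_path) || is.null(clinical_path)) {
        stop_with("expression_path and clinical_path are required unless simulate = TRUE")
      }
    })
    expression <- stage("load", read_expression(expression_path, housekeeping_ids))
    clinical <- stage("load", read_clinical(clinical_path))
    digests <- tools::md5sum(c(expression_path, clinical_path))
  }
  if (is.null(gene_sets) && !is.null(gmt_path)) {
    gene_sets <- stage("load", read_gmt(gmt_path))
    digests <- c(digests, tools::md5sum(gmt_path))
  }

  grouping <- NULL
  if ("partition" %in% stages) {
    grouping <- stage("partition", sample_grouping(clinical, config))
    p <- file.path(out_dir, "grouping.tsv")
    write_grouping(grouping, p)
    env$outputs["grouping"] <- p
    env$counts$samples_per_state <-
      as.list(table(paste(grouping$disease, grouping$state, sep = "_")))
  }

  analyses <- list()
  if ("associate" %in% stages) {
    if (is.null(grouping)) {
      stop_with("pipeline stage 'associate' failed: needs the partition stage")
    }
    stage("associate", {
      specs <- list(c("SJIA", "esr"), c("SJIA", "joint_count"),
                    c("POLY", "esr"), c("POLY", "joint_count"))
      for (sp in specs) {
        key <- sprintf("%s_%s", sp[1], if (sp[2] == "esr") "ESR" else "JC")
        an <- tryCatch(
          associate(expression, clinical, grouping, covariate = sp[2],
                    disease = sp[1], config = config),
          error = function(e) {
            say("association %s skipped: %s", key, conditionMessage(e))
            NULL
          })
        if (is.null(an)) next
        analyses[[key]] <- an
        p1 <- file.path(out_dir, sprintf("association_%s.tsv", key))
        p2 <- file.path(out_dir, sprintf("genes_%s.tsv", key))
        write_association(an, p1, p2)
        env$outputs[paste0("association_", key)] <- p1
        env$outputs[paste0("genes_", key)] <- p2
        env$counts[[paste0("selected_", key)]] <- nrow(an$combined)
      }
    })
  }

  pathway_scores <- list()
  if ("enrich" %in% stages) {
    stage("enrich", {
      if (is.null(gene_sets)) {
        stop_with("no gene-set collection supplied (gmt_path or gene_sets)")
      }
      universe <- rownames(expression$values)
      for (key in names(analyses)) {
        an <- analyses[[key]]
        if (!nrow(an$combined)) {
          say("enrichment %s skipped: empty gene list", key)
          next
        }
        sc <- score_condition(an$combined, gene_sets, universe, key,
                              config$direction_threshold)
        pathway_scores[[key]] <- sc
        p <- file.path(out_dir, sprintf("pathways_%s.tsv", key))
        write_pathway_scores(sc, p)
        env$outputs[paste0("pathways_", key)] <- p
      }
      env$counts$pathways_scored <- lapply(pathway_scores, nrow)
    })
  }

  if ("compare" %in% stages) {
    stage("compare", {
      pairs <- list(c("SJIA_ESR", "SJIA_JC"), c("SJIA_ESR", "POLY_ESR"))
      for (pr in pairs) {
        if (!all(pr %in% names(pathway_scores))) {
          say("comparison %s vs %s skipped: missing profile", pr[1], pr[2])
          next
        }
        key <- paste0(pr[1], "_vs_", pr[2])
        res <- compare_conditions(
          pathway_scores[[pr[1]]], pathway_scores[[pr[2]]], config,
          seed = derive_seed(config$rng_seed, paste0("compare_", key)))
        p <- file.path(out_dir, sprintf("comparison_%s.tsv", key))
        write_comparison(
          res, p,
          percentile_path = file.path(out_dir, sprintf("null_percentiles_%s.tsv", key)),
          curves_path = file.path(out_dir, sprintf("density_curves_%s.tsv", key)))
        env$outputs[paste0("comparison_", key)] <- p
        env$counts[[paste0("differentiating_", key)]] <- sum(res$report$differentiating)
        env$counts[[paste0("profile_correlation_", key)]] <-
          res$comparison$profile_correlation
      }
    })
  }

  if ("subgroup" %in% stages) {
    stage("subgroup", {
      if (is.null(grouping)) stop_with("needs the partition stage")
      jc_genes <- if (!is.null(analyses$SJIA_JC)) analyses$SJIA_JC$combined$gene else character()
      if (!length(jc_genes)) {
        say("subgroup analysis skipped: no joint-count gene list")
      } else {
        sub <- tryCatch(
          subgroup_jc_correlation(expression, clinical, grouping, jc_genes,
                                  config$subgroup_p_cutoff),
          error = function(e) {
            say("subgroup analysis skipped: %s", conditionMessage(e))
            NULL
          })
        if (!is.null(sub)) {
          p <- file.path(out_dir, "subgroup_jc_correlation.tsv")
          write_subgroup(sub, p)
          env$outputs["subgroup"] <- p
          env$counts$subgroup_significant <-
            as.list(table(sub$subgroup[sub$significant]))
        }
      }
    })
  }

  manifest <- structure(list(
    config = unclass(config),
    input_digests = as.list(digests),
    seed = config$rng_seed,
    outputs = as.list(env$outputs),
    counts = env$counts,
    log = env$log
  ), class = "run_manifest")
  missing_out <- unlist(manifest$outputs)[!file.exists(unlist(manifest$outputs))]
  if (length(missing_out)) {
    stop_with("manifest invariant violated; missing output(s): %s",
              paste(missing_out, collapse = ", "))
  }
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, %d outputs\n", x$seed, length(x$outputs)))
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
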