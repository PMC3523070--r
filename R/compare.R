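# Pathway-profile comparison between two clinical conditions: Pearson
# correlation of -log10 P vectors, a permutation null of absolute log-P
# differences, per-pathway 20/50/80 percentile summaries, and a
# permutation-derived threshold for calling differentiating pathways.

#' Align two pathway profiles into a comparison object
#'
#' Takes two conditions' pathway scores, aligns them on the union of
#' pathway ids (a pathway unscored in one condition is imputed
#' -log10 P = 0 there), and computes signed and absolute differences plus
#' the Pearson correlation of the two profiles.
#'
#' @param scores_a,scores_b `pathway_scores` data frames, or named numeric
#'   vectors of -log10 P values.
#' @param condition_a,condition_b labels (defaulted from score tables).
#' @return list of class `pathway_comparison`: `pathway_ids`, `neglogp_a`,
#'   `neglogp_b`, `signed_diff`, `observed_absdiff`, `profile_correlation`,
#'   `direction_a`, `direction_b`, condition labels.
#' @export
pathway_comparison <- function(scores_a, scores_b, condition_a = NULL,
                               condition_b = NULL) {
  pa <- as_profile(scores_a)
  pb <- as_profile(scores_b)
  condition_a <- condition_a %||% attr(pa, "condition") %||% "A"
  condition_b <- condition_b %||% attr(pb, "condition") %||% "B"
  ids <- union(names(pa$p), names(pb$p))
  if (length(ids) < 3L) stop_with("need >= 3 pathways in the union, got %d", length(ids))
  a <- stats::setNames(rep(0, length(ids)), ids)
  b <- a
  a[names(pa$p)] <- pa$p
  b[names(pb$p)] <- pb$p
  da <- stats::setNames(rep(NA_character_, length(ids)), ids)
  db <- da
  da[names(pa$dir)] <- pa$dir
  db[names(pb$dir)] <- pb$dir
  structure(list(
    pathway_ids = ids, neglogp_a = unname(a), neglogp_b = unname(b),
    signed_diff = unname(a - b), observed_absdiff = unname(abs(a - b)),
    profile_correlation = profile_correlation_vec(a, b),
    direction_a = unname(da), direction_b = unname(db),
    condition_a = condition_a, condition_b = condition_b
  ), class = "pathway_comparison")
}

as_profile <- function(x) {
  if (inherits(x, "pathway_scores") || is.data.frame(x)) {
    p <- stats::setNames(x$neglog10p, x$set_id)
    dirs <- if (!is.null(x$direction)) stats::setNames(x$direction, x$set_id) else
      stats::setNames(rep(NA_character_, nrow(x)), x$set_id)
    out <- list(p = p, dir = dirs)
    attr(out, "condition") <- if (nrow(x)) x$condition[1L] else NULL
    out
  } else {
    if (is.null(names(x))) stop_with("profile vectors must be named by pathway id")
    list(p = x, dir = stats::setNames(rep(NA_character_, length(x)), names(x)))
  }
}

profile_correlation_vec <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Pearson correlation between two pathway profiles
#'
#' Correlates two conditions' -log10 P vectors over the union of their
#' pathways (unscored pathways imputed 0).
#'
#' @inheritParams pathway_comparison
#' @return Pearson correlation coefficient (`NA` when exactly one profile is
#'   constant; an error when both are).
#' @export
profile_correlation <- function(scores_a, scores_b) {
  cmp <- pathway_comparison(scores_a, scores_b)
  if (stats::sd(cmp$neglogp_a) == 0 && stats::sd(cmp$neglogp_b) == 0) {
    stop_with("both pathway profiles are constant; correlation undefined")
  }
  cmp$profile_correlation
}

#' Permutation null of absolute pathway log-P differences
#'
#' For each simulation the assignment of -log10 P values to pathway ids is
#' permuted independently within each condition, and the per-pathway
#' absolute difference between the two permuted profiles is recorded. The
#' two conditions are permuted independently (not with a shared
#' permutation), matching a null in which pathway identity carries no
#' information in either profile.
#'
#' @param comparison a `pathway_comparison`.
#' @param n_simulations number of simulated profile pairs (default 500).
#' @param seed integer seed; deterministic given the seed.
#' @return matrix (n_pathways x n_simulations) of absolute differences.
#' @export
simulate_null <- function(comparison, n_simulations = 500L, seed = 1L) {
  stopifnot(inherits(comparison, "pathway_comparison"))
  if (n_simulations < 1L) stop_with("n_simulations must be >= 1")
  a <- comparison$neglogp_a
  b <- comparison$neglogp_b
  m <- length(a)
  null <- with_seed(seed, {
    vapply(seq_len(n_simulations), function(i) {
      abs(a[sample.int(m)] - b[sample.int(m)])
    }, numeric(m))
  })
  rownames(null) <- comparison$pathway_ids
  colnames(null) <- paste0("sim", seq_len(n_simulations))
  null
}

#' Percentile summaries and density curves of the pathway null
#'
#' Sorts each pathway's null differences and extracts the configured
#' percentiles (default 20/50/80, type-7 interpolation), then estimates
#' kernel density curves over pathways for the observed absolute
#' differences and for each percentile vector, reproducing the density
#' overlay used to pick the significance threshold.
#'
#' @param comparison a `pathway_comparison`.
#' @param null matrix from [simulate_null()].
#' @param percentiles percentiles in (0, 100), default `c(20, 50, 80)`.
#' @return list of class `null_percentiles`: `percentile_values`
#'   (n_pathways x length(percentiles)), `curves` (named list of
#'   data.frames with grid/density; `observed` plus one per percentile).
#' @export
percentile_summaries <- function(comparison, null, percentiles = c(20, 50, 80)) {
  stopifnot(inherits(comparison, "pathway_comparison"),
            nrow(null) == length(comparison$pathway_ids))
  pv <- t(apply(null, 1L, stats::quantile, probs = percentiles / 100,
                type = 7, names = FALSE))
  if (length(percentiles) == 1L) pv <- matrix(pv, ncol = 1L)
  colnames(pv) <- paste0("p", percentiles)
  rownames(pv) <- comparison$pathway_ids
  curve_of <- function(v) {
    d <- if (stats::sd(v) > 0) stats::density(v, bw = "nrd0", n = 512) else
      stats::density(v, bw = max(abs(v[1L]) * 1e-3, 1e-3), n = 512)
    data.frame(grid = d$x, density = d$y)
  }
  curves <- c(list(observed = curve_of(comparison$observed_absdiff)),
              stats::setNames(lapply(seq_along(percentiles),
                                     function(j) curve_of(pv[, j])),
                              paste0("p", percentiles)))
  structure(list(percentile_values = pv, curves = curves,
                 percentiles = percentiles),
            class = "null_percentiles")
}

#' Differentiating-pathway report
#'
#' Determines the significance threshold from the permutation null and
#' flags pathways whose observed absolute log-P difference exceeds it.
#' In `global` mode (default) the threshold is one number: the configured
#' percentile (default 95th) of the pooled per-pathway 80th-percentile
#' null values. In `per_pathway` mode each pathway is compared against its
#' own 80th-percentile null value. Rows are sorted by absolute signed
#' difference (then by the first condition's -log10 P), with pathways
#' scored equally in both conditions (|difference| < 1e-9, both nonzero)
#' reported as a separate `shared` block.
#'
#' @param comparison a `pathway_comparison`.
#' @param null matrix from [simulate_null()].
#' @param mode `"global"` or `"per_pathway"`.
#' @param threshold_percentile percentile of pooled 80th-percentile null
#'   values used in global mode (default 95).
#' @param reference_percentile the per-pathway null percentile the decision
#'   rests on (default 80).
#' @return data frame of class `differentiating_report`: pathway,
#'   neglogp_a, neglogp_b, signed_diff, observed_absdiff, direction_a,
#'   direction_b, null_reference (per-pathway reference-percentile value),
#'   differentiating, shared. Attribute `threshold` holds the global
#'   threshold (NA in per-pathway mode).
#' @export
differentiating_report <- function(comparison, null,
                                   mode = c("global", "per_pathway"),
                                   threshold_percentile = 95,
                                   reference_percentile = 80) {
  mode <- match.arg(mode)
  stopifnot(inherits(comparison, "pathway_comparison"))
  ref <- apply(null, 1L, stats::quantile, probs = reference_percentile / 100,
               type = 7, names = FALSE)
  if (mode == "global") {
    threshold <- stats::quantile(ref, probs = threshold_percentile / 100,
                                 type = 7, names = FALSE)
    differentiating <- comparison$observed_absdiff > threshold
  } else {
    threshold <- NA_real_
    differentiating <- comparison$observed_absdiff > ref
  }
  shared <- comparison$observed_absdiff < 1e-9 &
    comparison$neglogp_a > 0 & comparison$neglogp_b > 0
  out <- data.frame(
    pathway = comparison$pathway_ids,
    neglogp_a = comparison$neglogp_a, neglogp_b = comparison$neglogp_b,
    signed_diff = comparison$signed_diff,
    observed_absdiff = comparison$observed_absdiff,
    direction_a = comparison$direction_a, direction_b = comparison$direction_b,
    null_reference = unname(ref),
    differentiating = differentiating, shared = shared,
    stringsAsFactors = FALSE
  )
  ord <- order(-out$observed_absdiff, -out$neglogp_a, out$pathway)
  out <- out[ord, , drop = FALSE]
  out <- rbind(out[!out$shared, , drop = FALSE], out[out$shared, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  attr(out, "conditions") <- c(comparison$condition_a, comparison$condition_b)
  class(out) <- c("differentiating_report", "data.frame")
  out
}

#' Full two-condition pathway comparison
#'
#' Bundles [pathway_comparison()], [simulate_null()],
#' [percentile_summaries()] and [differentiating_report()].
#'
#' @inheritParams pathway_comparison
#' @param config a [run_config()].
#' @param seed seed for the profile permutations.
#' @return list of class `pathway_comparison_result` with elements
#'   `comparison`, `null`, `percentiles`, `report`.
#' @export
compare_conditions <- function(scores_a, scores_b, config = run_config(),
                               seed = derive_seed(config$rng_seed, "pathway_compare"),
                               condition_a = NULL, condition_b = NULL) {
  comparison <- pathway_comparison(scores_a, scores_b, condition_a, condition_b)
  null <- simulate_null(comparison, config$n_simulations_pathway, seed)
  pct <- percentile_summaries(comparison, null, config$percentiles)
  report <- differentiating_report(
    comparison, null, mode = config$pathway_threshold_mode,
    threshold_percentile = config$pathway_threshold_percentile
  )
  structure(list(comparison = comparison, null = null, percentiles = pct,
                 report = report),
            class = "pathway_comparison_result")
}

#' @export
print.pathway_comparison_result <- function(x, ...) {
  cat(sprintf(
    "pathway comparison %s vs %s: %d pathways, profile r = %.3f, %d differentiating (threshold %.3g)\n",
    x$comparison$condition_a, x$comparison$condition_b,
    length(x$comparison$pathway_ids), x$comparison$profile_correlation,
    sum(x$report$differentiating), attr(x$report, "threshold")))
  invisible(x)
}

#' Write a pathway comparison (report, null percentiles, curves) as TSVs
#'
#' @param result a `pathway_comparison_result`.
#' @param report_path TSV path for the differentiating report.
#' @param percentile_path optional TSV for per-pathway null percentiles.
#' @param curves_path optional TSV for the density curves (long format).
#' @return `report_path`, invisibly.
#' @export
write_comparison <- function(result, report_path, percentile_path = NULL,
                             curves_path = NULL) {
  utils::write.table(as.data.frame(result$report), report_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(percentile_path)) {
    pv <- result$percentiles$percentile_values
    utils::write.table(data.frame(pathway = rownames(pv), pv, check.names = FALSE),
                       percentile_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(curves_path)) {
    curves <- result$percentiles$curves
    long <- do.call(rbind, lapply(names(curves), function(nm) {
      cbind(curve = nm, curves[[nm]])
    }))
    utils::write.table(long, curves_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report_path)
}
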