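# Dual-track gene-covariate association: Pearson correlation against the
# continuous covariate and pooled-variance Student t between clinically
# defined groups, each gated by a permutation-null local FDR.

# Row-wise Pearson r of X (genes x samples) against one or more covariate
# columns. Returns a genes x ncol(V) matrix of correlations; rows with zero
# variance give NA.
row_pearson <- function(X, V) {
  V <- as.matrix(V)
  n <- ncol(X)
  stopifnot(nrow(V) == n)
  Xc <- X - rowMeans(X)
  Vc <- sweep(V, 2L, colMeans(V))
  sx <- sqrt(rowSums(Xc^2))
  sv <- sqrt(colSums(Vc^2))
  num <- Xc %*% Vc
  r <- sweep(num, 1L, sx, "/")
  r <- sweep(r, 2L, sv, "/")
  r[sx == 0, ] <- NA_real_
  r[, sv == 0] <- NA_real_
  # numerical safety: clamp to [-1, 1]
  r[] <- pmin(1, pmax(-1, r))
  r
}

pearson_p <- function(r, n) {
  df <- n - 2L
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p
}

# Row-wise pooled-variance two-sample t of X columns split by logical
# matrix G (samples x k; TRUE = high group). Returns list(t, m_high, m_low).
row_t <- function(X, G) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  n1 <- colSums(G)
  n2 <- nrow(G) - n1
  S1 <- X %*% G
  Q1 <- (X^2) %*% G
  s_all <- rowSums(X)
  q_all <- rowSums(X^2)
  S2 <- s_all - S1
  Q2 <- q_all - Q1
  m1 <- sweep(S1, 2L, n1, "/")
  m2 <- sweep(S2, 2L, n2, "/")
  ss1 <- Q1 - sweep(m1^2, 2L, n1, "*")
  ss2 <- Q2 - sweep(m2^2, 2L, n2, "*")
  df <- n1 + n2 - 2
  sp2 <- sweep(ss1 + ss2, 2L, df, "/")
  sp2[sp2 < 0] <- 0
  se <- sqrt(sweep(sp2, 2L, 1 / n1 + 1 / n2, "*"))
  t <- (m1 - m2) / se
  # zero pooled variance: equal means -> t = 0; unequal means -> undefined
  zero_var <- se == 0
  eq <- abs(m1 - m2) < 1e-12
  t[zero_var & eq] <- 0
  t[zero_var & !eq] <- NA_real_
  list(t = t, m_high = m1, m_low = m2, df = df)
}

#' Pearson track: correlate each gene with a clinical covariate
#'
#' Computes per-gene Pearson r between log2 housekeeping-normalized
#' expression and a per-sample covariate, with two-sided p-values.
#' Samples missing the covariate are dropped; constant genes are flagged
#' `undefined` and excluded from selection but kept in the result.
#'
#' @param x an `expr_matrix` with `scale = "log2_normalized"`.
#' @param covariate named numeric vector (names = sample ids).
#' @return data frame: gene, track, statistic, p_value, direction, note;
#'   attribute `n_samples`.
#' @export
pearson_track <- function(x, covariate) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2_normalized") {
    stop_with("association tracks run on log2_normalized expression (got '%s')", x$scale)
  }
  if (is.null(names(covariate))) stop_with("`covariate` must be named by sample id")
  keep <- intersect(colnames(x$values), names(covariate)[!is.na(covariate)])
  if (length(keep) < 4L) stop_with("need >= 4 samples with covariate values, got %d", length(keep))
  v <- covariate[keep]
  if (stats::sd(v) == 0) stop_with("covariate is constant across samples")
  X <- x$values[, keep, drop = FALSE]
  r <- drop(row_pearson(X, matrix(v)))
  p <- pearson_p(r, length(keep))
  res <- data.frame(
    gene = rownames(X), track = "pearson", statistic = unname(r),
    p_value = unname(p),
    direction = ifelse(is.na(r), NA_character_, ifelse(r > 0, "higher", "lower")),
    note = ifelse(is.na(r), "undefined: constant gene", ""),
    stringsAsFactors = FALSE
  )
  attr(res, "n_samples") <- length(keep)
  attr(res, "samples") <- keep
  res
}

#' t-test track: compare each gene between two clinical groups
#'
#' Pooled-variance two-sample Student t per gene on log2 expression, with
#' two-sided p-values. Direction is `higher` when the high-covariate group
#' has the larger mean. Genes with zero pooled variance get t = 0 / p = 1
#' when the group means are equal, otherwise they are flagged undefined.
#'
#' @param x an `expr_matrix` with `scale = "log2_normalized"`.
#' @param group_high,group_low disjoint sample-id vectors, each of size >= 2
#'   (e.g. F2 versus F1 plus quiescence for ESR; flare versus quiescence
#'   for joint count).
#' @return data frame: gene, track, statistic, p_value, direction, note.
#' @export
ttest_track <- function(x, group_high, group_low) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2_normalized") {
    stop_with("association tracks run on log2_normalized expression (got '%s')", x$scale)
  }
  group_high <- intersect(colnames(x$values), group_high)
  group_low <- intersect(colnames(x$values), group_low)
  if (length(intersect(group_high, group_low))) stop_with("groups overlap")
  if (length(group_high) < 2L || length(group_low) < 2L) {
    stop_with("both groups need >= 2 samples (got %d and %d)",
              length(group_high), length(group_low))
  }
  X <- x$values[, c(group_high, group_low), drop = FALSE]
  G <- matrix(c(rep(TRUE, length(group_high)), rep(FALSE, length(group_low))))
  tt <- row_t(X, G)
  t <- drop(tt$t)
  df <- tt$df[1L]
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  res <- data.frame(
    gene = rownames(X), track = "ttest", statistic = unname(t),
    p_value = unname(p),
    direction = ifelse(is.na(t), NA_character_,
                       ifelse(drop(tt$m_high) > drop(tt$m_low), "higher", "lower")),
    note = ifelse(is.na(t), "undefined: zero pooled variance", ""),
    stringsAsFactors = FALSE
  )
  res$direction[!is.na(t) & t == 0 & drop(tt$m_high) == drop(tt$m_low)] <- NA_character_
  attr(res, "df") <- df
  attr(res, "groups") <- list(high = group_high, low = group_low)
  res
}

#' Build a permutation null for an association track
#'
#' Permutes the covariate values (Pearson track) or the group labels
#' (t-test track) across samples, keeping the expression matrix fixed, and
#' recomputes every gene's statistic for each permutation. Permuting labels
#' rather than expression preserves the inter-gene correlation structure.
#'
#' @param x an `expr_matrix` with `scale = "log2_normalized"`.
#' @param covariate named numeric covariate (Pearson track), or `NULL`.
#' @param group_high,group_low sample-id groups (t-test track), or `NULL`.
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed; the null is deterministic given the seed.
#' @return list of class `permutation_null`: `stats` (genes x permutations),
#'   `scheme`, `seed`.
#' @export
build_null <- function(x, covariate = NULL, group_high = NULL, group_low = NULL,
                       n_permutations = 100L, seed = 1L) {
  if (n_permutations < 1L) stop_with("n_permutations must be >= 1")
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(covariate)) {
    keep <- intersect(colnames(x$values), names(covariate)[!is.na(covariate)])
    v <- covariate[keep]
    X <- x$values[, keep, drop = FALSE]
    n <- length(keep)
    P <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) v[sample.int(n)], numeric(n))
    })
    stats <- row_pearson(X, P)
    scheme <- "covariate permutation (pearson)"
  } else {
    group_high <- intersect(colnames(x$values), group_high)
    group_low <- intersect(colnames(x$values), group_low)
    ids <- c(group_high, group_low)
    X <- x$values[, ids, drop = FALSE]
    n <- length(ids)
    n1 <- length(group_high)
    G <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        g <- logical(n); g[sample.int(n, n1)] <- TRUE; g
      }, logical(n))
    })
    stats <- row_t(X, G)$t
    scheme <- "group-label permutation (ttest)"
  }
  colnames(stats) <- paste0("perm", seq_len(n_permutations))
  structure(list(stats = stats, scheme = scheme, seed = as.integer(seed)),
            class = "permutation_null")
}

#' Global false discovery rate curve from a permutation null
#'
#' For a threshold t on the absolute statistic, gFDR(t) is the mean number
#' of null statistics at or above t per permutation, divided by the number
#' of observed statistics at or above t (at least 1).
#'
#' @param observed numeric vector of observed statistics (NA allowed).
#' @param null a `permutation_null` (or a numeric matrix of null statistics).
#' @param thresholds thresholds on |statistic|; defaults to the sorted
#'   observed |statistics|.
#' @return data frame: threshold, n_observed, mean_n_null, gfdr.
#' @export
gfdr_curve <- function(observed, null, thresholds = NULL) {
  nul <- if (inherits(null, "permutation_null")) null$stats else null
  if (!length(nul)) stop_with("empty permutation null")
  B <- ncol(nul)
  obs <- abs(observed[!is.na(observed)])
  thresholds <- sort(unique(thresholds %||% obs))
  an <- abs(as.numeric(nul))
  an <- sort(an[is.finite(an)])
  obs_sorted <- sort(obs)
  # counts of values >= t via sorted search (#{x >= t} = N - #{x < t})
  n_obs <- length(obs_sorted) -
    findInterval(thresholds, obs_sorted, left.open = TRUE)
  mean_null <- (length(an) - findInterval(thresholds, an, left.open = TRUE)) / B
  data.frame(threshold = thresholds, n_observed = n_obs,
             mean_n_null = mean_null,
             gfdr = ifelse(n_obs == 0 & mean_null == 0, 0,
                           mean_null / pmax(1, n_obs)))
}

# Reflected Gaussian KDE for densities of absolute statistics: estimate on
# the sign-symmetrized sample, so f(|s|) = 2 * g(s) without boundary bias
# at zero. Bandwidth: Silverman (bw.nrd0) on the absolute values.
kde_abs <- function(x, at) {
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) stop_with("degenerate density: statistics have no spread")
  lo <- -4 * bw
  hi <- max(c(x, at)) + 4 * bw
  d <- stats::density(c(x, -x), bw = bw, n = 2048, from = lo, to = hi)
  2 * stats::approx(d$x, d$y, xout = at, rule = 2)$y
}

#' Local false discovery rate from observed and permutation-null statistics
#'
#' Empirical-Bayes density-ratio estimate: lfdr(s) = min(1, pi0 f0(|s|) /
#' f(|s|)), where f0 is a reflected Gaussian kernel density over the pooled
#' absolute null statistics, f the same estimate over the observed absolute
#' statistics, and pi0 = min(1, 2 * proportion of observed |statistics|
#' below the pooled-null median) (central matching). By default the
#' estimate is regularized to be non-increasing in |s| (each gene receives
#' the maximum lfdr among genes with larger-or-equal |statistic|), which
#' removes spurious dips without ever making a gene look more significant.
#'
#' @param observed numeric vector of observed statistics (NA allowed; NA
#'   genes receive NA lfdr).
#' @param null a `permutation_null` or numeric matrix; at least 50 pooled
#'   finite null values are required.
#' @param monotone apply the non-increasing regularization (default TRUE).
#' @return list of class `lfdr_fit`: `lfdr` (aligned with `observed`),
#'   `pi0`, `f0`, `f` (densities at the observed points), `bw_obs`,
#'   `bw_null`.
#' @export
local_fdr <- function(observed, null, monotone = TRUE) {
  nul <- if (inherits(null, "permutation_null")) null$stats else null
  an <- abs(as.numeric(nul))
  an <- an[is.finite(an)]
  if (length(an) < 50L) {
    stop_with("need >= 50 pooled null statistics (got %d); increase n_permutations",
              length(an))
  }
  obs <- abs(observed)
  ok <- is.finite(obs)
  if (sum(ok) < 2L) stop_with("need >= 2 finite observed statistics")
  if (stats::sd(obs[ok]) == 0 || stats::sd(an) == 0) {
    stop_with("degenerate densities: all statistics identical")
  }
  pi0 <- min(1, 2 * mean(obs[ok] < stats::median(an)))
  f0 <- kde_abs(an, obs[ok])
  f <- kde_abs(obs[ok], obs[ok])
  lf <- pmin(1, pmax(0, pi0 * f0 / pmax(f, .Machine$double.xmin)))
  if (monotone) {
    ord <- order(obs[ok])
    lf[ord] <- rev(cummax(rev(lf[ord])))
  }
  lfdr <- rep(NA_real_, length(observed))
  lfdr[ok] <- lf
  structure(list(lfdr = lfdr, pi0 = pi0,
                 f0 = replace(rep(NA_real_, length(observed)), ok, f0),
                 f = replace(rep(NA_real_, length(observed)), ok, f),
                 bw_null = stats::bw.nrd0(an), bw_obs = stats::bw.nrd0(obs[ok])),
            class = "lfdr_fit")
}

#' Run one association track end to end (statistic, null, gFDR, lFDR)
#'
#' @param x `expr_matrix` on the log2 scale.
#' @param covariate named numeric covariate (Pearson track) or `NULL`.
#' @param group_high,group_low sample groups (t-test track) or `NULL`.
#' @param config a [run_config()].
#' @param seed seed for the permutation null.
#' @return data frame with columns gene, track, statistic, p_value,
#'   direction, gfdr_at_stat, lfdr, selected, note.
#' @export
association_track <- function(x, covariate = NULL, group_high = NULL,
                              group_low = NULL, config = run_config(),
                              seed = config$rng_seed) {
  res <- if (!is.null(covariate)) {
    pearson_track(x, covariate)
  } else {
    ttest_track(x, group_high, group_low)
  }
  null <- build_null(x, covariate = covariate, group_high = group_high,
                     group_low = group_low,
                     n_permutations = config$n_permutations_gene, seed = seed)
  curve <- gfdr_curve(res$statistic, null)
  idx <- match(abs(res$statistic), curve$threshold)
  res$gfdr_at_stat <- curve$gfdr[idx]
  fit <- local_fdr(res$statistic, null)
  res$lfdr <- fit$lfdr
  res$selected <- !is.na(res$lfdr) & res$lfdr <= config$lfdr_cutoff
  attr(res, "null") <- null
  attr(res, "pi0") <- fit$pi0
  res
}

#' Combine the Pearson and t-test tracks into one gene list
#'
#' Union semantics: a gene is in the combined list when either track
#' selected it. Per-gene provenance records which track(s) selected it;
#' direction conflicts between tracks are flagged, and a gene undefined in
#' one track can still be selected by the other.
#'
#' @param pearson_res,ttest_res track result data frames (from
#'   [association_track()] or with compatible columns).
#' @param covariate_name label for the covariate (e.g. `"ESR"`).
#' @return data frame of class `combined_gene_list`: gene, selected_by,
#'   direction, direction_conflict; one row per selected gene.
#' @export
combine_tracks <- function(pearson_res, ttest_res, covariate_name = "covariate") {
  sel_p <- pearson_res$gene[pearson_res$selected %in% TRUE]
  sel_t <- ttest_res$gene[ttest_res$selected %in% TRUE]
  union_genes <- union(sel_p, sel_t)
  if (!length(union_genes)) {
    out <- data.frame(gene = character(), selected_by = character(),
                      direction = character(), direction_conflict = logical(),
                      stringsAsFactors = FALSE)
  } else {
    dir_p <- stats::setNames(pearson_res$direction, pearson_res$gene)[union_genes]
    dir_t <- stats::setNames(ttest_res$direction, ttest_res$gene)[union_genes]
    by <- ifelse(union_genes %in% sel_p & union_genes %in% sel_t, "pearson+ttest",
                 ifelse(union_genes %in% sel_p, "pearson", "ttest"))
    conflict <- !is.na(dir_p) & !is.na(dir_t) & dir_p != dir_t
    direction <- ifelse(union_genes %in% sel_p, dir_p, dir_t)
    out <- data.frame(gene = union_genes, selected_by = by,
                      direction = unname(direction),
                      direction_conflict = unname(conflict),
                      stringsAsFactors = FALSE)
  }
  attr(out, "covariate") <- covariate_name
  class(out) <- c("combined_gene_list", "data.frame")
  out
}

#' Dual-track association of a covariate within one disease cohort
#'
#' Orchestrates both tracks for a covariate: the Pearson track against the
#' covariate's values and the t-test track between the covariate's clinical
#' grouping (ESR: F2 versus F1 plus quiescence; joint count: flare versus
#' quiescence), each gated at lFDR <= the configured cutoff, then combines
#' the selections.
#'
#' @param x `expr_matrix` (normalized or log2; normalized input is
#'   log2-transformed internally).
#' @param clinical a `jia_clinical` data frame.
#' @param grouping a [sample_grouping()] for the same samples.
#' @param covariate `"esr"` or `"joint_count"`.
#' @param disease cohort to analyze, `"SJIA"` or `"POLY"`.
#' @param config a [run_config()].
#' @return list of class `association_analysis`: `pearson`, `ttest`
#'   (per-track results), `combined`, `covariate`, `disease`, `n_samples`.
#' @export
associate <- function(x, clinical, grouping, covariate = c("esr", "joint_count"),
                      disease = c("SJIA", "POLY"), config = run_config()) {
  covariate <- match.arg(covariate)
  disease <- match.arg(disease)
  stopifnot(inherits(clinical, "jia_clinical"), inherits(grouping, "sample_grouping"))
  if (x$scale == "normalized") x <- log2_expr(x)
  keep <- clinical$sample_id[clinical$disease == disease]
  keep <- intersect(colnames(x$values), keep)
  if (!length(keep)) stop_with("no %s samples present in the expression matrix", disease)
  xs <- subset_expr(x, samples = keep)
  cl <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  gr <- grouping[match(keep, grouping$sample_id), , drop = FALSE]
  cov_vals <- stats::setNames(cl[[covariate]], cl$sample_id)
  if (covariate == "esr") {
    high <- gr$sample_id[gr$esr_partition %in% "F2"]
    low <- gr$sample_id[gr$esr_partition %in% c("F1", "Q")]
  } else {
    high <- gr$sample_id[gr$state == "F"]
    low <- gr$sample_id[gr$state == "Q"]
  }
  seed_p <- derive_seed(config$rng_seed, paste0("pearson_", disease, "_", covariate))
  seed_t <- derive_seed(config$rng_seed, paste0("ttest_", disease, "_", covariate))
  pres <- association_track(xs, covariate = cov_vals, config = config, seed = seed_p)
  tres <- association_track(xs, group_high = high, group_low = low,
                            config = config, seed = seed_t)
  combined <- combine_tracks(pres, tres, toupper(covariate))
  structure(list(pearson = pres, ttest = tres, combined = combined,
                 covariate = covariate, disease = disease,
                 n_samples = length(keep),
                 groups = list(high = high, low = low)),
            class = "association_analysis")
}

#' @export
print.association_analysis <- function(x, ...) {
  cat(sprintf(
    "association_analysis: %s ~ %s (n = %d)\n  pearson selected: %d\n  ttest selected: %d\n  combined: %d\n",
    x$disease, x$covariate, x$n_samples,
    sum(x$pearson$selected, na.rm = TRUE), sum(x$ttest$selected, na.rm = TRUE),
    nrow(x$combined)))
  invisible(x)
}

#' Write association results as TSV
#'
#' One row per gene and track, with statistic, p, gFDR, lFDR and selection
#' flag; the combined list is written alongside.
#'
#' @param analysis an `association_analysis`.
#' @param path output TSV path for the per-track table.
#' @param combined_path optional output path for the combined gene list.
#' @return `path`, invisibly.
#' @export
write_association <- function(analysis, path, combined_path = NULL) {
  full <- rbind(analysis$pearson, analysis$ttest)
  full$covariate <- analysis$covariate
  full$disease <- analysis$disease
  utils::write.table(full, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(combined_path)) {
    utils::write.table(as.data.frame(analysis$combined), combined_path,
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}
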