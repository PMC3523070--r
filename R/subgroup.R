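#' Joint-count correlation of candidate genes within SAF and AF subgroups
#'
#' Within SJIA flare samples, correlates log2 expression of a supplied
#' joint-count-associated gene list with the active joint count separately
#' in the systemic-plus-arthritis (SAF) and arthritis-only (AF) subgroups.
#' Significance is gated on the raw two-sided p-value (default 0.05; no
#' FDR layer at this stage), and significant genes are returned in order
#' of decreasing significance (ascending p).
#'
#' @param x `expr_matrix` (normalized or log2 scale).
#' @param clinical a `jia_clinical` data frame.
#' @param grouping a [sample_grouping()] carrying the `saf_af` labels.
#' @param jc_genes character vector of genes to test (typically the
#'   joint-count combined gene list from [associate()]).
#' @param p_cutoff raw two-sided p gate (default 0.05).
#' @param subgroups which subgroups to analyze (default both).
#' @return data frame of class `subgroup_correlation`: subgroup, gene, r,
#'   p_value, significant, direction; sorted by subgroup then ascending p.
#'   Attribute `n_samples` records each subgroup's size.
#' @export
subgroup_jc_correlation <- function(x, clinical, grouping, jc_genes,
                                    p_cutoff = 0.05,
                                    subgroups = c("SAF", "AF")) {
  stopifnot(inherits(clinical, "jia_clinical"), inherits(grouping, "sample_grouping"))
  if (x$scale == "normalized") x <- log2_expr(x)
  missing_g <- setdiff(jc_genes, rownames(x$values))
  if (length(missing_g)) {
    stop_with("gene(s) absent from expression matrix: %s",
              paste(missing_g, collapse = ", "))
  }
  n_used <- integer(0)
  res <- lapply(subgroups, function(sg) {
    ids <- grouping$sample_id[grouping$saf_af == sg]
    ids <- intersect(colnames(x$values), ids)
    jc <- clinical$joint_count[match(ids, clinical$sample_id)]
    ok <- !is.na(jc)
    ids <- ids[ok]; jc <- jc[ok]
    if (length(ids) < 4L) {
      stop_with("subgroup %s has %d samples with joint counts; need >= 4",
                sg, length(ids))
    }
    if (stats::sd(jc) == 0) stop_with("joint count is constant within subgroup %s", sg)
    n_used[[sg]] <<- length(ids)
    X <- x$values[jc_genes, ids, drop = FALSE]
    r <- drop(row_pearson(X, matrix(jc)))
    p <- pearson_p(r, length(ids))
    data.frame(subgroup = sg, gene = jc_genes, r = unname(r),
               p_value = unname(p),
               significant = !is.na(p) & p <= p_cutoff,
               direction = ifelse(is.na(r), NA_character_,
                                  ifelse(r > 0, "positive", "negative")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(match(out$subgroup, subgroups), out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n_used
  attr(out, "p_cutoff") <- p_cutoff
  class(out) <- c("subgroup_correlation", "data.frame")
  out
}

#' Write subgroup correlations as TSV
#'
#' @param x a `subgroup_correlation` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subgroup <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
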