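#' Read a raw kinetic-PCR assay table with replicate columns
#'
#' Long TSV with columns `gene_id`, `sample_id`, then one column per
#' replicate reaction (typically two, SYBR-green duplicates). Missing
#' replicates may be empty; at least one positive measurement is required
#' per (gene, sample) pair.
#'
#' @param path file path.
#' @return a data frame of class `raw_assay` (gene_id, sample_id, rep columns).
#' @export
read_raw_assay <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           quote = "", comment.char = "",
                           na.strings = c("NA", ""))
  if (!all(c("gene_id", "sample_id") %in% colnames(raw))) {
    stop_with("raw assay table needs gene_id and sample_id columns")
  }
  rep_cols <- setdiff(colnames(raw), c("gene_id", "sample_id"))
  if (!length(rep_cols)) stop_with("raw assay table needs >= 1 replicate column")
  for (rc in rep_cols) raw[[rc]] <- as.numeric(raw[[rc]])
  validate_raw_assay(raw, rep_cols)
}

validate_raw_assay <- function(raw, rep_cols) {
  reps <- as.matrix(raw[rep_cols])
  if (any(reps <= 0, na.rm = TRUE)) {
    i <- which(apply(reps <= 0, 1L, any, na.rm = TRUE))[1L]
    stop_with("non-positive raw measurement at gene '%s', sample '%s'",
              raw$gene_id[i], raw$sample_id[i])
  }
  if (any(rowSums(!is.na(reps)) == 0L)) {
    i <- which(rowSums(!is.na(reps)) == 0L)[1L]
    stop_with("no replicate measurement at gene '%s', sample '%s'",
              raw$gene_id[i], raw$sample_id[i])
  }
  dup <- duplicated(raw[c("gene_id", "sample_id")])
  if (any(dup)) {
    stop_with("duplicated (gene, sample) rows in raw table: %s/%s",
              raw$gene_id[which(dup)[1L]], raw$sample_id[which(dup)[1L]])
  }
  class(raw) <- c("raw_assay", "data.frame")
  raw
}

#' Average duplicate kinetic-PCR reactions
#'
#' Collapses replicate measurements to their per-(gene, sample) arithmetic
#' mean, producing a raw-scale expression matrix.
#'
#' @param raw a `raw_assay` table.
#' @param housekeeping_ids housekeeping gene ids present in the table.
#' @return an `expr_matrix` with `scale = "raw"`.
#' @export
average_replicates <- function(raw, housekeeping_ids) {
  stopifnot(inherits(raw, "raw_assay"))
  rep_cols <- setdiff(colnames(raw), c("gene_id", "sample_id"))
  reps <- as.matrix(raw[rep_cols])
  m <- rowMeans(reps, na.rm = TRUE)
  gene_ids <- unique(raw$gene_id)
  sample_ids <- unique(raw$sample_id)
  vals <- matrix(NA_real_, length(gene_ids), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  vals[cbind(match(raw$gene_id, gene_ids), match(raw$sample_id, sample_ids))] <- m
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_with("no measurement for gene '%s' in sample '%s'",
              gene_ids[bad[1L]], sample_ids[bad[2L]])
  }
  expr_matrix(vals, housekeeping_ids, "raw")
}

#' Normalize a raw expression matrix against its housekeeping genes
#'
#' Divides each sample's values by the geometric mean of that sample's
#' housekeeping-gene measurements, yielding housekeeping-normalized units.
#' After normalization the per-sample geometric mean of the housekeeping
#' genes is exactly 1, and rescaling a whole sample's raw values leaves its
#' normalized values unchanged.
#'
#' @param x an `expr_matrix` with `scale = "raw"`.
#' @return an `expr_matrix` with `scale = "normalized"`.
#' @export
housekeeping_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw") stop_with("housekeeping_normalize() expects a raw matrix")
  hk <- x$values[x$housekeeping, , drop = FALSE]
  bad <- colnames(hk)[apply(hk, 2L, function(v) any(!is.finite(v) | v <= 0))]
  if (length(bad)) {
    stop_with("housekeeping gene non-positive or missing in sample(s): %s",
              paste(bad, collapse = ", "))
  }
  geo <- exp(colMeans(log(hk)))
  expr_matrix(sweep(x$values, 2L, geo, "/"), x$housekeeping, "normalized")
}

#' Per-gene fold ratios between two sample groups, with log2 density
#'
#' Computes each gene's ratio of linear-scale group means (A over B) and a
#' Gaussian-kernel density (Silverman bandwidth) of the log2 ratios,
#' emulating the fold-change probability-density diagnostic used to show
#' that selected genes vary between clinical groups. A quartile mode
#' forms the groups from the first and third quartiles of a per-sample
#' covariate (type-7 quantiles): group A = covariate >= Q3, group B =
#' covariate <= Q1.
#'
#' @param x an `expr_matrix` on a linear (raw or normalized) scale.
#' @param group_a,group_b disjoint non-empty character vectors of sample ids.
#' @param covariate optional named numeric vector (names = sample ids);
#'   when supplied, groups are derived from its quartiles and
#'   `group_a`/`group_b` must be omitted.
#' @param genes optional gene subset to restrict the diagnostic to.
#' @return a list of class `fold_ratio_result` with elements `fold_ratio`
#'   (named per-gene ratio), `log2_ratio`, `grid`, `density`, `groups`.
#' @export
fold_ratio_density <- function(x, group_a = NULL, group_b = NULL,
                               covariate = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "log2_normalized") {
    stop_with("fold_ratio_density() expects linear-scale values")
  }
  if (!is.null(covariate)) {
    if (!is.null(group_a) || !is.null(group_b)) {
      stop_with("supply either explicit groups or a covariate, not both")
    }
    cov <- covariate[!is.na(covariate)]
    qs <- stats::quantile(cov, c(0.25, 0.75), type = 7, names = FALSE)
    group_b <- names(cov)[cov <= qs[1L]]
    group_a <- names(cov)[cov >= qs[2L]]
  }
  if (!length(group_a) || !length(group_b)) stop_with("both groups must be non-empty")
  if (length(intersect(group_a, group_b))) {
    stop_with("groups overlap: %s", paste(intersect(group_a, group_b), collapse = ", "))
  }
  missing_s <- setdiff(c(group_a, group_b), colnames(x$values))
  if (length(missing_s)) stop_with("unknown sample id(s): %s", paste(missing_s, collapse = ", "))
  v <- x$values[genes %||% rownames(x$values), , drop = FALSE]
  fr <- rowMeans(v[, group_a, drop = FALSE]) / rowMeans(v[, group_b, drop = FALSE])
  lr <- log2(fr)
  d <- if (stats::sd(lr) > 0) {
    stats::density(lr, bw = "nrd0", n = 512)
  } else {
    # all ratios identical: represent as a narrow kernel around the value
    stats::density(lr, bw = max(abs(lr[1L]) * 1e-3, 1e-3), n = 512)
  }
  structure(list(fold_ratio = fr, log2_ratio = lr, grid = d$x, density = d$y,
                 groups = list(a = group_a, b = group_b)),
            class = "fold_ratio_result")
}

#' @export
print.fold_ratio_result <- function(x, ...) {
  cat(sprintf("fold_ratio_result: %d genes, groups %d vs %d, median ratio %.3g\n",
              length(x$fold_ratio), length(x$groups$a), length(x$groups$b),
              stats::median(x$fold_ratio)))
  invisible(x)
}

#' Write a fold-ratio density curve as TSV
#'
#' @param x a `fold_ratio_result`.
#' @param path output path (columns `log2_ratio_grid`, `density`).
#' @return `path`, invisibly.
#' @export
write_density <- function(x, path) {
  utils::write.table(
    data.frame(log2_ratio_grid = x$grid, density = x$density),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
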