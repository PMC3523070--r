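#' Expression matrix for a kinetic-PCR gene panel
#'
#' A genes x samples numeric matrix carrying the panel's designated
#' housekeeping (reference) genes and a scale tag. Values are either raw
#' assay units, housekeeping-normalized units (expression divided by the
#' per-sample geometric mean of the reference genes), or log2 of the
#' normalized units.
#'
#' @param values numeric matrix, rows = genes (rownames), cols = samples
#'   (colnames).
#' @param housekeeping character vector of housekeeping gene ids; must be a
#'   non-empty subset of the row names.
#' @param scale one of `"raw"`, `"normalized"`, `"log2_normalized"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, housekeeping,
                        scale = c("raw", "normalized", "log2_normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_with("`values` must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop_with("`values` must have gene rownames and sample colnames")
  }
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g)) {
    stop_with("duplicate gene ids: %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop_with("duplicate sample ids: %s", paste(dup_s, collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_with("non-finite expression value at gene '%s', sample '%s'",
              genes[bad[1L]], samples[bad[2L]])
  }
  if (scale %in% c("raw", "normalized") && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    stop_with("non-positive value on %s scale at gene '%s', sample '%s'",
              scale, genes[bad[1L]], samples[bad[2L]])
  }
  housekeeping <- unique(as.character(housekeeping))
  if (length(housekeeping) < 1L) {
    stop_with("at least one housekeeping gene is required")
  }
  missing_hk <- setdiff(housekeeping, genes)
  if (length(missing_hk)) {
    stop_with("housekeeping gene(s) absent from panel: %s",
              paste(missing_hk, collapse = ", "))
  }
  structure(
    list(values = values, housekeeping = housekeeping, scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale, %d housekeeping)\n",
              nrow(x$values), ncol(x$values), x$scale, length(x$housekeeping)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample ids of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of ids.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname genes
#' @export
samples <- function(x) colnames(x$values)

#' Subset an expression matrix by gene and/or sample ids
#'
#' @param x an `expr_matrix`.
#' @param genes,samples character ids to keep (default: all). Housekeeping
#'   genes not retained are dropped from the housekeeping set; at least one
#'   must remain.
#' @return an `expr_matrix`.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  g <- genes %||% rownames(x$values)
  s <- samples %||% colnames(x$values)
  missing_g <- setdiff(g, rownames(x$values))
  if (length(missing_g)) {
    stop_with("unknown gene id(s): %s", paste(missing_g, collapse = ", "))
  }
  missing_s <- setdiff(s, colnames(x$values))
  if (length(missing_s)) {
    stop_with("unknown sample id(s): %s", paste(missing_s, collapse = ", "))
  }
  hk <- intersect(x$housekeeping, g)
  if (!length(hk)) hk <- x$housekeeping[1L] # keep object valid; hk row dropped from values is disallowed
  if (!all(hk %in% g)) {
    stop_with("cannot drop every housekeeping gene from an expr_matrix")
  }
  expr_matrix(x$values[g, s, drop = FALSE], hk, x$scale)
}

#' Log2-transform a housekeeping-normalized expression matrix
#'
#' Association statistics in this pipeline are computed on log2 of the
#' housekeeping-normalized units, which symmetrizes multiplicative qPCR
#' variation.
#'
#' @param x an `expr_matrix` on the `normalized` scale.
#' @return an `expr_matrix` on the `log2_normalized` scale.
#' @export
log2_expr <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "log2_normalized") return(x)
  if (x$scale != "normalized") {
    stop_with("log2_expr() expects a normalized matrix, got scale '%s'", x$scale)
  }
  expr_matrix(log2(x$values), x$housekeeping, "log2_normalized")
}

#' Read an expression table
#'
#' Expects a TSV with gene rows and sample columns: first column holds gene
#' ids, the header row holds sample ids, cells are '.'-decimal numbers.
#'
#' @param path file path.
#' @param housekeeping_ids character vector of housekeeping gene ids that
#'   must be present in the table.
#' @param scale scale of the stored values (default `"normalized"`).
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, housekeeping_ids, scale = "normalized") {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) stop_with("expression table needs a gene id column plus >= 1 sample column")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop_with("duplicate gene ids in %s: %s", path, paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop_with("duplicate sample ids in %s: %s", path, paste(dup_s, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "NA")
    if (length(bad)) {
      stop_with("non-numeric cell '%s' at gene '%s', sample '%s' in %s",
                cell[bad[1L]], gene_ids[bad[1L]], sample_ids[j], path)
    }
    vals[, j] <- num
  }
  expr_matrix(vals, housekeeping_ids, scale)
}

#' Write an expression table
#'
#' Values are written at full double precision so a write/read round trip is
#' bitwise exact.
#'
#' @param x an `expr_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), stringsAsFactors = FALSE)
  for (s in colnames(x$values)) df[[s]] <- format_full(x$values[, s])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
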