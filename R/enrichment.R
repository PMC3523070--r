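#' Hypergeometric over-representation of a gene list in gene sets
#'
#' Scores each set for over-representation of the selected list against an
#' explicit universe (default: the full analyzed panel) with the one-sided
#' upper-tail hypergeometric probability P(X >= k), a transparent
#' equivalent of proprietary canonical-pathway scoring that preserves the
#' -log10 P interface. Sets with no members in the universe are skipped
#' with a warning.
#'
#' @param selected character vector of selected genes; must lie within
#'   `universe`.
#' @param sets a `gene_set_collection`.
#' @param universe character vector of all analyzable genes.
#' @param condition label recorded on each row (e.g. `"SJIA_ESR"`).
#' @return data frame of class `pathway_scores`: set_id, condition, k
#'   (overlap), K (set size in universe), n (selected size), N (universe
#'   size), p_value, neglog10p, overlap_genes (semicolon-joined).
#' @export
enrich <- function(selected, sets, universe, condition = "condition") {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_with("empty universe")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    stop_with("selected gene(s) outside the universe: %s",
              paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets$sets), function(id) {
    members <- intersect(sets$sets[[id]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    overlap <- intersect(members, selected)
    k <- length(overlap)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, condition = condition, k = k, K = K, n = n, N = N,
               p_value = p, neglog10p = -log10(p),
               overlap_genes = paste(overlap, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  skipped <- names(sets$sets)[vapply(rows, is.null, TRUE)]
  if (length(skipped)) {
    warning(sprintf("set(s) with no members in universe skipped: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  class(out) <- c("pathway_scores", "data.frame")
  out
}

#' Summarize per-pathway expression direction
#'
#' Labels a pathway `higher` (`lower`) when more than a threshold fraction
#' (default 2/3) of its overlap genes move up (down) with the higher
#' covariate value; ties and intermediate splits are `mixed`; empty
#' overlaps are `none`.
#'
#' @param overlap_genes character vector of overlap genes for one pathway.
#' @param directions named character vector (`"higher"`/`"lower"`) per gene.
#' @param threshold majority fraction required, in `[0.5, 1]`.
#' @return one of `"higher"`, `"lower"`, `"mixed"`, `"none"`.
#' @export
direction_summary <- function(overlap_genes, directions, threshold = 2 / 3) {
  if (!length(overlap_genes)) return("none")
  miss <- setdiff(overlap_genes, names(directions))
  d <- directions[overlap_genes]
  if (length(miss) || anyNA(d)) {
    stop_with("missing direction for gene(s): %s",
              paste(union(miss, overlap_genes[is.na(d)]), collapse = ", "))
  }
  frac_hi <- mean(d == "higher")
  if (frac_hi > threshold) "higher" else if (1 - frac_hi > threshold) "lower" else "mixed"
}

#' Score one condition's pathways: enrichment plus direction
#'
#' Convenience wrapper running [enrich()] on a combined gene list and
#' annotating each pathway with its [direction_summary()].
#'
#' @param combined a `combined_gene_list` (gene, direction columns).
#' @param sets a `gene_set_collection`.
#' @param universe gene universe (default: the panel used downstream).
#' @param condition condition label.
#' @param direction_threshold see [direction_summary()].
#' @return a `pathway_scores` data frame with a `direction` column.
#' @export
score_condition <- function(combined, sets, universe, condition,
                            direction_threshold = 2 / 3) {
  scores <- enrich(combined$gene, sets, universe, condition)
  dirs <- stats::setNames(combined$direction, combined$gene)
  scores$direction <- vapply(strsplit(scores$overlap_genes, ";", fixed = TRUE),
                             function(g) direction_summary(g[nzchar(g)], dirs,
                                                           direction_threshold),
                             "")
  scores
}

#' Write pathway scores as TSV
#'
#' @param scores a `pathway_scores` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
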