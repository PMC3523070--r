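#' Gene-set collection
#'
#' A named list of deduplicated member-gene vectors with per-set
#' descriptions, used as the canonical-pathway catalogue for
#' over-representation scoring. Supplied and stored in GMT format.
#'
#' @param sets named list of character vectors (member gene ids).
#' @param descriptions character vector of per-set descriptions, recycled.
#' @param universe optional explicit gene universe.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_with("`sets` must be a named list")
  }
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) stop_with("duplicate set ids: %s", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  empty <- names(sets)[vapply(sets, length, 0L) == 0L]
  if (length(empty)) stop_with("empty gene set(s): %s", paste(empty, collapse = ", "))
  descriptions <- rep_len(as.character(descriptions %||% ""), length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions,
                 universe = if (!is.null(universe)) unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, 0L)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x$sets), min(sizes), max(sizes),
              if (is.null(x$universe)) "" else sprintf(", universe %d genes", length(x$universe))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' Each line: set id, description, then one or more member genes,
#' tab-separated. Duplicate members within a set are stored once.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_with("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L)) {
    stop_with("malformed GMT line(s) (need id, description, >= 1 member): line %s",
              paste(which(nf < 3L), collapse = ", "))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  if (any(vapply(members, length, 0L) == 0L)) {
    stop_with("GMT set with no members: %s",
              paste(ids[vapply(members, length, 0L) == 0L], collapse = ", "))
  }
  names(members) <- ids
  gene_set_collection(members, desc)
}

#' Write a gene-set collection to a GMT file
#'
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$descriptions[[id]], x$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
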