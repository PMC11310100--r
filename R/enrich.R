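#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, member genes. Parsed with
#' `fgsea::gmtPathways`; descriptions are not retained.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene sets).
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between the query gene
#' list and each set: with universe size N, set size K, query size n and
#' overlap k, `p = P(X >= k)` for X hypergeometric(N, K, n). Sets are
#' first intersected with the universe; query genes outside the universe
#' are dropped and counted. Benjamini-Hochberg correction is applied
#' across all sets tested, and rows are sorted by p. This is a local,
#' database-agnostic stand-in for web-service GO enrichment: supply any
#' GMT collection; the universe defaults to the genes actually eligible
#' for selection (e.g. the post-filtering retained list), a
#' selection-consistent background.
#'
#' @param queryGenes character vector of genes of interest.
#' @param collection named list of gene sets (e.g. [readGmt()] output),
#'   optionally with a category attached per set via `categories`.
#' @param universe background gene universe.
#' @param categories optional named character vector (per set) recorded
#'   in the output.
#' @return data.frame of class `EnrichmentTable` with columns
#'   `set, category, k, K, n, N, p, q`, sorted by p; attribute
#'   `"nDroppedQuery"` counts query genes outside the universe.
#' @export
oraTest <- function(queryGenes, collection, universe,
                    categories = NULL) {
  universe <- unique(universe)
  query <- unique(queryGenes)
  dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  if (!length(query)) stop("empty query after intersecting with the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    if (!length(set)) return(NULL)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm,
               category = if (!is.null(categories)) categories[[nm]] else NA,
               k = k, K = K, n = n, N = N, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$q <- bhAdjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nDroppedQuery") <- dropped
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}
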