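#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) where X counts annotated genes in a sample of `n` drawn
#' without replacement from a universe of `N` genes of which `K` are
#' annotated. This is the standard over-representation test for gene-set
#' enrichment.
#'
#' @param k observed overlap, 0 <= k <= min(K, n).
#' @param K term size; n query size; N universe size.
#' @param n,N see above.
#' @return p-value in (0, 1].
#' @export
hypergeomPValue <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts")
  if (k == 0L) return(1.0)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene query against annotation sets
#'
#' Computes the upper-tail hypergeometric p-value of each term overlapping
#' the query, with optional Benjamini-Hochberg adjustment. Query ids not in
#' the universe are dropped with a warning. The enrichment score is
#' `-log10(p)`, matching the common bar-chart x-axis of enrichment plots.
#'
#' @param query character vector of gene ids.
#' @param sets a [GeneSets-class].
#' @param alpha significance level for the `significant` flag, default 0.05
#'   on the raw p by default.
#' @param adjust `"none"` (default; raw p against `alpha`) or `"bh"`
#'   (Benjamini-Hochberg adjusted p against `alpha`).
#' @return data.frame, one row per term with overlap k >= 1, sorted by
#'   ascending p (ties by term id): columns term_id, term_name, k, K, n, N,
#'   p_value, p_adjusted, enrichment_score, significant.
#' @export
enrichTargets <- function(query, sets, alpha = 0.05, adjust = c("none", "bh")) {
  stopifnot(is(sets, "GeneSets"))
  adjust <- match.arg(adjust)
  query <- unique(as.character(query))
  outside <- setdiff(query, sets@universe)
  if (length(outside)) {
    warning(length(outside), " query id(s) outside the annotation universe dropped")
    query <- intersect(query, sets@universe)
  }
  if (length(query) == 0L)
    stop("query is empty after intersecting with the universe")
  N <- length(sets@universe)
  n <- length(query)
  ov <- vapply(sets@sets, function(g) length(intersect(g, query)), integer(1))
  keep <- names(ov)[ov >= 1L]
  if (length(keep) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), enrichment_score = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  res <- data.frame(
    term_id = keep,
    term_name = unname(sets@termNames[keep]),
    k = unname(ov[keep]),
    K = unname(vapply(sets@sets[keep], length, integer(1))),
    n = n, N = N, stringsAsFactors = FALSE)
  res$p_value <- mapply(hypergeomPValue, res$k, res$K,
                        MoreArgs = list(n = n, N = N))
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$enrichment_score <- -log10(res$p_value)
  res$significant <- switch(adjust,
                            none = res$p_value <= alpha,
                            bh = res$p_adjusted <= alpha)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. The universe defaults
#' to the union of all genes in the file.
#'
#' @param path GMT file path.
#' @param namespace label stored on the collection, default "geneset".
#' @param universe optional explicit universe; must contain every annotated
#'   gene.
#' @return A [GeneSets-class].
#' @export
readGMT <- function(path, namespace = "geneset", universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad))
    stop("malformed GMT: every line needs term id, description and >=1 gene")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  termNames <- vapply(fields, `[[`, character(1), 2L)
  names(termNames) <- ids
  if (is.null(universe))
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  new("GeneSets", sets = sets, termNames = termNames,
      namespace = namespace, universe = universe)
}

#' Write a GeneSets collection to GMT
#'
#' @param sets a [GeneSets-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  stopifnot(is(sets, "GeneSets"))
  lines <- vapply(names(sets@sets), function(id) {
    paste(c(id, sets@termNames[[id]], sets@sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a GeneSets collection from a named list
#'
#' @param sets named list of character gene vectors (term id -> genes).
#' @param termNames optional named character of display names; defaults to
#'   the term ids.
#' @param namespace collection label.
#' @param universe gene universe; defaults to the union of all sets.
#' @return A [GeneSets-class].
#' @export
GeneSets <- function(sets, termNames = NULL, namespace = "geneset",
                     universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a list named by term id")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(termNames)) {
    termNames <- stats::setNames(names(sets), names(sets))
  }
  if (is.null(universe))
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  new("GeneSets", sets = sets, termNames = termNames,
      namespace = namespace, universe = universe)
}
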