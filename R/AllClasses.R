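#' @import methods
NULL

#' Reference drug-library property profile
#'
#' Per-property mean and standard deviation of a reference drug library
#' (e.g. the average molecular properties of an approved-drug collection).
#' Compound descriptors are standardized against this profile before the
#' continuous Tanimoto drug-likeness index is computed.
#'
#' @slot propertyNames character vector of descriptor names.
#' @slot meanVector numeric vector of per-property means.
#' @slot sdVector numeric vector of per-property standard deviations,
#'   all strictly positive.
#'
#' @seealso [dlIndex()], [tanimotoSimilarity()]
#' @export
setClass("ReferenceProfile",
  representation(
    propertyNames = "character",
    meanVector = "numeric",
    sdVector = "numeric"
  )
)

setValidity("ReferenceProfile", function(object) {
  p <- length(object@propertyNames)
  if (length(object@meanVector) != p || length(object@sdVector) != p)
    return("propertyNames, meanVector and sdVector must have equal length")
  if (p == 0L)
    return("profile must contain at least one property")
  if (any(!is.finite(object@meanVector)) || any(!is.finite(object@sdVector)))
    return("means and SDs must be finite")
  if (any(object@sdVector <= 0))
    return("all SDs must be strictly positive")
  TRUE
})

#' Set of compounds with molecular-property descriptors
#'
#' Holds compound identifiers, display names, a descriptor matrix
#' (compounds x properties, mixed units) and, once computed, the
#' drug-likeness (DL) index of each compound.
#'
#' @slot ids character, unique compound identifiers ("mol01" style).
#' @slot names character, display names, parallel to `ids`.
#' @slot descriptors numeric matrix, one row per compound, columns named by
#'   property.
#' @slot dlIndex numeric, DL index per compound in \[0, 1\], `NA` until
#'   computed by [dlIndex()].
#'
#' @export
setClass("CompoundSet",
  representation(
    ids = "character",
    names = "character",
    descriptors = "matrix",
    dlIndex = "numeric"
  )
)

setValidity("CompoundSet", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    return("compound ids must be unique")
  if (length(object@names) != n)
    return("names must be parallel to ids")
  if (nrow(object@descriptors) != n)
    return("descriptor matrix must have one row per compound")
  if (is.null(colnames(object@descriptors)))
    return("descriptor columns must be named")
  if (length(object@dlIndex) != n)
    return("dlIndex must be parallel to ids")
  set <- object@dlIndex[!is.na(object@dlIndex)]
  if (any(set < 0 | set > 1))
    return("computed dlIndex values must lie in [0, 1]")
  TRUE
})

#' Gene-set annotation collection
#'
#' Flat term -> gene-set annotations (GO BP terms, pathways) over a fixed
#' gene universe, as read from a GMT file or produced by the synthetic
#' generator. Every term's gene set must be contained in the universe.
#'
#' @slot sets named list of character vectors; names are term ids.
#' @slot termNames named character; display name per term id.
#' @slot namespace single string, e.g. "GOBP" or "pathway".
#' @slot universe character vector of all gene ids.
#'
#' @seealso [readGMT()], [enrichTargets()]
#' @export
setClass("GeneSets",
  representation(
    sets = "list",
    termNames = "character",
    namespace = "character",
    universe = "character"
  )
)

setValidity("GeneSets", function(object) {
  if (length(object@universe) == 0L)
    return("universe must be nonempty")
  if (anyDuplicated(object@universe))
    return("universe ids must be unique")
  if (!identical(sort(names(object@sets)), sort(names(object@termNames))))
    return("sets and termNames must cover the same term ids")
  for (id in names(object@sets)) {
    g <- object@sets[[id]]
    if (anyDuplicated(g))
      return(sprintf("term '%s' lists duplicate genes", id))
    if (!all(g %in% object@universe))
      return(sprintf("term '%s' contains genes outside the universe", id))
  }
  TRUE
})

#' Layered (bipartite / tripartite) interaction network
#'
#' A compound-target (two layers) or compound-target-pathway (three layers)
#' network. Edges are unordered pairs that may only join nodes in adjacent
#' layers; node ids are unique across layers.
#'
#' @slot layers named list of character vectors, in layer order
#'   (e.g. compound, target, pathway).
#' @slot edges data.frame with character columns `from` and `to`; `from`
#'   always lies in the earlier of the two adjacent layers.
#' @slot nodeLabels named character mapping node id to display name.
#'
#' @seealso [buildCTNetwork()], [buildCTPNetwork()], [degreeStatistics()]
#' @export
setClass("LayeredNetwork",
  representation(
    layers = "list",
    edges = "data.frame",
    nodeLabels = "character"
  )
)

setValidity("LayeredNetwork", function(object) {
  if (length(object@layers) < 2L)
    return("a layered network needs at least two layers")
  if (is.null(names(object@layers)) || any(names(object@layers) == ""))
    return("layers must be named")
  ids <- unlist(object@layers, use.names = FALSE)
  if (anyDuplicated(ids))
    return("node ids must be unique across layers")
  ed <- object@edges
  if (!all(c("from", "to") %in% names(ed)))
    return("edges must have 'from' and 'to' columns")
  if (nrow(ed)) {
    if (anyDuplicated(paste(ed$from, ed$to, sep = "\r")))
      return("duplicate edges are not allowed")
    if (any(ed$from == ed$to))
      return("self-loops are not allowed")
    layerOf <- rep(seq_along(object@layers), lengths(object@layers))
    names(layerOf) <- ids
    lf <- layerOf[ed$from]
    lt <- layerOf[ed$to]
    if (any(is.na(lf)) || any(is.na(lt)))
      return("edges reference unknown node ids")
    if (any(lt - lf != 1L))
      return("edges must join adjacent layers (from the earlier layer)")
  }
  TRUE
})

#' Degree statistics of a layered network
#'
#' @slot perNode named integer, degree of every node.
#' @slot nodeLayer named character, layer name of every node.
#' @slot partitionMeans named numeric, per layer: (edge endpoints in the
#'   layer) / (layer size).
#' @slot nEdges integer, total edge count.
#'
#' @seealso [degreeStatistics()], [hubNodes()]
#' @export
setClass("DegreeReport",
  representation(
    perNode = "integer",
    nodeLayer = "character",
    partitionMeans = "numeric",
    nEdges = "integer"
  )
)

setValidity("DegreeReport", function(object) {
  if (!identical(names(object@perNode), names(object@nodeLayer)))
    return("perNode and nodeLayer must be parallel")
  if (sum(object@perNode) != 2L * object@nEdges)
    return("degree sum must equal twice the edge count")
  TRUE
})

#' Probability Ensemble Approach synergy model
#'
#' A binned likelihood-ratio naive-Bayes scorer over pair-similarity
#' features. For each feature the unit interval is cut into equal-width
#' bins; each bin stores the Laplace-smoothed log likelihood ratio of the
#' synergistic versus non-synergistic class. Prediction multiplies the
#' prior odds by the per-feature ratios and returns the posterior synergy
#' probability.
#'
#' @slot features character, feature names in model order.
#' @slot binEdges named list of numeric vectors; ascending edges covering
#'   \[0, 1\] exactly, one vector per feature.
#' @slot logLR named list of numeric vectors; per feature, one finite log
#'   likelihood ratio per bin.
#' @slot prior numeric in (0, 1), prior synergy probability.
#' @slot alpha positive smoothing pseudo-count.
#'
#' @seealso [fitPEA()], [predictSynergy()]
#' @export
setClass("PEAModel",
  representation(
    features = "character",
    binEdges = "list",
    logLR = "list",
    prior = "numeric",
    alpha = "numeric"
  )
)

setValidity("PEAModel", function(object) {
  if (!identical(names(object@binEdges), object@features) ||
      !identical(names(object@logLR), object@features))
    return("binEdges and logLR must be named by the model features")
  for (f in object@features) {
    e <- object@binEdges[[f]]
    if (length(e) < 2L || is.unsorted(e, strictly = TRUE) ||
        abs(e[1L]) > 1e-12 || abs(e[length(e)] - 1) > 1e-12)
      return(sprintf("bin edges for '%s' must ascend from 0 to 1", f))
    if (length(object@logLR[[f]]) != length(e) - 1L)
      return(sprintf("'%s' needs one log-LR per bin", f))
    if (any(!is.finite(object@logLR[[f]])))
      return(sprintf("log-LRs for '%s' must be finite", f))
  }
  if (length(object@prior) != 1L || object@prior <= 0 || object@prior >= 1)
    return("prior must lie strictly inside (0, 1)")
  if (length(object@alpha) != 1L || object@alpha <= 0)
    return("alpha must be positive")
  TRUE
})
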