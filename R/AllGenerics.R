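#' @rdname dlIndex
#' @export
setGeneric("dlIndex", function(object, ref, ...) standardGeneric("dlIndex"))

#' @rdname degreeStatistics
#' @export
setGeneric("degreeStatistics", function(net) standardGeneric("degreeStatistics"))

#' @rdname hubNodes
#' @export
setGeneric("hubNodes", function(report, layer, threshold = "partition_mean")
  standardGeneric("hubNodes"))

#' @rdname exportNetwork
#' @export
setGeneric("exportNetwork", function(net, file, format = c("sif", "graphml", "tsv"))
  standardGeneric("exportNetwork"))

#' @rdname predictSynergy
#' @export
setGeneric("predictSynergy", function(model, feats) standardGeneric("predictSynergy"))

#' Accessors for herbSynergy classes
#'
#' Small accessor generics: `compoundIds()` and `descriptors()` for
#' [CompoundSet-class], `geneSets()` and `universe()` for
#' [GeneSets-class], `layers()` and `networkEdges()` for
#' [LayeredNetwork-class].
#'
#' @param object an object of the documented class.
#' @return The slot contents (vector, list, matrix or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname accessors
#' @export
setGeneric("descriptors", function(object) standardGeneric("descriptors"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("universe", function(object) standardGeneric("universe"))

#' @rdname accessors
#' @export
setGeneric("layers", function(object) standardGeneric("layers"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("compoundIds", "CompoundSet", function(object) object@ids)

#' @rdname accessors
#' @export
setMethod("descriptors", "CompoundSet", function(object) object@descriptors)

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSets", function(object) object@sets)

#' @rdname accessors
#' @export
setMethod("universe", "GeneSets", function(object) object@universe)

#' @rdname accessors
#' @export
setMethod("layers", "LayeredNetwork", function(object) object@layers)

#' @rdname accessors
#' @export
setMethod("networkEdges", "LayeredNetwork", function(object) object@edges)

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile with", length(object@propertyNames), "properties:",
      paste(utils::head(object@propertyNames, 5), collapse = ", "),
      if (length(object@propertyNames) > 5) "..." else "", "\n")
})

setMethod("show", "CompoundSet", function(object) {
  n <- length(object@ids)
  done <- sum(!is.na(object@dlIndex))
  cat(sprintf("CompoundSet: %d compounds, %d properties; DL index computed for %d\n",
              n, ncol(object@descriptors), done))
})

setMethod("show", "GeneSets", function(object) {
  cat(sprintf("GeneSets [%s]: %d terms over a universe of %d genes\n",
              object@namespace, length(object@sets), length(object@universe)))
})

setMethod("show", "LayeredNetwork", function(object) {
  sz <- paste(sprintf("%s=%d", names(object@layers), lengths(object@layers)),
              collapse = ", ")
  cat(sprintf("LayeredNetwork: %d layers (%s), %d edges\n",
              length(object@layers), sz, nrow(object@edges)))
})

setMethod("show", "DegreeReport", function(object) {
  cat("DegreeReport:", object@nEdges, "edges; partition means:",
      paste(sprintf("%s=%.3f", names(object@partitionMeans),
                    object@partitionMeans), collapse = ", "), "\n")
})

setMethod("show", "PEAModel", function(object) {
  cat(sprintf("PEAModel: features [%s], %d bins, prior %.3f, alpha %g\n",
              paste(object@features, collapse = ", "),
              length(object@logLR[[1L]]), object@prior, object@alpha))
})
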