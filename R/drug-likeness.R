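#' Continuous Tanimoto similarity of two real vectors
#'
#' Generalizes the bitstring Tanimoto/Jaccard coefficient to real vectors:
#' \deqn{T(a,b) = \frac{a \cdot b}{|a|^2 + |b|^2 - a \cdot b}}
#' For nonnegative vectors the value lies in \[0, 1\], equals 1 exactly when
#' `a == b`, and 0 when the vectors are orthogonal.
#'
#' @param a,b numeric vectors of equal, nonzero length; at least one must be
#'   nonzero.
#' @return A single numeric similarity.
#' @examples
#' tanimotoSimilarity(c(1, 1), c(1, 0))  # 0.5
#' @export
tanimotoSimilarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    stop("inputs must be numeric vectors")
  if (length(a) == 0L || length(a) != length(b))
    stop("vectors must have equal, nonzero length")
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0 && ab == 0)
    stop("Tanimoto similarity is undefined for two all-zero vectors")
  ab / denom
}

#' Standardize a descriptor vector against a reference profile
#'
#' z-scores each property using the reference mean and SD, then shifts by a
#' fixed constant and clamps at zero so the result is nonnegative. The same
#' transformation applied to the reference mean itself yields the constant
#' vector `rep(shift, p)`, so compound and reference are compared in one
#' common nonnegative frame, which continuous Tanimoto requires.
#'
#' @param x numeric descriptor vector, names matching
#'   `ref@propertyNames` (order is reconciled by name when both are named).
#' @param ref a [ReferenceProfile-class].
#' @param shift nonneg shift constant in SD units (default 1.0; see the
#'   methods vignette for why).
#' @return Nonnegative numeric vector in the standardized frame.
#' @export
standardizeDescriptor <- function(x, ref, shift = 1.0) {
  stopifnot(is(ref, "ReferenceProfile"))
  p <- length(ref@propertyNames)
  if (length(x) != p)
    stop("descriptor length does not match the reference profile")
  if (!is.null(names(x))) {
    if (!setequal(names(x), ref@propertyNames))
      stop("descriptor property names do not match the reference profile")
    x <- x[ref@propertyNames]
  }
  z <- (x - ref@meanVector) / ref@sdVector
  pmax(z + shift, 0)
}

#' Drug-likeness (DL) index of compounds
#'
#' Standardizes each compound descriptor and the reference mean into a
#' common frame (see [standardizeDescriptor()]) and returns their
#' continuous Tanimoto similarity. A compound identical to the reference
#' mean scores 1; compounds far from the drug-library profile score near 0.
#'
#' @param object a [CompoundSet-class], or a single numeric descriptor
#'   vector.
#' @param ref a [ReferenceProfile-class].
#' @param shift standardization shift constant, passed through.
#' @param ... unused.
#' @return For a `CompoundSet`, the same set with the `dlIndex` slot
#'   filled; for a numeric vector, the DL index itself.
#' @export
#' @rdname dlIndex
setMethod("dlIndex", signature("CompoundSet", "ReferenceProfile"),
  function(object, ref, shift = 1.0, ...) {
    if (ncol(object@descriptors) != length(ref@propertyNames))
      stop("descriptor dimensions do not match the reference profile")
    refStd <- rep(shift, length(ref@propertyNames))
    object@dlIndex <- vapply(seq_along(object@ids), function(i) {
      tanimotoSimilarity(
        standardizeDescriptor(object@descriptors[i, ], ref, shift), refStd)
    }, numeric(1))
    validObject(object)
    object
  })

#' @export
#' @rdname dlIndex
setMethod("dlIndex", signature("numeric", "ReferenceProfile"),
  function(object, ref, shift = 1.0, ...) {
    refStd <- rep(shift, length(ref@propertyNames))
    tanimotoSimilarity(standardizeDescriptor(object, ref, shift), refStd)
  })

#' Filter compounds at the drug-likeness threshold
#'
#' Retains compounds whose DL index is greater than or equal to the
#' threshold (the cutoff is inclusive). Input order is preserved.
#'
#' @param compounds a [CompoundSet-class] with DL indices computed.
#' @param threshold DL cutoff, default 0.18.
#' @return The filtered `CompoundSet`.
#' @export
filterDrugLike <- function(compounds, threshold = 0.18) {
  stopifnot(is(compounds, "CompoundSet"))
  if (anyNA(compounds@dlIndex))
    stop("dlIndex has not been computed for all compounds; call dlIndex() first")
  keep <- compounds@dlIndex >= threshold
  subsetCompounds(compounds, keep)
}

#' Build a CompoundSet
#'
#' @param ids unique compound identifiers.
#' @param descriptors numeric matrix (compounds x named properties).
#' @param names display names; default the ids.
#' @param dlIndex optional precomputed DL index vector.
#' @return A [CompoundSet-class].
#' @export
CompoundSet <- function(ids, descriptors, names = ids, dlIndex = NULL) {
  descriptors <- as.matrix(descriptors)
  if (is.null(rownames(descriptors))) rownames(descriptors) <- ids
  if (is.null(dlIndex)) dlIndex <- rep(NA_real_, length(ids))
  new("CompoundSet", ids = as.character(ids), names = as.character(names),
      descriptors = descriptors, dlIndex = as.numeric(dlIndex))
}

#' Build a ReferenceProfile
#'
#' @param propertyNames descriptor names.
#' @param meanVector,sdVector per-property mean and positive SD.
#' @return A [ReferenceProfile-class].
#' @export
ReferenceProfile <- function(propertyNames, meanVector, sdVector) {
  new("ReferenceProfile", propertyNames = as.character(propertyNames),
      meanVector = as.numeric(meanVector), sdVector = as.numeric(sdVector))
}

subsetCompounds <- function(compounds, keep) {
  new("CompoundSet",
      ids = compounds@ids[keep],
      names = compounds@names[keep],
      descriptors = compounds@descriptors[keep, , drop = FALSE],
      dlIndex = compounds@dlIndex[keep])
}

#' Extract compounds as a data.frame
#'
#' One row per compound: id, name, DL index and the descriptor columns.
#' This is the layout the TSV writer/reader uses.
#'
#' @param compounds a [CompoundSet-class].
#' @return data.frame.
#' @export
asCompoundTable <- function(compounds) {
  data.frame(compound_id = compounds@ids, name = compounds@names,
             dl_index = compounds@dlIndex,
             compounds@descriptors, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
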