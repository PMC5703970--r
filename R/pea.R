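#' Pair-similarity features for a compound pair
#'
#' The evidence the synergy scorer consumes, all in \[0, 1\]:
#' * `chemical_similarity` -- continuous Tanimoto of the two standardized
#'   descriptor vectors;
#' * `target_jaccard` -- Jaccard index of the compounds' target sets
#'   (0 when both are empty);
#' * `pathway_jaccard` -- Jaccard index of the pathway sets their targets
#'   belong to.
#'
#' @param compounds a [CompoundSet-class] containing both compounds.
#' @param id1,id2 distinct compound ids.
#' @param interactions filtered/normalized interaction data.frame.
#' @param pathwaySets a [GeneSets-class] of pathway memberships.
#' @param ref a [ReferenceProfile-class] used to standardize descriptors.
#' @param shift standardization shift constant (see
#'   [standardizeDescriptor()]).
#' @return Named numeric vector of the three features.
#' @export
pairFeatures <- function(compounds, id1, id2, interactions, pathwaySets,
                         ref, shift = 1.0) {
  stopifnot(is(compounds, "CompoundSet"), is(pathwaySets, "GeneSets"))
  if (identical(id1, id2))
    stop("a pair must consist of two distinct compounds")
  i1 <- match(id1, compounds@ids)
  i2 <- match(id2, compounds@ids)
  if (is.na(i1) || is.na(i2))
    stop("both compounds must be present in the CompoundSet")
  a <- standardizeDescriptor(compounds@descriptors[i1, ], ref, shift)
  b <- standardizeDescriptor(compounds@descriptors[i2, ], ref, shift)
  t1 <- unique(interactions$target_id[interactions$compound_id == id1])
  t2 <- unique(interactions$target_id[interactions$compound_id == id2])
  p1 <- pathwaysOf(t1, pathwaySets)
  p2 <- pathwaysOf(t2, pathwaySets)
  c(chemical_similarity = tanimotoSimilarity(a, b),
    target_jaccard = jaccard(t1, t2),
    pathway_jaccard = jaccard(p1, p2))
}

#' Feature table for many pairs
#'
#' Vectorized wrapper over [pairFeatures()].
#'
#' @param compounds,interactions,pathwaySets,ref,shift see [pairFeatures()].
#' @param pairs data.frame with `compound_a`, `compound_b` columns.
#' @return data.frame: compound_a, compound_b and one column per feature.
#' @export
pairFeatureTable <- function(compounds, pairs, interactions, pathwaySets,
                             ref, shift = 1.0) {
  feats <- t(mapply(function(a, b) {
    pairFeatures(compounds, a, b, interactions, pathwaySets, ref, shift)
  }, pairs$compound_a, pairs$compound_b))
  out <- data.frame(compound_a = pairs$compound_a,
                    compound_b = pairs$compound_b,
                    feats, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0L) return(0)
  length(intersect(x, y)) / u
}

pathwaysOf <- function(targets, pathwaySets) {
  names(pathwaySets@sets)[vapply(pathwaySets@sets, function(g)
    any(targets %in% g), logical(1))]
}

#' Fit the Probability Ensemble Approach model
#'
#' For each feature, cuts \[0, 1\] into `nBins` equal-width bins and
#' estimates the Laplace-smoothed likelihood ratio of the synergistic
#' versus non-synergistic class in each bin:
#' \deqn{LR_b = \frac{(s_b + \alpha)/(S + \alpha B)}{(t_b + \alpha)/(T + \alpha B)}}
#' with \eqn{s_b, t_b} the class counts in bin b, \eqn{S, T} the class
#' totals and B the number of bins. Smoothing keeps every ratio finite and
#' positive even for empty bins.
#'
#' @param features data.frame or matrix of feature columns, all values in
#'   \[0, 1\]. Non-feature id columns `compound_a`/`compound_b` are
#'   ignored if present.
#' @param labels logical (or 0/1) vector: `TRUE` = synergistic. Both
#'   classes must be present.
#' @param nBins bins per feature, default 10.
#' @param alpha Laplace pseudo-count, default 1.
#' @param prior `"auto"` (class fraction of `labels`) or a number in (0,1).
#' @return A [PEAModel-class].
#' @export
fitPEA <- function(features, labels, nBins = 10, alpha = 1.0, prior = "auto") {
  features <- dropPairColumns(features)
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be logical or 0/1")
  if (length(labels) != nrow(features))
    stop("labels must be parallel to feature rows")
  vals <- as.matrix(features)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1))
    stop("all feature values must be finite and in [0, 1]")
  if (!any(labels) || all(labels))
    stop("degenerate training set: both classes must be present")
  if (nBins < 2L) stop("need at least two bins")
  if (alpha <= 0) stop("alpha must be positive")
  edges <- seq(0, 1, length.out = nBins + 1L)
  S <- sum(labels); T <- sum(!labels)
  logLR <- lapply(colnames(vals), function(f) {
    b <- binIndex(vals[, f], edges)
    sb <- tabulate(b[labels], nbins = nBins)
    tb <- tabulate(b[!labels], nbins = nBins)
    log(((sb + alpha) / (S + alpha * nBins)) /
        ((tb + alpha) / (T + alpha * nBins)))
  })
  names(logLR) <- colnames(vals)
  pr <- if (identical(prior, "auto")) S / (S + T) else as.numeric(prior)
  new("PEAModel", features = colnames(vals),
      binEdges = stats::setNames(rep(list(edges), ncol(vals)), colnames(vals)),
      logLR = logLR, prior = pr, alpha = alpha)
}

binIndex <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

dropPairColumns <- function(features) {
  features <- as.data.frame(features)
  features[setdiff(names(features), c("compound_a", "compound_b"))]
}

#' Predict the synergy probability of compound pairs
#'
#' Posterior odds = prior odds x the product of each feature's likelihood
#' ratio at the bin the feature value falls in; the returned probability is
#' odds / (1 + odds), strictly inside (0, 1) thanks to smoothing.
#'
#' @param model a [PEAModel-class].
#' @param feats a named numeric vector (one pair) or a data.frame of
#'   feature columns, optionally with `compound_a`/`compound_b` id columns.
#' @return For a vector, a single probability; for a data.frame, the same
#'   frame with id columns (if present) plus a `probability` column.
#' @rdname predictSynergy
#' @export
setMethod("predictSynergy", signature("PEAModel", "numeric"),
  function(model, feats) {
    missing <- setdiff(model@features, names(feats))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    logOdds <- log(model@prior / (1 - model@prior))
    for (f in model@features) {
      b <- binIndex(feats[[f]], model@binEdges[[f]])
      logOdds <- logOdds + model@logLR[[f]][b]
    }
    unname(stats::plogis(logOdds))
  })

#' @rdname predictSynergy
#' @export
setMethod("predictSynergy", signature("PEAModel", "data.frame"),
  function(model, feats) {
    vals <- dropPairColumns(feats)
    missing <- setdiff(model@features, names(vals))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    logOdds <- rep(log(model@prior / (1 - model@prior)), nrow(feats))
    for (f in model@features) {
      b <- binIndex(vals[[f]], model@binEdges[[f]])
      logOdds <- logOdds + model@logLR[[f]][b]
    }
    idCols <- intersect(c("compound_a", "compound_b"), names(feats))
    out <- feats[, idCols, drop = FALSE]
    out$probability <- stats::plogis(logOdds)
    rownames(out) <- NULL
    out
  })

#' Rank pairs by synergy probability and keep the top k
#'
#' Sorted by probability descending; ties are broken by the lexicographic
#' pair id (the two compound names, sorted within the pair, pasted), so the
#' ranking is a deterministic function of the prediction set.
#'
#' @param predictions data.frame with `compound_a`, `compound_b`,
#'   `probability`.
#' @param k number of pairs to keep, default 10.
#' @return The top `min(k, n)` rows with a `rank` column 1..k.
#' @export
rankPairs <- function(predictions, k = 10) {
  stopifnot(k >= 1)
  pairId <- pairKey(predictions$compound_a, predictions$compound_b)
  ord <- order(-predictions$probability, pairId)
  out <- predictions[utils::head(ord, k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

pairKey <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Mann-Whitney AUC of scores against binary labels
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted 1/2 -- the rank-sum estimate of the area
#' under the ROC curve.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
mannWhitneyAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate evaluation set: both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out AUC of a fitted PEA model
#'
#' @param model a [PEAModel-class].
#' @param feats test feature data.frame.
#' @param labels test labels; both classes must be present.
#' @return Mann-Whitney AUC of the predicted probabilities.
#' @export
evaluateAUC <- function(model, feats, labels) {
  pred <- predictSynergy(model, as.data.frame(feats))
  mannWhitneyAUC(pred$probability, labels)
}

#' Serialize / restore a PEA model as JSON
#'
#' @param model a [PEAModel-class].
#' @param path JSON file path.
#' @return `writePEAModel`: `path` invisibly; `readPEAModel`: the model.
#' @export
writePEAModel <- function(model, path) {
  stopifnot(is(model, "PEAModel"))
  obj <- list(features = model@features,
              bin_edges = model@binEdges,
              log_lr = model@logLR,
              prior = model@prior,
              alpha = model@alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePEAModel
#' @export
readPEAModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.character(obj$features)
  new("PEAModel", features = feats,
      binEdges = stats::setNames(lapply(obj$bin_edges, as.numeric)[feats], feats),
      logLR = stats::setNames(lapply(obj$log_lr, as.numeric)[feats], feats),
      prior = as.numeric(obj$prior), alpha = as.numeric(obj$alpha))
}
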