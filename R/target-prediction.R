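#' Threshold candidate interactions on ensemble classifier scores
#'
#' Keeps a compound-target record when its random-forest score is at least
#' `rfThreshold` OR its support-vector score is at least `svmThreshold`
#' (both boundaries inclusive) -- the union rule, which is deliberately
#' permissive so that promising candidates scored highly by either
#' classifier survive.
#'
#' @param scores data.frame of interaction candidates with columns
#'   `compound_id`, `target_id`, `rf_score`, `svm_score` (both in \[0,1\])
#'   and optionally `gene_symbol`, `organism`, `direct_binding`.
#' @param rfThreshold random-forest cutoff, default 0.7.
#' @param svmThreshold support-vector cutoff, default 0.8.
#' @return The surviving rows, order preserved.
#' @export
filterInteractions <- function(scores, rfThreshold = 0.7, svmThreshold = 0.8) {
  scores <- validateInteractionTable(scores)
  keep <- scores$rf_score >= rfThreshold | scores$svm_score >= svmThreshold
  scores[keep, , drop = FALSE]
}

#' Restrict interactions to one organism and deduplicate targets
#'
#' Drops records whose organism differs from `organism`
#' (case-insensitive exact match), then collapses duplicate
#' (compound, target) records keeping the maximum of each score. Output is
#' sorted by compound id then target id, so the result is deterministic
#' regardless of input order. Records without an `organism` column are
#' treated as matching.
#'
#' @param scores interaction data.frame (see [filterInteractions()]).
#' @param organism organism to keep, default `"Homo sapiens"`.
#' @return Deduplicated, sorted interaction data.frame.
#' @export
normalizeTargets <- function(scores, organism = "Homo sapiens") {
  scores <- validateInteractionTable(scores)
  if (!is.null(scores$organism)) {
    keep <- tolower(trimws(scores$organism)) == tolower(trimws(organism))
    scores <- scores[keep, , drop = FALSE]
  }
  if (nrow(scores) == 0L) {
    rownames(scores) <- NULL
    return(scores)
  }
  key <- paste(scores$compound_id, scores$target_id, sep = "\r")
  grp <- split(seq_len(nrow(scores)), key)
  rows <- lapply(grp, function(idx) {
    first <- scores[idx[1L], , drop = FALSE]
    first$rf_score <- max(scores$rf_score[idx])
    first$svm_score <- max(scores$svm_score[idx])
    if (!is.null(scores$direct_binding))
      first$direct_binding <- any(scores$direct_binding[idx])
    first
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep interactions whose targets are annotated to a disease of interest
#'
#' A target is disease-relevant when any of its annotations matches one of
#' `diseaseTerms`, either as a case-insensitive substring of the disease
#' name or as an exact disease id.
#'
#' @param scores interaction data.frame.
#' @param annotations data.frame with columns `target_id`, `disease_id`,
#'   `disease_name`.
#' @param diseaseTerms nonempty character vector of query terms.
#' @return A list with `interactions` (surviving rows) and `targets`
#'   (sorted distinct disease-relevant target ids present in `scores`).
#' @export
mapToDisease <- function(scores, annotations, diseaseTerms) {
  scores <- validateInteractionTable(scores)
  if (length(diseaseTerms) == 0L || all(!nzchar(diseaseTerms)))
    stop("at least one disease term is required")
  stopifnot(all(c("target_id", "disease_id", "disease_name") %in%
                  names(annotations)))
  hit <- rep(FALSE, nrow(annotations))
  for (term in diseaseTerms) {
    hit <- hit |
      grepl(term, annotations$disease_name, ignore.case = TRUE, fixed = FALSE) |
      annotations$disease_id == term
  }
  relevant <- unique(annotations$target_id[hit])
  keep <- scores$target_id %in% relevant
  interactions <- scores[keep, , drop = FALSE]
  rownames(interactions) <- NULL
  list(interactions = interactions,
       targets = sort(unique(interactions$target_id)))
}

validateInteractionTable <- function(scores) {
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  required <- c("compound_id", "target_id", "rf_score", "svm_score")
  missing <- setdiff(required, names(scores))
  if (length(missing))
    stop("interaction table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("rf_score", "svm_score")) {
    v <- scores[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1))
      stop(col, " must be numeric in [0, 1] with no missing values")
  }
  scores
}
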