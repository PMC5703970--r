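#' Pipeline configuration
#'
#' Collects every cutoff of the screen with its standard default: the
#' drug-likeness threshold 0.18, the ensemble-score union thresholds
#' RF 0.7 / SVM 0.8, the organism restriction, the disease query terms,
#' the enrichment significance level 0.05, the synergy-scorer settings and
#' the top-k size 10.
#'
#' @param inputs named list/vector of input file paths: `compounds`,
#'   `reference`, `interactions`, `disease`, `gobp`, `pathways`, `pairs`
#'   (as written by [simulateBundle()]).
#' @param outDir output directory for the stage artifacts.
#' @param dlThreshold drug-likeness cutoff (inclusive), default 0.18.
#' @param rfThreshold,svmThreshold ensemble-score cutoffs (inclusive,
#'   union rule), defaults 0.7 and 0.8.
#' @param organism organism kept by target normalization.
#' @param diseaseTerms character vector of disease query terms.
#' @param alpha enrichment significance level, default 0.05.
#' @param adjust `"none"` or `"bh"` multiple-testing adjustment.
#' @param dlShift standardization shift constant for the DL index.
#' @param nBins,peaAlpha,prior synergy-scorer settings (see [fitPEA()]).
#' @param topK ranked pairs to keep, default 10.
#' @param seed integer seed echoed into the report.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(inputs, outDir,
                           dlThreshold = 0.18,
                           rfThreshold = 0.7, svmThreshold = 0.8,
                           organism = "Homo sapiens",
                           diseaseTerms = "neuroinflammation",
                           alpha = 0.05, adjust = "none",
                           dlShift = 1.0,
                           nBins = 10L, peaAlpha = 1.0, prior = "auto",
                           topK = 10L, seed = 1L) {
  cfg <- list(inputs = as.list(inputs), outDir = outDir,
              dlThreshold = dlThreshold, rfThreshold = rfThreshold,
              svmThreshold = svmThreshold, organism = organism,
              diseaseTerms = diseaseTerms, alpha = alpha, adjust = adjust,
              dlShift = dlShift, nBins = as.integer(nBins),
              peaAlpha = peaAlpha, prior = prior, topK = as.integer(topK),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Reports problems instead of throwing: an empty result means the
#' configuration satisfies all invariants.
#'
#' @param config a [pipelineConfig()].
#' @return Character vector of human-readable issues (empty if valid).
#' @export
validateConfig <- function(config) {
  issues <- character(0)
  chk01 <- function(name) {
    v <- config[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      sprintf("%s must be a number in [0, 1]", name)
  }
  for (nm in c("dlThreshold", "rfThreshold", "svmThreshold", "alpha"))
    issues <- c(issues, chk01(nm))
  if (!is.numeric(config$topK) || config$topK < 1L)
    issues <- c(issues, "topK must be >= 1")
  if (!config$adjust %in% c("none", "bh"))
    issues <- c(issues, "adjust must be 'none' or 'bh'")
  if (length(config$diseaseTerms) == 0L || all(!nzchar(config$diseaseTerms)))
    issues <- c(issues, "at least one disease term is required")
  if (!identical(config$prior, "auto") &&
      (!is.numeric(config$prior) || config$prior <= 0 || config$prior >= 1))
    issues <- c(issues, "prior must be 'auto' or a number in (0, 1)")
  if (config$nBins < 2L)
    issues <- c(issues, "nBins must be >= 2")
  if (config$peaAlpha <= 0)
    issues <- c(issues, "peaAlpha must be positive")
  required <- c("compounds", "reference", "interactions", "disease",
                "gobp", "pathways", "pairs")
  missing <- setdiff(required, names(config$inputs))
  if (length(missing))
    issues <- c(issues,
                paste("missing input path(s):", paste(missing, collapse = ", ")))
  issues[!is.na(issues)]
}

#' Run the end-to-end synergy screen
#'
#' Executes the fixed stage order: drug-likeness filter, interaction-score
#' filter, organism normalization, disease mapping, enrichment,
#' compound-target network with degree/hub statistics, synergy-scorer
#' training and candidate-pair prediction, top-k ranking, and the
#' compound-target-pathway network of the top pairs. Every intermediate is
#' written under `config$outDir`; stage in/out counts are collected into
#' the returned report. Identical configuration and inputs reproduce
#' identical artifacts.
#'
#' @param config a valid [pipelineConfig()].
#' @return A list of class `"RunReport"`: `stage_counts` (data.frame
#'   stage/n_in/n_out), `artifacts` (paths written), `config`, `seed`,
#'   `started`, `finished`.
#' @export
runScreen <- function(config) {
  issues <- validateConfig(config)
  if (length(issues))
    stop("invalid pipeline configuration:\n  - ",
         paste(issues, collapse = "\n  - "))
  started <- Sys.time()
  set.seed(config$seed)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  artifacts <- character(0)
  stage <- function(name, nIn, nOut)
    counts[[length(counts) + 1L]] <<- data.frame(
      stage = name, n_in = nIn, n_out = nOut, stringsAsFactors = FALSE)
  out <- function(name) {
    p <- file.path(config$outDir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  # stage 1: drug-likeness
  compounds <- readCompounds(config$inputs$compounds)
  ref <- readReferenceProfile(config$inputs$reference)
  compounds <- dlIndex(compounds, ref, shift = config$dlShift)
  kept <- filterDrugLike(compounds, config$dlThreshold)
  tab <- asCompoundTable(compounds)
  tab$passed <- compounds@dlIndex >= config$dlThreshold
  writeTSV(tab, out("compounds_dl.tsv"))
  stage("drug_likeness", length(compounds@ids), length(kept@ids))

  # stage 2: interaction-score filter (union rule), restricted to the
  # surviving compounds
  inter <- readTSV(config$inputs$interactions)
  interKept <- filterInteractions(inter, config$rfThreshold,
                                  config$svmThreshold)
  interKept <- interKept[interKept$compound_id %in% kept@ids, , drop = FALSE]
  stage("interaction_filter", nrow(inter), nrow(interKept))

  # stage 3: organism normalization + dedup
  interNorm <- normalizeTargets(interKept, config$organism)
  writeTSV(interNorm, out("interactions_filtered.tsv"))
  stage("organism_normalization", nrow(interKept), nrow(interNorm))

  # stage 4: disease mapping
  disease <- readTSV(config$inputs$disease)
  mapped <- mapToDisease(interNorm, disease, config$diseaseTerms)
  writeTSV(mapped$interactions, out("interactions_disease.tsv"))
  stage("disease_mapping", length(unique(interNorm$target_id)),
        length(mapped$targets))

  # stage 5: enrichment of the disease-mapped target set
  gobp <- readGMT(config$inputs$gobp, namespace = "GOBP")
  enr <- if (length(mapped$targets)) {
    enrichTargets(mapped$targets, gobp, alpha = config$alpha,
                  adjust = config$adjust)
  } else {
    data.frame()
  }
  writeTSV(enr, out("enrichment.tsv"))
  stage("enrichment", length(gobp@sets),
        if (nrow(enr)) sum(enr$significant) else 0L)

  # stage 6: compound-target network
  net <- buildCTNetwork(kept, mapped$interactions)
  exportNetwork(net, out("ct_network.sif"), "sif")
  exportNetwork(net, file.path(config$outDir, "ct_network"), "tsv")
  artifacts <- c(artifacts, file.path(config$outDir,
                                      c("ct_network.nodes.tsv",
                                        "ct_network.edges.tsv")))
  if (all(lengths(net@layers) > 0L)) {
    deg <- degreeStatistics(net)
    hubs <- if (nrow(net@edges)) hubNodes(deg, "compound") else character(0)
    degTab <- data.frame(id = names(deg@perNode),
                         layer = unname(deg@nodeLayer),
                         degree = unname(deg@perNode),
                         is_hub = names(deg@perNode) %in% hubs,
                         stringsAsFactors = FALSE)
  } else {
    degTab <- data.frame(id = character(), layer = character(),
                         degree = integer(), is_hub = logical())
  }
  writeTSV(degTab, out("ct_degrees.tsv"))
  stage("ct_network", length(kept@ids), nrow(net@edges))

  # stage 7: synergy scoring of candidate pairs
  pairsTrain <- readTSV(config$inputs$pairs)
  pathways <- readGMT(config$inputs$pathways, namespace = "pathway")
  ranked <- data.frame(compound_a = character(), compound_b = character(),
                       probability = numeric(), rank = integer(),
                       stringsAsFactors = FALSE)
  if (length(kept@ids) >= 2L &&
      length(unique(pairsTrain$synergistic)) == 2L) {
    featCols <- setdiff(names(pairsTrain),
                        c("compound_a", "compound_b", "synergistic"))
    model <- fitPEA(pairsTrain[featCols], pairsTrain$synergistic,
                    nBins = config$nBins, alpha = config$peaAlpha,
                    prior = config$prior)
    writePEAModel(model, out("pea_model.json"))
    cand <- t(utils::combn(kept@ids, 2L))
    candPairs <- data.frame(compound_a = cand[, 1L], compound_b = cand[, 2L],
                            stringsAsFactors = FALSE)
    feats <- pairFeatureTable(kept, candPairs, mapped$interactions,
                              pathways, ref, shift = config$dlShift)
    pred <- predictSynergy(model, feats)
    ranked <- rankPairs(pred, config$topK)
    writeTSV(pred, out("pair_predictions.tsv"))
    writeTSV(ranked, out("top_pairs.tsv"))
    stage("synergy_ranking", nrow(pred), nrow(ranked))
  } else {
    writeTSV(ranked, out("top_pairs.tsv"))
    stage("synergy_ranking", 0L, 0L)
  }

  # stage 8: compound-target-pathway network of the top pairs
  topCompounds <- if (nrow(ranked))
    unique(c(ranked$compound_a, ranked$compound_b)) else character(0)
  ctp <- buildCTPNetwork(topCompounds, mapped$interactions, pathways)
  exportNetwork(ctp, out("ctp_network.sif"), "sif")
  stage("ctp_network", length(topCompounds),
        sum(lengths(ctp@layers)) + nrow(ctp@edges))

  report <- list(stage_counts = do.call(rbind, counts),
                 artifacts = artifacts,
                 config = config, seed = config$seed,
                 started = started, finished = Sys.time())
  class(report) <- "RunReport"
  jsonlite::write_json(
    list(stage_counts = report$stage_counts,
         artifacts = artifacts, seed = config$seed),
    file.path(config$outDir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Synergy-screen run (seed", x$seed, ")\n")
  for (i in seq_len(nrow(x$stage_counts)))
    cat(sprintf("  %-24s %6d -> %d\n", x$stage_counts$stage[i],
                x$stage_counts$n_in[i], x$stage_counts$n_out[i]))
  cat(length(x$artifacts), "artifacts under",
      dirname(x$artifacts[1]), "\n")
  invisible(x)
}
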