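#' Configuration of the synthetic-data generators
#'
#' One seeded configuration drives every generator, so a full pipeline
#' input bundle is reproducible from a single integer. Defaults mirror the
#' study scale the pipeline is aimed at: 103 library compounds of which a
#' 63/103 fraction is drug-like, 117 candidate targets of which 43 are
#' annotated to the query disease.
#'
#' @param seed integer seed; fully determines every generated artifact.
#' @param nCompounds,nProperties library size and descriptor count.
#' @param druglikeFraction fraction of compounds planted near the
#'   reference drug profile.
#' @param dlNoiseSD within-class descriptor noise, in SD units of the
#'   reference profile.
#' @param nTargets candidate target count.
#' @param edgeDensity fraction of the compound x target grid planted as
#'   true interactions.
#' @param scoreNoiseSD SD of the (correlated) noise on the two classifier
#'   scores.
#' @param scoreCorrelation correlation between the two scores' noise.
#' @param nonhumanFraction fraction of interaction records tagged with a
#'   non-human organism.
#' @param nDiseaseTargets targets annotated to the query disease.
#' @param nTerms annotation terms per collection.
#' @param plantedTermFold fold over chance overlap planted into the
#'   designated term (> 1).
#' @param universeSize gene-universe size for annotation collections.
#' @param nPairs labeled training pairs.
#' @param synergyFraction fraction of pairs labeled synergistic.
#' @param featureShift shift of each similarity feature for the
#'   synergistic class, in units of the feature SD.
#' @return A validated list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(seed = 1L,
                            nCompounds = 103L, nProperties = 8L,
                            druglikeFraction = 63 / 103, dlNoiseSD = 0.5,
                            nTargets = 117L, edgeDensity = 0.10,
                            scoreNoiseSD = 0.08, scoreCorrelation = 0.7,
                            nonhumanFraction = 0.1, nDiseaseTargets = 43L,
                            nTerms = 50L, plantedTermFold = 4,
                            universeSize = 500L,
                            nPairs = 500L, synergyFraction = 0.3,
                            featureShift = 1.5) {
  cfg <- list(seed = as.integer(seed), nCompounds = as.integer(nCompounds),
              nProperties = as.integer(nProperties),
              druglikeFraction = druglikeFraction, dlNoiseSD = dlNoiseSD,
              nTargets = as.integer(nTargets), edgeDensity = edgeDensity,
              scoreNoiseSD = scoreNoiseSD, scoreCorrelation = scoreCorrelation,
              nonhumanFraction = nonhumanFraction,
              nDiseaseTargets = as.integer(nDiseaseTargets),
              nTerms = as.integer(nTerms), plantedTermFold = plantedTermFold,
              universeSize = as.integer(universeSize),
              nPairs = as.integer(nPairs), synergyFraction = synergyFraction,
              featureShift = featureShift)
  class(cfg) <- "GeneratorConfig"
  props <- c("druglikeFraction", "edgeDensity", "nonhumanFraction",
             "synergyFraction")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$nCompounds < 2L || cfg$nProperties < 2L)
    stop("invalid configuration: need at least 2 compounds and 2 properties")
  if (cfg$nTargets < 1L)
    stop("invalid configuration: need at least one target")
  if (cfg$scoreNoiseSD < 0 || cfg$dlNoiseSD < 0)
    stop("noise SDs must be nonnegative")
  if (cfg$plantedTermFold <= 1)
    stop("plantedTermFold must exceed 1")
  if (abs(cfg$scoreCorrelation) > 1)
    stop("scoreCorrelation must lie in [-1, 1]")
  if (!is.finite(cfg$seed) || abs(cfg$seed) >= 2^31 - 10)
    stop("seed must be a 32-bit integer")
  cfg
}

# each generator re-seeds from the config with a fixed offset, so the ops
# are individually deterministic no matter the call order
reseed <- function(cfg, offset) set.seed(cfg$seed + offset)

#' Generate a compound library with a planted drug-like subpopulation
#'
#' Simulates a reference drug-library profile (mixed-scale property means
#' with proportional SDs) and draws `druglikeFraction` of the compounds
#' near the reference mean (within-class noise `dlNoiseSD` SD) and the
#' rest 6-10 SD away per property, so the DL filter at 0.18 separates the
#' two groups.
#'
#' @param cfg a [generatorConfig()].
#' @return List with `compounds` (a [CompoundSet-class], with a
#'   `"druglike"` logical attribute marking the planted class) and
#'   `reference` (a [ReferenceProfile-class]).
#' @export
generateCompoundLibrary <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  reseed(cfg, 0L)
  p <- cfg$nProperties
  n <- cfg$nCompounds
  propNames <- sprintf("prop_%d", seq_len(p))
  mu <- stats::runif(p, 1, 500)
  sd <- pmax(0.2 * mu, 1e-3)
  nLike <- round(n * cfg$druglikeFraction)
  druglike <- rep(FALSE, n)
  druglike[sample.int(n, nLike)] <- TRUE
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, propNames))
  for (i in seq_len(n)) {
    if (druglike[i]) {
      z <- stats::rnorm(p, 0, cfg$dlNoiseSD)
    } else {
      off <- sample(c(-1, 1), p, replace = TRUE) * stats::runif(p, 6, 10)
      z <- off + stats::rnorm(p, 0, cfg$dlNoiseSD)
    }
    X[i, ] <- mu + sd * z
  }
  ids <- sprintf("mol%03d", seq_len(n))
  compounds <- CompoundSet(ids, X, names = sprintf("compound_%d", seq_len(n)))
  attr(compounds, "druglike") <- druglike
  list(compounds = compounds,
       reference = ReferenceProfile(propNames, mu, sd))
}

#' Generate ensemble interaction-score tables over a planted bipartite
#' topology
#'
#' Every (compound, target) cell gets a record. A planted `edgeDensity`
#' fraction of cells are true interactions whose two classifier scores are
#' drawn high (around 0.85 and 0.90) with correlated noise; the rest are
#' drawn low (around 0.30 and 0.35). A `nonhumanFraction` of records is
#' tagged with a non-human organism.
#'
#' @param compounds a [CompoundSet-class].
#' @param nTargets number of targets.
#' @param cfg a [generatorConfig()].
#' @return Interaction data.frame (`compound_id`, `target_id`,
#'   `gene_symbol`, `rf_score`, `svm_score`, `organism`) with a
#'   `"planted"` attribute holding the true-edge data.frame.
#' @export
generateInteractionScores <- function(compounds, nTargets, cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"), is(compounds, "CompoundSet"))
  if (length(compounds@ids) == 0L) stop("compounds must be nonempty")
  if (nTargets < 1L) stop("invalid configuration: nTargets must be >= 1")
  reseed(cfg, 1L)
  targets <- sprintf("T%03d", seq_len(nTargets))
  grid <- expand.grid(compound_id = compounds@ids, target_id = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  nEdges <- round(m * cfg$edgeDensity)
  true <- rep(FALSE, m)
  if (nEdges > 0L) true[sample.int(m, nEdges)] <- TRUE
  rho <- cfg$scoreCorrelation
  u <- stats::rnorm(m)
  v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(m)
  rf <- ifelse(true, 0.85, 0.30) + cfg$scoreNoiseSD * u
  svm <- ifelse(true, 0.90, 0.35) + cfg$scoreNoiseSD * v
  organism <- rep("Homo sapiens", m)
  nNon <- round(m * cfg$nonhumanFraction)
  if (nNon > 0L) organism[sample.int(m, nNon)] <- "Mus musculus"
  out <- data.frame(grid,
                    gene_symbol = sub("^T", "GENE", grid$target_id),
                    rf_score = pmin(pmax(rf, 0), 1),
                    svm_score = pmin(pmax(svm, 0), 1),
                    organism = organism, stringsAsFactors = FALSE)
  attr(out, "planted") <- grid[true, , drop = FALSE]
  out
}

#' Generate target-disease annotations with a designated relevant subset
#'
#' `nDiseaseTargets` of the supplied targets are annotated to the query
#' disease (`neuroinflammation`, id `D001`); every target additionally
#' gets 1-3 decoy disease annotations.
#'
#' @param targets character target ids.
#' @param cfg a [generatorConfig()].
#' @return Annotation data.frame (`target_id`, `disease_id`,
#'   `disease_name`) with a `"diseaseTargets"` attribute.
#' @export
generateDiseaseAnnotations <- function(targets, cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  reseed(cfg, 2L)
  nRel <- min(cfg$nDiseaseTargets, length(targets))
  relevant <- sort(sample(targets, nRel))
  decoys <- sprintf("decoy disease %d", 1:20)
  rows <- lapply(targets, function(t) {
    k <- sample(1:3, 1L)
    d <- sample(seq_along(decoys), k)
    data.frame(target_id = t, disease_id = sprintf("D%03d", d + 1L),
               disease_name = decoys[d], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(data.frame(target_id = relevant, disease_id = "D001",
                          disease_name = "neuroinflammation",
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  attr(out, "diseaseTargets") <- relevant
  out
}

#' Generate an annotation collection with one planted enriched term
#'
#' Builds `nTerms` gene sets over a universe containing the supplied
#' targets plus filler genes. One designated term overlaps the target set
#' `plantedTermFold`-fold above its chance expectation; the remaining
#' terms are uniform draws from the universe.
#'
#' @param targets character vector: the designated query gene set.
#' @param cfg a [generatorConfig()].
#' @param namespace label for the collection.
#' @return A [GeneSets-class] with a `"plantedTerm"` attribute naming the
#'   enriched term id.
#' @export
generateAnnotationSets <- function(targets, cfg, namespace = "GOBP") {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  reseed(cfg, 3L)
  nFill <- max(cfg$universeSize - length(targets), 0L)
  uni <- c(targets, sprintf("FILL%04d", seq_len(nFill)))
  N <- length(uni)
  n <- length(targets)
  sizes <- sample(10:50, cfg$nTerms, replace = TRUE)
  plantedId <- "TERM001"
  K <- sizes[1L]
  expected <- K * n / N
  kPlant <- min(n, K, ceiling(cfg$plantedTermFold * expected))
  sets <- vector("list", cfg$nTerms)
  names(sets) <- sprintf("TERM%03d", seq_len(cfg$nTerms))
  sets[[1L]] <- c(sample(targets, kPlant),
                  sample(setdiff(uni, targets), K - kPlant))
  for (j in 2:cfg$nTerms) sets[[j]] <- sample(uni, sizes[j])
  termNames <- stats::setNames(
    c("planted response process",
      sprintf("background process %d", 2:cfg$nTerms)), names(sets))
  out <- GeneSets(sets, termNames, namespace = namespace, universe = sort(uni))
  attr(out, "plantedTerm") <- plantedId
  out
}

#' Generate synergy-labeled training pairs with planted feature signal
#'
#' Samples `nPairs` unordered compound pairs and labels a
#' `synergyFraction` of them synergistic. Each similarity feature
#' (chemical, target-profile, pathway-profile) is drawn from a truncated
#' normal baseline (mean 0.30, SD 0.15) for the non-synergistic class and
#' the same distribution shifted up by `featureShift` x SD for the
#' synergistic class, so a correctly implemented scorer recovers the
#' signal.
#'
#' @param compounds a [CompoundSet-class] (pair ids are drawn from it).
#' @param cfg a [generatorConfig()].
#' @return data.frame: `compound_a`, `compound_b`, the three feature
#'   columns, and logical `synergistic`.
#' @export
generateSynergyPairs <- function(compounds, cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"), is(compounds, "CompoundSet"))
  reseed(cfg, 4L)
  ids <- compounds@ids
  nAll <- choose(length(ids), 2L)
  if (cfg$nPairs > nAll)
    stop("nPairs exceeds the number of distinct unordered pairs")
  allPairs <- t(utils::combn(ids, 2L))
  pick <- sample.int(nAll, cfg$nPairs)
  pairs <- allPairs[pick, , drop = FALSE]
  nSyn <- round(cfg$nPairs * cfg$synergyFraction)
  lab <- rep(FALSE, cfg$nPairs)
  if (nSyn > 0L) lab[sample.int(cfg$nPairs, nSyn)] <- TRUE
  mu0 <- 0.30; sdF <- 0.15
  drawFeature <- function() {
    x <- stats::rnorm(cfg$nPairs, mu0 + ifelse(lab, cfg$featureShift * sdF, 0),
                      sdF)
    pmin(pmax(x, 0), 1)
  }
  data.frame(compound_a = pairs[, 1L], compound_b = pairs[, 2L],
             chemical_similarity = drawFeature(),
             target_jaccard = drawFeature(),
             pathway_jaccard = drawFeature(),
             synergistic = lab, stringsAsFactors = FALSE)
}

#' Top-10 synergy ranking fixture
#'
#' The published top ten compound pairs with their synergy probabilities,
#' used as a ranking fixture for [rankPairs()]. The probabilities are not
#' model outputs of this package.
#'
#' @return data.frame: `compound_a`, `compound_b`, `probability` (10 rows,
#'   12 distinct compounds).
#' @export
topPairsFixture <- function() {
  data.frame(
    compound_a = c("echinacoside", "isoacteoside", "echinacoside",
                   "cistansinenside A", "cistantubuloside B1",
                   "\u03b2-sitosterol", "kankanoside O", "tubuloside A",
                   "cistansinenside A", "kankanoside O"),
    compound_b = c("verbascoside", "2\u2032-acetylacteoside",
                   "2\u2032-acetylacteoside", "tubuloside A",
                   "cistantubuloside A", "2\u2032-acetylacteoside",
                   "kankanoside K1", "syringin", "kankanoside K1",
                   "verbascoside"),
    probability = c(0.97, 0.95, 0.92, 0.86, 0.85, 0.82, 0.79, 0.73, 0.67,
                    0.61),
    stringsAsFactors = FALSE)
}

#' Random bipartite network at the published compound-target scale
#'
#' A random wiring with exactly 63 compound nodes, 43 target nodes and 482
#' distinct edges -- the size of the published compound-target network --
#' for exercising degree statistics at that scale.
#'
#' @param seed integer seed for the wiring.
#' @return A two-layer [LayeredNetwork-class].
#' @export
ctCountsFixture <- function(seed = 1L) {
  set.seed(seed)
  nc <- 63L; nt <- 43L; ne <- 482L
  cells <- sample.int(nc * nt, ne)
  compounds <- sprintf("mol%02d", seq_len(nc))
  targets <- sprintf("T%02d", seq_len(nt))
  edges <- data.frame(
    from = compounds[(cells - 1L) %% nc + 1L],
    to = targets[(cells - 1L) %/% nc + 1L], stringsAsFactors = FALSE)
  LayeredNetwork(list(compound = compounds, target = targets), edges)
}

#' Write a complete synthetic input bundle
#'
#' Runs every generator under one configuration and writes the pipeline's
#' input files to `dir`: compound descriptors, reference profile,
#' interaction scores, disease annotations, two GMT collections (GO-BP
#' style and pathway style), labeled training pairs, and a JSON
#' run-manifest echoing the configuration.
#'
#' @param cfg a [generatorConfig()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written, invisibly; the
#'   manifest records the same paths.
#' @export
simulateBundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generateCompoundLibrary(cfg)
  inter <- generateInteractionScores(lib$compounds, cfg$nTargets, cfg)
  targets <- sort(unique(inter$target_id))
  disease <- generateDiseaseAnnotations(targets, cfg)
  gobp <- generateAnnotationSets(attr(disease, "diseaseTargets"), cfg,
                                 namespace = "GOBP")
  pwCfg <- cfg
  pwCfg$nTerms <- max(10L, cfg$nTerms %/% 3L)
  pwCfg$universeSize <- max(length(targets), 2L * cfg$nTargets)
  pwCfg$seed <- cfg$seed + 5L
  pathways <- generateAnnotationSets(attr(disease, "diseaseTargets"), pwCfg,
                                     namespace = "pathway")
  pairs <- generateSynergyPairs(lib$compounds, cfg)
  files <- c(compounds = file.path(dir, "compounds.tsv"),
             reference = file.path(dir, "reference_profile.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             disease = file.path(dir, "disease_annotations.tsv"),
             gobp = file.path(dir, "gobp.gmt"),
             pathways = file.path(dir, "pathways.gmt"),
             pairs = file.path(dir, "training_pairs.tsv"),
             manifest = file.path(dir, "manifest.json"))
  writeCompounds(lib$compounds, files[["compounds"]])
  writeReferenceProfile(lib$reference, files[["reference"]])
  writeTSV(inter, files[["interactions"]])
  writeTSV(disease, files[["disease"]])
  writeGMT(gobp, files[["gobp"]])
  writeGMT(pathways, files[["pathways"]])
  writeTSV(pairs, files[["pairs"]])
  manifest <- list(config = unclass(cfg), files = as.list(files))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
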