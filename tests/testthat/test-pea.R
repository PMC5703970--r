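# a model whose every bin carries log-LR 0: predictions equal the prior
flatModel <- function(features = "f1", prior = 0.5, nBins = 2L) {
  edges <- seq(0, 1, length.out = nBins + 1)
  new("PEAModel", features = features,
      binEdges = setNames(rep(list(edges), length(features)), features),
      logLR = setNames(rep(list(rep(0, nBins)), length(features)), features),
      prior = prior, alpha = 1)
}

test_that("pair features: Jaccard identities and hand case", {
  toy <- toyCompounds()
  pw <- GeneSets(list(P1 = c("T1", "T2"), P2 = c("T3")),
                 universe = c("T1", "T2", "T3"))
  mk <- function(map) do.call(rbind, lapply(names(map), function(cid)
    data.frame(compound_id = cid, target_id = map[[cid]],
               stringsAsFactors = FALSE)))
  same <- mk(list(c1 = c("T1", "T2"), c2 = c("T1", "T2")))
  f <- pairFeatures(toy$compounds, "c1", "c2", same, pw, toy$reference)
  expect_equal(f[["target_jaccard"]], 1.0)
  expect_true(f[["chemical_similarity"]] >= 0 &&
              f[["chemical_similarity"]] <= 1)
  disj <- mk(list(c1 = "T1", c2 = "T3"))
  f2 <- pairFeatures(toy$compounds, "c1", "c2", disj, pw, toy$reference)
  expect_equal(f2[["target_jaccard"]], 0.0)
  expect_equal(f2[["pathway_jaccard"]], 0.0)
  # T1 = {A,B,C}, T2 = {B,C,D} -> 2/4
  abc <- mk(list(c1 = c("A", "B", "C"), c2 = c("B", "C", "D")))
  f3 <- pairFeatures(toy$compounds, "c1", "c2", abc,
                     GeneSets(list(P = "A"), universe = "A"), toy$reference)
  expect_equal(f3[["target_jaccard"]], 0.5)
  # both empty target sets -> 0, not NaN
  f4 <- pairFeatures(toy$compounds, "c1", "c2", mk(list(c3 = "T1")), pw,
                     toy$reference)
  expect_equal(f4[["target_jaccard"]], 0.0)
  expect_error(pairFeatures(toy$compounds, "c1", "c1", same, pw,
                            toy$reference), "distinct")
})

test_that("training reproduces the hand-computed two-bin Laplace example", {
  feats <- data.frame(f1 = c(0.8, 0.9, 0.1, 0.2))
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  model <- fitPEA(feats, labels, nBins = 2, alpha = 1, prior = 0.5)
  lr <- exp(model@logLR$f1)
  # upper bin: (2+1)/(2+2) over (0+1)/(2+2) = 3; lower bin is its mirror
  expect_equal(lr[2], 3, tolerance = 1e-12)
  expect_equal(lr[1], 1 / 3, tolerance = 1e-12)
  # posterior for a single feature in the LR = 3 bin at prior 0.5
  expect_equal(predictSynergy(model, c(f1 = 0.9)), 0.75, tolerance = 1e-12)
})

test_that("smoothing keeps every bin finite even with empty bins, and
           degenerate training errors", {
  feats <- data.frame(f1 = c(0.05, 0.95))
  model <- fitPEA(feats, c(TRUE, FALSE), nBins = 10, alpha = 0.5)
  expect_true(all(is.finite(model@logLR$f1)))
  expect_error(fitPEA(feats, c(TRUE, TRUE)), "degenerate")
  expect_error(fitPEA(data.frame(f1 = 1.5), TRUE), "\\[0, 1\\]")
})

test_that("an identically distributed feature is uninformative in the large-n
           limit", {
  # with 10 bins and ~500 counts per class per bin the smoothed log-LR has
  # binomial noise of SD sqrt(2/500) ~ 0.063, so bins hover near LR = 1
  set.seed(101)
  n <- 10000
  feats <- data.frame(f1 = runif(n))
  labels <- rep(c(TRUE, FALSE), n / 2)
  model <- fitPEA(feats, labels, nBins = 10, alpha = 1)
  expect_lt(mean(abs(model@logLR$f1)), 0.1)
  expect_lt(max(abs(model@logLR$f1)), 0.25)
  # an uninformative feature barely moves any prediction
  probs <- predictSynergy(model, feats)$probability
  expect_true(all(abs(probs - 0.5) < 0.07))
})

test_that("prediction follows the posterior-odds algebra", {
  m <- flatModel(c("f1", "f2"), prior = 0.5)
  # all features in LR = 1 bins -> the prior comes back
  expect_equal(predictSynergy(m, c(f1 = 0.3, f2 = 0.9)), 0.5)
  m2 <- flatModel("f1", prior = 0.2)
  expect_equal(predictSynergy(m2, c(f1 = 0.5)), 0.2)
  # canceling evidence: LR 3 and 1/3 at prior 0.5 -> 0.5
  m3 <- flatModel(c("f1", "f2"), prior = 0.5)
  m3@logLR$f1 <- c(log(3), log(3))
  m3@logLR$f2 <- c(log(1 / 3), log(1 / 3))
  expect_equal(predictSynergy(m3, c(f1 = 0.5, f2 = 0.5)), 0.5,
               tolerance = 1e-12)
  expect_error(predictSynergy(m, c(f1 = 0.5)), "missing feature")
  # probabilities stay strictly inside (0, 1)
  set.seed(3)
  tr <- data.frame(f1 = c(runif(50, 0, 0.3), runif(50, 0.7, 1)))
  model <- fitPEA(tr, rep(c(FALSE, TRUE), each = 50))
  p <- predictSynergy(model, data.frame(f1 = seq(0, 1, 0.01)))$probability
  expect_true(all(p > 0 & p < 1))
})

test_that("ranking is deterministic: probability-descending, ties broken
           lexicographically, stable under permutation", {
  fx <- topPairsFixture()
  top <- rankPairs(fx, 10)
  expect_equal(top$compound_a[1], "echinacoside")
  expect_equal(top$compound_b[1], "verbascoside")
  expect_equal(top$probability[1], 0.97)
  expect_equal(top$rank, 1:10)
  expect_equal(nrow(rankPairs(fx, 100)), 10L)  # k > n returns everything
  tied <- data.frame(compound_a = c("b", "a"), compound_b = c("c", "z"),
                     probability = c(0.5, 0.5), stringsAsFactors = FALSE)
  expect_equal(rankPairs(tied, 2)$compound_a, c("a", "b"))
  set.seed(8)
  perm <- fx[sample.int(10), ]
  expect_equal(rankPairs(perm, 10), top)
})

test_that("Mann-Whitney AUC matches enumeration, handles ties, and agrees
           with an independent ROC implementation", {
  expect_equal(mannWhitneyAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(mannWhitneyAUC(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # positives {0.8, 0.3}, negatives {0.5, 0.1}: 3 of 4 comparisons won
  expect_equal(mannWhitneyAUC(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(mannWhitneyAUC(1:3, c(1, 1, 1)), "degenerate")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)  # rounding forces occasional ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    expect_equal(mannWhitneyAUC(scores, labels), bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
  scores <- runif(60)
  labels <- rep(c(TRUE, FALSE), 30)
  expect_equal(mannWhitneyAUC(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("the scorer recovers planted synergy signal on held-out pairs", {
  aucs <- vapply(1:20, function(s) {
    cfg <- generatorConfig(seed = s, nPairs = 500L, featureShift = 1.5)
    lib <- generateCompoundLibrary(cfg)
    pairs <- generateSynergyPairs(lib$compounds, cfg)
    nTr <- floor(0.7 * nrow(pairs))
    idx <- seq_len(nTr)
    featCols <- c("chemical_similarity", "target_jaccard", "pathway_jaccard")
    model <- fitPEA(pairs[idx, featCols], pairs$synergistic[idx])
    evaluateAUC(model, pairs[-idx, featCols], pairs$synergistic[-idx])
  }, numeric(1))
  expect_gte(median(aucs), 0.85)
})

test_that("PEA models survive a JSON round-trip", {
  set.seed(12)
  tr <- data.frame(f1 = runif(40), f2 = runif(40))
  model <- fitPEA(tr, rep(c(TRUE, FALSE), 20), nBins = 5, alpha = 2,
                  prior = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  writePEAModel(model, path)
  back <- readPEAModel(path)
  expect_equal(back@features, model@features)
  expect_equal(back@logLR, model@logLR, tolerance = 1e-12)
  expect_equal(back@prior, model@prior)
  probe <- data.frame(f1 = runif(10), f2 = runif(10))
  expect_equal(predictSynergy(back, probe), predictSynergy(model, probe),
               tolerance = 1e-12)
})
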