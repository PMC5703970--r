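# Independent oracles and small fixtures shared across the suite.

# Exhaustive upper-tail hypergeometric probability: sum the point masses
# C(K,j) C(N-K, n-j) / C(N, n) over j = k..min(K, n). Kept deliberately
# separate from the implementation under test.
hyperTailEnum <- function(k, K, n, N) {
  if (k == 0L) return(1.0)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force Mann-Whitney AUC: count all cross-class comparisons.
bruteAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Tiny compound set: descriptors chosen by hand around a unit-scale
# reference profile.
toyReference <- function(p = 3) {
  ReferenceProfile(sprintf("prop_%d", seq_len(p)),
                   meanVector = rep(10, p), sdVector = rep(2, p))
}

toyCompounds <- function() {
  ref <- toyReference()
  desc <- rbind(rep(10, 3),          # exactly the reference mean
                rep(10, 3) + 2 * 1,  # 1 SD up on every property
                rep(10, 3) + 2 * 10) # 10 SD up: far outlier
  colnames(desc) <- ref@propertyNames
  list(compounds = CompoundSet(c("c1", "c2", "c3"), desc),
       reference = ref)
}

# Hand-built interaction table covering boundary scores.
toyInteractions <- function() {
  data.frame(
    compound_id = c("c1", "c1", "c2", "c2", "c3"),
    target_id = c("T1", "T2", "T1", "T3", "T2"),
    rf_score = c(0.70, 0.69, 0.00, 0.95, 0.50),
    svm_score = c(0.10, 0.79, 0.80, 0.10, 0.50),
    organism = rep("Homo sapiens", 5),
    stringsAsFactors = FALSE)
}
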