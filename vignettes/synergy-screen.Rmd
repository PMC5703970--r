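---
title: "Screening herbal compound libraries for synergistic pairs"
author: "herbSynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening herbal compound libraries for synergistic pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbSynergy)
```

# The screen

Herbal extracts act through many weakly potent constituents at once, which
makes them a natural hunting ground for synergistic two-compound
combinations. `herbSynergy` implements the in-silico part of such a hunt as
a fixed pipeline:

1. **Drug-likeness filter** — keep compounds whose molecular-property
   profile resembles an approved-drug library (DL index ≥ 0.18).
2. **Target filter** — keep predicted compound–target interactions scored
   by an ensemble of two classifiers (random-forest score ≥ 0.7 *or*
   support-vector score ≥ 0.8), restricted to one organism, duplicates
   max-merged.
3. **Disease mapping** — keep targets annotated to the disease of
   interest.
4. **Enrichment** — hypergeometric over-representation of the surviving
   target set against GO-BP-style annotations.
5. **Networks** — bipartite compound–target and tripartite
   compound–target–pathway graphs with degree and hub statistics.
6. **Synergy scoring** — a Probability Ensemble Approach (PEA): a binned
   likelihood-ratio naive-Bayes model over pair-similarity features that
   returns a synergy probability per pair, ranked top-k.

Every stage is a plain function; `runScreen()` wires them together and a
seeded synthetic-data module generates all inputs, so the whole screen is
testable offline.

# Drug-likeness: continuous Tanimoto against a reference profile

For real-valued vectors the Tanimoto coefficient is

$$T(a,b) = \frac{a\cdot b}{\lVert a\rVert^2 + \lVert b\rVert^2 - a\cdot b},$$

which generalizes the bitstring Jaccard/Tanimoto and lies in $[0,1]$ for
nonnegative inputs. The DL index of a compound is the Tanimoto similarity
between its descriptor vector and the *mean* property vector of a
reference drug library.

Molecular properties live on wildly different scales (molecular weight in
the hundreds, logP near zero, H-bond counts small integers), and continuous
Tanimoto is scale-sensitive, so both vectors must first be brought into a
common frame. The package's convention, applied identically to compound
and reference:

* z-score each property with the reference library's mean and SD;
* add a fixed shift constant $c$ (default **1.0**) and clamp at zero so
  the vectors are nonnegative.

Under this convention the standardized reference is the constant vector
$c\mathbf{1}$, a compound exactly at the reference mean scores 1, and a
compound offset by $d$ SD on every property scores
$r/(r^2-r+1)$ with $r=(c+d)/c$. The default $c=1$ places the 0.18
threshold at roughly 6 SD of uniform displacement: far outliers (10 SD)
score ≈ 0.10, compounds within ~1 SD score well above 0.5. Larger shifts
(e.g. $c=3$) would compress the z-scale so much that even 10-SD outliers
stay above 0.18, defeating the filter; the shift is exposed as a parameter
(`shift` in `dlIndex()`, `dlShift` in the pipeline) and documented here as
the package's fixed convention. All threshold comparisons in the pipeline
are **inclusive** (a DL index of exactly 0.18, an RF score of exactly 0.7
pass).

# Target filtering and disease mapping

The two classifier scores are combined with the permissive union rule
("either classifier is confident"), not an intersection: the screen's goal
is recall of plausible interactions, with the disease-mapping stage acting
as the specificity filter. Duplicate (compound, target) records — common
after accession normalization — are collapsed keeping the **maximum** of
each score, the least destructive deterministic rule; output is sorted by
compound then target id so results never depend on input order.

Disease annotation queries match either the disease name as a
case-insensitive substring or the disease id exactly; both modes are
supported because annotation-database query semantics differ, and the
pipeline accepts several terms at once.

# Enrichment

Over-representation uses the upper-tail hypergeometric test,
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, computed with
`stats::phyper`. The test suite checks it against exhaustive enumeration
of the tail (exact binomial-coefficient sums) for every configuration with
$N \le 25$. Web enrichment services often use an EASE-style modified
Fisher test; the plain hypergeometric is used here deliberately — it has a
well-defined null and is reproducible offline, and the ranking of terms is
in practice the same. The gene universe defaults to all genes appearing in
the annotation collection (the information a GMT file carries);
significance is flagged at raw $p \le 0.05$ to match common reporting,
with Benjamini–Hochberg adjustment available (`adjust = "bh"`). The
reported enrichment score is $-\log_{10} p$.

# Networks

`LayeredNetwork` stores an ordered list of node layers and edges that may
only join adjacent layers; validity enforces uniqueness, no self-loops, no
duplicates. Compounds that survive screening but hit no target are kept as
isolated nodes (they were screened; their degree is informative), while
targets and pathways appear only when connected.

Degree statistics report, for each layer, (edges incident to the layer) /
(layer size), computed exactly before any rounding and printed to 3
decimals. For a two-layer network both layers are incident to every edge,
so a network with 482 edges over 63 compounds and 43 targets has partition
means $482/63 = 7.651$ and $482/43 = 11.209$ regardless of wiring.
Published descriptions of networks at exactly this size attach the labels
"per compound" and "per target" the other way around from the arithmetic;
the package computes and reports both layer means and leaves the labeling
to the arithmetic rather than guessing intent. **Hubs** are nodes whose
degree *strictly* exceeds their partition's mean (or an explicit cutoff),
sorted by degree with ties broken by id.

Exports: SIF (`source TAB relation TAB target`, relation naming the layer
pair), GraphML via igraph with `layer`/`label` vertex attributes, and a
node/edge TSV pair that `importNetworkTSV()` round-trips. Pathway→module
assignments (e.g. cell death, inflammation, neuroprotection) are static
metadata a user can attach to node labels; they involve no computation and
the package does not hard-code any particular mapping.

# The PEA synergy scorer

The scorer is a reconstruction of a probability-ensemble approach
described in the literature only as a Bayesian network combined with a
similarity algorithm; the internals here are the minimal model consistent
with that description, and every choice is exposed as a parameter.

Each candidate pair is described by similarity features in $[0,1]$:

* `chemical_similarity` — Tanimoto of the standardized descriptors;
* `target_jaccard` — Jaccard index of the two target sets (0 when both
  empty);
* `pathway_jaccard` — Jaccard of the pathway sets their targets belong to.

Training cuts $[0,1]$ into $B$ equal-width bins per feature (default
$B=10$) and estimates a Laplace-smoothed likelihood ratio per bin:

$$LR_b = \frac{(s_b+\alpha)/(S+\alpha B)}{(t_b+\alpha)/(T+\alpha B)},$$

with $s_b, t_b$ the synergistic / non-synergistic counts in bin $b$,
$S, T$ the class totals and $\alpha = 1$ by default. Smoothing keeps every
ratio finite and strictly positive, so predicted probabilities are always
strictly inside $(0,1)$. Prediction multiplies the prior odds (prior =
training class fraction when `"auto"`) by the per-feature ratios,
naive-Bayes style:

$$\mathrm{odds} = \frac{\pi}{1-\pi}\prod_f LR_{f}, \qquad
  p = \frac{\mathrm{odds}}{1+\mathrm{odds}}.$$

Values at bin boundaries fall into the lower bin except 1.0, which closes
the last bin (`findInterval` with a closed right edge) — with equal-width
bins on $[0,1]$ this affects only exact boundary values. Ranking sorts by
probability descending with ties broken by the lexicographic pair id, so
the top-k list is a deterministic function of the prediction set.
Performance is summarized by the rank-based Mann–Whitney AUC (ties counted
½), cross-checked in the tests against both brute-force comparison counts
and an independent ROC implementation.

With 10 bins and $n = 10{,}000$ uninformative training pairs the log-LRs
hover near zero with binomial noise of SD $\approx \sqrt{2/500} = 0.06$;
the tests assert that scale (mean $|\log LR| < 0.1$, max $< 0.25$) rather
than exact flatness.

# The synthetic-data module

Each generator plants exactly the signal its downstream stage is meant to
detect; one seed determines every artifact (each generator re-seeds from
the configured seed plus a fixed offset, so calls are individually
reproducible in any order).

* **Compound library** — property means $\sim U(1, 500)$ with SD = 20% of
  the mean (mimicking the heterogeneous scales of MW/logP-style
  descriptors); drug-like compounds sit within 0.5 SD of the reference
  mean, the rest are offset 6–10 SD per property with random sign. Default
  103 compounds with a 63/103 drug-like fraction.
* **Interaction scores** — a planted 10% of the compound × target grid is
  "true"; true cells draw (RF, SVM) around (0.85, 0.90), background
  around (0.30, 0.35), with noise SD 0.08 correlated at 0.7 between the
  two scores, so the union filter behaves like the intended "or" rule and
  recovers > 90% of planted edges. 10% of records carry a non-human
  organism tag. Default 117 targets, 43 of them disease-annotated.
* **Annotation sets** — 50 terms over a 500-gene universe; one designated
  term overlaps the query set four-fold above its chance expectation, the
  rest are uniform draws.
* **Synergy pairs** — features for the non-synergistic class are drawn
  from a clamped normal with mean 0.30 and SD 0.15; the synergistic class
  is shifted up by `featureShift` × SD (default 1.5). Labels are planted
  at the feature level — sufficient to exercise the scorer's statistical
  machinery, and deliberately not a mechanistic model of synergy.

These defaults were chosen once, as plausible desk-scale conditions, and
are what the test suite runs under. What the generator does **not**
emulate: real descriptor covariance (properties are independent given the
class), structure-derived similarity (no SMILES or fingerprints),
annotation bias and term overlap structure of real ontologies, and any
dose–response notion of synergy. Passing tests therefore demonstrate that
the statistical machinery is correct and recovers planted signal at
realistic effect sizes — not that the pipeline's biological conclusions
transfer to any particular real library.

Two fixtures carry published-scale shapes for exercising the topology and
ranking code: a random bipartite graph with exactly 63/43 nodes and 482
edges, and a ten-row pair table (12 distinct compounds, top probability
0.97) used purely as a ranking fixture — its probabilities are inputs, not
outputs of this package's model.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: the full
synthetic screen uses the 103-compound / 117-target defaults (a ~12k-row
interaction grid, ~2k candidate pairs); scorer recovery uses 500 pairs per
seed over 20 seeds with a 70/30 split; enumeration checks cover every
hypergeometric configuration with $N \le 25$. A complete run of suite plus
acceptance script takes well under a minute on one core.

Degenerate inputs are handled explicitly: an all-zero pair of standardized
vectors is an error (undefined Tanimoto); an empty query after universe
intersection is an error; a screen whose DL stage keeps nothing cascades
empty outputs without crashing; single-class training or evaluation sets
are errors rather than silent NaNs.

# Limitations

* The PEA internals are a reconstruction; the original model's features,
  bin structure and prior are not published, so Table-style probability
  values from the original study are not reproduction targets — only the
  ranking machinery is.
* Classifier score tables are consumed, never produced: the upstream
  chemogenomic models are out of scope.
* Annotations are flat sets; no ontology propagation.
* No dose–response synergy indices (Loewe, Bliss, Chou–Talalay) — the
  synergy probability is a screening prior, not a pharmacological effect
  size.
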