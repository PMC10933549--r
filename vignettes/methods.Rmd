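---
title: "Methods: literature-order gene recommendation in nextgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-order gene recommendation in nextgene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nextgene)
```

## The model

`nextgene` treats "which gene should the next experiment analyze?" as a
ranking problem supervised by the literature itself. Result sections
describe experiments in a largely sequential order, and consecutive
descriptions of *different* genes overwhelmingly reflect sequentially
performed experiments — the package's audit statistic,
`sequentiality_stats()`, quantifies this as a proportion with a
percentile-bootstrap CI (10,000 resamples). Ordered tuples
(*gene_prev*, *gene_next*) harvested from per-article experiment lists are
therefore used as positive examples; negatives are constructed by
replacing *gene_next* with a random gene (3 per positive by default),
turning whole-universe ranking into binary classification. At query time
every candidate tuple (query, candidate) is scored and the universe —
restricted to protein-coding genes — is sorted by that probability.

The biological rationale is the functional module: genes act in concert,
so the partners of a gene's next experiment are typically its module
co-members, and module co-membership is visible simultaneously in
annotation overlap, profile correlation, embedding proximity and network
linkage. The feature encoding exposes exactly these signals.

## Extraction assumptions

Dictionary matching is case-insensitive and word-boundary anchored. The
stopword filter exists because common-word aliases ("was", "can") would
otherwise flood extraction with false positives; case-insensitive matching
is what makes that filter meaningful, so both decisions come as a pair.
Overlapping dictionary hits are resolved longest-match-first with ties to
the leftmost start — a longer surface is more specific evidence. A surface
string claimed by two different genes identifies neither and is excluded
outright rather than guessed. Each occurrence of a gene matched twice in a
sentence generates its own candidates: occurrences are distinct evidence.

Relation classification is a pluggable contract (`score(masked) → [0,1]`).
The package ships two deterministic baselines — all-positive (recall 1 by
construction, precision equal to the label positive rate) and
nearest-method — because the transformer that would normally fill this
slot is an external component; everything downstream only assumes the
contract. Cross-sentence relations are out of scope. Sentence segmentation
is a simple rule-based splitter and is equally pluggable; pre-segmented
corpora bypass it.

## Encoding rules and their edge cases

Each categorical term contributes three slots: (1,0,0) both genes
annotated, (0,1,0) previous only, (0,0,1) next only, (0,0,0) neither.
Terms annotating fewer than 10 genes are dropped (defaults follow the
thresholds the sources are normally used with); dictionary-learning
loadings annotate a gene only when |loading| > 0.1, strictly. Numerical
sources contribute the pair's Pearson correlation, embeddings the cosine
similarity.

Conventions where the inputs are silent: a gene missing from a source, a
zero-variance profile, a zero-norm embedding, or fewer than 3
pairwise-complete samples all encode as 0 — the no-evidence point of both
correlation-like encodings. The term vocabulary is frozen when the schema
is built (training time); unseen terms at inference are ignored. Swapping
the pair order exchanges the prev-only/next-only slots and leaves
everything else unchanged, which the tests assert as a property.

## Training and attribution

Seven classifier families sit behind one interface; hyperparameters are
the library defaults recorded in the model artifact (gradient boosting:
100 rounds, depth 6, learning rate 0.3; logistic regression is
ridge-penalized at λ = 1e-3 for a well-defined fit on separable,
high-dimensional encodings; forests: 500 trees; MLP: 8 hidden units,
decay 0.01; k-NN: k = 10). Scores are raw classifier probabilities — no
calibration — because the ranking only needs a monotone score. Training is
single-threaded and seeded, so fits and predictions are reproducible, and
artifacts serialize/reload with bit-identical predictions.

Per-suggestion explanations use sampled-permutation Shapley values: for
each sampled permutation, features switch from a background draw to the
instance value in permutation order, accumulating marginal score changes.
The estimator satisfies efficiency exactly (contributions sum to
score − mean background score) and converges to the exact
subset-enumeration Shapley value, which the test suite verifies by brute
force on ≤ 10-feature models. The background is a fixed, seeded sample of
training rows (default ~100). This model-agnostic estimator is the
package's attribution contract; tree-specific fast paths would be an
optimization, not a behavioral change.

The method-category predictor is a ridge multinomial regression over the
closed 20-category set, fitted along the regularization path and read off
at λ = 0.01 (a single tiny λ is numerically fragile for near-separable
multinomial fits). Categories unseen in training get probability 0;
single-example categories are excluded from the fit with a warning; ties
in the argmax break by the fixed category order.

## Evaluation rules

AUROC is computed in its rank form (Mann-Whitney probability, ties ½).
AUROC@k first adds uniform tie-breaking jitter in (0, 1e-10) from a
dedicated seeded generator — drawn once per ranking, before zeroing — then
sets all scores below rank k to 0. Genes that followed the query in the
training period but not in the evaluation period are removed before
scoring: they can be counted neither as positives nor fairly as negatives.
Queries left without a positive are skipped and counted, matching the
per-query definedness of AUROC.

The network comparator is a random walk with restart,
r ← (1−c)·P·r + c·e with P the column-normalized weighted adjacency
(transitions out of each node), restart c = 0.15, L1 convergence at 1e-9.
These values are explicit stand-ins for a library default and are
oracle-checked: the iterative solution must agree with the dense linear
solve r = c(I − (1−c)P)⁻¹e within 10× the tolerance. Column normalization
is the mass-preserving choice, so proximities form a probability
distribution; nodes unreachable from the seed get proximity 0 and are
flagged, and an isolated seed returns the degenerate restart vector with a
warning. When RWR proximities are exported as features for an augmented
model, values below an integration cutoff (e.g. 5e-4 or 1e-3 depending on
the network) are zeroed.

Model comparison uses two-sided Mann-Whitney tests, Bonferroni-corrected
over all pairwise comparisons reported in one run, plus percentile
bootstrap (10,000 resamples) for per-model mean CIs and paired
query-resampled CIs of mean differences.

## The synthetic world

The generator's defaults define the package's standard study conditions:
300 genes in 15 modules, 400 articles of 3–8 experiments, years 2015–2022
uniform per article, within-module continuation probability 0.9, term sets
of 5 terms per module per categorical source carried by members with
probability 0.9 and leaked to non-members at 0.02, profile noise set so
within-module correlation is ~0.8 over 50 samples, 100-dimensional
embeddings around module centroids (noise sd 0.6), within/between edge
densities 0.3/0.01, and a favored method category per module used with
probability 0.7. These sizes are what a fully grown in-silico cohort of
this design needs to give every module enough articles, every term enough
genes to survive the ≥10-gene filter, and every split enough queries,
while a full pipeline run stays comfortably within interactive time on a
single core.

Sentence templates are deliberately trivial so dictionary matching is
exact on the fixture corpus: the extraction tests measure extraction
logic, not NLP. Consequently, passing the end-to-end recovery criterion
(mean AUROC@100 > 0.75 and above the frequency baseline, seed-0 world)
demonstrates that the pipeline recovers planted module structure through
every stage — it does not demonstrate performance on real text, real
nomenclature ambiguity, publication bias, or release-dependent annotation
sets, none of which the generator emulates.

## Numerical choices and limitations

Half-open 1-based character spans everywhere in extraction; masking
replaces right-to-left so offsets stay valid; ranking sorts are stable
with ties left to the evaluation jitter; negative sampling is implemented
as sampling-without-replacement from the legal partner set, which is
distributionally identical to uniform draws with rejection and redraw.
Determinism is a package-wide contract: fixed seeds give byte-identical
worlds, feature matrices and evaluation reports, and all seeded helpers
restore the caller's RNG state.

Known limitations: the relation-extraction slot ships only with
deterministic baselines; annotation sources are consumed as flat tables
(no ontology-graph propagation); the frequency baseline ignores query
context by design; and the sequential-order supervision inherits the
literature's own biases, which the synthetic world does not model.
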