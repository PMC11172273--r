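---
title: "Semantic re-ranking with Medical-Dependent Features: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic re-ranking with Medical-Dependent Features: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semrank)
```

## The problem

Text-based medical image retrieval ranks images by matching a textual query
against image captions or metadata. Plain term-weighting models (BM25) treat
captions as bags of words and miss the closed, highly structured vocabulary
that medical captions actually use: imaging modality, microscopy type,
dimensionality, colour, test and condition descriptors. `semrank` implements
a re-ranker that represents both queries and captions over such a closed
vocabulary of **Medical-Dependent Features (MDF)** — 87 canonical values in
9 categories in the packaged default — and fuses a semantic matching score
with the BM25 first-pass score.

The pipeline is:

1. **Annotation** (`mdf_annotate()`): deterministic, case-insensitive,
   longest-match-first lexicon matching of canonical values and synonyms on
   token boundaries, keeping duplicate occurrences in text order (positions
   feed the proximity and organization filters).
2. **Semantic embedding** (`load_ssm()` / `fixture_ssm()`,
   `build_feature_matrix()`): an n x n semantic similarity matrix (SSM) over
   the vocabulary; each item's binary presence vector V is broadcast
   row-wise (M[i,j] = V[i]) and masked against the SSM to give the item's
   feature matrix NQM = M * SSM (elementwise).
3. **Filter bank** (`compute_filter_scores()`): twelve scalar relevance
   filters — six query-side (confidence, length, inverse rank, proximity,
   PMI, feature difference) and six document-side analogues.
4. **Forward pass** (`represent()`): each filter score is lifted to a filter
   vector, convolved against the item's NQM row-by-row, passed through ReLU,
   max-pooled to a scalar, and the six pooled scalars are mapped through a
   fully connected layer (identity by default).
5. **Matching and fusion** (`rsv_cosine()`, `semrank_fuse()`): cosine
   similarity of the two six-dimensional representations gives the deep
   matching model (DMM) score; the re-ranking score is
   `alpha * bm25/max(bm25) + (1 - alpha) * dmm/max(dmm)` over each query's
   candidate list, with `alpha = 0.3` by default.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.3 | fusion weight of the normalized baseline score; 0 = DMM only, 1 = BM25 only |
| `depth` | 1000 | number of baseline candidates re-scored per query (TREC convention) |
| `k1`, `b` | 1.2, 0.75 | standard BM25 saturation / length normalization |
| `within_category_boost` | 0.5 | fixture-SSM increment for same-category value pairs |
| `tau` | 0.6 | synthetic relevance threshold on the mean best-match similarity |
| `epsilon` | 0.05 | synthetic label-noise flip probability |

## Numerical and design choices

* **Vocabulary indexing is 1-based and dense**, in category-then-list order;
  the index is stable across runs for a fixed source file.
* **n counts feature values (87), not categories (9)**: the binary vector is
  defined by "contains the feature value or not", which is only well defined
  over values.
* **External SSM normalization.** Information-content similarity measures
  (e.g. Resnik over a medical metathesaurus) are unbounded above, so loading
  min-max rescales off-diagonal entries to [0, 1], symmetrizes asymmetric
  files by averaging, and forces the diagonal to 1. A constant positive
  off-diagonal maps to 1 (no contrast to preserve); an all-zero off-diagonal
  stays 0. Set `normalize = FALSE` to keep raw values.
* **PMI** uses the natural logarithm; the base only rescales scores. The
  document-side PMI filter substitutes the document's occurrence count for
  the collection size, which makes it strongly negative in realistic
  collections (document sizes are far below document frequencies); after the
  ReLU it is then usually silent.
* **Zero-evidence conventions.** Every filter is a total function; all
  0-denominator or no-evidence cases return 0, except the feature-difference
  filters, whose form 1/(1 + missing-count) is positive by construction.
* **Organization factor.** The rank document filter multiplies the
  within-document frequency of query values by 1 when the query's
  first-occurrence value order (restricted to values present in the
  document) appears as a subsequence of the document's occurrence list, else
  by 0.5. The restriction means a document is not penalized for values it
  does not contain.
* **No training.** The method defines no loss, labels, or optimizer, so the
  fully connected layer defaults to the identity and the network is a
  deterministic feature aggregator; a seeded random weight matrix exists for
  ablation only.
* **Fusion normalization** divides by the maximum over the per-query
  candidate list, not the whole collection: a re-ranking architecture only
  ever scores the baseline's top-K candidates. Ties break by higher baseline
  score, then document id, so runs are byte-reproducible.
* **Query-side feature-difference filter**: the implemented form counts
  query values missing from the document (1/(1 + |Q \ D|)), which matches
  the filter's stated intent; a variant counting the intersection instead is
  exposed as `fdqf_variant = "intersection"`.

## What the synthetic generator emulates

`generate_collection()` draws captions as MDF value strings interleaved with
Zipf-distributed filler tokens, queries as 1–3 MDF values plus 0–2 filler
tokens, and binary relevance from the semantic overlap score
`S(q, d) = mean_j max_i SSM[i, j]` thresholded at `tau`, then flipped with
probability `epsilon`. Two structural choices matter:

* **Zipf ranks are spread over the vocabulary by a seeded permutation.**
  Assigning ranks in vocabulary order would put nearly all probability mass
  in the first category and make most pairs relevant.
* **Items are topically coherent**: each document or query draws a focus
  category and samples values within it with probability 0.8
  (`topic_cross_rate = 0.2` otherwise from the global distribution). Real
  captions mention features of one modality family together; this gives the
  collection genuine co-occurrence structure, which the confidence and PMI
  filters consume. Without it, independent sampling makes collection
  co-occurrence statistics carry no semantic signal at all.

Filler tokens give BM25 signal the DMM cannot see, so the `alpha = 0` limit
is demonstrably inferior to the fused ranking. What the generator does *not*
emulate: real caption syntax, graded relevance, vocabulary gaps in the
annotator (every planted value is recoverable by the lexicon matcher), and
visual features. Passing tests on synthetic collections therefore validate
the pipeline's mechanics and internal consistency, not clinical retrieval
quality.

The default study conditions — 500 documents, 20 queries, 20 replicates —
keep a full replicated end-to-end run within a few minutes on one CPU while
leaving per-query candidate lists several hundred deep.

## A structural property of the matching network, and a known limitation

With the row-broadcast feature matrix, per-filter convolution, max-pooling
and an identity fully connected layer, the forward pass has a closed form:
for filter score `s`, the feature map is `C[i] = s * V[i] * sum_{k in item}
SSM[i, k]`, so the pooled value is `max(s, 0) * A`, where
`A = max_{i in item} sum_{k in item} SSM[i, k]` is a per-item positive
constant. Each side's representation is therefore
`relu(filter scores) * A`, and because cosine similarity is scale-invariant,

* the semantic similarity matrix **cancels out of the DMM score entirely**,
  and
* the DMM score reduces to the cosine between the clipped query-filter and
  document-filter score vectors.

This has a consequence users should know: candidate pairs with *no* shared
evidence align almost perfectly, because the feature-difference components
(1/(1 + missing)) are the only non-zero coordinates on both sides, giving
cosine close to 1. Well-matched pairs score *lower*, since the
document-side count-valued components (shared-value count, frequency times
organization) grow past the bounded query-side components and rotate the
document vector away. On synthetic collections the DMM score is therefore
negatively correlated with relevance among BM25 candidates, DMM-only
ranking (`alpha = 0`) is consistently the worst of the three systems, and
the fused ranking at `alpha = 0.3` — which weights the DMM component 0.7 —
trails the BM25 baseline rather than improving on it; in the replicated
default study the fused MAP exceeds the baseline MAP in 0 of 20 replicates,
while DMM-only is below the fused ranking in 20 of 20. A trained fully
connected layer could in principle re-weight the components (that is
presumably what the original system's network contributed), but no training
signal is part of the published method, and this package deliberately ships
the deterministic, reproducible form with the defect documented rather than
an invented training procedure.

## Evaluation machinery

MAP, P@5 and P@10 follow trec_eval conventions: P@k divides by k even for
short lists; average precision divides by the total number of relevant
documents in the qrels; queries with no relevant documents are skipped from
MAP with a warning. Relevance is binary (grade > 0). `compare_runs()` pairs
per-query metric values and applies a two-sided Wilcoxon signed-rank test
with zero differences dropped, flagging significance at p < 0.05; with
fewer than two non-zero differences the p-value is undefined and reported
as not significant with a reason.

## Worked example

```{r example, eval = FALSE}
vocab <- mdf_vocabulary()
ssm <- fixture_ssm(vocab, seed = 42)
coll <- generate_collection(synth_config(n_docs = 200, n_queries = 10,
                                         seed = 42), vocab, ssm)
rr <- semrank_rerank(coll$corpus, coll$queries, ssm, vocab)
evaluate_run(rr$run, coll$qrels)
sw <- alpha_sweep(coll$corpus, coll$queries, ssm, vocab, coll$qrels)
autoplot(sw)
```
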