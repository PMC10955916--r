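---
title: "Topic-ensemble consensus clustering: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-ensemble consensus clustering: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicensemble)
```

## The model

`topicensemble` screens a corpus of respondent-level transcripts into
two groups without labels. The working assumption is that the two
populations of interest (e.g. low- and high-stress family caregivers)
emphasize different themes, that those themes surface as different
*discriminative* words, and that the remaining vocabulary is either
*common* (said by nearly everyone, hence uninformative) or *rare*
(said by one or two people, hence unestimable). The pipeline has four
stages.

**TF-IDF with rule-based pruning.** Raw term counts are weighted by the
smoothed inverse document frequency $\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1$
and each document row is scaled to unit Euclidean norm. This is the
most widely used TF-IDF variant; since the two pruning thresholds are
defined on the resulting weights, using another variant would change
what they mean, so both are exposed as parameters. A term survives iff

* total weight $\sum_d w(d,t) \ge \tau_{total}$ (default 0.5) — fails
  for rare words, whose few occurrences contribute little mass; and
* $\max_d w(d,t) / \sum_d w(d,t) \ge \tau_{ratio}$ (default 0.1) —
  fails for common words: a word spread evenly over $N$ documents has
  ratio $\approx 1/N$, far below 0.1 for $N = 100$, while a word
  concentrated in a handful of documents keeps a large ratio.

Pruning happens once, before the ensemble, and the surviving columns
are *not* renormalized: a second normalization would silently change
the geometry the thresholds were calibrated on.

**Ensemble member generation.** NMF ($V \approx WH$, Frobenius
objective, multiplicative updates) is a standard topic model, but its
solution depends on the random initialization. Instead of fighting that
randomness, the ensemble exploits it: `n_runs = 70` fits with
consecutive seeds and `k = 10` topics each yield 700 topic vectors
(L2-normalized rows of $H$) that over-cover the corpus's thematic
structure. Initialization is seeded uniform random — deliberately *not*
a deterministic scheme like NNDSVD, which would collapse the ensemble's
diversity to a single basin.

**Consensus function.** The pooled topics are clustered by
agglomerative hierarchical clustering, complete linkage, cosine
distance, cut at `n_clusters = 2`. Cosine is the natural choice because
NMF factors are scale-indeterminate and the topics are already
direction-only after normalization; complete linkage is conservative —
it only merges clusters whose *farthest* members are close, so the two
final clusters are compact rather than chained.

**Document assignment.** The method needs a rule mapping documents onto
the two topic clusters, and this was a genuinely open design point. The
package uses cluster mass: each run's $W$ columns are first multiplied
by the norms of the matching $H$ rows (preserving $WH$), each
document's per-run loading row is L1-normalized so every run
contributes exactly one unit of mass per document, and a document's
score for a cluster is the summed mass on that cluster's topics.
Scores therefore add up to `n_runs` per document, every ensemble member
votes symmetrically, and the rule reduces to "majority topic mass";
exact ties go to the lower cluster id.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tau_total` | 0.5 | minimum total TF-IDF mass of a word (unitless, on row-normalized weights) |
| `tau_ratio` | 0.1 | minimum max/total mass ratio; roughly "concentrated in ≲ 10 documents" |
| `k` | 10 | topics per NMF run |
| `n_runs` | 70 | ensemble size; 700 members at the defaults |
| `n_clusters` | 2 | consensus groups |
| `seed_base` | 0 | seeds are `seed_base, …, seed_base + n_runs − 1` |
| `max_iter`, `tol` | 200, 1e-4 | NMF stops at `max_iter` sweeps or when the relative Frobenius-error improvement drops below `tol` |

The defaults for `k`, `n_runs` and the two thresholds are the reference
operating point of the method; `tol = 1e-4` with `max_iter = 200` makes
a 100-document fit converge in well under a second while leaving
reconstruction error within a fraction of a percent of a much longer
run.

## Numerical choices

* NMF multiplicative updates carry an additive `1e-9` in each
  denominator; factors initialized from `runif` stay strictly positive,
  so no row of $H$ can collapse to exact zero. The recorded
  per-sweep Frobenius error is non-increasing (a property the tests
  check on random matrices).
* All randomness is locally scoped: `fit_nmf()` and
  `generate_corpus()` save and restore the caller's RNG state, so a
  fixed seed gives bit-identical results regardless of context.
* Vocabulary order, keyword tie-breaks and mutual-information
  tie-breaks use byte (radix) order, not locale collation.
* Complete linkage is delegated to `stats::hclust`. On *exactly* tied
  merge distances its merge order may differ from the package's test
  oracle, which merges the pair with the smallest member indices; ties
  have probability zero for continuous topic vectors, and the
  oracle-equivalence tests use continuous random pools.
* Classical (Torgerson) MDS is used for visualization because it is
  deterministic — no iterative stress minimization, no restarts. Signs
  of the two axes follow a fixed convention (largest-magnitude
  coordinate positive). When the profile geometry is essentially
  one-dimensional — which genuinely happens when two clusters are
  perfectly separated, since all consensus profiles then sit near two
  points — the embedding falls back to 1D plus a zero column with a
  warning rather than failing.
* Mutual information between a word and the label is computed on the
  *binarized* feature (weight > 0 vs = 0) with the plug-in estimator,
  in bits. Binarization is the most conservative choice given that no
  binning scheme for continuous TF-IDF features is canonical.
* `match_clusters_to_labels()` tries both cluster-to-label permutations
  and keeps the accuracy-maximizing one (identity on ties), because
  unsupervised cluster ids carry no semantics. Consequently reported
  accuracy is ≥ 50% by construction. Rate naming follows the
  screening convention used with these metrics: *positive* = low
  stress, *negative* = high stress — the reverse of the usual clinical
  reading; the functions document this prominently.

## What the synthetic generator emulates

`generate_corpus()` draws each document token by token: a background
word with probability 0.5 (uniform over a 60-word shared vocabulary), a
group word with probability 0.45, and a rare word with probability 0.05,
where each of the 30 rare words is used exactly once corpus-wide and
then retired (exhaustion falls back to background words with a
warning). Labels are the group memberships; 50 documents per group.

The group-word distribution is the load-bearing design choice. Each
document draws its own-group words from a document-specific
Dirichlet(0.1) preference over the group's 40 words, mixed with a
uniform within-group floor of weight 0.2. This emulates how interview
speech actually behaves: respondents in a group share a lexicon but
each emphasizes a handful of personally salient themes. The two
components map directly onto the two pipeline requirements:

* the *concentration* makes each discriminative word's weight peak in a
  few documents, so the max/total rule retains it — a uniform
  within-group distribution would spread every group word over ~45 of
  100 documents, giving ratios near 0.02 and causing the common-word
  rule to delete the entire discriminative vocabulary (and with it any
  possibility of recovery);
* the *floor* keeps every pair of same-group documents (and hence every
  pair of same-group NMF topics) positively correlated, which complete
  linkage needs in order to assemble each group into one compact
  cluster — pure concentration would leave same-group topics mutually
  orthogonal and the 2-cluster cut arbitrary.

The `separation` parameter scales how exclusive the group vocabularies
are: a group-word draw uses the document's own vocabulary with
probability $(1 + s)/2$. At $s = 1$ vocabularies are fully exclusive;
at $s = 0$ both groups draw group words identically and the corpus
contains no label signal at all, so matched accuracy sits at the
chance floor of 50%.

What the generator does **not** emulate: Zipfian frequency structure
across roles, polysemy and segmentation ambiguity, transcription (ASR)
errors, varying document lengths, topic correlation between groups, or
any linguistic structure at all — tokens are opaque strings. Passing
the recovery tests therefore shows the pipeline's machinery is sound
under its own assumptions, not that any particular accuracy carries
over to real interview data.

## Problem sizes in the test suite

Unit and property tests run on corpora of 8–30 documents and ensembles
of 3–8 runs, where every oracle (brute-force rule evaluation, naive
$O(n^3)$ complete linkage, entropy-identity mutual information) is
exact and fast. End-to-end checks use the generator's full default
scale — 100 documents, 70 × 10 ensemble members — across five
generator seeds at separation 1.0 and five at 0.0; a complete fit at
that scale takes well under a minute, so the whole suite stays
comfortably interactive.

## Known limitations

* The two pruning thresholds are calibrated to row-L2-normalized
  TF-IDF at $N \approx 100$ documents; corpora that are much larger, or
  weighted by another TF-IDF variant, will need different values.
* With `n_clusters = 2` the method is a screener, not a diagnostic: it
  separates two populations whose vocabularies differ, and its cluster
  ids acquire meaning only after matching against external labels.
* The document-assignment rule is a declared design choice (the
  consensus literature offers several); alternatives such as
  co-association matrices are out of scope.
* Complete linkage is sensitive to outlier topics: a single ensemble
  member far from everything else can absorb one merge late in the
  tree. The 70-fold redundancy of the pool is what makes this rare in
  practice.
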