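---
title: "Rubric-mapped semantic spaces: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rubric-mapped semantic spaces: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbuiltr)
```

## The problem

Automated scoring of constructed responses (student summaries, short
answers) with latent semantic analysis usually compares a response vector
against gold-standard vectors. The coordinates of an LSA space are latent:
vectors are comparable but not interpretable. The Inbuilt Rubric method
takes the opposite route — it *imposes* an assessment rubric onto the space
by a change of basis, so that the leading coordinates of any projected
response directly read as "how much does this text cover concept j". This
package implements that method, its bifactor extension with a general
knowledge dimension, the psychometric battery used to validate such scores
against human raters, and a seeded synthetic-data generator so the whole
pipeline can be exercised and tested without any external corpus.

## The semantic space

A lemmatized corpus is counted into a term-document matrix; terms appearing
in fewer than `min_doc_freq = 2` documents are dropped by default (a
single-document term has log-entropy weight exactly 1 and can dominate a
concept vector built from it). Entries are weighted by log-entropy,

\[ x_{td} = \log(1 + f_{td}) \cdot \Big( 1 + \frac{\sum_d p_{td} \log p_{td}}{\log n} \Big), \qquad p_{td} = f_{td} \Big/ \sum_d f_{td}, \]

so that ubiquitous terms (maximal entropy) are annihilated and
concentrated terms keep weight near 1. The weight is invariant to the
logarithm base; natural logarithms are used throughout. A truncated SVD
\(X \approx U_k S_k V_k'\) yields term vectors as rows of \(U_k S_k\) — the
"US" matrix — and \(V\) is discarded; new documents are represented by
fold-in, the plain sum of their terms' vectors. Document vectors are *not*
length-normalized by default: raw projection scores grow with text length,
which is a real and interpretable property of summary data (longer
summaries cover more), and the validation battery consumes raw scores. A
unit-normalization flag exists for scale-free scoring. Whether fold-in
should additionally weight each token by its global entropy weight is not
settled; both behaviors are available (`weight_terms`), with the unweighted
sum as default.

## Mapping the rubric into the basis

Each rubric concept is a handful of lexical descriptors (about three is the
usual working recipe; the package warns, not errors, at other counts) or,
in the automatic variant, all nouns inside a fragment of the instructional
text. The concept vector is the sum of the corresponding term vectors,
normalized **once, after** summation — component vectors keep their natural
\(US\) magnitudes, so strongly represented terms carry more weight
(`prenormalize_terms` flips this). Repeated fragment nouns contribute once
per occurrence (multiset semantics); `unique_terms` collapses to a set. The
quality of a descriptor set is checked by its semantic neighborhood
(`neighborhood_check`): the nearest vocabulary terms of the concept vector
should belong to the intended concept.

The basis matrix has the \(k\) concept vectors in its leading columns and
standard-basis vectors, drawn uniformly at random without replacement under
a seed, in the remaining \(p - k\). Modified Gram-Schmidt orthonormalizes
the columns strictly in order — meaningful block first — so the concept
vectors retain maximal fidelity; the classical and modified variants
coincide in exact arithmetic, and the modified one is numerically stabler.
Fidelity is the Pearson correlation between each meaningful column before
and after orthogonalization, with 0.80 as the reliability gate (warning by
default, error in strict mode). In degenerate low-dimensional cases where a
column has zero coordinate variance the uncentered correlation (cosine) is
used instead; at realistic dimensionality the two are indistinguishable. A
fill column that leaves a near-zero residual (norm below 1e-10) aborts with
an error naming the column, and the pipeline driver re-seeds the draw
rather than silently skipping.

The rotation itself is exact: every term vector is re-expressed as its
inner products with the orthonormal basis columns, so all norms and
pairwise cosines are preserved (asserted within 1e-8 in tests). Scoring a
response is then fold-in plus reading the leading coordinates.

## The bifactor variant

Orthogonalization forces concept dimensions to share no variance, but the
concept *vectors* do share variance — general topical knowledge. The
bifactor variant estimates one extra basis vector for it: each concept's
lemma list is split at random into two balanced subsets, each subset
becomes a unit vector, a one-factor EFA (minimum-residual extraction; no
rotation is needed for one factor) treats the \(2k\) subset vectors as
variables over the \(p\) coordinates, and the general vector is the
loadings-weighted sum of the subset vectors, normalized at the end. Raw
loadings are used as weights; only the final vector is normalized. Small
numerical overshoots of a loading beyond 1 are clamped; a genuine Heywood
configuration errors with the loadings printed.

Where the general column goes is a genuinely open design point: placing it
*after* the concepts leaves the concept dimensions identical to the classic
variant and residualizes G against them; placing it *first*
(`general_position = "general_first"`) residualizes every concept dimension
against G, which matches bifactor semantics — specific dimensions orthogonal
to a general dimension — and is what produces the "distillation" effect
(concept-score intercorrelations drop once their common variance is routed
to G). Both orders are exposed and recorded in the output; the
distillation analyses in this package use `general_first`.

## The validation battery

The battery mirrors standard practice for validating computational scores
against human criteria:

* **Inter-rater reliability**: Shrout-Fleiss intraclass correlations from
  two-way ANOVA mean squares. The two-way mixed family is fully
  configurable (single/average, consistency/agreement) because reports
  often do not say which form was used; the default is single-rater
  consistency, and the variant is recorded in the result.
* **Descriptive contrasts**: paired t tests with Cohen's d. The default d
  is the mean difference over the SD of differences (d_z); the pooled-SD
  alternative is available.
* **Factor retention**: Horn's parallel analysis with the 95th-percentile
  criterion, for both principal-component eigenvalues and common-factor
  eigenvalues (squared multiple correlations on the diagonal). Retention
  stops at the first non-exceeding eigenvalue.
* **EFA**: maximum-likelihood extraction (minimum-residual available) with
  direct oblimin rotation implemented by gradient projection; factor
  scores by the regression (Thomson) method; fit reported as RMSEA with a
  90% CI from the noncentral chi-square, TLI, and RMSR.
* **Standardized-beta regressions**: OLS on z-scored outcome and
  predictors, one model per human concept, with an exact-collinearity
  guard that names the offending columns.
* **ULS CFA/SEM**: a RAM-parameterized engine minimizing
  \(\tfrac12\lVert S - \Sigma(\theta)\rVert_F^2\). ULS has no native
  chi-square; the reported statistic is \((N-1)\) times twice the minimized
  discrepancy — a software convention, not a distributional claim — and
  CFI/TLI/RMSEA are computed from it against the independence baseline
  fitted under the same estimator. SRMR is the usual standardized residual
  root mean square. Standard errors come from the numerical Hessian of the
  scaled discrepancy, carrying the normal-theory convention over to ULS;
  they are approximate and are flagged as such. Data are standardized
  before fitting by default so indicators on a 0-2 rating scale and
  computational scores of much smaller natural magnitude enter the
  discrepancy on an equal footing.

The cross-loading structural model regresses each human concept factor
(measured by the raters' scores for that concept) on *all* computational
concept scores; convergent/discriminant validity holds when the largest
standardized path for every human factor is its matching computational
score. The bifactor form adds a human general factor loading on every
rating, fixes specific-factor residual correlations to zero, and predicts
the general factor from the observed general score(s) of the bifactor
computational variant, with a free covariance between the two general
indicators when both the descriptor- and fragment-based versions are
supplied.

No multiple-testing correction is applied anywhere; raw p-values are
reported. Missing ratings are handled by listwise deletion with a logged
count.

## What the synthetic generator emulates — and what it does not

The generator is a seeded multinomial topic mixture, generation only:

* **Corpus** (`topic_spec`): 5 topics of 200 exclusive words, 200 documents
  per topic, mean length 60 — a desk-scale stand-in for an
  instructional-domain corpus that trains in about a second. Tokens come
  from the document's own topic under a Zipf profile, from a 100-word
  shared pool with probability `shared_vocab_fraction` (the planted
  general-knowledge component), or from another topic with probability
  `topic_leak = 0.05`. The leak matters: if topics never co-occur in any
  document, their trained centroids are *exactly* orthogonal (their
  cross-covariance blocks are identically zero) and no common variance
  exists for a general factor to capture — unlike any real corpus. Each
  document also perturbs its topic's word distribution with a Dirichlet
  draw (`burstiness = 0.2`), emulating word burstiness; without it the
  space collapses to roughly one usable direction per topic and a basis of
  k concepts plus a general vector becomes near-singular.
* **Summaries** (`summary_spec`): coverage weights from a symmetric
  Dirichlet (concentration 2, so summaries cover most concepts to varying
  degree), lengths gamma-distributed with mean 80 and SD 25, 20% off-topic
  noise. Length variance plays the role of writer ability and produces the
  positive manifold — concept scores and ratings correlating positively —
  that real summary data show and that the bifactor analysis presupposes.
  The realized per-topic token counts are returned as ground truth.
* **Raters** (`rater_spec`): each rater observes a noisy version of the
  (normal-scored) true concept amount and discretizes it to the 0-2 rubric
  scale at equal-probability cutpoints. The latent noise is calibrated so
  the *discretized* between-rater correlation hits the reliability target
  (default 0.8): a closed-form categorization-attenuation approximation
  provides the starting value and a common-random-numbers simulation
  refines it, because the approximation degrades near perfect reliability.

Passing tests on these fixtures shows that the algebra and the estimators
do what they claim under a known generative model of topical text. It does
not show that three descriptors suffice for any real rubric, that real
rater behavior is Gaussian-then-discretized, or that a real corpus' general
dimension means "knowledge" — those are substantive questions outside the
package's scope. Fixture sizes (1,000 training documents, vocabulary about
1,000, k = 50, 200 summaries, 20 seeds for the end-to-end batteries) were
chosen so the full test suite and the acceptance script each run in a few
minutes on a single CPU; they are stated here as the package's standard
desk-scale conditions.

## Numerical choices

* Tolerances are named constants (`ir_tolerances`): rotation invariance
  1e-8, Gram-Schmidt orthonormality and degeneracy 1e-10, general-vector
  collinearity gate |cos| > 0.999, fidelity gate 0.80.
* The SVD is dense (LAPACK) — exact and fast at desk scale; sparse storage
  is used for counts and the weighted matrix.
* `nlminb` drives both minres extraction (bounded uniquenesses) and the
  ULS engine (variances bounded below by 1e-8); SEM starting values are
  sample moments for saturated blocks, 0.8 for free loadings, and small
  positive values for paths.
* The oblimin rotation is the oblique gradient-projection algorithm with
  the direct-quartimin criterion (the oblimin family parameter is exposed);
  its analytic gradient is verified against finite differences in the test
  suite.
* Ties in neighborhood rankings break lexicographically; EFA factor
  columns are ordered by sum of squared loadings and sign-aligned to
  positive column sums.
* All stochastic steps (basis fill, descriptor splits, simulations) take
  explicit seeds and restore the caller's RNG state.

## Known limitations

* ULS standard errors and the chi-square-based indices inherit a
  convention, not a sampling theory; treat them as descriptive at small n.
* The general-vector EFA operates on space coordinates as observations;
  with very low-dimensional or rank-deficient spaces the one-factor
  solution can latch onto a single concept block (reported as a Heywood
  error) — a fixture-scale phenomenon worth knowing about when k is close
  to the effective rank of the space.
* With `general_first`, concept fidelities necessarily drop below 1; in
  fixtures whose effective rank is close to k + 1 the last-orthogonalized
  column can fall under the 0.80 gate. The gate is the method's own
  diagnostic for exactly this situation; the package warns and records the
  fidelities rather than hiding them.
* Lemmatization, POS tagging, and noun extraction are out of scope: inputs
  arrive pre-lemmatized, and fragment nouns arrive as explicit lists
  (an external tagger can populate them).
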