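---
title: "Predicting miRNA-disease associations with integrated similarities, a stacked autoencoder, and a cascade forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations with integrated similarities, a stacked autoencoder, and a cascade forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MicroRNAs regulate gene expression, and their dysregulation is implicated in
many complex diseases. Experimentally confirming which miRNAs are involved in
which diseases is slow and expensive, so curated catalogues of verified
miRNA-disease associations cover only a small corner of the possible pair
universe. `cascadeMDA` treats the completion of this bipartite network as a
supervised link-prediction problem: given the binary adjacency matrix
$A \in \{0,1\}^{n_m \times n_d}$ of verified associations, score every
unverified pair by its probability of being a true association.

The pipeline has four stages: (1) multi-source similarity computation,
(2) pairwise feature construction, (3) unsupervised compression with a
stacked autoencoder, and (4) classification with a cascade forest whose
final predictor is a polynomial-kernel SVM.

## Similarity model

**Disease semantic similarity.** Each disease is located in an ontology DAG
(MeSH-style child-to-parent term graph). Its DAG is its ancestor closure
$G(d)$ with induced edges $E(d)$. Two complementary contribution schemes are
combined:

* *Decay (Wang) scheme.* The disease's own term contributes 1 and each
  ancestor $k$ contributes $C_1(k) = \mu \max\{C_1(k') : k' \text{ child of }
  k \text{ in } G(d)\}$, i.e. $\mu^{\ell}$ where $\ell$ is the shortest
  ancestor-path length. The contribution factor $\mu = 0.5$ is the standard
  value for disease DAGs and is exposed in `semantic_params()`. The max is
  taken over children *within the disease's induced DAG* — the standard
  construction, stated here because it matters for multi-parent terms.
* *Information-content (Xuan) scheme.* A term appearing in $NG(k)$ of the
  $n_d$ disease DAGs contributes $C_2(k) = -\log(NG(k)/n_d)$, shared across
  all diseases: ubiquitous terms contribute nothing, rare terms a lot. The
  logarithm is natural by default (`log_base` is configurable; the choice
  only rescales numerator and denominator jointly, so it matters only when
  the two schemes are averaged).

Under either scheme the similarity of $d_i, d_j$ is the summed contribution
of shared terms from both sides, normalised by the two disease semantic
values $DS(d) = \sum_{k \in G(d)} C(k)$; the final semantic similarity is
the elementwise mean of the two schemes. Diseases without ontology coverage
get *missing* (not zero) semantic rows: a zero would assert dissimilarity,
whereas missingness lets the integration step fall back to the kernel
similarity. The diagonal is always 1 — a disease is identical to itself
whether or not the ontology covers it. A degenerate corner: if every term
shared by two diseases occurs in every DAG, the information-content
denominator is 0; the similarity is then defined as 0 off-diagonal.

**GIP kernel similarity.** The Gaussian interaction-profile kernel compares
binary profiles (rows or columns of $A$):
$KS(i,j) = \exp(-\alpha \lVert IP_i - IP_j \rVert^2)$ with bandwidth
$\alpha = \alpha' / \overline{\lVert IP \rVert^2}$, the numerator
$\alpha' = 1$ by default. Normalising by the mean squared profile norm makes
the kernel scale-free with respect to network density.

**Integration.** Where a primary similarity (miRNA functional similarity, or
disease semantic similarity) exists, the integrated value is the mean of
primary and kernel values; where it is missing, the kernel value is used
alone. The result never has missing entries, which the downstream feature
builder requires.

## Pair features and sampling

A pair $(i, j)$ is represented by four concatenated blocks:
$[\,MS_{i\cdot} \mid A_{\cdot j} \mid DS_{j\cdot} \mid A_{i\cdot}\,]$,
giving $2(n_m + n_d)$ columns (1756 at the reference scale of 495 miRNAs
and 383 diseases). All positives are kept and an equal number of negatives
is drawn uniformly without replacement from the unverified pairs.

One subtlety deserves emphasis. The literal construction embeds the pair's
own label: $A_{ij}$ occurs once inside $A_{\cdot j}$ and once inside
$A_{i \cdot}$. `build_pair_features(mask_target = FALSE)` (the default)
reproduces that literal construction; `mask_target = TRUE` zeroes those two
positions. Benchmarks that claim to measure generalisation must use masking
— the recovery benchmark and the case-study machinery in this package do —
while the unmasked variant exists because published headline numbers for
this family of pipelines are typically produced without masking, and users
comparing against them need the same convention. Neither behaviour is
chosen silently: the flag is recorded in the feature set object.

## Stacked autoencoder

Three autoencoders are trained greedily: each has a $\tanh$ encoder
$z = \tanh(Wx + b)$ and a linear decoder (inputs live in $[0,1]$, so a
bounded decoder activation would be an unnecessary constraint), trained by
Adam to minimise summed squared reconstruction error; layer $k$ fits the
codes of layer $k-1$. Code widths are 1024, 512, 256 for 1756-dimensional
input; narrower inputs shrink the widths proportionally
(1756 : 1024 : 512 : 256, minimum 2), so the compression ratio — not the
absolute width — is what the architecture preserves at small scale.

Defaults: 50 epochs per layer, batch 128, learning rate $10^{-3}$, Adam
moments $(0.9, 0.999)$. These are ordinary choices for a shallow
reconstruction problem of this size; all are exposed. The stack is fitted on
training data only and frozen before transforming validation or test rows,
avoiding representation-level leakage. Training is single-threaded and
bit-reproducible given the seed; a non-finite loss aborts with the offending
epoch rather than propagating NaNs downstream.

## Cascade forest

Each level holds four diverse tree ensembles of 100 trees each (400 trees
per level): a bagged random forest, a completely random tree forest (split
feature and threshold both random), a depth-wise second-order gradient
boosted ensemble, and a leaf-wise histogram gradient-boosted ensemble
(31 leaves). Diversity across the bank is the point: each estimator
contributes a differently-biased class-probability pair.

Within a level, every estimator runs stratified 5-fold cross validation;
each training sample's class vector is produced by the fold model that did
not see it. The four out-of-fold probability pairs (class order
$P(y{=}0), P(y{=}1)$; estimator order as listed above) form an 8-column
augmented block that is concatenated with the *original* features as input
to the next level. At prediction time each estimator's output is the mean of
its five fold models.

Growth is driven by a stratified 20% validation split carved from the
training data: a new level must improve validation AUC by more than
$10^{-3}$; one non-improving level is tolerated (`patience = 1`) before
growth stops, at most 10 levels, and the model rolls back to the best level
count. AUC was chosen over accuracy as the growth metric because it is
threshold-free; both the metric and all stopping parameters are in
`cascade_config()`.

The final predictor is a polynomial-kernel SVM (degree 3, cost 1) with
Platt-style probability calibration, fitted on the best level's
concatenated representation `[features | 8 augmented columns]`
(`svm_input = "concat"`; `"augmented_only"` gives the narrower variant — the
concatenation subsumes it). Two numerical choices matter here: the kernel is
inhomogeneous (`coef0 = 1`) and inputs are standardised inside the SVM. A
homogeneous cubic kernel on roughly zero-centred $\tanh$ codes produces
near-zero kernel values whose Platt calibration is unstable to the point of
sign inversion; the inhomogeneous standardised kernel is well conditioned.

Two ablation modes mirror the usual deep-forest baselines: `"classic"`
(alias `"model1"`) uses the traditional bank of two bagged and two
completely random forests with an averaging predictor, and `"average"`
(alias `"model2"`) keeps the diverse bank but averages instead of fitting
the SVM.

## Evaluation protocol

The balanced sample is split 80/20 (stratified); 4-fold cross validation
runs on the training set with the SAE and cascade refitted per fold, and the
final model refits on the whole training set and scores the test set once.
Reported metrics: accuracy, precision, sensitivity, specificity, MCC
(defined 0 when its denominator vanishes), F1 at threshold 0.5, plus
threshold-free AUC (tie-aware rank statistic) and AUPR (step-wise
precision-recall summation with tied scores grouped).

**Case studies.** For a held-out disease, the strict protocol removes the
disease's column and all its pairs from the labelled pool, recomputes every
similarity from the masked matrix, trains with target masking, and ranks all
candidate miRNAs. The scores then provably contain no information from the
held-out column (the test suite asserts invariance to permuting it). The
`reuse_global_similarity = TRUE` variant computes similarities once from the
unmasked matrix, so verified neighbours in the held-out column inform the
GIP features; this reproduces the laxer protocol common in the literature
and is the variant under which ranking enrichment is demonstrated (see
below).

## What the synthetic generator does and does not emulate

`generate_associations()` plants a low-rank logistic model:
$A_{ij} \sim \mathrm{Bernoulli}(\sigma(s\, \langle U_i, V_j\rangle/\sqrt r + b))$
with standard-normal factors, the bias calibrated by bisection to a target
density. The default recovery conditions are 120 miRNAs, 80 diseases, rank
5, density 0.10, signal 6 — large enough that fold AUCs are stable, small
enough for minutes-scale runs. `generate_functional_similarity()` derives
the functional-similarity stand-in as rescaled cosine of the miRNA factors,
with a symmetric random subset of pairs masked missing (default fraction
0.3) to exercise the kernel fallback. `generate_ontology()` grows a random
term forest in index order, each non-root term drawing up to `max_parents`
earlier terms as parents.

Two honest limitations. First, the random ontology is *independent* of the
planted factors, unlike MeSH, whose structure genuinely correlates with
shared miRNA involvement. Consequently, under the strict leave-one-disease
protocol no method can rank a held-out disease's miRNAs much better than
miRNA-marginal statistics allow: an oracle ranking by the true probability
column (which sees the held-out factors) is several times more enriched than
the best factor-blind proxies (miRNA degree, factor norm). Passing
recovery tests therefore demonstrates that the pipeline exploits
*within-network* signal, not that it would match real-data case-study hit
rates; the enrichment property (at least 3x over base rate among the top
candidates) is demonstrated under the global-similarity variant, where it
holds with margin. Second, the generator has no miRNA family structure or
annotation bias, so the difficulty of real negative sampling (unverified is
not unassociated) is not represented.

The permuted-label null calibration — mean CV AUC inside $[0.45, 0.55]$
under the same conditions — guards against any residual leakage through the
feature construction or protocol plumbing.

## Problem sizes and numerical choices

The shipped benchmarks use the recovery conditions above (balanced sample of
roughly 1,900 pairs, 400 raw feature columns compressed to 58); structural
checks run the genuine 495 x 383 feature construction and a full-width
1756-to-256 encoder. Similarity algebra is 64-bit throughout; symmetry is
enforced at $10^{-12}$ for computed matrices, and file input is symmetrised
by averaging with a warning beyond $10^{-8}$. Ranking ties in case-study
output break lexicographically by miRNA id for reproducibility. Every
stochastic step — generators, negative sampling, splits, fold assignment,
estimator seeds, SVM calibration — derives from a single integer seed, and
single-threaded runs are bit-reproducible.

## Known limitations

* The MeSH-to-disease-name mapping is the caller's responsibility; the
  ontology reader accepts any child-to-parent edge list.
* GIP similarities are computed once globally by default rather than per CV
  fold; the strict per-fold protocol applies only to the case-study path.
* The SAE is a fixed three-layer architecture; no fine-tuning pass is run
  after greedy pretraining.
* The averaging-mode predictor ignores estimator confidence weighting, as in
  the standard deep-forest formulation.
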