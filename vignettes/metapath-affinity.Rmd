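---
title: "Predicting drug-target binding affinity from a weighted heterogeneous network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target binding affinity from a weighted heterogeneous network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Measuring a dissociation constant for every compound against every kinase is
infeasible, so computational models are asked to predict the *continuous*
binding affinity of unmeasured drug-target pairs — a regression problem, in
contrast to the binary interaction-prediction setting. `dtbanet` implements a
structure-free (no protein 3D coordinates) network approach built on the
guilt-by-association premise: similar drugs tend to bind similar targets with
similar strength.

The data are arranged as a weighted heterogeneous graph with three edge
classes:

* **D-D edges** — drug-drug similarity (e.g. 2D-fingerprint Tanimoto, or the
  cosine similarity of learned SMILES fingerprints), min-max normalised to
  $[0,1]$ and thresholded;
* **T-T edges** — target-target similarity (e.g. normalised Smith-Waterman
  alignment scores, or cosine similarity of sequence embeddings), likewise;
* **D-T edges** — *training* affinities transformed to $[0,1]$ "binding
  strength" weights.

For a drug $d_i$ and target $t_j$, every path of at most three edges that
starts at $d_i$, ends at $t_j$, and repeats no node belongs to one of six
structures: $C_1$ = D-D-T, $C_2$ = D-T-T, $C_3$ = D-D-D-T, $C_4$ = D-T-T-T,
$C_5$ = D-D-T-T, $C_6$ = D-T-D-T. The score of a path is the **product** of
its edge weights — since all weights lie in $[0,1]$, longer, weaker chains of
evidence are automatically penalised. Per structure the package records the
*sum* of path scores (total evidence) and the *maximum* (strongest single
chain), giving 12 features per pair per graph, or 24 when two similarity
sources are used side by side. A gradient-boosted regression tree ensemble
(xgboost, squared-error objective) maps these features — optionally
concatenated with raw drug/protein embedding vectors — to the affinity.

## Edge construction choices

**Orientation.** Affinity scales disagree about direction: raw $K_d$ is a
distance (lower = stronger) while $pK_d = -\log_{10}(K_d/10^9\,\mathrm{nM})$
is a strength (higher = stronger). Published discussions of these benchmarks
are themselves inconsistent about which scale is meant, so the dataset
container carries an explicit `orientation` flag rather than a guessed
convention. `assemble_graph()` always forms a distance-like quantity first
($\max - y$ under `higher_is_stronger`, $y - \min$ otherwise, with the
min/max taken over *training* edges only) and maps it through the transform,
so a larger D-T weight always means stronger binding regardless of the input
scale.

**Transform.** Two transforms are provided. The exponential
$f(z) = e^{-\alpha z}$ maps distance 0 (the strongest training binder) to
weight 1 and decays at rate $\alpha$ (default 0.5; the conventional
validation grid is $\{0.1, 0.5, 1\}$ — the smaller $\alpha$, the more distant
affinities still contribute to path products). The SoftMax alternative
normalises the strength-oriented values into a probability vector over all
observed training edges — a single global normalisation, not per drug row,
because the transform is defined over the one vector of all affinity values.
It is computed with the usual max-shift so large affinities cannot overflow.

**Thresholds.** Similarity edges below a cutoff are removed (and the diagonal
is always zeroed). Defaults are 0.3 for drugs and 0.04 for targets — the
published operating points for 2D-structure and normalised Smith-Waterman
similarities on a dense kinase panel. Both are plain config values
(`transform_config()`): the right cutoff is a property of the similarity
measure, not of the method, and should be re-examined per dataset.

## Walks versus simple paths

Commuting-matrix products ($DD\cdot A$, $A\cdot TT$, $DD\cdot DD\cdot A$,
$A\cdot TT\cdot TT$, $DD\cdot A\cdot TT$, $A A^\top A$) count *walks*, but
the path definition demands each node appear only once. The zero diagonals
of the similarity blocks already kill immediate self-transitions; the
remaining offenders have closed forms that are subtracted exactly:

* $C_3$: walks $d_i \to d_k \to d_i \to t_j$, total $(DD^2)_{ii} A_{ij}$;
* $C_4$: walks $d_i \to t_j \to t_l \to t_j$, total $A_{ij} (TT^2)_{jj}$;
* $C_6$: walks revisiting $d_i$ or $t_j$, total
  $A_{ij}\left[(AA^\top)_{ii} + (A^\top A)_{jj}\right] - A_{ij}^3$
  by inclusion-exclusion.

Max scores use $(\max, \times)$ semiring products; the endpoint-revisit
exclusions there cannot be "subtracted", so the implementation keeps the best
*and second-best* candidate per intermediate node and falls back to the
second best wherever the best re-uses the endpoint. Both semantics are
available (`semantics = "simple"` is the default, `"walk"` reproduces the
uncorrected matrix products, since published matrix implementations do not
state whether they corrected for revisits); the whole machinery is verified
against an exhaustive path-enumeration oracle in the test suite. Tiny
negative values from floating-point cancellation (below $10^{-12}$) are
clamped to zero.

## Sequence encoders

**Proteins.** The ProtVec-style pipeline: each training sequence is cut into
three lists of *shifted non-overlapping* 3-grams (shifts 0, 1, 2 — a corpus
of $N$ sequences yields $3N$ token "sentences"), a skip-gram model with
negative sampling learns a vector (default dimension 100) per 3-gram, and a
protein is represented by **summing** the vectors of all *overlapping*
3-grams of its sequence. Published work says "summing"; an averaging flag is
provided for sensitivity analysis but is off by default. Unknown 3-grams
contribute zero and are reported through a coverage attribute rather than
silently. Pre-trained vectors in word2vec text format can be loaded with
`read_word_vectors()`, so the full SwissProt-scale corpus is never required.
Skip-gram hyperparameters not fixed by convention (window 5, min_count 1,
10 epochs, 5 negative samples) are exposed in `train_kmer_embeddings()`.

**Drugs.** SMILES fingerprints are a pluggable contract (`fit_corpus()`,
`encode()`). The default is a deterministic hashed token-n-gram encoder
(character tokens with `Cl`/`Br`/bracket-atoms kept atomic, n = 1..3,
FNV-1a hashing, seeded ±1 random projection to the target dimension): it
needs no training and keeps the full pipeline reproducible on any machine. A
trainable GRU sequence autoencoder (`gru_autoencoder()`) implements the
seq2seq-fingerprint idea — the encoder's final hidden state is the
fingerprint, a teacher-forced decoder reconstructs the token stream, and the
canonical tuning grid (fingerprint length $\{128, 256, 512, 1024\}$, learning
rate $\{0.1, 0.01, 0.001\}$, 2-4 layers, dropout $\le 0.3$) is honoured. Its
hand-derived backpropagation is validated against numerical gradients in the
tests. Reproducing any particular published pre-trained fingerprint model is
out of scope (the pre-training corpora are not identified); the contract lets
such a model be slotted in.

## Feature assembly and normalisation

The three variants are `pscore` (12/24 meta-path scores), `embed`
(drug fingerprint ∥ protein embedding, e.g. $128 + 100 = 228$ columns) and
`hybrid` (both, e.g. $12 + 228 = 240$). Pairs with missing affinity labels
are excluded from training outright — never imputed.

Features are min-max normalised. The literature phrase "normalised training
and testing sets separately" admits two readings, and both are implemented:
`independent` (each block scaled by its own column ranges — the literal
reading, and the default) and `fit_on_train` (training ranges applied to
both, test clipped to $[0,1]$ — the leakage-safer protocol we recommend for
new work). A column that is constant on the fitted block maps to zeros.

## Splits, leakage discipline and aggregation

Under the nested-CV protocol the labelled pairs are partitioned into six
near-equal sets: one hold-out test set, five inner folds. For each inner
fold, a model trains on the other four; crucially the graph passed to the
feature extractor is rebuilt with that fold's *and* the hold-out's D-T edges
masked, so no validation or test affinity can reach any feature. A training
pair's own edge *does* remain in the graph for other pairs' paths — only
held-out data is removed. Every run re-asserts programmatically that all
masked edges carry exactly zero weight, and the acceptance suite includes a
perturbation audit: changing a held-out affinity must leave every training
feature bit-identical.

Whether "the five models' averages on the hold-out" means averaging the five
metric values or evaluating the averaged prediction vector is ambiguous;
`dtba_nested_cv()` computes both (`report_mean_metrics`, the default report,
and `report_mean_predictions`) so the choice is always visible. The
time-based protocol (`dtba_time_split()`) trains on pairs up to a boundary
year (default 2011), early-stops on the following year (2012) and tests on
everything later (2013+).

One global seed fans out deterministically to the split, the encoders and
the per-fold regressor fits; identical config + seed gives byte-identical
reports.

The regressor defaults (500 rounds with early stopping against the inner
validation fold, depth 6, learning rate 0.05, subsample 0.8,
`colsample_bytree` 1 — all features per tree, appropriate for 12-24 column
score sets) follow common boosted-tree practice; the winning published
values are not available, so `tune_boost()` can grid-search them per run
with ties broken toward fewer, shallower trees.

## Evaluation metrics

* **MSE / RMSE** — the training objective and headline error.
* **Concordance index** — over all pairs with distinct true affinities, the
  probability the predictions rank them correctly, with half credit for
  prediction ties (Heaviside step). The $O(n\log n)$ Fenwick-tree sweep is
  checked exactly against an $O(n^2)$ reference.
* **$r_m^2 = r^2(1-\sqrt{r^2-r_0^2})$** — the QSAR external-validation
  statistic; $r^2$ is squared Pearson correlation and $r_0^2$ the squared
  coefficient of the least-squares fit *through the origin*. The references
  defining it allow either regression axis; the default regresses observed
  on predicted, the alternate axis is returned alongside, and the radicand
  is floored at zero before the square root (it can dip negative
  numerically).
* **Thresholded AUPR** — affinities binarised at conventional cutoffs (7 on
  a pKd scale; 12.1 for KIBA-style scores; 6/7/10 averaged for
  PDBBind-style use). The positive rule (`ge`/`le`) is explicit because the
  KIBA cutoff is quoted on the transformed scale in some papers and the raw
  scale in others. AUPR uses step interpolation (average precision);
  thresholds that leave a single class are reported `NA` and dropped from
  the mean with a warning.
* **Y-randomization** — the model refitted on label-shuffled training data
  (features fixed) 100 times; the observed held-out $r^2$ (coefficient of
  determination, $1-SS_{res}/SS_{tot}$ — deliberately *not* squared
  correlation, since scrambled models should go negative) is located in the
  permuted distribution both parametrically (normal tail) and by empirical
  rank $(\#\{r^2_{perm} \ge r^2_{obs}\}+1)/(n_{iter}+1)$.

## What the synthetic generator does and does not emulate

`generate_synthetic()` draws drug latents $u_i$ and target latents $w_j$
i.i.d. standard normal in a low dimension (default 5), maps the inner
products $u_i \cdot w_j$ affinely onto the affinity range via the sample
min/max, adds Gaussian measurement noise, and exposes the min-max-normalised
cosine similarities of the latents as the two similarity matrices. This
makes guilt-by-association true *by construction* — similar latents imply
similar affinity profiles — so network features have honest signal to find,
and recovery tests are meaningful rather than vacuous. Defaults (60 drugs ×
50 targets, full density, pKd-like range 5-11, noise sd 0.6 = 10% of the
range) emulate a dense kinase-panel study; `density = 0.244` mimics
KIBA-style sparsity, with the missingness mask uniform at random because the
real mechanism is unspecified.

Two caveats matter when reading test results. First, the attached
protein-like sequences and SMILES-like strings are random; they exercise
tokenisation and encoding, not chemistry, so nothing here validates that
*real* fingerprints carry affinity information. Second, the min-max affine
map is stretched by the extreme inner products of the $n\times m$ sample, so
the bulk of the noise-free affinities occupies a fairly narrow band: with
the default 10%-of-range noise even the Bayes-optimal predictor (the
noise-free values themselves) attains a hold-out concordance index well
below 1, and model CIs must be read against that ceiling — which
`scripts/acceptance.R` reports per seed as `synthetic_oracle_ceiling_ci`
alongside the model's metrics. The
regular test suite therefore asserts the properties that are true under
these conditions — the pipeline beats the mean-predictor baseline, recovers
rank signal well above chance, and collapses to CI ≈ 0.5 when noise is 100×
the signal — at study sizes (up to 60 × 50, 20 replicates) chosen so the
whole suite runs comfortably on one CPU.

## Known limitations

* Similarity computation itself (SIMCOMP-style 2D similarity,
  Smith-Waterman alignment) is out of scope: the package accepts
  precomputed matrices, and the hashed-fingerprint cosine route exists for
  self-contained tests.
* Headline published benchmark figures require the original similarity
  matrices and pre-trained embeddings, which are external downloads; they
  are not reproduced here.
* Dense matrix algebra throughout; graphs beyond a few thousand entities
  per side would need a sparse backend.
* The feedforward neural regressor variant reported alongside boosted trees
  in the literature is intentionally absent — the boosted-tree results are
  the ones that were reported, and xgboost is the only regression backend.
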