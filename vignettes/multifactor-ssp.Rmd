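---
title: "Multi-factor features for secondary structure prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-factor features for secondary structure prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ssfactors studies how four per-residue feature factors contribute to
protein secondary structure prediction (PSSP) with classical
classifiers. This vignette explains the model, the estimation procedures,
the synthetic corpus that stands in for external training data, and the
design decisions taken where more than one reasonable choice existed.

## The prediction problem

Each residue of a protein is assigned a structural state: H (α-helix),
E (β-strand) or C (coil) in the three-state task, or the eight DSSP
states H, G, I, E, B, T, S, C in the eight-state task (reduced to three
by the common convention H,G,I→H; E,B→E; T,S,C→C when needed). A
classifier sees, for the residue at position *i*, the concatenated
features of a window of `window` consecutive residues centred on *i*
(all-zero rows pad positions beyond the termini), and predicts the state
of the centre residue.

## The four factors

Per residue, four feature blocks are available:

* **onehot** (20 columns) — the residue's identity as an indicator
  vector, in the fixed alphabetical one-letter ordering.
* **pssm** (20 columns) — the PSI-BLAST position-specific scoring
  matrix row, i.e. per-position amino-acid log-odds from iterative
  database search. Raw log-odds are unbounded, so by default each score
  *x* is squashed to `1/(1+exp(-x))`; KNN and SVM are scale-sensitive
  and all other blocks live in [0, 1]. `pssm_scaling = "none"` keeps raw
  scores.
* **properties** (4 columns) — physicochemical scale values of the
  residue: hydrophobicity H, the two dissociation constants pKb2
  (α-amino) and pKa1 (α-carboxyl), and the isoelectric point pI. The
  shipped 20×4 table is a fixed reference fixture
  (`aa_property_table()`); together the columns track residue charge and
  hydrophobicity, the properties most implicated in helix/strand/coil
  preference. By default each column is rescaled to [0, 1] by the
  table's own range (`property_scaling = "minmax"`). A z-score variant
  fitted on the training split exists, but unit-variance property
  columns dominate the Euclidean metric over the [0, 1]-ranged blocks
  (four z-scored columns carry as much squared-distance mass as all
  twenty one-hot columns), which measurably *hurts* the distance-based
  learners; range-normalisation keeps the factors scale-commensurate and
  is data-independent, so nothing is fitted from labels.
* **trend** (one column per state) — the corpus-fitted propensity of
  the residue's amino acid for each state.

### Trend-factor estimation

For amino acid *a* and state *s*, the raw trend factor is the
conditional frequency

P(a, s) = A_as / T_s,

where A_as counts residues of amino acid *a* observed in state *s* and
T_s is the total residue count of state *s*. Each state's 20 raw values
therefore sum to 1. Raw values are min–max rescaled to [0, 1]. The axis
of that rescaling is not forced by the definition; the default runs
within each state across the 20 amino acids, so every state's propensity
profile spans the full unit interval and states with unequal frequencies
are still comparable. The axis is configurable (`normalize_over`)
because the alternative — normalising each amino acid across states —
is equally coherent and emphasises within-residue contrasts instead.

Reading A_as as a count is the only interpretation under which A_as/T_s
is well-defined from corpus statistics alone, and it makes the trend
factor a plug-in estimate of P(amino acid | state).

Trend tables are fitted **on the training split only** and applied
frozen to held-out data: the labels they consume are the prediction
target, and fitting them on test data would leak it. The same rule
applies to the (optional) z-score property statistics. The no-leakage
property is asserted in the test suite.

## Classifier families

Four families run behind one train/predict contract
(`train_ss_model()` / `predict()`), with these reference settings:

| family | backend | defaults |
|---|---|---|
| svm | e1071 (libsvm) | RBF kernel, cost 1, gamma 1/d |
| random_forest | ranger | 120 trees, max depth 15 |
| knn | in-package | k = 3, Euclidean distance |
| naive_bayes | in-package | Gaussian likelihood per feature |

Two implementation notes:

* libsvm training is between quadratic and cubic in the number of
  residues, so the SVM family subsamples its training set to
  `subsample_cap` residues (default 6000, seeded, announced with a
  message) when larger. At the package's default corpus scale this keeps
  an SVM fit around a minute on one core while leaving held-out accuracy
  within a point or two of larger caps; the cap is an ordinary argument
  for users with more patience.
* KNN and Gaussian naive Bayes are implemented in vectorised form
  inside the package (chunked BLAS distance computation; closed-form
  per-class moments), because the classic reference implementations
  evaluate residue-scale test sets with interpreted per-row loops and
  become the bottleneck of every experiment. Both are cross-checked
  against `class::knn` and `e1071::naiveBayes` in the test suite. KNN
  vote ties are broken by the nearest neighbour among the tied classes,
  which is deterministic; naive Bayes variances are floored at 1e-9 to
  keep degenerate (constant-within-class) columns finite.

`grid_search()` reproduces the usual exploration grids (SVM kernel in
Linear/RBF/Poly/Sigmoid; trees in 100–130; k in 1–4) and ranks values by
held-out Q with stable ties.

Class imbalance (E is rarer than H and C under the default generator, as
in real corpora) is left unweighted to match the reference settings.

## Scoring

**Q accuracy** (Q3/Q8) is the percentage of residues whose predicted
state matches the observed state.

**Sov** (segment overlap) compares maximal same-state runs. For each
observed segment S1 overlapping a predicted segment S2 of the same
state, the pair contributes

((minov + σ) / maxov) · len(S1),

where minov is the intersection length, maxov the extent of their union,
and σ = min(maxov − minov, minov, ⌊len(S1)/2⌋, ⌊len(S2)/2⌋) a
boundary-tolerance allowance, with minov + σ clamped to maxov so no pair
exceeds ratio 1 (required for the 100-point upper bound). Observed
segments with no same-state overlap contribute zero. The normaliser is
the length-weighted Sov'99 form: len(S1) counted once per overlapping
pair plus once per unmatched segment. A fragment-count normaliser — the
mean per-pair overlap ratio — is available as `sov_norm = "fragments"`
for comparison, since the score's verbal description ("total number of
fragments") is sometimes given that way even though the length-weighted
form is what the segment-length weighting implies.

Corpus-level Sov is computed per sequence and aggregated with length
weights by default (`sov_aggregate = "pooled"` sums numerators and
normalisers instead); the two differ only in how long sequences are
weighted, and neither is canonical.

The implementation is verified exactly — double-precision identical —
against an independent brute-force reference over enumerated segment
pairs, on 10,000 random string pairs.

## Grouped permutation importance

The importance of a whole factor is measured by jointly permuting all of
its columns (every window position) over the rows of the held-out set,
re-predicting, and averaging the drop in Q over `repeats` permutations.
Drops are floored at zero (a permutation can raise accuracy by chance;
negative drops carry no evidence) and normalised to shares summing to
100, with the raw drops reported alongside. Permutation importance was
chosen because it is model-agnostic — it treats all four families
identically — and because grouped (block-wise) permutation is the
natural unit here: single columns of a one-hot block are meaningless in
isolation. Run it on held-out data; on training rows the drops measure
memorisation.

A known property of the method: factors that duplicate each other's
information split credit between them. Under a naive Bayes model with
four exchangeable, equally informative blocks, each share converges to
25% — which is also the behaviour expected of naive Bayes given its
conditional-independence assumption, and is checked in the acceptance
suite.

## The synthetic corpus

External PSSP corpora and PSI-BLAST profile banks are large downloads;
the package instead ships a seeded generator whose output has the
statistical structure the analysis needs:

* **Labels** follow a first-order Markov chain over states. Segment
  scores are meaningless on i.i.d. labels, so self-transition
  "stickiness" (defaults 0.9 for H and E, 0.8 for C) produces realistic
  mean segment lengths around 10/10/5 residues. Initial states are drawn
  from the chain's stationary distribution.
* **Residues** are drawn from state-conditioned emission distributions:
  mild multiplicative boosts over a uniform background (helix favours
  A, E, L, M, Q, K, R, I; strand V, I, Y, F, W, T, G, C; coil
  P, G, S, N, D, T; largest boost 3.5×, every amino acid nonzero in
  every state so no encoder column is dead).
* **PSSMs** draw, per position, a 20-simplex profile from a Dirichlet
  whose centre mixes the true residue (65%) with the generating state's
  emission distribution (35%, `pssm_context`), at concentration
  `pssm_noise = 14`, then round to integer log-odds against the uniform
  background in half-bit units, clamped to ±13 — the PSI-BLAST ASCII
  dialect the readers consume. The context blend mirrors the fact that
  real profiles encode position-specific conservation that co-varies
  with local structure, which is precisely why profile features are the
  strongest single factor in practice; with the blend at zero the PSSM
  degenerates to a noisy copy of the one-hot factor.

The default scale (200 sequences of 80–200 residues, ≈28,000 residues)
and the parameters above were chosen once so that the four families'
held-out Q3 (≈58–75% at the canonical seed, majority baseline ≈43%)
brackets the operating range classical PSSP methods reach on standard
benchmarks, and so that adding the property and trend factors to a
one-hot + PSSM base helps every family. They are study conditions, not
tuning knobs.

What the generator does **not** emulate: real homology structure
(profiles here are position-independent draws, not alignments), chain
breaks and non-standard residues, long-range dependencies between
segments, the true joint distribution of amino-acid properties within
segments, and dataset shift between training and test corpora. Passing
tests on this corpus therefore show that the estimators, scores and
pipeline are correct and well-calibrated at realistic difficulty — not
that any particular accuracy will transfer to CB513-like data.

Parameter recovery is checkable: on a simulated corpus the raw trend
value for (a, s) is a binomial proportion with T_s trials, so
`fit_recovery_check()` compares fitted values against the generating
emissions with the 3·√(p(1−p)/T_s) entry-wise bound (corpora under
50,000 residues are flagged as too small for the bound to be reliable).

## Factor ablation

`run_ablation()` holds the grouped split, seed and model settings fixed
and compares one-hot + PSSM (the conventional inputs) against the same
base plus properties and trend. On the default corpus the gain is
positive for every family with an average a little over one Q3 point at
the canonical seed.

A limitation worth stating plainly: given the one-hot block, the
property and trend blocks add no *information* — they are deterministic
per-residue functions of the sequence. Their benefit is purely
representational (compact, graded, state-aligned columns that trees can
split on directly, that dominate distances less wastefully, and that
vote coherently in naive Bayes), and its size is therefore strongly
family-dependent: the forest gains most, the margin- and
likelihood-based models least, sometimes within noise of zero. On real
corpora the reported gains are more uniform (about two points); a
synthetic corpus with exactly controlled structure makes the
representational nature of the effect visible instead of averaging it
away.

## Numerical and interface choices

* Indexing is 1-based everywhere (segments, error positions), per R
  convention.
* The canonical amino-acid order for all 20-wide blocks is alphabetical
  by one-letter code; PSSM files keep PSI-BLAST's own column order on
  disk and are re-mapped on read.
* Window length defaults to 13 residues (odd; a standard context size
  in the PSSP literature); `window = 1` reproduces single-residue
  classification.
* Terminal padding is all-zero feature rows rather than sequence
  truncation, so every residue keeps a prediction.
* Non-standard residues (X, B, Z, ...) drop the whole record with a
  logged report by default (`strict = FALSE`); `strict = TRUE` makes
  them fatal.
* Propensity argmax ties go to the earlier state in alphabet order
  (H before E before C), documented and deterministic.
* Min–max of an all-equal vector returns zeros (the degenerate case has
  no spread to rescale).
* All randomness flows from explicit integer seeds: corpus generation,
  splits, subsampling, tree growing and permutations are reproducible
  byte-for-byte, which the test suite asserts.

## Problem sizes used in the shipped checks

The test and acceptance suites run entirely on simulated data sized for
a single core: the full-scale checks use the default 200-sequence corpus
(~28,000 residues, 611 feature columns at window 13), trend-recovery
uses a ~100,000-residue corpus, and the Sov cross-validation enumerates
10,000 random string pairs. Unit tests use corpora of 6–40 sequences
with windows of 1–5.
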