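---
title: "Influence-based hit triage for HTS campaigns: models and methods"
author: "MVSATriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence-based hit triage for HTS campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MVSATriage)
```

## The problem

Primary high-throughput screens (HTS) call thousands of compounds
"active" from a single-dose readout, and a large fraction of those calls
do not survive confirmation: colloidal aggregators, autofluorescent
compounds, assay-technology interferents, reactive molecules and plain
statistical fluctuations all produce readouts that look like activity.
Which hits to advance is usually decided by sorting on the primary
readout, an approach that cannot distinguish a potent inhibitor from a
strongly fluorescent artifact.

MVSATriage implements MVS-A (minimal variance sampling analysis), a
sample-influence approach to this triage problem. It requires nothing
beyond the primary screen itself: no interference-mechanism model, no
historical library of known artifacts, no confirmatory data at training
time. Confirmatory outcomes are used only to *evaluate* rankings.

## The score

A gradient-boosting classifier (GBM) is trained on the full primary
screen to separate hits from inactives. Write \(F_t(x_i)\) for the raw
additive margin of training sample \(i\) after boosting iteration
\(t\), starting from the base score
\(F_0 = \log(\bar p / (1-\bar p))\) at the label prevalence
\(\bar p\). Under binary log-loss the per-sample derivatives at
iteration \(t\) are

\[ g_{i,t} = p_{i,t} - y_i, \qquad h_{i,t} = p_{i,t}(1 - p_{i,t}),
   \qquad p_{i,t} = \frac{1}{1 + e^{-F_t(x_i)}} . \]

The MVS-A influence of sample \(i\) accumulates the
minimal-variance-sampling magnitude of these derivatives over the whole
training run, in-sample:

\[ s_i = \sum_{t=0}^{T-1} \sqrt{g_{i,t}^2 + \lambda\, h_{i,t}^2} . \]

A sample the ensemble fits quickly saturates (\(|g| \to 0\),
\(h \to 0\)) and stops contributing, so \(s_i\) stays small. A sample
that persistently contradicts the pattern the ensemble is learning -
e.g. a compound labeled active whose features look like everything
inactive - keeps large gradients throughout training and accumulates a
large score. Among primary hits, high \(s_i\) therefore flags likely
false positives and low \(s_i\) likely true actives; among primary
*inactives*, high \(s_i\) flags false-negative candidates ("dark
chemical matter" mining).

The per-iteration magnitude \(\sqrt{g^2 + \lambda h^2}\) is the
importance weight used by minimal-variance sampling in stochastic
gradient boosting, which is what gives the method its name. The exact
form of the accumulation admits variants (weighting by iteration,
\(\lambda\) handling), so the formula is isolated in one function
(`mvsaInfluence()`) with \(\lambda\) exposed; \(\lambda = 1\) is the
default and \(\lambda = 0\) reduces the score to
\(\sum_t |g_{i,t}|\) exactly. Aggregation is a sum by default; the mean
(`aggregation = "mean"`) is rank-equivalent at fixed \(T\) and
comparable across different \(T\).

### Properties used as tests

* At \(F = 0, y = 1, \lambda = 1\) a single-iteration score is
  \(\sqrt{0.25 + 0.0625} = \sqrt{0.3125}\).
* \(g \in (-1, 1)\), \(h \in (0, 0.25]\), so
  \(s_i \le T\sqrt{1 + 0.0625\lambda}\).
* On small instances the score correlates positively with a brute-force
  leave-one-out oracle: retrain without sample \(i\) and measure the
  log-loss increase at \(i\) itself (self-influence). This is the
  quantity the trace approximates without \(n\) retrainings.
* Flipping the label of a well-fit sample strictly increases its score
  after refitting.

## Training configuration

`boostingConfig()` fixes out-of-the-box defaults; the method is meant
to be used without per-campaign tuning.

* `nIterations` (T): 100 boosting rounds.
* `learningRate`: 0.1.
* `maxDepth`: 6.
* `minChildSamples`: 20. The backend (xgboost) constrains leaves by
  hessian mass, not sample count, so this is mapped to
  `min_child_weight = minChildSamples * p(1-p)` at the label base rate -
  exact at 50 percent prevalence, approximate elsewhere, and documented
  as such.
* `classWeighting`: none by default; `"balanced"` applies the class
  ratio as a positive-class weight.
* `seed`: recorded in every output; training is single-threaded
  histogram-based, so identical inputs give bit-identical scores.

Margins are recorded after every iteration. The backend exposes final
models plus per-tree leaf assignments, so \(F_t\) is reconstructed as
the cumulative sum of leaf values along the tree sequence; the unit
tests verify this agrees with the trainer's own staged predictions
(`iterationrange`) to float32 resolution, which is the backend's output
precision.

## Triage rule

`triageHits()` sorts hits by score, descending, breaking ties by stable
input order, and flags the top \(\lceil f \cdot n_{hits}\rceil\) as
likely false positives and the bottom \(\lceil f \cdot n_{hits}\rceil\)
as likely true positives, with \(f = 0.1\) by default. The ceiling
guarantees non-empty flag sets for small campaigns; the full ranking is
retained so any validation budget can be accommodated.

## Evaluation protocol

Rankings are scored on *confirmed hits only*: a hit inactive or
inconclusive in the confirmatory screen is a ground-truth false
positive, a confirmed hit a true positive, untested hits are excluded
(never counted as false positives). Campaign eligibility for
benchmarking requires more than 200 confirmed hits and a false-positive
fraction inside [0.05, 0.95]; outside that window a ranking method can
hardly be distinguished from random picking.

Metrics (`evaluateRankings()`):

* **Relative precision at K** - precision in the top
  \(K = \lceil 0.1\,n \rceil\) scaled by prevalence, minus one; 0 equals
  random sorting. K matches the triage fraction and is configurable.
* **Enrichment factor** at the same K; algebraically
  \(EF = \text{relative precision} + 1\), asserted on every run.
* **BEDROC** with \(\alpha = 20\) (the community default for early
  recognition, putting roughly 80 percent of the weight on the first 8
  percent of the list), in the Truchon-Bailey closed form; the tests
  validate it against an independent min-max-scaled RIE implementation
  over exhaustive small instances.
* **Scaffold diversity** - unique Bemis-Murcko scaffolds over selection
  size, computed when structures are available. Acyclic molecules share
  one empty-scaffold class (a conservative choice that cannot inflate
  diversity).

Method comparisons across datasets use one-tailed paired Wilcoxon
signed-rank tests ("method beats comparator"), exact for up to 25
untied non-zero differences and the continuity-corrected normal
approximation otherwise, with Bonferroni correction over the number of
comparators. Zero differences are dropped, following the classic
signed-rank construction.

Baselines: primary-readout ranking (most-active-first for true-positive
prioritization - the de facto industry approach - and its reverse as
the false-positive baseline), seeded random permutations, and an
isolation-forest anomaly ranking (100 trees, subsample 256, the
conventional setting) behind a pluggable scorer interface. External
predictors integrate through a precomputed-scores CSV adapter; none of
the baselines can see confirmatory outcomes by construction.

## The synthetic screen generator

`simulateScreen()` provides the package's no-download test bed. It
emulates the *statistical* structure of a primary/confirmatory pair,
not chemistry: compounds carry sparse binary fingerprint-like features
(1,024 by default, per-feature Bernoulli rates log-uniform in
[0.002, 0.1]).

* **True actives** are driven by 8 causal features with strong weights -
  a compact, learnable pharmacophore. Group membership is drawn without
  replacement with probability following a logistic propensity on those
  features, with the count matching the target exactly; exact counts
  keep the top-quantile hit cut inside the effect clusters, so
  composition targets hold by construction rather than only in
  expectation.
* **Interferents** are driven by 64 diffuse, weakly weighted
  interference features - heterogeneous mechanisms, detectable in
  principle but much harder to fit than the pharmacophore.
* **Readouts**: actives shift by 8 noise SDs; interferents by a
  per-compound \(N(9, 2^2)\) shift, so interferent readouts overlap the
  active cluster while an outlier tail exceeds it (interferents *can*
  top the readout ranking, but the readout alone cannot separate them -
  if it could, influence-based triage would be redundant and the
  simulated benchmark meaningless).
* **Statistical flukes**: a quarter of the false positives by default
  carry no feature signal at all, just an activity-sized readout boost -
  the purely random component of assay noise. These are the FPs no
  feature-based predictor could anticipate, but in-sample influence
  still flags them because the model cannot fit them.
* **Hit calling** takes the top `hitRate` quantile of the readout
  (campaigns define thresholds case by case; a quantile is the neutral
  stand-in).
* **Confirmatory outcomes** exist for hits only: truly active hits
  confirm; the rest are false positives, a third of them reported
  "inconclusive" rather than "inactive" to exercise the rule that both
  count as false positives.
* **False negatives**: `fnCount` truly active hits have their readout
  forced just below threshold, giving the false-negative mining path a
  known target.

Defaults are the package's reference conditions: 20,000 compounds, 1
percent hit rate, false-positive fractions spanning 0.2-0.8 in the
validation runs (the realistic range for usable campaigns), seed-exact
reproducibility. A spec whose effect sizes cannot realize its targets
(e.g. effects below the noise) aborts with a diagnostic rather than
silently delivering a different composition.

What the generator does *not* emulate: real structure-activity
landscapes, correlated fingerprint bits, plate/batch artifacts,
dose-response curve shapes, or assay-specific interference chemistry.
Passing the simulated end-to-end checks therefore demonstrates that the
pipeline detects feature-linked and feature-free label noise under
realistic class imbalance - not that any particular real campaign will
behave the same way. The SMILES fixture grammar
(`fixtureSmiles()`) covers the cheminformatics path (parsing,
standardization, fingerprints, scaffolds) with controllable scaffold
multiplicity; the feature simulator covers the statistics.

## Structures and featurization

SMILES parsing, canonicalization and physicochemical properties go
through ChemmineR/ChemmineOB (OpenBabel). Hashed circular
(Morgan-style) fingerprints are computed in-package on the molecular
graph: atom invariants (element, degree, total bond order, framework
membership) are iteratively re-hashed with sorted neighbor
(bond order, invariant) lists, and every identifier at every radius
sets one bit. Radius 2 with 1,024 bits is the default representation -
hit-triage performance is known to be robust to the representation
choice, so one robust default plus a config switch suffices. Hashing
uses a platform-independent polynomial over the identifier string, so
fingerprints are reproducible bit-for-bit everywhere.

Bemis-Murcko scaffolds are extracted by iteratively pruning terminal
atoms (leaving ring systems plus linkers), restoring atoms
multiply-bonded to the framework (e.g. carbonyl oxygens), and emitting
canonical SMILES; acyclic molecules map to the empty-scaffold sentinel.

Structure standardization canonicalizes, keeps the largest organic
fragment (salt stripping), and merges duplicate structures; duplicates
that disagree on the primary call are dropped by default
(`drop_conflicts` - contradictory replicates are unreliable), with
`keep_first` available. Tautomer and charge normalization are not
attempted; deduplication to unique canonical structures is the
documented scope.

## Numerical and policy choices

* Ties in any ranking break by stable input order; rankings are 1-based
  with rank 1 the highest score.
* Degenerate inputs fail fast with named errors: single-class labels,
  empty hit sets, all-zero paired differences, prevalence 0 or 1.
* All-equal score vectors still rank and flag (stable order) but warn.
* Readout orientation is declared at load; "lower is more active"
  inputs are sign-flipped so every downstream consumer can assume
  larger = more active.
* Descriptor failures are imputed with column medians (and counted),
  never dropped, preserving row alignment with labels.
* Every output file carries a `# config_hash=... seed=...` provenance
  comment; two runs of the same configuration are byte-identical, which
  the tests assert at the file level.

## Validation problem sizes

The shipped validation suite runs at sizes chosen to make every check
exact or statistically decisive while staying desk-scale: closed-form
gradient checks on a 482-point margin grid; leave-one-out oracle
agreement on 20 replicates of 60 samples at 20 iterations and depth 2;
label-flip recovery on 5 seeds of a 60-sample two-cluster fixture;
end-to-end triage on fifteen 20,000-compound simulated screens (three
false-positive fractions, five seeds each); exhaustive metric recounts
over all rank subsets at N = 10. `scripts/acceptance.R` recomputes all
of these from scratch for any seed.

## Limitations

* Scores are in-sample by design - influence of each sample on its own
  training run. They are not generalization estimates and should not be
  read as probabilities.
* Performance varies across campaigns and is hard to forecast from
  dataset descriptors; the method should complement, not replace,
  orthogonal tools (structural alerts, frequent-hitter and
  interference-mechanism predictors), especially since it does not model
  promiscuity at all.
* True-positive selections tend toward the learned boundary's chemical
  neighborhood and can be scaffold-homogeneous; pair the ranking with a
  diversity-aware selection if scaffold coverage matters.
* The `minChildSamples` mapping onto hessian mass is approximate away
  from balanced prevalence.
* The isolation-forest scorer and the fingerprint/scaffold code are
  compact reference implementations; they favor determinism and
  auditability over raw speed.
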