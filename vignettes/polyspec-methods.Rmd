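---
title: "Methods: sequence-based polyspecificity prediction with polyspec"
author: "polyspec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based polyspecificity prediction with polyspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyspec)
```

## The problem

Polyspecific antibodies bind structurally unrelated molecules in addition
to their cognate antigen — an undesirable property for therapeutic
candidates. `polyspec` models polyspecificity as a binary classification
problem on the antibody heavy-chain variable region (VH): given an aligned
VH amino-acid sequence, predict whether the clone is polyspecific
(positive class) or antigen-specific (negative class). The package
implements the complete analysis chain — physico-chemical encoding,
neural classification, cross-validation with overlap control, and
permutation-based feature attribution — together with a synthetic
repertoire generator that makes every stage testable without access to an
immunization campaign.

The package's contract starts at *aligned* sequences: inputs are VH
sequences pre-aligned into a fixed positional frame (147 positions by
default), with `.` for alignment gaps and `X` for undetermined residues.
Producing that alignment (antibody numbering) is upstream of this package.

## Physico-chemical PCA encoding

An amino-acid property table (AAindex1 format) is parsed into a matrix
with 20 rows (amino acids) and one column per property. Properties with
missing values are dropped by default; `naPolicy = "impute-mean"` instead
fills them with the property mean. Imputation injects information the
data do not contain, so dropping is the default; the switch exists because
the cumulative-variance figure below is sensitive to the policy.

The columns are centered and scaled to unit variance (sample SD, $n-1$
denominator throughout) and the matrix is decomposed by SVD. With the
bundled AAindex collection (531 complete properties out of 544) the first
six principal components explain close to 79% of the variance. A
column-centered 20-row matrix has rank at most 19, so variance fractions
are reported over the nontrivial components only. SVD signs are arbitrary;
each component is deterministically oriented so that its
largest-magnitude property loading is positive.

Each retained component's 20 amino-acid scores are standardized
(mean 0, SD 1 across the 20 amino acids). A sequence is encoded by
replacing the residue at position $i$ with its standardized score on
component $j$, stored at element $((j-1) \times L) + i$ of the feature
vector — with $L = 147$ and six components, 882 features. Gaps encode to
0 and `X` to the per-component median score. The flattening preserves
positional information while compressing the property space.

```{r encoding}
panel <- parseAAindex(system.file("extdata", "aaindex_panel.txt",
                                  package = "polyspec"))
pca <- fitPropertyPCA(panel, nComponents = 6)
fv <- encodeSequence(paste0(strrep("A", 100), strrep(".", 47)), pca)
length(fv)
```

The bundled 12-property panel (`inst/extdata/aaindex_panel.txt`) holds
twelve classic published scales — hydropathy, net charge, flexibility,
accessible surface area, secondary-structure propensities, mutability,
volume-related and transfer-energy scales — chosen to be physically
diverse with pairwise correlations below 0.75 in magnitude. The
decorrelation constraint matters for the planted-signal experiment below:
a panel containing two nearly collinear scales cannot support recovering
*which* of them was planted. For full-scale encodings, `aaindexTable()`
provides the complete AAindex collection.

## The classifier

The model is a small fully connected network: three hidden layers of 6, 3
and 2 units, each dense layer followed by batch normalization, an ELU
activation ($\alpha = 1$) and dropout (rate 0.5), then a single sigmoid
output unit giving the probability of polyspecificity. It is trained by
Adam on binary cross-entropy. Defaults mirror the repertoire-scale setup:
learning rate $6 \times 10^{-7}$, batch size 128, 10 epochs. That learning
rate was tuned for training sets of millions of sequences; the desk-scale
experiments in this package raise it (typically to $5 \times 10^{-3}$)
through `modelConfig()`.

Because polyspecific clones are roughly two orders of magnitude rarer
than antigen-specific ones, minibatches are class-balanced: every batch
draws exactly `batchSize/2` clones per class, uniformly with replacement
within class. Sampling with replacement is forced — the minority class is
usually smaller than half a batch. An epoch is defined as
$\lceil N / \text{batchSize} \rceil$ update steps, keeping "epoch"
proportional to the training-set size under balanced resampling.

Choices the architecture description leaves open are fixed as follows and
exposed in `modelConfig()`: batch-normalization $\epsilon = 10^{-3}$ and
moving-average momentum $0.99$, Glorot-uniform weight initialization,
Adam $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$.
Probabilities entering the cross-entropy are clipped to
$[10^{-7}, 1 - 10^{-7}]$ so the loss is always finite. Inference is
deterministic: dropout off, batch normalization on running statistics.

## Partitioning and evaluation

Four splitting schemes are provided: random 10-fold cross-validation,
10-times repeated 90/10 subsampling, and blocked cross-validation by
animal (9 folds) or antigen group (3 folds). The unit of splitting is the
*unique aligned sequence*: tables are deduplicated first, sequences
carrying both class labels in different records are dropped entirely, and
any sequence occurring on both sides of a split (a clone present in
several animals, say) is removed — from the training side by default,
preserving the validation distribution that performance is reported on.
The opposite policy is available via `eliminateOverlap(removeFrom =
"validation")`. Deduplicating before or after fold assignment commutes
under these policies.

Clones first observed before antigen exposure (preimmune or
adjuvant-only timepoints) or shared between antigen groups are likely
immunization-independent; `markHoldout()` moves every record carrying
such a sequence into a separate holdout table, which never enters
training or cross-validation and is scored once with the same metric
panel.

Metrics: binary cross-entropy, AUROC (midrank statistic, so ties receive
half credit), and — at a probability cutoff of 0.5, with ties predicted
positive — F1, MCC, sensitivity, specificity and balanced accuracy.
Denominator-zero cases (single-class validation folds) are reported as
`NA` rather than silently coerced. Cross-validation reports per-fold
panels and their mean and SD across folds. Per-fold training seeds are
derived from the fold's id content, so identical folds reproduce
identically. `baselineF1()` gives the F1 of a label-independent reference
classifier, defined with precision equal to the positive prevalence and
recall 1/2 (so the baseline approaches twice the prevalence as it becomes
small) — one of several possible conventions, chosen because it
reproduces the familiar repertoire-scale baseline of about 0.017 at a
prevalence of 0.134M/15.134M.

## Permutation importance and back-calculation

Feature importance is the *dropout loss ratio*: in each of `nRounds`
resampling rounds, a balanced subsample (default 1,500 clones per class,
with replacement) is scored; each feature column is then permuted across
the subsample `nPerm = 3` times and the mean ratio of permuted to
unpermuted cross-entropy is recorded. Permutation is confined to the
subsample. A ratio above 1 means the model relies on the feature. The
one-tailed p-value of a feature is the fraction of rounds with ratio
$\le 1$; Benjamini–Hochberg correction across features gives FDRs.
Permuting a disconnected input or a constant column provably leaves the
loss unchanged, so such features sit at ratio exactly 1 — a useful
self-check that the engine honors (permuting one input feature shifts
only the first layer's pre-activation by a rank-one update, which is also
what makes the computation fast).

Importance is mapped back from (position, component) features onto raw
properties by the loading-weighted mean
$$\text{back}_{p, q} = \frac{\sum_{j} \text{ratio}_{p, j} \,
\ell_{q, j}}{\sum_{j} \ell_{q, j}},$$
with $\ell_{q, j}$ the loading of property $q$ on component $j$, applied
round-wise, then summarized exactly like the direct features (means,
fraction of rounds $\le 1$, BH FDR pooled over all defined
position-property pairs). Two numerical caveats are handled explicitly:

* **Near-zero denominators.** With signed loadings the denominator
  $\sum_j \ell_{q,j}$ can approach zero, silently inflating the ratio for
  that property by orders of magnitude. Entries whose denominator is
  below $10^{-8}$ in magnitude are flagged undefined and excluded from
  the FDR pool; `absLoadings = TRUE` switches to absolute-value weights,
  a plausible alternative reading that is always defined. The signed
  form is the default.
* **Identifiability of the ranking.** `rankProperties()` orders
  properties by their maximum mean importance across positions. The
  per-component ratio profile reflects the *model's* internal reliance,
  which concentrates on the dominant discriminative component; the
  ranking therefore resolves properties only up to their loading
  geometry, and the top rank goes to the property whose loading pattern
  is most concentrated on that component. A planted-recovery experiment
  is identifiable only if the planted property is its panel's
  representative of that dominant direction (see below).

`summarizeByRegion()` tabulates significant features per antibody region.
The default region map (FR1 1–25, CDR1 26–35, FR2 36–49, CDR2 50–65, FR3
66–104, CDR3 105–140, FR4 141–147) is a stand-in layout for the
147-position frame; analyses of real numbering schemes should pass their
own boundaries.

## The synthetic repertoire generator

`generateRepertoire()` emulates the structure of an immunization study:
3 antigen groups × 3 animals, timepoints preimmune/bleed0 (pre-antigen)
and bleed1–bleed4, per-animal class assignment by a Bernoulli draw with
1:113 polyspecific:antigen-specific odds, polyspecific first-observation
mass skewed to bleed1–2 and antigen-specific mass to bleed4, a fraction
of clones first observed pre-antigen (default 5%) and a fraction of
sequences duplicated into a second animal (default 2%) to exercise the
holdout and overlap-elimination rules. Sequences are drawn position-wise
from a fixed background residue profile (protein-like base frequencies
with deterministic per-position perturbation); a variable-length gap
block in the CDR3 region mimics length variation under a fixed positional
frame.

Class-dependent signal is planted by exponential tilting: at each planted
position, the polyspecific class draws residues from
$q(a) \propto p(a)\, e^{\theta s_a}$, where $s_a$ is the standardized
value of the planted property and $\theta$ is solved (by root-finding) so
the expected value of $s$ shifts by exactly `effectSize` standardized
units. Tilting changes only the residue composition, never the alphabet,
which makes importance recovery a well-posed question. The achievable
shift is bounded by $\max_a s_a - E_p[s]$; effect sizes at or beyond the
bound trigger a warning and saturate toward the extreme residue.

Defaults are fixed once: 2,000 clones per animal keeps full-pipeline
demonstrations tractable while preserving the imbalance structure; the
planted positions default to five framework-3 positions (66–104 block),
where gaps never occur in the generated data.

What the generator does *not* emulate: somatic-hypermutation lineages,
V(D)J recombination statistics, animal-specific repertoire structure, and
duplicate-read noise (deduplication is assumed upstream). Passing tests
on this generator demonstrates that the pipeline's machinery is correct
and well-calibrated — not that real repertoires are this easy.

## The two standard synthetic experiments

The package's acceptance checks (and `scripts/acceptance.R`) run two
designed experiments:

**Planted-signal recovery.** 4,000 clones per animal (so the ~315-clone
minority class supports the 300-per-class balanced subsample of the
importance run), average flexibility (`BHAR880101`) planted at positions
70, 75, 80, 85, 90 with effect size 0.9 — about 80% of the tightest
achievable shift over the planted positions, the strongest clean signal
that avoids saturation. Flexibility is also a property the polyspecificity
literature repeatedly flags as relevant, and within the bundled panel it
is the representative of the dominant principal direction, which is what
makes "the planted property ranks first" a well-posed expectation (see
the identifiability caveat above). Training uses learning rate
$5 \times 10^{-3}$ for 20 epochs; importance runs 100 rounds × 300 per
class × 3 permutations. Expected outcome: validation AUROC well above
0.8, every planted position carrying features at FDR < 0.05, at least
95% of unplanted positions below the significance call, and the planted
property at rank 1.

**Null calibration.** Effect size 0 with balanced classes (the balanced
design gives the AUROC null distribution an SD of ~0.013 at a 2,000+
clone validation set, making the chance-level window [0.45, 0.55] a
meaningful check; under a 1:113 imbalance the handful of validation
positives would make the same window mostly noise), 2,600 clones per
animal, same training and importance settings. Expected outcome:
validation AUROC within [0.45, 0.55] and at most 10% of features with
permutation p ≤ 0.05.

Problem sizes throughout the test suite (repertoires of $10^4$–$10^5$
clones, importance at 100 rounds) are the package's chosen desk-scale
study conditions; the repertoire-scale defaults (1,000 rounds, 1,500 per
class) remain the function defaults.

## Reproducibility

Every stochastic stage takes an explicit integer seed; `stageSeed()`
fans a single global seed out to per-stage seeds via a fixed counter
scheme, so stages can be rerun in isolation. `runPipeline()` writes each
run into a fresh directory stamped with the seed and a hash of the full
configuration, refuses to overwrite a non-empty run directory, and
reruns of the same configuration reproduce the same artifacts.

## Known limitations

* The alignment step (antibody numbering) is out of scope; sequences must
  arrive pre-aligned to a fixed frame.
* The pure-R training loop is appropriate for the package's desk-scale
  experiments, not for repertoires of $10^7$ sequences.
* The back-calculated ranking resolves properties only up to their
  loading geometry (see above); correlated property clusters share
  importance by construction.
* The default region map is a stand-in; region-level claims about real
  antibodies require the numbering scheme's true boundaries.
* Cumulative-variance figures for the property PCA depend on the AAindex
  revision and on the missing-value policy.
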