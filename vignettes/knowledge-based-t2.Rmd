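---
title: "A knowledge-based T² statistic for pathway analysis of ratio proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A knowledge-based T² statistic for pathway analysis of ratio proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathT2)
```

## The model

Quantitative proteomics frequently delivers exactly one expression ratio per
protein — experiment over control, as in a SILAC run — so the sample
covariance matrix that a multivariate pathway test would normally use cannot
be estimated. `pathT2` tests each pathway under a *self-contained* null
("the mapped proteins of this pathway are not differentially expressed")
with a Hotelling-type statistic in which the covariance is *constructed from
prior knowledge* rather than estimated:

$$T^2 = \mathbf{x}^\top \mathbf{S}^{-1} \mathbf{x} \sim \chi^2_q$$

where $\mathbf{x}$ is the vector of processed log2 ratios over the pathway's
mapped proteins and $\mathbf{S}$ is filled by four rules from a
protein–protein-interaction confidence database (STRING-style experiment
channel, HitPredict high-quality set, or any `(a, b, score)` table):

1. $s_{ii} = d$ with $d = 0.4$ by default — no evidence score exists for a
   variance, so a constant expresses the confidence placed in the data; 0.4
   is STRING's "medium confidence" level.
2. $s_{ij} = +c_{ij}$ when a score is stored and $x_i x_j \ge 0$. A zeroed
   (unqualified) protein therefore never induces a negative entry.
3. $s_{ij} = -c_{ij}$ when a score is stored and the signs disagree.
4. $s_{ij} = 0$ when the database has no score for the pair.

The underlying assumption is that a strongly supported physical interaction
manifests as a strong covariance of expression ratios whose sign follows the
observed directions. The sample size is effectively one (medians already
collapse replicate ratios), so $\mathbf{x}$ itself estimates the mean vector
and the statistic is referred to $\chi^2$ rather than an F distribution.

Because $\mathbf{S}$ is assembled from a database, it can be singular —
e.g. two proteins with identical interaction patterns — or even indefinite,
since off-diagonal scores may exceed the 0.4 diagonal. The package:

* uses the Moore–Penrose pseudoinverse (`MASS::ginv`) when the numeric rank
  of $\mathbf{S}$ falls below its dimension, and reduces the degrees of
  freedom to that rank;
* computes the numeric rank as the number of singular values above
  $10^{-10} q$ times the largest one — a conventional relative tolerance; no
  canonical value exists for this construction;
* flags a negative $T^2$ (possible only for indefinite $\mathbf{S}$) and
  forces $p = 1$. Reporting the computed value with a conservative p-value
  seemed preferable to either hiding the pathway or fabricating
  significance; the `indefinite` column makes such rows auditable.

## Preprocessing

`buildProfile()` applies, in order: identifier mapping, log2 transformation,
winsorization, multi-identifier resolution, fold-change qualification, and
standardization.

* **Winsorization** (threshold 10 on the log2 scale, i.e. about a 1024-fold
  change) limits the influence of proteins quantified near the detection
  limit. The replacement value is the *maximum permitted magnitude observed
  in the data*: with ratios (−7, −1, 3, 4, 6) and threshold 5, the value 6
  becomes 4 and −7 becomes −4. The rule is sign-preserving and idempotent;
  when no in-range value exists at all it clamps to ±threshold and warns.
* **Multi-identifier resolution**: a ratio reported for several accessions is
  fanned out to each of them; an accession reported with several ratios
  receives their median (midpoint of the central pair for even counts).
  Fan-out runs before the median collapse, matching the order in which the
  two ambiguities arise during identifier mapping.
* **Standardization** divides by the sample standard deviation (n − 1) of
  all log2 ratios. The mean is *not* subtracted: zero means "unchanged" and
  the null is centred there.
* **Qualification**: only proteins with at least a 1.5-fold change
  ($|\log_2 r| \ge \log_2 1.5$) keep their ratio in $\mathbf{x}$; the others
  are treated as direction noise and zeroed, while remaining mapped members
  (they still contribute the diagonal constant to the rank). The comparison
  uses the *pre-standardization* ratios: "fold change" is a raw-scale
  notion, and standardization would otherwise make the cutoff depend on the
  dataset's dispersion. The mask is configurable (`foldThreshold = 1`
  disables it).

Degenerate inputs fail loudly where silence would corrupt results: an
all-constant ratio list cannot be standardized (fatal), an expression file
with no parsable row is fatal, while individually unparsable rows are
dropped and counted in the profile and the run manifest.

## Pathway integration

Shared-member modules can make many overlapping pathways significant at
once. `integratePathways()` groups the tested pathways greedily: the
remaining pathway with the most mapped proteins becomes a *delegate* (ties
broken lexicographically — the procedure must be deterministic and no
domain-meaningful tie-break exists), absorbing every remaining pathway whose
mapped set is an inclusive subset of its own; groups whose delegate has a
raw p-value ≤ α are retained. Three choices deserve note:

* Subset relations are evaluated on **mapped** protein sets (pathway ∩
  data), not full database membership — the redundancy to remove is in the
  *expressed* evidence. A switch (`qualifiedOnly`) restricts this further to
  qualified proteins.
* A pathway absorbed by a delegate is removed permanently, even if that
  delegate ends up non-significant; the loop never revisits it. A pathway
  contained in two disjoint delegates is claimed by whichever is processed
  first (larger, then lexicographically earlier).
* No multiplicity adjustment feeds the retention decision; a
  Benjamini–Hochberg column is emitted for reference only. Self-contained
  p-values are per-pathway statements, not a ranking.

## Robustness experiments

`robustnessExperiment()` quantifies how sensitive each pathway's call is to
corruption of the score database: for each mode and fraction (defaults:
permuted and purged at 30% and 60%, 100 experiments each) it rebuilds every
covariance from a corrupted score set and reports the percentage of
experiments in which the pathway stayed significant. "Permuted" reassigns
the chosen pairs scores drawn with replacement from the empirical score
multiset — the phrase "same score distribution" admits both this and an
exact value shuffle, so the shuffle is available behind `shuffle = TRUE`.
The expression profile, qualification mask and test vectors are computed
once and reused: corrupting interaction knowledge does not touch the data.
One master seed derives per-experiment seeds (`baseSeed + e`) and is
recorded in the report header, so reports reproduce bit-identically. The
corruption is drawn once per experiment, globally, not per pathway.

Two limits anchor the implementation: at fraction 0 every originally
significant pathway is retained in 100% of experiments, and at purge
fraction 1 the matrix collapses to $d\,I$, so $T^2 = \sum_i x_i^2 / d$
exactly — both are asserted in the test suite.

## What the synthetic generators emulate — and what they do not

The package is testable without any database download. `simulationDesign()`
fixes a protein universe, an Erdős–Rényi-style scored network (each pair
kept with probability `edgeDensity`, scores uniform on `scoreRange`, default
[0.4, 1] since lower scores would be discarded at read time), a pathway
collection in which a `nestedFraction` share of pathways are strict subsets
of earlier ones (guaranteeing delegate/absorbed cases), and ratio profiles
whose perturbed pathway receives a mean log2 shift (`effectSize`, default 2,
a clearly regulated module under unit noise). Every generator is a pure
function of (design, seed).

The generators do not emulate mass-spectrometry measurement error models,
missingness correlated with abundance, phosphosite-level structure, or the
hub-dominated degree distribution of real interactomes. Passing tests
therefore demonstrate the statistical machinery — calibration, invariances,
determinism — not biological recovery on real data.

For calibration, the rule-built matrix is made usable as a *generating*
covariance by `makePsdRulebookSigma()`, which shifts the diagonal by
$|\lambda_{\min}| + 10^{-6}$ when the smallest eigenvalue is non-positive.
`calibrationPreset()` carries the reference design — 20 variables, unit
diagonal, all correlations 0.5 (eigenvalues 10.5 and 0.5), 10000 draws. Data
drawn from that matrix and evaluated with it give a rejection rate at
$\alpha = 0.05$ within Monte-Carlo error of 0.05; evaluated with the
identity instead ("correlated data misread as independent"), the rate is
visibly off — the case that motivates building $\mathbf{S}$ at all.
Calibration checks bypass the 1.5-fold mask (`foldThreshold = 1`): zeroing
entries truncates the null distribution, so the thresholded statistic's null
is not exactly $\chi^2$ and is only ever interpreted as conservative.

There is a genuine tension worth recording: the method is *self-contained*,
which usually implies a subject-sampling null distribution, yet with one
sample no resampling is possible and the p-value is analytic $\chi^2$. The
package implements the analytic reference; the calibration experiments above
are the evidence for when that reference is accurate.

## Problem sizes and numerical conventions

The shipped tests use 60–200-protein universes, 8–20 pathways, up to 100
corruption experiments and 10000-draw calibration runs — sizes at which the
full suite completes in well under a minute while leaving every property
(closed forms, oracle equivalences, Monte-Carlo bands at ±3 standard errors)
sharply testable. Mapped members are ordered lexicographically so matrices
are reproducible across runs; duplicate interaction rows keep the maximum
score (conservative toward interaction strength); score files with any
value above 1 are treated as STRING's 0–1000 integer scale and divided by
1000; results files render floats with 9 significant digits, and row order
is fixed (group size descending, then pathway id) so identical runs produce
byte-identical outputs.

## Known limitations

* The diagonal constant, fold threshold and winsorization threshold are
  conventions, not estimates; users with calibration data should adjust
  them (`t2Config()`).
* The indefinite-matrix policy (flag, p = 1) is conservative by design; a
  pathway dominated by sign-inconsistent strong interactions will never be
  called significant.
* KGML parsing reads `entry` elements of type gene/enzyme/group only
  (groups expanded to their components); relation/graphics information and
  species handling beyond identifier strings are out of scope, as is any
  live database download.
* With replicated designs, a genuine sample covariance (or a shrinkage
  combination of sample and knowledge covariance) would be preferable; the
  package addresses the n = 1 regime.
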