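---
title: "Gene discovery from coding-variant deleteriousness: models and design choices"
author: "eamlr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene discovery from coding-variant deleteriousness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamlr)
```

# The problem

Case-control exome studies of complex disease face a resolution problem:
single-variant association needs very large cohorts for all but the most
common risk alleles, and gene-based burden tests discard most of what is
known about *which* variants in a gene are likely to matter.  `eamlr`
implements an alternative: summarise each gene's coding variation in each
individual by the predicted functional damage of the variants
(Evolutionary Action scores), and ask — gene by gene, with an ensemble of
off-the-shelf classifiers — how well that summary separates cases from
controls.  Because every gene is evaluated independently and the score is
a cross-validated classification metric rather than an asymptotic test
statistic, the approach degrades gracefully at small sample sizes, which
is what makes sex-stratified analyses of moderate cohorts possible.

EA scores are consumed as input (0–100 per missense variant, higher =
more damaging); computing them is upstream of this package.

# The gene-level model: pEA

For one individual and one gene, the qualifying variant records are
aggregated into the *EA probability*

$$pEA \;=\; 1 - \prod_{j=1}^{k} \left(1 - EA_j/100\right)^{zygo_j},$$

the probability that at least one allele of the gene is functionally
compromised, treating each variant's scaled EA as an independent
probability of damage.  The zygosity exponent is 1 for heterozygous and 2
for homozygous calls.  A silent-only genotype scores 0; stop-gain and
frameshift (and, by default, inframe indel) records enter the product with
an effective EA of 100, which forces $pEA = 1$ whenever they qualify.

Three design points deserve comment:

* **Hemizygous calls** (male X) use exponent 2: one damaged allele is
  functionally total when there is no second copy.  This is a package
  decision; it is configurable (`hemizygousExponent`).
* **Stop/indels inside the product** rather than a hard override: in the
  dominant features this reproduces "pEA = 1 for truncating carriers"
  exactly, and it resolves the otherwise undefined case of a heterozygous
  stop in a *recessive* feature (it contributes nothing, because only
  homozygous records qualify there).
* **Strict threshold**: a variant qualifies when $EA > C$, never at
  equality.

Six features per gene cross two inheritance assumptions with three EA
thresholds $C \in \{1, 30, 70\}$: *dominant* features aggregate all
qualifying variants, *recessive* features homozygous/hemizygous ones only.
The design matrix is therefore $n \times 6G$; `buildDesignMatrix()` stores
it as a `SummarizedExperiment` (features in rows) and `geneFeatureSlice()`
extracts one gene's $n \times 6$ block.  Two invariants hold cell-wise and
are property-tested: dominant $\ge$ recessive at equal threshold, and pEA
non-increasing in $C$.

# Per-gene scoring: nine classifiers, one MCC each

Each gene's 6-column block is evaluated under stratified 10-fold
cross-validation by nine classifiers spanning rule induction, function
optimisation, instance-based learning, trees and boosting.  Settings
follow the published configuration wherever the setting is portable:

| learner | implementation | settings |
|---|---|---|
| rule learner (PART-like) | `rpart`, entropy | min 5 per leaf, cp 0.25-analog |
| rule learner (RIPPER-like) | `rpart`, gini | min 2 per split, depth 3 |
| perceptron | `nnet` | 1 hidden layer, 4 units |
| naive Bayes | weighted KDE (package code) | Gaussian kernel, Silverman bandwidth |
| logistic | `glmnet` | ridge, $\lambda = 10^{-3}$ |
| k-NN | `class::knn` | k = 3, Euclidean |
| random forest | `randomForest` | 10 trees |
| pruned tree (C4.5-like) | `rpart`, entropy | min 2 per leaf |
| AdaBoost | exhaustive stumps (package code) | 10 rounds, depth 1 |

The two rule learners of the original toolkit have no exact R port; greedy
recursive-partitioning surrogates with the stated pruning settings
preserve the family structure of the roster, which is the contract that
matters: *nine learners of distinct inductive biases, averaged*.  The
perceptron note: the original toolkit's hidden-layer spec "4" denotes one
hidden layer of four units, which is what `nnet` fits.  No hyperparameter
tuning is performed anywhere, deliberately — reproducibility across nine
untuned learners substitutes for per-learner optimisation.

Per classifier, confusion counts are **pooled across the ten held-out
folds** into a single Matthews correlation coefficient

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with $MCC = 0$ when a denominator factor vanishes.  Pooling (rather than
averaging per-fold MCCs) is a package interpretation: per-fold confusion
tables of weakly informative genes frequently contain empty cells, where
the per-fold average is unstable.  The gene's score is the arithmetic mean
of the nine MCCs.  MCC rather than accuracy because the score must remain
comparable when the case:control ratio is not 1:1 (sex strata rarely are).

**Computational note.** Gene feature blocks contain few distinct rows
(most individuals carry no qualifying variant).  The CV engine therefore
maps samples to unique feature profiles once per gene and hands the
learners whose loss is weight-linear (perceptron, KDE naive Bayes,
AdaBoost stumps) a frequency-weighted collapsed representation — exactly
equivalent to the expanded fit.  Learners whose semantics involve row
counts or bootstrap draws (the three `rpart` surrogates, ridge logistic,
k-NN, random forest) keep the expanded rows.  Predictions are always made
on unique test profiles and expanded back through label counts.  This is
what keeps a 300-gene, 1000-sample run in minutes on one CPU.

# From MCC to significance

The mapping from the mean-MCC distribution to p-values is provided in two
modes, both seeded:

* **Permutation (default for inference).** Case/control labels are
  permuted $B$ times; each permutation re-evaluates a random subset of
  genes with the full roster and pools their mean MCCs into one null
  (exchangeable across genes under the null).  Empirical
  $p = (1 + \#\{null \ge obs\})/(1 + \#null)$.
* **Parametric (fast screening).** A robust z-score of each gene's mean
  MCC against the genome-wide distribution (median/MAD), one-sided normal
  p.  This assumes the overwhelming majority of genes are null and is the
  mode used inside the down-sampling harness, where only the *ranking*
  matters.

Benjamini–Hochberg adjustment over all evaluated genes gives q; the
conventional significance set is $q < 0.01$.  Genes with no qualifying
carrier are excluded from evaluation and from the multiplicity count, and
reported separately.  Ranks sort by mean MCC with deterministic
tie-breaking (best single-classifier MCC, then gene name).

Sex-stratified analysis (`runSexStratified()`) is three independent full
runs (combined, male, female) plus the overlap counts of their
significant sets; a stratum with fewer than $2k$ samples of either class
is skipped with a warning.

# Combined risk prediction

`trainStacked()` asks whether the genes found individually also work
together: each individual becomes a vector of per-gene pEA values
(dominant mode at $C = 1$ — the threshold is a package decision, all
non-synonymous variants, configurable), and a stacked ensemble of random
forest, ridge logistic regression and AdaBoost-on-stumps is trained with a
decision-tree meta learner on inner out-of-fold predictions (split
threshold $10^{-6}$, minimum information-gain weight fraction 0.01; the
original meta learner is a streaming Hoeffding tree, whose grace periods
have no batch analog and are carried as inert configuration).  Performance
is the per-held-out-fold ROC AUC over stratified 10-fold CV.  The
comparator is a 2-feature baseline: the pEA of the individual's APOE
variants and the cohort-z-scored age (sample SD; the cohort-wide
normalisation mirrors the published protocol and leaks test-fold means —
a fold-wise option exists).  Runs are compared by an unpaired two-sided
t-test on the fold AUCs (pairing unstated in the protocol; paired mode
available).

One quantitative caveat, computed in the test suite: under the reference
planted-cohort conditions (10 dominant risk genes, carrier frequency 0.1,
carrier odds ratio 2.5, APOE-like and age covariates at generator
defaults), the *Bayes-optimal* AUC of the gene-feature representation —
the AUC of the true gene-plus-APOE linear predictor itself — is about
0.73.  No classifier on those features can exceed it at any sample size,
and the stacked model reaches about 0.70.  Claims of substantially higher
discrimination on such a cohort would require stronger planted effects,
more risk genes, or covariates in the feature set.

# Down-sampling robustness

`runDownsampling()` repeats the whole ranking on random equal-size
case/control subsamples over a grid of sizes and measures agreement with
a reference ranking by (i) top-K overlap with a one-tailed hypergeometric
p-value over the universe of genes actually evaluated in the reference
run, and (ii) Kendall's tau-b.  Two tau alignments are offered because
the choice is genuinely open:

* `union` (default): tau over the union of the two top-K lists, rank
  $K + 1$ for a gene absent from one list.  This alignment rewards shared
  *ordering* but is **not centred at zero for independent rankings** —
  cross-list pairs are systematically discordant and pull the null mean
  to about $-0.5$ (a property test documents it).  Comparisons are
  therefore meaningful against the same-aligned value of another method,
  not against 0.
* `intersection`: tau over the shared top-K genes only; zero-centred
  null, but undefined when fewer than two genes are shared.

The harness accepts any external per-gene ranking as the reference or the
re-ranker, so other association methods' outputs can be placed on the
same curves without re-implementing them.

# Network diffusion with degree-matched nulls

Connectivity of a candidate gene set to an established gene set is scored
by random walk with restart on a weighted undirected network (the
operator choice; restart 0.5, column-normalised weighted adjacency,
L1 tolerance $10^{-8}$), giving node scores that sum to 1.  Edge weights
enter only through the column normalisation, so any positive confidence
score (e.g. a combined interaction score) works unscaled.  The observed
seeds-to-targets prioritisation AUC (targets vs. other non-seed nodes) is
compared with 100 random seed sets matched to the seeds' log2-degree bins
(widening to neighbouring bins when a bin is exhausted), yielding
$z = (AUC - \overline{AUC}_{rand})/sd(AUC_{rand})$; the random AUCs'
normality is checked (Shapiro–Wilk) and reported, not enforced.
$z > 2.5$ is the conventional significance line.  `diffuseScores()` is
verified against the exact fixed-point solution
$(I - (1-r)W)^{-1} r e$ on small graphs.

The synthetic network generator grows a preferential-attachment
background (3 edges per node) and densifies a planted module to edge
density 0.1.  Both values are deliberate: at attachment 3 the background
degree distribution has substantial mass at the module members' degrees,
so module membership is *not* inferable from degree alone.  A much denser
module (e.g. 0.5) turns its members into global hubs; degree-matched
random seed sets then consist largely of other module members and the
null AUC saturates near 1, destroying the very contrast the z-score is
designed to detect.  This mirrors real interactome modules, whose members
are connected above background but are rarely the network's hubs.

# The analytic power comparator

The comparator curve answers: what would a conventional single-variant
association scan detect at the same sample sizes?  Under HWE genotype
frequencies at disease-allele frequency $p$, genotype relative risks
$(1, r, 2r\!-\!1)$ (additive; the other standard models are available)
scaled so the population prevalence constraint holds, the case and
unaffected-control risk-allele frequencies follow by Bayes' rule.  Power
of the two-sided 1-df allelic test is the normal approximation with the
**alternative-hypothesis (unpooled) variance**

$$SE = \sqrt{\tfrac{p_a(1-p_a)}{2N_a} + \tfrac{p_u(1-p_u)}{2N_u}},
\qquad power = \Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2}).$$

The unpooled form is the convention of the standard GWAS power
calculators and is the variant that agrees with the Monte-Carlo
rejection-rate oracle bundled in the tests (a pooled-variance SE
understates power by about half a point at the reference settings).  At
$\alpha = 5\times10^{-6}$, prevalence 0.01, DAF 0.05, GRR 1.6, the curve
gives 0.85 at 2500 cases/2500 controls and 0.00 at 250/250 — the two
data-free quantities `scripts/acceptance.R` recomputes.

# The synthetic cohort generator

Every simulation-based claim in the package is made against
`simulateCohort()`, so its assumptions bound what the tests show:

* **Sites.** Poisson(8) sites per gene; MAF $\sim$ Beta(0.2, 4) truncated
  to (0, 0.5] (rare-skewed, mean ~0.05); classes 82% missense /
  12% synonymous / 4% stop-frameshift / 2% inframe; missense EA from a
  90:10 mixture of Uniform(0, 100) and a Uniform(70, 100) high-impact
  tail.  Genotypes are independent HWE draws per site.
* **Planted risk genes** act on *carrier indicators of a designated
  high-EA site* (dominant: any carrier; recessive: homozygous carriers,
  with the risk-site MAF solved from the target carrier frequency), not
  on allele dosage — so the planted mechanism is exactly the mechanism
  the thresholded pEA features assume, and recovery tests measure the
  pipeline, not a model mismatch.  Effects may be sex-restricted.
* **Covariates.** An APOE-like two-site gene whose pEA enters the
  liability at +1.2 log-odds (carrier OR ~3, in line with the major
  common risk genotype of late-onset dementia), and age
  $\sim N(74, 6^2)$ truncated to [55, 95] at +0.04 log-odds/year.
  Disease status is Bernoulli from the logistic liability, with the
  intercept solved so the population case fraction matches `base_rate`
  (0.5 by default), then cases and controls are subsampled to the
  requested counts.
* **Not emulated:** linkage disequilibrium, population structure and
  relatedness, sequencing/annotation error, variable gene length and
  site-frequency-spectrum realism, genuine APOE allele structure.
  Passing recovery tests therefore demonstrates correctness of the
  machinery under its own assumptions, not robustness to the confounders
  real cohorts carry — those are handled upstream (QC, PCA, kinship) and
  are out of scope here.

The truth record (`cohortMetadata(x)$truth`) stores the planted table,
the solved intercept and the realised case/control carrier frequencies,
so recovery metrics never need the configuration object.

# Reference study conditions used by the test suite

The package's end-to-end checks run at sizes chosen to exercise each
property with margin while keeping a full suite run in tens of minutes on
a single CPU:

* *Null calibration*: 10 cohorts, 100 genes, 100 cases/100 controls,
  B = 50 permutations pooling 1 random gene each.
* *Recovery*: 5 seeds, 300 genes, 500 cases/500 controls, 10 planted
  dominant genes ($\beta = \log 2.5$, carrier frequency 0.1, EA cut 70);
  success = at least 8 planted genes in the top 20.
* *Sex specificity*: 5 seeds, 50 genes, 800 individuals per sex, one
  female-restricted gene ($\beta = \log 3$, carrier frequency 0.1).
  This check is deliberately demanding and fails more seeds than it
  passes: at this effect size the best attainable carrier-phenotype
  correlation in a 400/400 stratum is about 0.17 (sampling SD 0.035),
  while clearing $q < 0.01$ after BH adjustment requires a robust z
  above roughly 3.5 — detection at that stringency needs either a
  larger stratum, a commoner risk allele or a stronger effect, which is
  itself an informative statement about sex-stratified designs at this
  scale.
* *Risk stacking*: 1000 cases/1000 controls at the recovery-cohort
  settings (see the Bayes-ceiling discussion above).
* *Diffusion*: 2000-node network, 30-node planted module, 100 random
  sets; *down-sampling*: 100 genes, 500/500, sizes 400/200/100 with
  3 iterations.

# Numerical and degenerate-input policy

Missense records with missing EA are skipped with a warning, never
imputed.  All-constant feature blocks are not fit (all MCCs 0, flagged).
A learner that errors in a fold falls back to the training-fold majority
class.  Zero-variance AUC comparisons report $p$ below machine epsilon
with a `degenerate` flag.  Empirical p-values use the add-one rule and
can never be 0.  Every stochastic step — fold assignment, permutations,
subsampling, random seed sets, the generator itself — is driven by an
explicit integer seed, and seeded reruns are bit-identical (tested).

# Known limitations

* The published FDR's exact null model is not recoverable from the
  protocol; the two modes here bracket reasonable choices but neither is
  claimed to match the original bit-for-bit.  The same holds for the
  diffusion operator's parameters and the Kendall-tau alignment.
* The rule-learner surrogates share their inductive family with PART and
  RIPPER but not their exact rule lists.
* pEA treats variants within a gene as independent damage probabilities;
  compound heterozygotes are handled per-variant, and phase is ignored.
* The VCF reader expects per-ALT annotations in INFO fields and does not
  parse CSQ/ANN transcript blocks; annotation and transcript selection
  are upstream concerns.
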