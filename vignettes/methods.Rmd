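---
title: "Host-gene surrogate prediction of intronic miRNA targets: model and design notes"
author: "intromiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-gene surrogate prediction of intronic miRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Intronic miRNAs are frequently co-transcribed with their host genes, so a
host mRNA's expression profile can serve as a surrogate for the miRNA's
activity. intromiR predicts which sequence-predicted miRNA/target pairs are
functional by asking whether, across many independent expression studies,
the host profiles of a target's candidate regulators linearly explain the
target's *down-regulation*.

For target $i$ in dataset $k$ with $S$ samples the response is
$d_i^k[s] = \bar e^k[s] - e_i^k[s]$, the dataset-wide mean expression at
sample $s$ minus the target's expression there. The model is

$$ d_i^k = X^k\, w_i^k + \varepsilon^k, \qquad
   \varepsilon^k \sim \mathcal N(0, \sigma^2 I), $$

where the columns of $X^k$ are the host profiles rescaled to unit Euclidean
length. The assumptions worth stating explicitly:

* **Additivity on the linear scale.** Repression by several miRNAs adds up
  in expression units; expression is therefore *not* log-transformed, and
  the readers perform no transformation. Feeding in pre-logged data will
  produce mis-scaled weights.
* **Spherical Gaussian noise.** Under it, the ordinary least-squares
  solution of the ULM is the maximum-likelihood estimate.
* **No intercept.** The response is already referenced to the dataset mean;
  an intercept would break the mean-centering identity
  $\sum_i d_i^k[s] = 0$.
* **Weights are comparable only after L1 rescaling.** Each fitted
  $w_i^k$ is divided by $\sum_m |w_{im}^k|$ before pooling across datasets.
  All-zero ("degenerate") fits have no defined rescaling and are excluded
  from both the real samples and the null pool instead of being recorded as
  zeros, which would concentrate spurious mass at 0.

A positive weight means the host profile tracks the target's
down-regulation — the model's signature of repression by the host's
intronic miRNA(s). Negative weights are allowed (the *unconstrained*
model); constraining them to be non-negative (the CLM, solved by
non-negative least squares) changes little in practice and is provided for
comparison, as is a Pearson-correlation baseline (CORR) that replaces the
fitted weights by per-host correlations within the identical enrichment
framework.

## From DAG to design

Host/miRNA/target relations are many-to-many: one host may carry several
miRNAs, one miRNA may be duplicated in several hosts. Because weights are
assigned to *host genes* (the observable), the DAG is collapsed: each
distinct host contributes exactly one regressor column per target; hosts of
duplicated miRNAs keep separate columns; several miRNAs in one host share
one column whose final score is fanned back out to each miRNA when the
network is exported. Columns are ordered lexicographically by host symbol
so weight vectors align across datasets. Hosts missing from a particular
dataset (absent probe sets) are masked from that dataset's design only.

## Permutation null, P and Q

Host labels are permuted — each design column is reassigned a uniformly
drawn *different* host from the dataset's host universe, without
replacement within a design — and every (target, dataset) model is refitted.
All rescaled permuted coefficients form the pooled empirical null. For each
pair, `p_real` is the two-sided Wilcoxon-Mann-Whitney P-value of its real
weights against the pool, and `p_perm` (the negative control) the same
statistic for the pair's own permuted weights. The rank-sum P-value uses
the exact U distribution when $\min(n,m) \le 8$ and the data are tie-free,
otherwise the normal approximation with midranks, tie-corrected variance
and continuity correction.

Design choices here, made where conventions genuinely diverge:

* One permuted solve per dataset is the default (`nPerms = 1`); more
  permutations smooth the pool and the per-pair Q samples.
* The pair's own permuted weights are *not* removed from the pool when its
  Q is computed; at compendium scale the self-contribution is negligible.
* One pool per method — pools are never shared across ULM/CLM/CORR.
* Whole-universe relabelling is the default; `scope = "design"` restricts
  the permutation to the design's own columns for narrow designs.

## Cutoff, interaction calls, surrogacy

The ROC uses $-\log_{10}$ `p_real` as positive scores and
$-\log_{10}$ `p_perm` as negative scores; `chooseCutoff` returns the least
stringent threshold whose false-positive rate stays within
$1-\text{specificity}$, scanning thresholds at the observed score values.
The pipeline's default instead fixes the cutoff at $P \le 0.01$, a
conventional near-zero-false-positive operating point, for comparability
across runs; the ROC-chosen cutoff is opt-in (`rocSpecificity`).

A significant pair is *negative* (repressive) when its mean weight exceeds
the null mean. Hosts are then called: `good_surrogate` if strictly more of
their significant interactions are negative than not, `bad_surrogate`
otherwise, and `uninformative` with no significant interaction at all. The
tie goes to `bad_surrogate` deliberately — a good-surrogate call licenses
downstream target claims, so the boundary case stays conservative.
Zero-significant hosts are reported as their own class rather than folded
into either call.

## What the synthetic compendium emulates

`simulationConfig()` defaults define the package's reference study
conditions; they are chosen to mimic, at desk scale, the statistical
structure a real compendium presents to the method:

* **50 datasets x 30 samples**, 12 hosts, 20 targets, 1000 background
  genes. The background universe keeps the per-sample mean (the reference
  for $d$) as stable as in genome-scale data; with very small universes the
  hosts' own rows visibly perturb the column means, an artifact of tiny
  simulations rather than of the method.
* **Host co-expression in two anti-correlated programs.** Host
  transcription profiles load (balanced signs, `hostCor = 0.5`) on a
  per-dataset shared factor. Co-expression among regulators is the central
  confound that separates multivariate regression from marginal
  correlation.
* **A dominant shared expression program in targets.** Each target loads
  the factor with a per-dataset $\mathcal N(0, \texttt{confounderSd}=4)$
  coefficient — program variation (cell type, proliferation) unrelated to
  miRNA action, typically the largest variance component of real data. It
  leaves the regression unbiased but makes marginal correlations noisy in
  both directions.
* **Combinatorial regulation across programs.** Each target draws its
  3 planted regulators (effect size $w^*=1$) from both programs (2+1), so
  for part of the true pairs the co-regulators' correlation structure
  cancels the marginal signal — invisible to CORR, transparent to the ULM.
* **Decoy hosts (3 per design).** Sequence-based candidate sets carry
  substantial false-positive rates; decoys make the design, and the
  specificity measurements, honest.
* **Noise sd 0.5** per sample on targets, emitted as
  `baseline - sum(w* x_host) + noise` with baseline 10 so values stay on a
  positive linear scale.
* **Surrogacy scenarios.** `coupled` hosts are emitted exactly as the
  regulator profile; `independent_promoter` hosts regulate through a latent
  profile uncorrelated with the emitted host mRNA; `mirna_targeted_host`
  hosts are co-transcribed with their miRNA but degraded by another miRNA
  (`decoupleImpact = 1.5`) which also represses the host's targets
  (`sharedMirWeight = 1`) — the shared-regulation confound that makes such
  hosts look *positively* co-expressed with their targets and hence called
  bad surrogates.
* Host rows are emitted as scaled unit-norm Gaussian profiles
  (`hostScale = 30`), matching the model's own normalization; the scale
  only needs to clear the low-signal gene filter.
* Planted effect sizes default to $w^* = 1$; real interaction strengths
  are unknown, so this is a convention, not an estimate.

What the generator does **not** emulate: probe-level noise, batch effects,
platform differences, heavy-tailed intensity distributions, or annotation
errors beyond decoy edges. Passing the recovery tests therefore shows the
statistical machinery works under the stated structure, not that real-data
accuracy will match the simulated numbers.

## Numerical choices and degenerate inputs

* The ULM is solved by SVD; rank-deficient designs (duplicated or collinear
  hosts, $S < M$) get the minimum-norm solution with a warning.
* The low-signal filter drops genes whose max absolute value falls
  *strictly below* the 10th percentile (linear interpolation between order
  statistics) of that per-gene statistic; threshold ties survive. Genes
  with any missing value are dropped first.
* Zero-norm host rows raise an error; hosts absent from a dataset raise a
  typed condition (`intromiR_missing_host`) and are masked.
* All randomness flows through R's RNG; every pipeline stage takes or
  derives an explicit seed, and identical inputs plus seed give
  byte-identical outputs.

## Validation protocol and problem sizes

The test suite validates the fits against generic numerical minimizers
(multi-start BFGS for the ULM, projected gradient for the CLM), the exact
rank-sum branch against exhaustive enumeration of rank assignments, and the
pipeline against the generator's ground truth. The simulation-based checks
run at the reference conditions above: null calibration pools three
replicate compendia; planted-edge recovery compares ULM and CORR on five
paired replicates at the specificity-1.0 cutoff (the cutoff is a
max-statistic over the permuted controls, so single-run sensitivities are
noisy and the criterion is evaluated on the replicate mean); surrogacy
recovery uses 20 hosts (10 coupled, 5 independent-promoter,
5 miRNA-targeted) over two replicates. `scripts/acceptance.R` re-runs the
same protocol from scratch with seeds derived from `--seed`.

## Known limitations

* Power depends on the candidate sets: a target whose design omits a true
  regulator pushes that signal into noise (or into correlated hosts).
* The permutation null assumes hosts are exchangeable within a dataset;
  strongly atypical host profiles (extreme variance) weaken that.
* The good/bad surrogate call is relative to the compendium: a host whose
  miRNA is active only in conditions absent from the data will be called
  uninformative.
* CORR is implemented as correlation with the down-regulation vector (so a
  positive coefficient means repression for all three methods); whether
  published correlation baselines used $d$ or raw target expression differs
  only by sign conventions.
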