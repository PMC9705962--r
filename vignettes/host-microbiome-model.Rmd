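---
title: "Modeling host-microbiome-diet interactions with obesonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling host-microbiome-diet interactions with obesonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

obesonet chains four models of the mouse gut ecosystem — community
response to diet, metagenome content from community structure, metabolome
capacity from metagenome content, and host phenotype from either — into a
single pipeline that can replay a microbiome-transplant experiment *in
silico*. This vignette explains each model, its assumptions and tunable
parameters, what the synthetic-data generators do and do not emulate, and
the numerical and design choices a maintainer should know about.

## Data model and normalizations

Communities are described over a fixed vocabulary of 20 taxa (15 genera,
4 supra-genus groups tagged `"Order"`, and an `"Other"` catch-all;
`taxon_vocabulary()`). Relative abundances are normalized so every
sample sums to 100, and all modeling happens on `log2(abundance + 0.01)`
values. The pseudocount (1% of one abundance unit) keeps zeros finite and
is configurable everywhere it appears; results are insensitive to it
within an order of magnitude because the evaluation metric — per-sample
Pearson correlation across taxa — is shift-invariant on the log scale.

Diets are 48-feature nutrient vectors (17 protein/amino acids, 7
carbohydrates including fiber, 4 fats, 8 minerals, 11 vitamins, and
energy density; `reference_diet()`). Two design notes on the built-in
tables: fiber is tagged as a carbohydrate, because the stated category
counts only balance under that assignment even though feed data sheets
often group cellulose with fats; and the mineral list contains two
distinct "Magnesium" rows in the source tables — the second is kept as
its own feature, labeled `"Magnesium_2 (sic)"`, to preserve the count of
8 minerals rather than silently merging or dropping a column.

Each nutrient is normalized by a linear map anchored on the two reference
diets — the smaller reference value goes to 20, the larger to 80 — and
then log2-transformed. The anchors deliberately leave headroom: any value
whose mapped position falls in [0, 100] is accepted, so diets moderately
outside the reference span remain representable. Mixed diets are blended
on the raw g/kg scale first (a physical mixture of pellets) and
normalized afterwards; blending after the log transform would not
correspond to any physical feeding protocol.

## The community interaction network and MAP regression

The interaction network is a directed acyclic graph over three node
layers: diet features, taxa at the initial timepoint (`t0`), and taxa
after the diet period (`t1`). Only `t1` taxa may have parents; diet and
`t0` nodes are roots; a taxon never parents itself at `t1`; in-degree is
capped (default 5). Structure is learned by greedy hill climbing over
single-edge additions, deletions and `t1`-`t1` reversals, scoring each
candidate by the sum over taxa of a BIC-penalized Gaussian
linear-regression score. A continuous score is the coherent choice here
because the downstream regression is linear-Gaussian; discretizing the
data for a multinomial score would throw away exactly the information the
regression uses. The search runs from multiple starts (the empty network
plus random sparse DAGs, default 10 restarts, seeded); on small instances
it provably attains the exhaustive-search optimum (see the test suite's
brute-force oracle), and every accepted move strictly increases the
score, so termination is guaranteed.

Given a network, `fit_map_regression()` fits each taxon's log2 `t1`
abundance on its parents by ordinary least squares. During fitting,
observed values are used for `t1` parents (standard two-stage practice
for simultaneous systems); at prediction time `predict_community()`
re-evaluates `t1` taxa in topological order so each `t1` parent
contributes its freshly predicted value. Rank-deficient designs get the
minimum-norm (pseudoinverse) solution rather than an error: with 48 diet
features on a one-dimensional diet gradient, collinearity is the normal
state of affairs, and the minimum-norm fit leaves predictions — the
quantity that is actually validated — well-defined.

The dense control (`fit_nonnetwork_regression()`) regresses every taxon
on all diet features and all `t0` taxa, with no `t1` terms. With 68
predictors and ~26 training samples per fold it interpolates its training
data; its held-out accuracy is the meaningful comparison, and on
synthetic studies the network model reliably beats it out of sample.

Accuracy is always the mean over samples of the Pearson correlation
between predicted and observed log2 abundance vectors across the 20 taxa
(`evaluate_mean_pcc()`), with a zero-variance vector scored 0 under a
warning. Cross-validation uses one 5-fold partition — five disjoint 20%
test sets — rather than five independent 80/20 draws, so every sample is
tested exactly once. Enrichment of nutrient categories among the diet
features participating in the network is assessed by the upper-tail
hypergeometric probability, uncorrected, reported against the 0.05 level.

## Enzyme function profiles and offset optimization

`predict_efp()` computes each enzyme function's community abundance as
the abundance-weighted sum of per-taxon mean gene counts (`AveEC`),
optionally shifted by per-cell offsets `e` bounded element-wise by the
genome standard deviation — the offsets represent which strains of a
taxon a particular environment actually selects. Negative sums are
floored at zero, since gene counts cannot be negative.

`optimize_offsets()` is a stochastic hill climber: start at `e = 0`,
sample a (taxon, EC) cell with probability proportional to
`exp(SD / T)`, propose a uniform redraw within `±SD`, and accept only
strict improvements of the objective (mean per-sample Pearson correlation
between predicted and observed EFPs on `log2(x + 1)` values; raw-count
mode is a flag). Numerical choices worth knowing:

* the temperature `T` defaults to the mean positive SD, which makes the
  selection pressure scale-free in the SD units;
* cells with `SD = 0` are pinned at offset 0 and excluded from the
  proposal distribution — proposing them would be a guaranteed no-op;
* proposals are redraws, not random-walk steps, so the chain cannot creep
  outside its bounds;
* with fewer than 3 enzyme functions the correlation objective is
  degenerate, and negative RMSE is used instead;
* ties are rejected, so the objective trace is strictly monotone at
  accepted moves and non-decreasing overall.

Because `e = 0` is the starting point, the optimized objective can never
fall below the plain genome-average baseline. `run_variation_audit()`
repeats the optimization under distinct sub-seeds and reports the percent
coefficient of variation of the final objectives; values well under 1%
on the synthetic fixtures indicate run-to-run convergence to very similar
solutions.

## PRMT metabolome scoring

`compute_prmt()` turns EFPs into Predicted Relative Metabolic Turnover
scores: normalize each sample's EFP to sum 1 (removing sequencing-depth
scale), stabilize as `log2(x + 1)`, center each enzyme function on its
cohort mean, and push the deviations through a signed connection matrix
`W[m, e] = sign / degree(e)` built from an enzyme-metabolite link table
(+1 produced, −1 consumed; duplicates rejected; the degree normalization
spreads an enzyme's contribution evenly over the metabolites it
touches). The scores are cohort-relative by construction — each
metabolite's scores sum to zero over the samples — and the sign
convention is: positive means above-cohort-average capacity to
synthesize. The matrix builder and the scorer are separate functions so
an alternative weighting can be swapped in. Note that an enzyme absent
from the network contributes no term to any score, but it does
participate in the sum-1 normalization of the profile, as it should — it
is still part of the metagenome.

Feature ranking for phenotype models uses the Fisher score
`(μ₊ − μ₋)² / (s₊² + s₋²)` with unbiased class variances (0/0 scored 0,
positive/0 scored infinite) and `select_top_fraction()` takes the top 5%
by default — at the full scale of 2560 metabolites, 128 features — with
ties at the cutoff broken lexically for determinism. Pure ranking is
used, with no secondary significance filter.

## Symbolic phenotype classifiers

`evolve_classifier()` is a genetic-programming engine over arithmetic
expression trees: operators {+, −, ×, protected ÷} (quotients with a
near-zero denominator are defined as 1, so every expression is finite),
terminals drawn from the feature variables, the fixed constants 0 and 1,
and ephemeral constants in [−2, 2]. Selection is tournament-based on
mean squared error against the 0/1 labels plus a small parsimony term
(default 0.001 per node); variation is subtree crossover, point mutation
(which jitters constants half the time, letting the search fine-tune
coefficients), and subtree mutation, with elitism. Every evaluated
individual updates a (complexity, error) Pareto archive; the returned
model is the least-complex front member within 1% of the best front
error, matching the view that the simplest adequate equation is the
model.

Termination quantifies the stated stability/convergence idea
operationally: over a 50-generation window, stability is the percentage
of generations in which the front's best error moved by less than 1e-6,
and convergence is the mean percentage of front members unchanged
generation-to-generation; both at 95% ends the run, else the generation
cap does. Classification thresholds the function value at 0.5 strictly
(`f > 0.5` is class 1; exactly 0.5 falls to class 0 — the boundary is
assigned to the negative class by convention since only the strict
inequalities are meaningful). Accuracy is the Matthews correlation
coefficient with the usual zero-denominator-gives-0 convention;
train/test splits are stratified and seeded.

Two practical notes. First, classifier features should be standardized
(`standardize_features()`) before evolution: the engine's constants are
bounded, so a threshold-at-0.5 surface over features living at a 1e-3
scale — PRMT scores, for instance — is out of reach without
standardization, while commercial symbolic-regression tools absorb scale
into unbounded constants. The transplant stage applies the training
cohort's standardization statistics to new metabolomes for the same
reason. Second, single-class label vectors are accepted with a warning
rather than rejected — the evolved model is then a constant, which is the
correct answer.

## The in silico transplant experiment

`run_transplant()` takes labeled starting communities and diets plus the
fitted stages, and for each condition predicts the community after the
diet period, its EFP, and its PRMT metabolome — with the run's own
conditions as the scoring cohort — then evaluates the obesity function
and converts the values to obesogenesis scores
`log2(value / mean over conditions)` (the log base is a flag; base 2 is
the default for consistency with every other transform in the package).
A score above 0 marks a condition more obesogenic than the run average.
Because evolved expressions are unbounded, an obesity value can be
non-positive; such conditions are reported as missing with a warning
rather than silently clamped, and `clamp_epsilon` offers an explicit
floor for pipelines that need complete tables.

`run_pipeline()` executes the stages in dependency order on synthetic
inputs, persists every table (TSV) and model (JSON) plus a manifest
recording the seed and configuration, and errors with the name of the
missing stage if prerequisites are absent. Identical seed and
configuration reproduce identical outputs byte for byte. The pipeline
reuses the diet-study network and regression for the transplant rather
than re-learning anything, and the manifest records exactly which
artifacts were used. Donor "Lean"/"Obese" communities are the mean
communities of the cohort hosts with the most extreme fitted
obesity-function values (default the bottom and top 8 of 54) — donor
archetypes discordant for the phenotype — rather than label-group means,
whose difference is diluted by label noise.

## What the synthetic generators emulate — and what they do not

`simulate_diet_study()` reproduces the *structure* of a diet-gradient
feeding study: 33 mice on 7 pellet mixtures from 0 to 100% high-fat,
profiled before and after, 66 community states in all. Initial
communities are Dirichlet draws on the sum-100 scale; `t1` log2
abundances come from a hidden sparse DAG (uniform [−1, 1] weights,
Gaussian noise of SD 0.1 on the log2 scale) and are renormalized to sum
100. Two realism choices matter downstream. Every taxon keeps a
positive-weight edge from its own `t0` abundance (weights in [0.5, 1]):
gut communities are temporally persistent over a one-week window, and
without that persistence a predicted community would carry no memory of
the starting community, emptying the transplant experiment of meaning.
And each mouse's diet vector receives a small formulation jitter (SD 2
units on the 20–80 band, about 3%): exact pellet blends make every
normalized nutrient an affine function of the single mixing fraction, so
the 48 diet features would collapse to two distinct profiles and
multi-nutrient effects would be structurally unidentifiable. The jitter
represents batch-to-batch feed variability and restores identifiability.
The exact pre-normalization log2 abundances are recorded in the ground
truth, because renormalization adds a per-sample constant on the log
scale; recovery tests use the recorded values, while correlation-based
evaluation is unaffected (Pearson is shift-invariant).

`simulate_metagenome_study()` draws Poisson-shaped genome matrices (SD
proportional to the square root of the mean), true offsets uniform within
one SD, and observed EFPs as community sums plus truncated Gaussian
noise. `simulate_reaction_network()` guarantees every enzyme at least one
signed metabolite link. The full-scale preset records the real-data
dimensions (1558 enzyme functions; 2560 metabolites, whose top 5% is
128); tests and the acceptance script run at reduced sizes — around
100 enzyme functions, 200 metabolites, 20–30 samples — chosen so the
whole suite completes in minutes while leaving every estimator
overdetermined.

`simulate_obesity_cohort()` (default 54 hosts, matching the combined
two-genotype cohort it emulates) labels each host's diet, shifts
community composition for high-fat hosts (6 taxa, log-scale effect 1.5,
so diet is predictable from community structure), and sets the obesity
label by a hidden sparse linear rule over the host's PRMT metabolome,
with 5% label flips. The observed EFPs mix a compositional part with
non-compositional, strain-level variation (`efp_noise`, default 0.3
relative SD, under which roughly 70% of the rule-score variance is not
explainable from genus-level composition). That default is the
generator's central construction: genus-level abundances are a coarse
proxy for gene content, and the cohort is built so the metabolome is
genuinely more informative than community structure for obesity — the
ordering the pipeline is expected to reproduce. At low `efp_noise` the
cohort would violate its own construction, with community structure
nearly as predictive.

None of the generators attempt to match the real datasets' empirical
abundance distributions, taxon covariances or noise shapes — only their
sizes, structure and information flow. Passing tests therefore
demonstrate that the algorithms recover what they are designed to
recover under the stated generative assumptions, not that the biology of
any particular mouse experiment is captured.

## Known limitations

* The interaction network spans exactly two timepoints; no longer
  dynamics are unrolled, and no edge-confidence (bootstrap) measures are
  provided.
* The continuous BIC score means the learner is not a reimplementation
  of discretized Bayesian-network scoring; on data with strongly
  non-Gaussian conditionals the learned structures will differ.
* PRMT is a topology score, not a flux model: it has no mass balance,
  reversibility thermodynamics, or growth objective.
* The genetic-programming engine is deliberately small (four operators,
  bounded constants); it finds threshold-style surfaces reliably only
  after feature standardization, and its absolute accuracy on weak
  signals is below what a large commercial engine reaches.
* Obesity is treated as a binary label; the obesogenesis score is
  relative to the run's own conditions and has no absolute calibration.
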