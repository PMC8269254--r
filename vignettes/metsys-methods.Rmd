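---
title: "Methods: systems analysis of metabolic disease across omic layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: systems analysis of metabolic disease across omic layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsys)
```

# Overview

`metsys` implements a systems-level analysis of metabolic disease for
multi-omic cohort studies of the kind run in HIV-positive and high-risk
MSM populations: a composite metabolic disease score built from fasting
blood markers, co-occurrence module detection on compositional
microbiome counts, random-forest feature selection across clinical,
immune, diet, and microbial layers, interaction and correlation
networks, and two-pronged attribution of plasma metabolites to the gut
microbiome. Because the cohort data such analyses run on are not
redistributable, the package ships a synthetic cohort generator that
reproduces the statistical structure every stage assumes, with planted,
recoverable effects. All tests and the acceptance script run on
generated data.

# The metabolic disease score

Seven fasting markers — triglycerides, glucose, insulin, LDL, HDL,
leptin, adiponectin — are z-scored and the first principal component is
extracted. The PC is oriented so the triglycerides loading is positive
(high score = dyslipidemia and insulin resistance), shifted so its
minimum on the fitting panel equals 1, and log-transformed:

$$s_i = \log\!\big(\sigma\, \mathbf{w}^\top \mathbf{z}_i + c\big),
\qquad c = 1 - \min_j \sigma\, \mathbf{w}^\top \mathbf{z}_j,$$

where $\mathbf{z}_i$ is the z-scored marker vector, $\mathbf{w}$ the
unit PC1 loadings, and $\sigma = \pm 1$ the orientation. The minimum
subject of the fitting panel scores exactly 0. The log base is not
dictated by the construction; we use the natural log and record it as a
model field so serialized models are auditable.

Subjects are classified as metabolically impaired above a cutoff of
1.4 on the score scale. That number is the mean of four regression
intersections: OLS of score on each of triglycerides, glucose, HDL, and
LDL, evaluated at the marker's clinical threshold. Triglycerides use
the published 200 mg/dl bound; glucose 100 mg/dl, HDL 40 mg/dl, and
LDL 160 mg/dl are conventional values and configurable, since only the
triglyceride bound is printed in the source material. `derive_cutoff()`
recomputes the cutoff for any panel; on synthetic panels, whose marker
location/spread are plausible but not fitted to any real cohort, the
derived value differs from 1.4 (about 2.1 at the default generator
settings) — the recorded default cutoff is used for classification and
the derived value is reported alongside.

The score model may be fitted on a larger reference panel than the
analysis cohort (the fitting panel is an explicit argument), and new
subjects below the fitting panel's minimum legitimately score below 0;
they are flagged, never clamped.

Cohort differences in the score are assessed with
`score ~ age + cohort + age:cohort` under treatment coding;
`age_cohort_model()` reports one age slope per cohort (base slope plus
interaction) with delta-method standard errors, so statements like
"the score increases with age only in cohort X" map onto rows of its
output.

# Compositional co-occurrence modules

OTU counts are rarefied without replacement to a common depth (default
19,986 reads; shallower samples are dropped), and features present in
at most 20% of samples are removed (strictly more than 20% is
required to survive — a feature in exactly 20% is removed). Diet
features are normalized per 1,000 kcal.

Correlations between OTUs are estimated with the SparCC procedure for
compositional data: with a pseudocount of 1, pairwise log-ratio
variances $t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$ are collected, basis
variances $\omega_i^2$ are solved from the sparse-approximation linear
system $\sum_{j \ne i} t_{ij} = (d-2)\,\omega_i^2 + \sum_j \omega_j^2$,
and correlations follow as
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$,
clipped to $[-1, 1]$. Pairs whose estimated $|\rho|$ exceeds 0.8 are
iteratively excluded from the system (up to 10 rounds, the estimator's
conventional defaults, recorded in the output) and the basis re-solved.
The default is a single deterministic estimate; Dirichlet-resampled
averaging — the stochastic variant of the original algorithm — is
available behind a seed, since the source analysis does not state which
variant it used.

Modules are shared-minimum-distance (SMD) subtrees: complete-linkage
clustering on $1 - r$, with a module being a **maximal** subtree in
which *every* pairwise correlation meets the threshold (SparCC
$R \ge 0.35$ for microbiome; Pearson $r^2 \ge 0.75$ for diet).
Maximality makes modules disjoint; a feature belongs to at most one
module, and the highest qualifying ancestor wins. For the squared
threshold we additionally require $r > 0$: summing anti-correlated diet
features would not produce an interpretable composite, and whether the
original diet modules admitted negative correlations is not stated.
Modules are summarized by elementwise summation of member rows, which
conserves per-sample totals exactly and shrinks the feature count by
$\sum (\text{size} - 1)$.

# Feature selection and the permutation null

`vsurf_select()` follows the published three-phase variable-selection
scheme for random forests (thresholding / interpretation / prediction):

1. **Thresholding.** Features are ranked by mean permutation importance
   over `n_forests` forests (25 by default, the published setting); a
   CART model is fitted to the curve of importance standard deviations
   versus rank, and features whose mean importance exceeds the minimum
   CART prediction are kept.
2. **Interpretation.** Nested forests over growing prefixes of the
   ranked retained features; the smallest prefix whose mean OOB error is
   within one standard deviation of the minimum is the interpretation
   set (the "important variables").
3. **Prediction.** Stepwise addition of interpretation variables,
   keeping those that reduce OOB error by more than the mean absolute
   jump of the tail of the interpretation error curve.

The sets nest (prediction ⊆ interpretation ⊆ threshold). Forest sizes,
`mtry` (regression default $\lceil p/3 \rceil$), and repetition counts
are recorded in the output, since the source analysis states none; the
test suite and the acceptance script run with reduced forest sizes
(e.g. 8–10 forests of 100–150 trees) that are stable at the problem
sizes used (n = 100–200, p ≤ 110) and quick on one CPU.

The significance of the selected set's predictive value is assessed by
a permutation null: the response is permuted B times (1,000 for study
fidelity, 99 as the fast default), each permutation is passed through
the full selection, a standard forest is fitted on whatever was
selected, and its OOB percent variance explained is recorded. A
permutation that selects nothing contributes 0, the intercept-only
value. The one-tailed p uses the add-one convention
$p = (1 + \#\{r^2_{perm} \ge r^2_{obs}\})/(B + 1)$, so it is never 0.
On null data this p is approximately uniform — verified by a KS check
in the acceptance suite.

Under honest simulation, pure-noise selection retains a median of 3
variables in the interpretation set (not fewer) even at the published
repetition counts; the tests assert that measured level.

# Interaction extraction from iterated forests

Following the iterated random forest idea, forests are refitted with
split-candidate sampling biased by the previous iteration's
(non-negative, normalized) importances — 3 iterations by default, with
a floor of $1/(10p)$ on every feature's weight so none is permanently
excluded. A feature pair "interacts" in a tree when the two features
split parent–child internal nodes; adjacency is counted at most once
per tree, and an edge is emitted when the pair is adjacent in at least
30% of trees. Same-path but non-adjacent co-occurrence is *not*
counted — "adjacent nodes" is read literally.

Trees are depth-limited (default `max_depth = 4`). This is a
deliberate design choice: an unlimited-depth regression tree at
moderate n contains so many internal nodes that almost every feature
pair becomes adjacent somewhere in almost every tree, and the 30%
prevalence threshold stops discriminating. Reading adjacency from the
top of the tree, where nodes still carry enough samples for splits to
be signal-driven, restores the intended sparsity: a planted XOR-style
interaction (`y = sign(x1) sign(x2) + noise`, n = 400) passes the 30%
threshold and ranks first in 19–20 of 20 seeds, while pure-noise data
yield no edges in ≥ 90% of seeds (n = 400, p = 40).

# Association networks and group tests

All pairwise Spearman correlations (average ranks, two-sided p via the
t approximation; an exact mode would be feasible only at very small n)
are corrected by Benjamini–Hochberg over all tested pairs as one
family, with edges at adjusted q below 0.25. Outcome correlations
correct within the feature set supplied per call — 0.1 is the preset
for selected features against the disease score, 0.05 for metabolites.
The multiple-testing family is therefore logged per call, since the
source analysis does not state its families precisely.

Group tests mirror a cohort-characteristics table: Kruskal–Wallis (via
`stats::kruskal.test`, tie-corrected) for continuous measures and an
exact Fisher test for r×c contingency tables. The Fisher p-value is
computed by full enumeration of all tables with the observed margins,
summing hypergeometric probabilities at most the observed table's
probability (with a $1 + 10^{-7}$ relative tolerance absorbing float
jitter). Enumeration is capped (default 2 × 10⁶ tables) with a seeded
Monte Carlo fallback via `stats::r2dtable`.

# Metabolite origin and rank regression

A compound is called **microbiome-associated** when it is producible by
the microbial gene set *or* differential between germfree and colonized
mice, *and* observed in human plasma. Producibility is single-step
product membership: the union of product compounds over all reactions
linked to any gene in the set, matching the cited attribution tool's
behavior; a transitive-reachability mode exists behind a flag, off by
default. A host gene set can be mapped the same way so compounds
explainable *exclusively* by microbial production are identifiable.

The mouse contrast removes compounds present in fewer than 20% of
samples (at-least-20% survives here, unlike the strict > 20% OTU
filter — both boundary readings follow their respective sources), then
applies a two-sided pooled-variance Student t test per compound on
log(x+1) intensities — the log is standard for LC-MS intensity scales
and switchable, as the source does not state a transform — with BH
correction at q < 0.05.

Age-adjusted associations between metabolites and the score use
rank-based regression: slopes minimize Jaeckel's dispersion
$D(\beta) = \sum_i a(R(e_i))\, e_i$ with Wilcoxon scores
$a(i) = \sqrt{12}\,(i/(n+1) - \tfrac12)$, a convex piecewise-linear
objective (solved by line search for one predictor, Nelder–Mead from
the OLS start otherwise; the grid-search oracle in the tests agrees to
1e-3). The intercept is the median residual. Standard errors use the
rank-regression asymptotic variance $\tau^2 (X_c^\top X_c)^{-1}$ with
$\tau^{-1} = \sqrt{12}\int f^2$ estimated by a kernel-density plug-in
on the residuals. The screen fits every compound with and without age
and reports both significant sets and their overlap, which is how age
confounding is judged.

# Diversity

Shannon entropy (natural log), observed features, and Pielou's evenness
$J = H/\ln(\text{observed})$ per sample; a single-feature sample has
undefined evenness and is reported as $J = 0$ with a warning so
degenerate synthetic samples do not break pipelines. The Mantel test
correlates upper triangles of two distance matrices (Pearson, the
classical choice; the source does not state the correlation type) with
a two-sided permutation p via simultaneous row/column shuffling, and an
exact enumeration mode for n ≤ 8. Phylogeny-dependent metrics
(UniFrac, Faith's PD) are out of scope; distance matrices are inputs.

# The synthetic cohort generator

One latent metabolic-health factor $z_i \sim N(0,1)$ per subject drives
everything that should co-vary:

* **Markers**: value = location + scale × (loading · z + √(1−loading²) ·
  noise), with loadings +0.85 (triglycerides), +0.75 (glucose), +0.80
  (insulin), +0.55 (LDL), −0.75 (HDL), +0.65 (leptin), −0.65
  (adiponectin). The signs encode dyslipidemia/insulin-resistance
  biology; the magnitudes are chosen so the seven-marker composite can
  actually recover the factor — a PC1 of seven markers reaches
  cor(score, z) ≥ 0.9 only when the average loading is at this level,
  and planted-effect recoverability at default settings is a design
  requirement of the generator.
* **Cohorts**: five groups of 22/32/14/20/25 subjects with age medians
  33/34/34/46/60 (treated cohorts older), BMI truncated at 30 (obese
  subjects excluded by design), and an ordinal bloating symptom score.
* **Immune panel**: 21 analytes; the first (LBP, the bacterial
  translocation marker) loads on z at 0.7, the rest are noise.
* **OTU counts**: logistic-normal log-abundances — planted module
  members share a latent component at the configured within-module
  correlation (default one 3-member block at r = 0.9), planted
  informative OTUs add effect × z — closed to proportions and sampled
  multinomially at depths of 20,000–30,000 reads so the 19,986-read
  rarefaction is always usable.
* **Metabolome**: 200 log-normal human plasma compounds (a tail subset
  tracks z at r = 0.5); a balanced germfree/colonized mouse experiment
  with 8 mice per arm and 10 compounds shifted by 2 natural-log units
  in the colonized arm. Mouse log-intensities use sd 0.5 versus 1.0 in
  humans: genetically identical mice on a fixed diet vary far less than
  free-living humans, and at sd 0.5 the planted shifts are reliably
  recoverable (10/10 in every tested seed). The real design gavaged
  eight mice with donor feces against PBS controls; the generator uses
  balanced arms so the Student t test is well powered.
* **Reaction map**: a toy gene → reaction → compound map in which the
  microbial gene set produces compounds 1–30 and a host set produces
  21–50, so producible, shifted, and human-observed sets overlap
  partially — the intersection structure the two-pronged origin logic
  must resolve.

All randomness flows from one root seed through named sub-streams
(`cohort`, `counts`, `metabolome`, …), so stages can be regenerated
independently and byte-identically.

What the generator does **not** emulate: taxonomy and phylogeny, read
simulation, chemical identities, batch effects, missingness, diet–
microbiome coupling, and the full 21-variable clinical layer (only
age, BMI, bloating, cohort are generated). Passing tests therefore
demonstrate that the estimators recover the structure they assume — not
that real cohorts satisfy those assumptions.

# Numerical choices and limitations

* SparCC needs ≥ 4 features; basis variances are clamped at 1e-12 if a
  solve turns non-positive, and exclusion stops before any feature
  loses identifiability.
* The permutation p-value can never be 0 (add-one convention); B < 19
  is refused outright.
* Fisher enumeration uses log-gamma arithmetic; enumerated
  probabilities sum to 1 within 1e-9 in the tests.
* Spearman p-values use the t approximation throughout; at n ≤ 10 this
  is coarse, which matters only for toy inputs.
* Rank-regression p-values are asymptotic (normal); at very small n
  they are approximate, and the τ plug-in assumes a smooth residual
  density.
* Problem sizes in tests and the acceptance script (n = 100–400
  subjects, 40–60 OTUs, 200 compounds, forests of 30–300 trees,
  20-seed recovery designs, B = 19–99 permutation nulls) are the
  package's chosen trade-off between statistical resolution and a
  single-CPU run measured in minutes; every threshold the analysis
  inherits from its source (19,986 reads; 20% prevalence; SparCC
  R 0.35; diet r² 0.75; FDR 0.25/0.1/0.05; 30% interaction prevalence;
  cutoff 1.4) is kept at full fidelity.
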