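---
title: "Discrete discriminant analysis for case-control genotype data: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete discriminant analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddagwas)
```

## The model

Case-control association inference usually conditions on genotypes:
logistic regression maximizes `Pr(y | a)` and ignores the marginal genotype
distribution of the sample. Discrete discriminant analysis does the
opposite of that simplification: it models the full joint distribution
`Pr(a, y) = Pr(a | y) p_y` by fitting the genotype distribution of each
phenotype group separately,

$$\Pr(\mathbf a \mid y) \propto \exp\Big(\sum_i h_i^{(y)} a_i +
\sum_{i<j} J_{ij}^{(y)} a_i a_j\Big), \qquad y \in \{0, 1\},$$

where `a_i` is the encoded genotype at SNP `i`. For the dominant and
recessive encodings `a_i ∈ {0, 1}` and this is an inverse Ising problem;
for the genotypic encoding `a_i ∈ {0, 1, 2}` and the package uses a
reference-category parameterization in which level 0 carries zero energy,
each SNP has one field per non-reference level, and each pair a 2×2
coupling block. Internally both cases share one representation: each SNP is
expanded into level indicators, so every fitting routine operates on a
binary design with zero within-SNP coupling blocks. The fields `h` play the
role of the group means of a classical (Gaussian) discriminant analysis and
the couplings `J` the role of the inverse covariance; with all `J = 0` the
model reduces to independent per-SNP frequencies.

Fitting maximizes the penalized log-likelihood per individual,

$$L_y/n_y = \frac{1}{n_y}\sum_{k \in y} \ln \Pr(\mathbf a^k \mid y)
 - \frac{\lambda}{2}\sum_{i<j}\big(J_{ij}^{(y)}\big)^2,$$

an l2 (ridge) penalty on couplings only — fields are never penalized, so
the `λ → ∞` limit is exactly the analytic independent-SNP solution rather
than a degenerate one. The same `λ` is used for the control, case, and
pooled (concatenated) fits so that likelihood-ratio statistics compare
like with like.

Bayes' theorem turns the two fitted distributions into the logistic risk
model

$$\Pr(y{=}1 \mid \mathbf a) = \frac{1}{1 + e^{-\alpha - \sum_i \beta_i a_i -
\sum_{i<j} \gamma_{ij} a_i a_j}}, \qquad
\beta_i = h_i^{(1)} - h_i^{(0)}, \quad \gamma_{ij} = J_{ij}^{(1)} - J_{ij}^{(0)},$$

with `α = ln(p₁/p₀) + ln Z₀ − ln Z₁`. The prevalence `p₁` defaults to the
sample case fraction and can be re-specified for prospective samples; doing
so shifts only `α` and leaves ranking metrics such as AUC untouched.

## The three estimators

**Exact enumeration (EE).** For panels small enough to enumerate every
genotype state (`2^m` binary, `3^m` genotypic; capped at m = 25 and 15),
the penalized likelihood is maximized exactly. The objective is concave and
its gradient is the gap between data moments and model moments, so the
package uses a Newton solver (implemented in C++ with step halving and a
step cap) on the enumerated state table; at `λ = 0` the optimum reproduces
the empirical single and pair moments to the gradient tolerance
(default `1e-6` per individual, iteration cap 500). Sufficient statistics
are state counts, so the cost is independent of `n` once the data are
tallied — this is what makes the permutation protocol below affordable.

**Pseudo-likelihood (PL).** Each SNP's conditional distribution given the
rest is a logistic (binary) or multinomial (genotypic) regression; the
joint objective is defined as
`Σ_i condll_i − n (λ/2) Σ_i Σ_{j≠i} J_ij²`, which decouples exactly into
independent per-site ridge problems (each pair is penalized once in each of
the two conditionals where it appears). The per-site problems run through a
user-suppliable `map_fun` (an `lapply` contract), so parallel and serial
execution give identical results; the two per-site estimates of each
coupling are symmetrized by averaging. Reported PL "likelihood" values are
the sums of the decoupled per-site optima, and the same definition is used
for full and restricted models in the test statistics.

**Mean field (MF).** The connected covariance `C_ij = f_ij − f_i f_j` of
the level indicators is shrunk by multiplying between-SNP entries by
`ε ∈ [0, 1]` (within-SNP blocks are kept, rebuilt from the pseudo-counted
multinomial frequencies); couplings are minus the between-SNP blocks of
`C(ε)⁻¹` and fields follow from the self-consistency relation
`h_i = logit(f_i) − Σ_j J_ij f_j` (block analog for the genotypic model).
`ε = 0` reproduces the independent-SNP fit exactly; `ε = 1` is the standard
naive mean-field inversion. A singular shrunk covariance receives one
diagonal jitter of `1e-8` (logged) before failing. The log-partition value
attached to MF fits is the variational (mean-field) free energy, and MF
likelihood values are computed against it.

**Independent SNPs.** With `J ≡ 0` the solution is closed-form:
`h = logit(f)` for binary encodings and `h(g) = ln(f(g)/f(0))` for the
genotypic one. SNPs with a boundary frequency get a 0.5 pseudo-count per
genotype cell (logged) so fields stay finite. The independent-SNP
likelihood-ratio power calculation uses the noncentral χ²₁ distribution
with noncentrality equal to the expected statistic at the true carrier
frequencies.

## Significance tests

The overall statistic is `q = 2[(L₁ + L₀) − L_pooled]`, clipped at zero.
Per-site and per-pair statistics pin the tested parameters of *both*
groups to their pooled-fit values at the same penalizer and re-optimize all
remaining free parameters. Degrees of freedom follow the parameter-count
difference: 1 per site and per pair for binary encodings, 2 and 4 for the
genotypic encoding. Single-SNP p-values use the asymptotic χ² distribution
and should be read as upper bounds when `λ > 0`, because the penalizer
compresses the null distribution. Interaction p-values never rely on
asymptotics: the phenotype labels are reshuffled (group sizes preserved),
the full fit plus all-pair restricted fits are re-run at the same
penalizer, and per-pair empirical null distributions are accumulated. The
pooled fit is label-invariant and computed once. Empirical p-values use the
add-one estimator `(1 + #{q_null ≥ q_obs})/(1 + N)`, so they are never zero;
per-pair nulls are kept separate, with an option to pool draws across pairs
when the permutation count is small. One master seed spawns one child
stream per permutation, so results do not depend on execution order or
worker count, and extending the number of permutations leaves earlier draws
unchanged.

For PL the statistic is a pseudo-likelihood ratio; for MF, whose estimator
is closed-form rather than iterative, the restricted model substitutes the
pinned couplings and re-derives the affected fields from the
self-consistency relation before evaluating the mean-field likelihood. In
both cases validity rests on the permutation null, not on asymptotics.

## Risk prediction and cross-validation

AUC uses the Mann-Whitney estimator with midrank ties and a Hanley-McNeil
95% confidence interval. Cross-validation stratifies folds by phenotype,
fits at every grid value on each training fold, pools the test-fold scores
across folds before computing one AUC per grid point (stabler than
averaging five fold-AUCs at n ~ 10³), and breaks ties in the argmax toward
the stronger penalizer. The default grids are 13 logarithmic points from
`1e-4` to `1e2` for `λ` and 11 linear points from 0 to 1 for `ε`.

When an independent-SNP p-value cutoff `p_c` pre-selects SNPs, the
unbiased protocol computes those p-values on each training fold only. If
pre-selection instead uses the full sample, the resulting score is labelled
`pAUC` (pseudo-AUC) because it over-estimates the true AUC — the package
keeps the two labels distinct. For PL fits, which have no partition
function, `α` is calibrated by a one-parameter maximum-likelihood fit of
the labels given the fixed linear predictor on the training data; EE and
independent fits use their exact `ln Z`, MF its free energy.

## The simulator

Simulation draws group parameters from normal distributions —
`h ~ N(h̄_y, σ_h²)`, `J ~ N(J̄_y, σ_J²)` — enumerates both genotype
distributions exhaustively, and samples each group i.i.d. from its state
table (exact sampling, no MCMC; feasible because simulation panels are
small). Parameter draws and genotype draws consume disjoint child streams
of the master seed, so enlarging the panel does not perturb earlier draws.

Two drawing modes exist because they answer different questions. With
independent per-group draws (the default), every effect difference
`β, γ` is a random variable — appropriate for parameter-recovery studies,
where the truth should vary. For sensitivity/specificity studies of a
single causal interaction, the package draws one deviation per entry
*shared* by both groups and lets only the group means differ
(`share_deviations = TRUE` with `mean_overrides` for the causal pair).
With independent draws every "null" pair would carry a real coupling
difference of SD `σ_J√2` — at the study's sample sizes those are partly
detectable, null p-values are visibly non-uniform, and the notion of a
single causal pair dissolves. The shared mode makes non-causal effects
cancel between groups exactly, which is the premise of a
specificity analysis.

What the generator emulates: group-specific allele frequencies, LD induced
by the couplings, and differential LD between case and control groups. What
it does not emulate: haplotype block structure from recombination,
genotyping error, population stratification, or missingness. Passing tests
on simulated panels therefore demonstrate correctness of the estimators and
the statistical protocol under the model's own assumptions, not robustness
to those real-data features (the QC module addresses missingness and
Hardy-Weinberg violations on real input).

## Problem sizes in the test suite

The test suite scales the simulation studies to desk size as the package's
own choice of problem sizes. Parameter recovery uses 20 parameter
realizations of a 10-SNP dominant panel at n ∈ {10², 10³, 10⁴}, with `λ`
selected by 5-fold cross-validation over a 5-point logarithmic grid; the
median error of the DDA fits decreases monotonically in `n` and undercuts
the marginal pairwise-test error at n = 10⁴. The sensitivity study runs 20
replicates of the single-causal-pair design (10 SNPs, n = 10⁴, shared
deviations, ΔJ = 0.1) with 199 permutations each. A caveat worth stating
plainly: at those conditions the causal pair's likelihood-ratio statistic
has noncentrality ≈ 1 (measured by fitting at n = 10⁶ and rescaling), so no
test statistic can rank it first among all 45 pairs in a large majority of
replicates; the suite asserts the full prescribed protocol and records the
shortfall, while the specificity half (uniformity of null-pair empirical
p-values) holds.

## Numerical choices and edge cases

* Optimization: Newton with gradient tolerance `1e-6` per individual and a
  500-iteration cap for EE (concave, unique optimum); BFGS with analytic
  gradients for PL site problems and the logistic baseline.
* Boundary frequencies: 0.5 pseudo-count per genotype cell in all analytic
  formulas, always logged, never silent infinities.
* Missing genotypes: imputed to the per-SNP modal genotype of the pooled
  sample before encoding — deterministic, so likelihood pipelines are
  reproducible. Samples with phenotype codes other than 1/2 are dropped
  with a logged count.
* Quality control: minor alleles are re-identified from pooled allele
  frequencies before filtering; the Hardy-Weinberg exact test runs on
  control samples only (standard practice for a disease sample, since cases
  may deviate under association); the genotyping-rate criterion is applied
  as per-SNP missingness ≤ 5%.
* Grid argmax ties go to the stronger penalizer; statistics are clipped at
  zero; empirical p-values lie in (0, 1] by construction.
* Degenerate pairwise tests (constant columns) are flagged with p = 1
  rather than dropped, so output tables keep one row per pair.

## Design decisions that were genuinely open

* The Hardy-Weinberg filter's sample (controls vs pooled) is not dictated
  by the QC thresholds alone; controls-only was chosen as the conservative
  standard.
* Whether fold AUCs are pooled or averaged is unspecified in common
  descriptions of the CV protocol; pooling was chosen for stability and is
  reported with its CI method.
* Per-pair permutation nulls are kept separate rather than pooled because
  pairs differ in information content; pooling is available as an option
  when few permutations are affordable.
* The logistic baseline penalizes interaction terms only, mirroring the
  DDA convention of unpenalized fields, so the two methods differ in their
  modeling assumption and not in their regularization surface.
* Calibration of SNP-set AUC to p-values uses the sets with AUC nearest
  0.5 plus a spread up to the maximum (configurable), a linear fit of
  `−log₁₀ p` on AUC above 0.52 with the slope floored at zero to keep the
  mapping monotone, and a Bonferroni threshold computed from the number of
  sets actually scored.

## Known limitations

Exact enumeration is limited to ~25 binary SNPs; PL and MF scale further
but inherit their usual biases (PL mildly inefficient, MF biased outside
the weak-coupling regime — the tests quantify both against EE). Third- and
higher-order interactions are out of scope, as are l1 penalties, covariate
adjustment, sex chromosomes, sample-level QC, and LD pruning (pre-pruned
panels are accepted as input). LD-proxy lists for enrichment are consumed
as user-supplied tables; the package computes r² only from user-provided
phased haplotypes for synthetic tests.
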