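---
title: "Internal validation for MDR: cross-validation, the three-way split, and pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal validation for MDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrsplit)
```

## The model

Multifactor Dimensionality Reduction is a nonparametric constructive-induction
method for case–control genotype data. For a candidate combination of $k$
biallelic loci, each individual falls into one of $3^k$ multi-locus genotype
cells (genotypes are minor-allele counts 0/1/2; cells are indexed in base 3
with the first locus most significant, see `mdr_cell_index()`). A cell is
labelled *high-risk* when its case:control ratio exceeds the threshold
$T = n_1/n_0$ of the fitting data, and the resulting binary attribute is
scored by balanced accuracy

$$BA = \tfrac12\left(\frac{n_{11}}{n_1} + \frac{n_{00}}{n_0}\right),$$

the mean of sensitivity and specificity; for balanced samples this equals
classification accuracy. No mode of inheritance or statistical distribution
is assumed — the cell labelling *is* the model.

Three conventions complete the definition, all pinned by tests:

* a ratio exactly equal to $T$ labels the cell low-risk (the threshold must
  be *exceeded*);
* an empty cell is low-risk, and a cell unseen at fitting time keeps that
  label at evaluation time — the conservative choice for sensitivity;
* a cell with cases but no controls has infinite ratio, hence high-risk.

Internally the comparison is integer arithmetic
(`cases * n0 > controls * n1`), so these rules hold exactly, with no
floating-point ratio involved. Ties between equally accurate locus
combinations are always broken toward the lexicographically smallest tuple,
making every search deterministic.

## The two validation engines

**Cross-validation** (`mdr_cv()`, default $m = 5$) stratifies individuals
into $m$ folds with case and control counts balanced to within one. For
each fold and each size $k$, the best model is found by exhaustive search on
the other $m-1$ folds and its *prediction accuracy* (PA) is the balanced
accuracy on the held-out fold, using the training-derived labels and
threshold. Cross-validation consistency (CVC) is the number of folds in
which the per-size modal locus set won; its mean PA is averaged over those
winning folds. The final model maximizes both mean PA and CVC; if the two
maximizers disagree, the smaller (more parsimonious) model wins, and any
residual tie goes to the smallest $k$, then lexicographic order.

**Three-way split** (`mdr_3ws()`) makes one stratified partition into
training, testing and validation subsets (default weights 1:1:1,
largest-remainder rounding per class stratum, cases apportioned before
controls). Training ranks all $C(K,k)$ combinations per size and carries
the top `x_top` forward (default: the number of loci, matching the
practice of setting $x$ to the locus count). Testing determines the MDR
parameterization of each carried model afresh on its own data and keeps the
best per size; validation does the same for each per-size winner. The final
model maximizes validation balanced accuracy across sizes; that accuracy is
the reported predictive-ability estimate. A two-way variant
(`mode = "2ws"`) omits the validation subset and selects on testing-stage
accuracy. Work accounting is explicit: 3WS performs
$\sum_k C(K,k)$ exhaustive-stage fits against $m\sum_k C(K,k)$ for CV —
the tested basis of the roughly five-fold speed difference.

Each 3WS stage *re-fits* the cell labels (and threshold) on its own subset
by default. The alternative — carrying the previous stage's labels forward
and scoring prediction accuracy — is available as `refit = FALSE` for
sensitivity analysis; we keep refitting as the default because each stage
is meant to determine the high/low-risk parameterization on its own data.

## Post-hoc pruning

Because fitted balanced accuracy can only improve with model size, 3WS
tends to select models as large as the search allows; CV counters this with
CVC and parsimony, 3WS has no analogous brake. `mdr_prune()` therefore
refits the selected loci with logistic regression on the **entire**
dataset, using per-locus genotype indicator variables (heterozygote and
minor homozygote; common homozygote as reference) and all interaction
terms: every non-empty subset of the loci contributes $2^{|S|}$ product
columns, so no inheritance mode is imposed. Backward selection then removes
whole terms:

* `criterion = "p"`: repeatedly drop the term with the largest
  likelihood-ratio p-value while it exceeds `p_cut`;
* `criterion = "AIC"`/`"BIC"`: drop the removal that most decreases the
  criterion, stopping when none does.

The pruned model is the union of loci in the surviving terms and may be
empty ("no model survives"), which the power harness counts as incorrect.
Removal is term-wise by default to preserve the indicator-group semantics
(`column_wise = TRUE` treats single columns as units). Ties in the removal
order go to the larger term, then lexicographic. Sparse $3^k$ designs can
separate perfectly; fits that fail outright fall back to a
ridge-stabilized IRLS likelihood (penalty $10^{-3}$ on slopes), and a term
whose removal test is still undefined is treated as removable — this
guarantees termination. No hierarchy constraint is enforced: an interaction
may outlive its main effects, since only the loci involved matter.

## The simulator and what it does (not) emulate

`simulate_mdr_data()` draws each locus independently under Hardy–Weinberg
equilibrium and assigns disease status by a Bernoulli draw from the
penetrance of the individual's disease-locus genotype, rejecting until the
case and control quotas are filled — a prospective scheme equivalent in
distribution to retrospective genotype-given-status sampling but easier to
verify. Defaults mirror a balanced candidate-gene study: 500 cases, 500
controls, 25 loci, nuisance loci at the disease-locus MAF. The canonical
epistatic tables are built in: XOR (risk 0.1 when the minor-allele parity
is odd) and ZZ (0.1 at the opposite homozygotes, 0.05 at the double
heterozygote), both with no marginal effects at MAF 0.5 and heritability
rounding to 0.05. Prevalence is $K=\sum_g f_g p_g$ and heritability the
genotypic-variance ratio $h^2 = \sum_g f_g (p_g - K)^2 / K(1-K)$, both
checked against exhaustive enumeration.

`solve_penetrance()` builds single-locus dominant, recessive and additive
tables attaining a target $(h^2, \mathrm{OR})$ pair at a given MAF. The
effect size is parameterized as the genotype **relative risk** (penetrance
ratio; per-allele multiplicative for the additive mode): on a strict odds
scale, published $(h^2, \mathrm{OR})$ pairs such as a dominant model with
$h^2 = 0.05$ and OR 2.5 at MAF 0.5 are jointly unattainable (the odds-scale
maximum is $h^2 \approx 0.039$), so the risk-ratio scale is evidently what
such model grids mean by "OR". The solver root-finds the baseline
penetrance on the rising branch of the heritability curve and verifies the
solution by recomputing both quantities.

The simulator deliberately omits linkage disequilibrium, genotyping error,
missingness, covariates and quantitative traits. Power estimates obtained
with it therefore speak to the validation engines' behaviour under clean,
independent-locus signals — not to robustness against real-data artefacts.

## The power harness

`mdr_power()` simulates replicate datasets, analyses each with a configured
engine (optionally followed by pruning), and reports **conservative power**
(selected set equals the true loci exactly) and **liberal power** (selected
set contains them), each with binomial standard error
$\sqrt{\hat p(1-\hat p)/n}$ — at most $0.050$ for 100 replicates — plus the
mean selected-model size and the bias/variance of the prediction-accuracy
estimate. The bias reference is the analytic Bayes balanced accuracy of the
generating penetrance model (exact cell enumeration), used in place of a
simulated large holdout because it is the same quantity without Monte-Carlo
noise. Replicate seeds are derived deterministically from the master seed
and recorded per replicate, so any single replicate can be re-run exactly.
`mdr_permute()` wraps whole-pipeline permutation testing with
$p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(B+1)$.

## Problem sizes and numerical choices in the test suite

The acceptance-level checks run the full study conditions (100 replicates,
$1000 \times 25$ datasets, sizes $k = 1..3$). Property-style tests use
reduced scales chosen to keep the whole suite fast while leaving the tested
directions unambiguous: oracle comparisons at $K \le 6$, $n \le 60$;
tie/CVC distribution checks over 30 seeds; pruning behaviour over 15–25
simulated replicates; permutation calibration at $B = 19$ over 40 nulls;
and a 200,000-individual draw for the asymptotic cell-composition check.
All stochastic tests fix their seeds, so the suite is deterministic.

## Known limitations

* **Exact validation ties in 3WS.** If the testing-stage winner of size
  $k+1$ contains the size-$k$ winner, its refit on the validation set can
  only split cells; when no sub-cell label flips, the two validation
  accuracies tie *exactly*. Such ties are common (they occur in more than
  half of strong-epistasis replicates), so the conservative power of 3WS
  depends heavily on the tie convention. This package resolves ties by
  parsimony (smaller $k$, then lexicographic), which is deterministic and
  favourable to exact recovery; implementations that resolve ties by
  iteration order will report substantially lower conservative power with
  identical liberal power. The direction of all comparative conclusions
  (CV-5 conserves better before pruning; 3WS inflates model size; BIC
  pruning restores conservative power) is unaffected.
* Pruning is logistic-regression-based only, and its selected model need
  not be consistent with the MDR high/low-risk parameterization.
* Model sizes above $k = 4$ are permitted but untested at scale; searches
  are single-threaded.
* The reader accepts only complete 0/1/2 genotypes; handle missing data
  upstream.
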