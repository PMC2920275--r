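# mdrsplit

Multifactor Dimensionality Reduction (MDR) for detecting epistatic
(gene–gene) interactions in case–control genotype data, with two
interchangeable internal-validation engines — classical *m*-fold
cross-validation and a single **three-way split** (3WS) of the data — plus
post-hoc model pruning, a penetrance-based case–control simulator, and a
Monte-Carlo power harness for comparing the validation strategies.

## The method

For a combination of *k* biallelic loci (genotypes coded 0/1/2 minor-allele
counts), MDR tabulates cases and controls in each of the 3^*k* genotype
cells and labels a cell **high-risk** when its case:control ratio exceeds
the threshold *T* = *n*₁/*n*₀ (1.0 for balanced samples). This collapses the
*k*-dimensional genotype space to one binary attribute; the balanced
accuracy of that attribute as a classifier,

> BA = ½ (n₁₁/n₁ + n₀₀/n₀),

scores the combination, and an exhaustive search over all C(K, k)
combinations finds the best model per size. A final model across sizes is
chosen by internal validation:

* **Cross-validation (CV-*m*)** — per fold, the best model is refit on
  *m* − 1 intervals and scored on the held-out interval (prediction
  accuracy, PA). Per size, cross-validation consistency (CVC) counts how
  often the modal locus set wins across folds; the final model maximizes
  both mean PA and CVC, with ties resolved by parsimony.
* **Three-way split (3WS)** — one stratified split into training, testing
  and validation sets. Training ranks all combinations and carries the top
  *x* per size forward; testing re-parameterizes those and keeps the best
  per size; validation re-parameterizes the per-size winners, and the final
  model maximizes validation balanced accuracy. 3WS costs roughly one fifth
  of CV-5's exhaustive-search work.
* **Pruning** — the 3WS winner can be pruned by backward-selection logistic
  regression on genotype indicator variables with all interaction terms,
  under AIC, BIC or a p-value threshold.

The simulator draws genotypes under Hardy–Weinberg equilibrium and disease
status from a penetrance model (the canonical purely epistatic XOR and ZZ
two-locus tables are built in; single-locus dominant/recessive/additive
tables are solved numerically for a target heritability and effect ratio).
The power harness reports conservative power (the selected model equals the
true disease loci exactly) and liberal power (it contains them) over
replicate datasets.

## Worked example

```r
library(mdrsplit)

pm <- penetrance_xor()                  # two-locus epistasis, no main effects
round(heritability(pm), 4)              # 0.0526 — rounds to the nominal 0.05
prevalence(pm)                          # 0.05

d <- simulate_mdr_data(pm, n_cases = 500, n_controls = 500,
                       n_loci = 25, seed = 7)

mdr_cv(d, k = 1:3, m = 5, seed = 42)
#>       k model       loci        cvc mean_pa
#> 1     1 L17         <chr [1]>     2   0.51
#> 2     2 L1, L2      <chr [2]>     5   0.758
#> 3     3 L1, L2, L24 <chr [3]>     2   0.742
#> final model: L1, L2 (CVC 5/5, mean prediction accuracy 0.7580)

ws <- mdr_3ws(d, k = 1:3, x_top = 25, seed = 42)
#>       k model       loci      testing_ba validation_ba
#> 1     1 L17         <chr [1]>      0.572         0.512
#> 2     2 L1, L2      <chr [2]>      0.749         0.744
#> 3     3 L1, L2, L22 <chr [3]>      0.769         0.744
#> final model: L1, L2 (validation balanced accuracy 0.7440)

mdr_prune(d, ws$final$loci[[1]], criterion = "BIC")
#> Post-hoc pruning (BIC): L1, L2 -> L1, L2
```

Both engines recover the simulated interacting pair `L1, L2`. The CV run
reports a cross-validation consistency of 5/5 and a mean out-of-fold
balanced accuracy of 0.758 (the population-optimal accuracy for this model
is about 0.763); the 3WS run reaches the same model about five times
faster, and BIC pruning confirms both loci carry signal. Results are
tibble-friendly: `tidy()`, `glance()` and `autoplot()` methods are provided
for all fitted objects, and `mdr_power()` / `mdr_permute()` wrap the
replicate-level power study and permutation testing. A thin command-line
wrapper is installed as `exec/mdr` (subcommands `simulate`, `cv`, `3ws`,
`prune`, `power`, `permute`).

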