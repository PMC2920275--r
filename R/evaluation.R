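# Power-study harness: conservative/liberal power with standard errors,
# average selected-model size, prediction-error bias/variance against the
# analytic Bayes accuracy, and permutation testing of a final model.

#' Score a selected locus set against the truth
#'
#' *Conservative* correctness requires the selected set to equal the true
#' disease loci exactly (no false positives, no false negatives); *liberal*
#' correctness only requires all true loci to be contained in the selection,
#' false positives allowed. An empty selection is incorrect under both.
#'
#' @param selected Character (or integer) vector of selected loci; may be
#'   empty.
#' @param truth Vector of true disease loci.
#' @return A one-row tibble with logical columns `conservative` and
#'   `liberal`.
#' @examples
#' classify_selection(c("L1", "L2", "L3"), c("L1", "L2"))  # liberal only
#' @export
classify_selection <- function(selected, truth) {
  lib <- length(selected) > 0 && all(truth %in% selected)
  cons <- lib && length(setdiff(selected, truth)) == 0
  tibble::tibble(conservative = cons, liberal = lib)
}

#' Bayes balanced accuracy of a penetrance model
#'
#' The best achievable balanced accuracy of any classifier on the disease
#' loci under balanced case-control sampling: cell `g` is optimally labelled
#' high-risk when its expected case:control ratio
#' \eqn{p_g (1-K) / ((1-p_g) K)} exceeds 1. Sensitivity and specificity are
#' then exact sums over cells.
#'
#' @inheritParams prevalence
#' @return The Bayes balanced accuracy in `[0.5, 1]`.
#' @export
bayes_balanced_accuracy <- function(model) {
  K <- prevalence(model)
  if (K <= 0 || K >= 1) abort("degenerate prevalence")
  f <- cell_freqs(model)
  p <- model$table
  high <- p * (1 - K) > (1 - p) * K
  sens <- sum(f[high] * p[high]) / K
  spec <- sum(f[!high] * (1 - p[!high])) / (1 - K)
  (sens + spec) / 2
}

# Run one configured analysis (cv / 3ws / 2ws [+ pruning]) on a dataset;
# returns selected loci, the reported predictive accuracy, and fit counts.
run_method <- function(data, method, k, m, proportions, x_top, prune, p_cut,
                       seed, pheno_col = "Class") {
  res <- switch(method,
    cv = mdr_cv(data, k = k, m = m, seed = seed, pheno_col = pheno_col),
    `3ws` = mdr_3ws(data, k = k, x_top = x_top, proportions = proportions,
                    seed = seed, mode = "3ws", pheno_col = pheno_col),
    `2ws` = mdr_3ws(data, k = k, x_top = x_top, proportions = proportions,
                    seed = seed, mode = "2ws", pheno_col = pheno_col),
    abort(sprintf("unknown method '%s'", method))
  )
  selected <- res$final$loci[[1]]
  pred_ba <- if (method == "cv") res$final$mean_pa else res$final$ba
  if (!is.null(prune)) {
    pr <- mdr_prune(data, selected, criterion = prune, p_cut = p_cut,
                    pheno_col = pheno_col)
    selected <- pr$loci
  }
  list(selected = selected, pred_ba = pred_ba, n_fits = res$n_fits)
}

#' Monte-Carlo power study of an MDR internal-validation strategy
#'
#' Simulates `n_datasets` replicate case-control datasets from a penetrance
#' model, analyses each with the configured method (cross-validation,
#' three-way split or two-way split, optionally followed by pruning), and
#' aggregates conservative and liberal power with binomial standard errors
#' \eqn{\sqrt{\hat p (1-\hat p)/n}}, the mean selected-model size, and the
#' bias and variance of the prediction-accuracy estimate against the
#' analytic Bayes balanced accuracy of the generating model. Replicate seeds
#' are derived deterministically from `seed` and recorded per replicate.
#'
#' @param model A `penetrance_model` describing the true disease model.
#' @param method `"cv"`, `"3ws"` or `"2ws"`.
#' @param n_datasets Number of replicate datasets (default 100).
#' @param k Model sizes searched (default `1:3`).
#' @param m Folds for `method = "cv"`.
#' @param proportions Split weights for `"3ws"`/`"2ws"`.
#' @param x_top Top models carried forward per size (default: `n_loci`).
#' @param prune `NULL` (no pruning) or a [backward_select()] criterion
#'   (`"BIC"`, `"AIC"`, `"p"`).
#' @param p_cut Threshold when `prune = "p"`.
#' @inheritParams simulate_mdr_data
#' @param seed Master seed for the whole experiment.
#' @return An object of class `mdr_power`; `tidy()` gives per-replicate
#'   rows, `glance()` the power summary.
#' @examples
#' pm <- penetrance_xor()
#' pw <- mdr_power(pm, method = "3ws", n_datasets = 3, k = 1:2,
#'                 n_cases = 60, n_controls = 60, n_loci = 6, seed = 1)
#' glance(pw)
#' @export
mdr_power <- function(model, method = c("cv", "3ws", "2ws"), n_datasets = 100,
                      k = 1:3, m = 5, proportions = NULL, x_top = NULL,
                      prune = NULL, p_cut = 0.001,
                      n_cases = 500, n_controls = 500, n_loci = 25,
                      maf_nuisance = NULL, seed = NULL) {
  method <- match.arg(method)
  if (n_datasets < 1) abort("`n_datasets` must be at least 1")
  x_top <- x_top %||% n_loci
  seeds <- matrix(derive_seeds(seed, 2 * n_datasets), ncol = 2)
  bayes_ba <- bayes_balanced_accuracy(model)

  reps <- lapply(seq_len(n_datasets), function(i) {
    dat <- simulate_mdr_data(model, n_cases = n_cases,
                             n_controls = n_controls, n_loci = n_loci,
                             maf_nuisance = maf_nuisance,
                             seed = seeds[i, 1])
    truth <- attr(dat, "disease_loci")
    res <- run_method(dat, method, k, m, proportions, x_top, prune, p_cut,
                      seed = seeds[i, 2])
    cls <- classify_selection(res$selected, truth)
    tibble::tibble(
      replicate = i, sim_seed = seeds[i, 1], analysis_seed = seeds[i, 2],
      loci = list(res$selected), size = length(res$selected),
      conservative = cls$conservative, liberal = cls$liberal,
      pred_ba = res$pred_ba, n_fits = res$n_fits
    )
  })
  replicates <- dplyr::bind_rows(reps)

  se <- function(p) sqrt(p * (1 - p) / n_datasets)
  summary <- tibble::tibble(
    method = method, prune = prune %||% "none", n_datasets = n_datasets,
    conservative_power = mean(replicates$conservative),
    se_conservative = se(mean(replicates$conservative)),
    liberal_power = mean(replicates$liberal),
    se_liberal = se(mean(replicates$liberal)),
    mean_size = mean(replicates$size),
    se_size = stats::sd(replicates$size) / sqrt(n_datasets),
    mean_pred_ba = mean(replicates$pred_ba),
    bayes_ba = bayes_ba,
    pred_bias = mean(replicates$pred_ba) - bayes_ba,
    pred_var = stats::var(replicates$pred_ba),
    n_fits = sum(replicates$n_fits)
  )
  structure(list(replicates = replicates, summary = summary,
                 model = model, seed = seed),
            class = "mdr_power")
}

#' @export
print.mdr_power <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MDR power study: %s%s, %d replicates\n", s$method,
              if (s$prune != "none") paste0(" + pruning (", s$prune, ")") else "",
              s$n_datasets))
  cat(sprintf("conservative power %.2f (SE %.3f), liberal power %.2f (SE %.3f)\n",
              s$conservative_power, s$se_conservative,
              s$liberal_power, s$se_liberal))
  cat(sprintf("mean selected size %.2f (SE %.3f)\n", s$mean_size, s$se_size))
  invisible(x)
}

#' Per-replicate results of a power study
#'
#' @param x An `mdr_power` object.
#' @param ... Unused.
#' @return A tibble with one row per replicate dataset.
#' @export
tidy.mdr_power <- function(x, ...) x$replicates

#' Summary row of a power study
#'
#' @inheritParams tidy.mdr_power
#' @return A one-row tibble with powers, standard errors, mean model size and
#'   prediction-error bias/variance.
#' @export
glance.mdr_power <- function(x, ...) x$summary

#' Permutation test of a final MDR model
#'
#' Re-runs the configured analysis pipeline on `B` datasets with the
#' phenotype labels permuted over the whole sample, and compares the
#' observed final-model accuracy statistic (mean prediction accuracy for
#' cross-validation; validation balanced accuracy for 3WS) with the
#' permutation distribution. The empirical p-value is
#' \eqn{(1 + \#\{stat_{perm} \ge stat_{obs}\}) / (B + 1)}.
#'
#' @inheritParams mdr_fit
#' @inheritParams mdr_power
#' @param B Number of permutations (default 99).
#' @param seed Master seed (drives the permutations and the per-run split
#'   assignment).
#' @return An object of class `mdr_permute` with the observed statistic, the
#'   permuted statistics and `p_value`.
#' @export
mdr_permute <- function(data, method = c("cv", "3ws", "2ws"), B = 99,
                        k = 1:3, m = 5, proportions = NULL, x_top = NULL,
                        seed = NULL, pheno_col = "Class") {
  method <- match.arg(method)
  if (B < 1) abort("`B` must be at least 1")
  gd <- geno_matrix(data, pheno_col)
  x_top <- x_top %||% ncol(gd$G)
  seeds <- matrix(derive_seeds(seed, 2 * (B + 1)), ncol = 2)

  observed <- run_method(data, method, k, m, proportions, x_top,
                         prune = NULL, p_cut = NULL,
                         seed = seeds[1, 2], pheno_col = pheno_col)$pred_ba
  perm_stats <- vapply(seq_len(B), function(b) {
    perm_data <- data
    perm_data[[pheno_col]] <- with_seed_(seeds[b + 1, 1],
                                         sample(data[[pheno_col]]))
    run_method(perm_data, method, k, m, proportions, x_top,
               prune = NULL, p_cut = NULL,
               seed = seeds[b + 1, 2], pheno_col = pheno_col)$pred_ba
  }, 0)

  structure(
    list(observed = observed, perm_stats = perm_stats, B = B,
         p_value = (1 + sum(perm_stats >= observed)) / (B + 1),
         method = method),
    class = "mdr_permute"
  )
}

#' @export
print.mdr_permute <- function(x, ...) {
  cat(sprintf("Permutation test (%s, B = %d): observed %.4f, p = %.4g\n",
              x$method, x$B, x$observed, x$p_value))
  invisible(x)
}

#' Summary of a permutation test
#'
#' @param x An `mdr_permute` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, `B` and the
#'   empirical p-value.
#' @export
glance.mdr_permute <- function(x, ...) {
  tibble::tibble(observed = x$observed, B = x$B, p_value = x$p_value)
}
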