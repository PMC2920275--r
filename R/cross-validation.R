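# m-fold stratified cross-validation with cross-validation consistency (CVC)
# and the parsimony-based final selection.

#' Stratified cross-validation folds
#'
#' Randomly partitions the rows of `data` into `m` folds with representative
#' numbers of cases and controls in each: within each class the fold sizes
#' differ by at most one, and which folds receive the remainder individuals is
#' randomised. Deterministic given `seed`.
#'
#' @inheritParams mdr_fit
#' @param m Number of folds (default 5).
#' @param seed Integer seed for the fold assignment (NULL uses the ambient
#'   RNG stream).
#' @return A list of `m` integer vectors of row indices.
#' @export
stratified_folds <- function(data, m = 5, seed = NULL, pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col)
  if (m < 2) abort("`m` must be at least 2")
  if (gd$n1 < m || gd$n0 < m) {
    abort(sprintf("cannot stratify: need at least m = %d cases and controls (have %d/%d)",
                  m, gd$n1, gd$n0))
  }
  with_seed_(seed, {
    assign <- integer(length(gd$y))
    for (cls in c(1L, 0L)) {
      idx <- which(gd$y == cls)
      # shuffled fold labels balanced to within one individual per fold
      assign[idx] <- sample(rep(seq_len(m), length.out = length(idx)))
    }
    lapply(seq_len(m), function(f) which(assign == f))
  })
}

#' MDR with m-fold cross-validation
#'
#' For each fold, the best MDR model of every size in `k` is found by
#' exhaustive search on the remaining `m - 1` folds and its prediction
#' accuracy (balanced accuracy on the held-out fold, using the
#' training-derived cell labels and training threshold) is recorded. Per
#' size, cross-validation consistency (CVC) is the number of folds in which
#' the modal locus combination was the fold winner, and its mean prediction
#' accuracy is averaged over those folds. The final model maximizes both
#' mean prediction accuracy and CVC; when the two maximizers differ the more
#' parsimonious (smaller) model is chosen.
#'
#' @inheritParams stratified_folds
#' @param k Integer vector of model sizes to consider (default `1:3`).
#' @return An object of class `mdr_cv`; see [tidy.mdr_cv()] and
#'   [glance.mdr_cv()].
#' @examples
#' pm <- penetrance_xor()
#' d <- simulate_mdr_data(pm, n_cases = 60, n_controls = 60, n_loci = 5, seed = 1)
#' fit <- mdr_cv(d, k = 1:2, m = 5, seed = 2)
#' glance(fit)
#' @export
mdr_cv <- function(data, k = 1:3, m = 5, seed = NULL, pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col)
  K <- ncol(gd$G)
  if (any(k < 1) || any(k > K)) abort("model sizes `k` must lie in [1, K]")
  folds <- stratified_folds(data, m = m, seed = seed, pheno_col = pheno_col)

  combos_by_k <- lapply(k, function(kk) combo_matrix(K, kk))
  fold_rows <- list()
  for (f in seq_len(m)) {
    test_idx <- folds[[f]]
    train <- subset_gd(gd, setdiff(seq_along(gd$y), test_idx))
    test <- subset_gd(gd, test_idx)
    for (j in seq_along(k)) {
      top <- rank_combos(train, combos_by_k[[j]], x = 1)
      idx <- matrix(top$loci_idx[[1]], nrow = 1)
      # refit labels on training counts, evaluate on the held-out fold
      tr <- scan_counts(train, idx)
      high <- labels_from_counts(tr$case, tr$control, train$n1, train$n0)
      te <- scan_counts(test, idx)
      pa <- ba_from_counts(te$case, te$control, high, test$n1, test$n0)
      fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
        k = k[j], fold = f, loci = top$loci, train_ba = top$ba, test_ba = pa
      )
    }
  }
  fold_results <- dplyr::bind_rows(fold_rows)

  k_summary <- dplyr::bind_rows(lapply(k, function(kk) {
    rows <- fold_results[fold_results$k == kk, ]
    keys <- vapply(rows$loci, paste, "", collapse = "\r")
    tab <- table(keys)
    cvc <- max(tab)
    modal_keys <- names(tab)[tab == cvc]
    cand <- lapply(modal_keys, function(key) {
      sel <- rows[keys == key, ]
      list(loci = sel$loci[[1]], mean_pa = mean(sel$test_ba))
    })
    # CVC ties: highest mean prediction accuracy, then lexicographic
    pas <- vapply(cand, `[[`, 0, "mean_pa")
    cand <- cand[pas == max(pas)]
    pick <- cand[[lex_which_min(lapply(cand, `[[`, "loci"))]]
    tibble::tibble(k = kk, loci = list(pick$loci), cvc = as.integer(cvc),
                   mean_pa = pick$mean_pa)
  }))

  final <- select_cv_final(k_summary)
  n_train_fits <- m * sum(vapply(combos_by_k, nrow, 0L))
  structure(
    list(folds = folds, fold_results = fold_results, k_summary = k_summary,
         final = final, m = m, k = k, seed = seed,
         n_fits = n_train_fits, n_eval = m * length(k)),
    class = "mdr_cv"
  )
}

# Restrict a geno_matrix object to a row subset.
subset_gd <- function(gd, idx) {
  y <- gd$y[idx]
  list(G = gd$G[idx, , drop = FALSE], y = y, loci = gd$loci,
       n1 = sum(y == 1L), n0 = sum(y == 0L))
}

#' Final-model selection for cross-validation results
#'
#' Applies the CVC/prediction-accuracy/parsimony rule to a per-size summary
#' table: if one candidate maximizes both mean prediction accuracy and CVC it
#' is selected; otherwise the more parsimonious (smaller `k`) of the two
#' maximizers is chosen. Residual ties go to the smallest `k`, then the
#' lexicographically smallest locus tuple.
#'
#' @param k_summary A tibble with columns `k`, `loci` (list), `cvc`,
#'   `mean_pa`, one row per model size (as in an `mdr_cv` object).
#' @return A one-row tibble: the selected `k`, `loci`, `cvc`, `mean_pa`.
#' @export
select_cv_final <- function(k_summary) {
  if (nrow(k_summary) == 0) abort("empty cross-validation summary")
  pick_one <- function(rows) {
    rows <- rows[rows$k == min(rows$k), ]
    rows[lex_which_min(rows$loci), ]
  }
  best_pa <- which(k_summary$mean_pa == max(k_summary$mean_pa))
  best_cvc <- which(k_summary$cvc == max(k_summary$cvc))
  both <- intersect(best_pa, best_cvc)
  if (length(both) > 0) return(pick_one(k_summary[both, ]))
  a <- pick_one(k_summary[best_pa, ])
  b <- pick_one(k_summary[best_cvc, ])
  pick_one(dplyr::bind_rows(a, b))
}

#' @export
print.mdr_cv <- function(x, ...) {
  cat(sprintf("MDR with %d-fold cross-validation (k = %s)\n",
              x$m, paste(x$k, collapse = ",")))
  print(tidy(x))
  f <- x$final
  cat(sprintf("final model: %s (CVC %d/%d, mean prediction accuracy %.4f)\n",
              paste(f$loci[[1]], collapse = ", "), f$cvc, x$m, f$mean_pa))
  invisible(x)
}

#' Per-size cross-validation summary
#'
#' @param x An `mdr_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per model size: modal combination, CVC and
#'   mean prediction accuracy.
#' @export
tidy.mdr_cv <- function(x, ...) {
  out <- x$k_summary
  out$model <- vapply(out$loci, paste, "", collapse = ", ")
  out[c("k", "model", "loci", "cvc", "mean_pa")]
}

#' One-row summary of a cross-validation run
#'
#' @inheritParams tidy.mdr_cv
#' @return A tibble with the final model, its CVC and mean prediction
#'   accuracy, and the number of exhaustive-search fits performed.
#' @export
glance.mdr_cv <- function(x, ...) {
  f <- x$final
  tibble::tibble(
    model = paste(f$loci[[1]], collapse = ", "),
    k = f$k, cvc = f$cvc, mean_pa = f$mean_pa,
    m = x$m, n_fits = x$n_fits
  )
}
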