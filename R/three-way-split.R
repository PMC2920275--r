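# Three-way split (3WS) internal validation: stratified
# training/testing/validation split, exhaustive search in training, top-x
# carry-forward to testing, per-stage refitting, validation-BA final
# selection; plus the two-way split (2WS) variant.

# Largest-remainder apportionment of n units over positive weights.
apportion <- function(n, weights) {
  if (any(weights < 0) || sum(weights > 0) < 1) abort("invalid split proportions")
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(q - base), seq_along(q))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified three-way (or two-way) split
#'
#' Randomly partitions the rows of `data` into disjoint subsets with sizes
#' proportional to `proportions`, stratified so each subset has
#' representative numbers of cases and controls. Subset sizes within each
#' class stratum follow largest-remainder rounding (cases apportioned first,
#' then controls), so e.g. 500 cases at proportions 1:1:1 give 167/167/166.
#'
#' @inheritParams stratified_folds
#' @param proportions Positive weights for the subsets, e.g. `c(1, 1, 1)` or
#'   `c(2, 2, 1)` for training:testing:validation; a length-2 vector gives a
#'   two-way split.
#' @return A named list of row-index vectors (`training`, `testing`, and for
#'   three-way splits `validation`).
#' @export
split_stratified <- function(data, proportions = c(1, 1, 1), seed = NULL,
                             pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col)
  s <- length(proportions)
  if (!s %in% c(2L, 3L)) abort("`proportions` must have length 2 or 3")
  with_seed_(seed, {
    parts <- rep(list(integer(0)), s)
    for (cls in c(1L, 0L)) {
      idx <- sample(which(gd$y == cls))
      sizes <- apportion(length(idx), proportions)
      if (any(sizes < 1)) {
        abort("each subset must receive at least one case and one control; adjust `proportions`")
      }
      stops <- cumsum(sizes)
      starts <- c(1L, head(stops, -1) + 1L)
      for (i in seq_len(s)) {
        parts[[i]] <- c(parts[[i]], idx[starts[i]:stops[i]])
      }
    }
    parts <- lapply(parts, sort)
    names(parts) <- if (s == 3) c("training", "testing", "validation")
                    else c("training", "testing")
    parts
  })
}

#' MDR with a three-way split
#'
#' Implements the 3WS internal-validation scheme: the data are split once
#' into training, testing and validation subsets. For each model size in
#' `k`, all \eqn{C(K,k)} combinations are ranked by balanced accuracy in the
#' training set and the top `x_top` are carried forward; in the testing set
#' the MDR parameterization of each carried model is determined afresh and
#' the best per size is retained; in the validation set each per-size winner
#' is parameterized again and its validation balanced accuracy recorded. The
#' final model maximizes validation balanced accuracy across sizes (ties:
#' smaller size, then lexicographic); that accuracy is the predictive-ability
#' estimate. With `mode = "2ws"` there is no validation subset and the final
#' model maximizes the testing-stage balanced accuracy.
#'
#' By default each stage refits the high/low-risk cell labels (and the
#' threshold \eqn{n_1/n_0}) on its own subset; `refit = FALSE` instead
#' carries the previous stage's labels forward and scores prediction
#' accuracy, as a sensitivity analysis.
#'
#' @inheritParams mdr_cv
#' @param x_top Number of top-ranked training models carried to the testing
#'   stage per size (default: the number of loci, `K`).
#' @param proportions Split weights; default `c(1, 1, 1)` (`c(1, 1)` for
#'   `mode = "2ws"`).
#' @param mode `"3ws"` (default) or `"2ws"`.
#' @param refit Refit cell labels at each stage (default `TRUE`).
#' @return An object of class `mdr_3ws`; see [tidy.mdr_3ws()] and
#'   [glance.mdr_3ws()].
#' @examples
#' pm <- penetrance_xor()
#' d <- simulate_mdr_data(pm, n_cases = 90, n_controls = 90, n_loci = 5, seed = 1)
#' fit <- mdr_3ws(d, k = 1:2, seed = 2)
#' glance(fit)
#' @export
mdr_3ws <- function(data, k = 1:3, x_top = NULL, proportions = NULL,
                    seed = NULL, mode = c("3ws", "2ws"), refit = TRUE,
                    pheno_col = "Class") {
  mode <- match.arg(mode)
  gd <- geno_matrix(data, pheno_col)
  K <- ncol(gd$G)
  if (any(k < 1) || any(k > K)) abort("model sizes `k` must lie in [1, K]")
  x_top <- x_top %||% K
  if (x_top < 1) abort("`x_top` must be at least 1")
  proportions <- proportions %||% if (mode == "3ws") c(1, 1, 1) else c(1, 1)
  if (mode == "2ws" && length(proportions) != 2) {
    abort("`mode = \"2ws\"` requires length-2 proportions")
  }
  if (mode == "3ws" && length(proportions) != 3) {
    abort("`mode = \"3ws\"` requires length-3 proportions")
  }

  split <- split_stratified(data, proportions, seed = seed,
                            pheno_col = pheno_col)
  train <- subset_gd(gd, split$training)
  test <- subset_gd(gd, split$testing)

  training_rows <- list()
  testing_rows <- list()
  n_train_fits <- 0L
  n_test_fits <- 0L
  for (kk in k) {
    combos <- combo_matrix(K, kk)
    n_train_fits <- n_train_fits + nrow(combos)
    top <- rank_combos(train, combos, x = x_top)
    top$rank <- seq_len(nrow(top))
    training_rows[[length(training_rows) + 1]] <-
      tibble::tibble(k = kk, rank = top$rank, loci = top$loci, ba = top$ba)

    retained <- do.call(rbind, top$loci_idx)
    retained <- lex_sort_rows(retained)
    n_test_fits <- n_test_fits + nrow(retained)
    stage2 <- stage_scores(train, test, retained, refit)
    best <- order(-stage2$ba, seq_along(stage2$ba))[1]
    testing_rows[[length(testing_rows) + 1]] <-
      tibble::tibble(k = kk, loci = stage2$loci[best],
                     loci_idx = stage2$loci_idx[best], ba = stage2$ba[best])
  }
  training <- dplyr::bind_rows(training_rows)
  testing <- dplyr::bind_rows(testing_rows)

  if (mode == "3ws") {
    valid <- subset_gd(gd, split$validation)
    validation <- dplyr::bind_rows(lapply(seq_len(nrow(testing)), function(i) {
      sc <- stage_scores(test, valid,
                         matrix(testing$loci_idx[[i]], nrow = 1), refit)
      tibble::tibble(k = testing$k[i], loci = sc$loci, ba = sc$ba)
    }))
    final <- select_3ws_final(validation)
    n_valid_fits <- nrow(validation)
  } else {
    validation <- NULL
    final <- select_3ws_final(testing[c("k", "loci", "ba")])
    n_valid_fits <- 0L
  }

  structure(
    list(split = split, training = training, testing = testing[c("k", "loci", "ba")],
         validation = validation, final = final,
         mode = mode, k = k, x_top = x_top, proportions = proportions,
         seed = seed, refit = refit,
         n_fits = n_train_fits, n_carry = n_test_fits, n_valid = n_valid_fits),
    class = "mdr_3ws"
  )
}

# Score a fixed set of combinations on `eval_gd`. With refit = TRUE the MDR
# parameterization (labels, threshold) is determined on eval_gd itself
# (fitting BA); otherwise labels come from `fit_gd` and the score is
# prediction BA on eval_gd.
stage_scores <- function(fit_gd, eval_gd, combos, refit) {
  ev <- scan_counts(eval_gd, combos)
  if (refit) {
    high <- labels_from_counts(ev$case, ev$control, eval_gd$n1, eval_gd$n0)
  } else {
    fc <- scan_counts(fit_gd, combos)
    high <- labels_from_counts(fc$case, fc$control, fit_gd$n1, fit_gd$n0)
  }
  list(
    loci = lapply(seq_len(nrow(combos)), function(i) eval_gd$loci[combos[i, ]]),
    loci_idx = lapply(seq_len(nrow(combos)), function(i) combos[i, ]),
    ba = ba_from_counts(ev$case, ev$control, high, eval_gd$n1, eval_gd$n0)
  )
}

#' Final-model selection for a three-way split
#'
#' Selects the row maximizing balanced accuracy from a per-size validation
#' (or testing, for 2WS) table; ties go to the smaller size, then the
#' lexicographically smallest locus tuple. The winning balanced accuracy is
#' the predictive-ability estimate of the final model.
#'
#' @param stage_results A tibble with columns `k`, `loci` (list) and `ba`,
#'   one row per model size.
#' @return A one-row tibble with the selected `k`, `loci` and `ba`.
#' @export
select_3ws_final <- function(stage_results) {
  if (is.null(stage_results) || nrow(stage_results) == 0) {
    abort("no stage results to select from")
  }
  rows <- stage_results[stage_results$ba == max(stage_results$ba), ]
  rows <- rows[rows$k == min(rows$k), ]
  rows[lex_which_min(rows$loci), c("k", "loci", "ba")]
}

#' @export
print.mdr_3ws <- function(x, ...) {
  lab <- if (x$mode == "3ws") "three-way split" else "two-way split"
  cat(sprintf("MDR with %s (proportions %s, x = %d, k = %s)\n", lab,
              paste(x$proportions, collapse = ":"), x$x_top,
              paste(x$k, collapse = ",")))
  print(tidy(x))
  f <- x$final
  stage <- if (x$mode == "3ws") "validation" else "testing"
  cat(sprintf("final model: %s (%s balanced accuracy %.4f)\n",
              paste(f$loci[[1]], collapse = ", "), stage, f$ba))
  invisible(x)
}

#' Stage-by-stage summary of a three-way-split run
#'
#' @param x An `mdr_3ws` object.
#' @param ... Unused.
#' @return A tibble with one row per size and stage (testing winner and, for
#'   3WS, its validation balanced accuracy).
#' @export
tidy.mdr_3ws <- function(x, ...) {
  out <- x$testing
  out$model <- vapply(out$loci, paste, "", collapse = ", ")
  out <- dplyr::rename(out, testing_ba = "ba")
  if (!is.null(x$validation)) out$validation_ba <- x$validation$ba
  out[c("k", "model", "loci", "testing_ba",
        if (!is.null(x$validation)) "validation_ba")]
}

#' One-row summary of a three-way-split run
#'
#' @inheritParams tidy.mdr_3ws
#' @return A tibble with the final model, its predictive-ability estimate and
#'   the training/testing/validation fit counts.
#' @export
glance.mdr_3ws <- function(x, ...) {
  f <- x$final
  tibble::tibble(
    model = paste(f$loci[[1]], collapse = ", "),
    k = f$k, ba = f$ba, mode = x$mode,
    n_fits = x$n_fits, n_carry = x$n_carry, n_valid = x$n_valid
  )
}
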