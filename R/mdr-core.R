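# MDR core: genotype-cell tabulation, high/low-risk labelling, balanced
# accuracy, and exhaustive/bounded search over locus combinations.

#' Base-3 cell index of multi-locus genotype combinations
#'
#' MDR classifies individuals into the \eqn{3^k} genotype cells spanned by a
#' combination of `k` biallelic loci. Cells are indexed by a bijective base-3
#' encoding of the minor-allele counts with the first locus most significant,
#' so `(2, 1)` maps to `2 * 3 + 1 = 7`.
#'
#' @param genotypes An integer vector of `k` genotype codes in `{0, 1, 2}`, or
#'   an `n x k` matrix of such codes (one row per individual).
#' @return A zero-based integer cell index in `[0, 3^k)`, vectorised over rows.
#' @examples
#' mdr_cell_index(c(2, 1))       # 7
#' mdr_cell_index(c(1, 1, 1))    # 13
#' @export
mdr_cell_index <- function(genotypes) {
  if (is.vector(genotypes)) genotypes <- matrix(genotypes, nrow = 1)
  if (anyNA(genotypes) || !all(genotypes %in% c(0L, 1L, 2L))) {
    abort("genotype codes must all be 0, 1 or 2")
  }
  k <- ncol(genotypes)
  if (k < 1) abort("at least one locus is required")
  pw <- 3L^((k - 1L):0L)
  as.integer(as.matrix(genotypes) %*% pw)
}

#' Decode a base-3 cell index back to genotype codes
#'
#' Inverse of [mdr_cell_index()].
#'
#' @param index Zero-based cell index (vectorised).
#' @param k Number of loci in the combination.
#' @return An integer matrix with `k` columns of genotype codes.
#' @export
mdr_cell_genotypes <- function(index, k) {
  if (any(index < 0 | index >= 3^k)) abort("cell index out of range")
  out <- matrix(0L, nrow = length(index), ncol = k)
  rem <- as.integer(index)
  for (j in seq_len(k)) {
    pw <- as.integer(3^(k - j))
    out[, j] <- as.integer(rem %/% pw)
    rem <- rem %% pw
  }
  out
}

# High/low-risk labels from per-cell counts. Integer arithmetic realizes the
# threshold conventions exactly: a cell is high-risk iff
# cases/controls > n1/n0, i.e. cases * n0 > controls * n1; equality at the
# threshold, and empty (0/0) cells, are low-risk; cases > 0 with 0 controls
# is an infinite ratio, hence high-risk. Works elementwise on matrices.
labels_from_counts <- function(case_counts, control_counts, n1, n0) {
  case_counts * as.numeric(n0) > control_counts * as.numeric(n1)
}

# Balanced accuracy per combination from count matrices (rows = combos,
# cols = cells) and a logical high-risk matrix of the same shape.
ba_from_counts <- function(case_counts, control_counts, high, n1, n0) {
  n11 <- rowSums(case_counts * high)
  n00 <- rowSums(control_counts * !high)
  0.5 * (n11 / n1 + n00 / n0)
}

# Scan a set of combinations (C x k index matrix) on one dataset; returns
# list(case, control) count matrices each C x 3^k.
scan_counts <- function(gd, combos) {
  counts <- cell_counts_scan(gd$G, gd$y, combos)
  M <- 3L^ncol(combos)
  list(case = counts[, seq_len(M), drop = FALSE],
       control = counts[, M + seq_len(M), drop = FALSE])
}

#' Fit the MDR high/low-risk model for one locus combination
#'
#' Tabulates cases and controls in each of the \eqn{3^k} genotype cells of the
#' combination and labels a cell *high-risk* when its case:control ratio
#' exceeds the threshold \eqn{T = n_1/n_0} computed from the fitting data
#' (1.0 for balanced data). Cells whose ratio equals the threshold, and empty
#' cells, are labelled low-risk; cells with cases but no controls are
#' high-risk.
#'
#' @param data Data frame of genotype columns plus a binary phenotype column.
#' @param loci Locus names (or column indices) of the combination.
#' @param pheno_col Name of the phenotype column (1 = case, 0 = control).
#' @return An object of class `mdr_model` with the cell counts, the high/low
#'   labels and the threshold.
#' @examples
#' d <- tibble::tibble(A = c(0, 0, 1, 1), B = c(0, 1, 0, 1),
#'                     Class = c(1, 1, 0, 0))
#' mdr_fit(d, c("A", "B"))
#' @export
mdr_fit <- function(data, loci, pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col)
  idx <- resolve_loci(gd, loci)
  cc <- scan_counts(gd, matrix(idx, nrow = 1))
  high <- labels_from_counts(cc$case, cc$control, gd$n1, gd$n0)
  new_mdr_model(
    loci = gd$loci[idx],
    labels = as.vector(high),
    case_counts = as.vector(cc$case),
    control_counts = as.vector(cc$control),
    n1 = gd$n1, n0 = gd$n0
  )
}

# Low-level constructor (also used by tests to build models directly).
new_mdr_model <- function(loci, labels, case_counts, control_counts, n1, n0) {
  k <- length(loci)
  stopifnot(length(labels) == 3^k)
  structure(
    list(loci = loci, k = k, labels = labels,
         case_counts = case_counts, control_counts = control_counts,
         n1 = n1, n0 = n0, threshold = n1 / n0),
    class = "mdr_model"
  )
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("MDR model: %s (k = %d)\n", paste(x$loci, collapse = ", "), x$k))
  cat(sprintf("threshold n1/n0 = %.4g; %d of %d cells high-risk\n",
              x$threshold, sum(x$labels), length(x$labels)))
  invisible(x)
}

#' Per-cell summary of an MDR model
#'
#' @param x An `mdr_model`.
#' @param ... Unused.
#' @return A tibble with one row per genotype cell: the genotype codes, case
#'   and control counts from the fitting data, and the high/low-risk label.
#' @export
tidy.mdr_model <- function(x, ...) {
  g <- mdr_cell_genotypes(seq_along(x$labels) - 1L, x$k)
  colnames(g) <- x$loci
  dplyr::bind_cols(
    tibble::as_tibble(g),
    tibble::tibble(cases = x$case_counts, controls = x$control_counts,
                   risk = ifelse(x$labels, "high", "low"))
  )
}

#' Balanced accuracy of an MDR model on a dataset
#'
#' Classifies each individual as a case when their genotype cell is labelled
#' high-risk and computes the balanced accuracy
#' \eqn{BA = (n_{11}/n_1 + n_{00}/n_0)/2}, the arithmetic mean of sensitivity
#' and specificity, together with the balanced error \eqn{BE = 1 - BA}. For
#' balanced data (equal cases and controls) BA equals classification accuracy.
#' Cells unseen at fitting time carry the low-risk label.
#'
#' @param model An `mdr_model` from [mdr_fit()].
#' @param data Evaluation data (may differ from the fitting data).
#' @inheritParams mdr_fit
#' @return A one-row tibble with `n1`, `n0`, `n11`, `n00`,
#'   `balanced_accuracy` and `balanced_error`.
#' @export
mdr_accuracy <- function(model, data, pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col)
  idx <- resolve_loci(gd, model$loci)
  cc <- scan_counts(gd, matrix(idx, nrow = 1))
  high <- matrix(model$labels, nrow = 1)
  ba <- ba_from_counts(cc$case, cc$control, high, gd$n1, gd$n0)
  tibble::tibble(
    n1 = gd$n1, n0 = gd$n0,
    n11 = sum(cc$case[high]), n00 = sum(cc$control[!high]),
    balanced_accuracy = ba, balanced_error = 1 - ba
  )
}

#' Predict case/control status from an MDR model
#'
#' @param object An `mdr_model`.
#' @param new_data Data frame containing the model's locus columns.
#' @param ... Unused.
#' @return An integer vector: 1 where the individual's genotype cell is
#'   high-risk, 0 otherwise.
#' @export
predict.mdr_model <- function(object, new_data, ...) {
  g <- as.matrix(new_data[object$loci])
  idx <- mdr_cell_index(g)
  as.integer(object$labels[idx + 1L])
}

# Shared engine: rank combinations by fitting balanced accuracy on `gd`.
# `combos` is a C x k index matrix (rows lexicographically sorted by the
# caller); returns a tibble of the top `x` rows with ties broken in favour of
# the lexicographically smallest locus tuple (ranking is stable because
# combos arrive lexicographically ordered).
rank_combos <- function(gd, combos, x = Inf) {
  cc <- scan_counts(gd, combos)
  high <- labels_from_counts(cc$case, cc$control, gd$n1, gd$n0)
  ba <- ba_from_counts(cc$case, cc$control, high, gd$n1, gd$n0)
  ord <- order(-ba, seq_along(ba))
  keep <- ord[seq_len(min(x, length(ba)))]
  tibble::tibble(
    loci = lapply(keep, function(i) gd$loci[combos[i, ]]),
    loci_idx = lapply(keep, function(i) combos[i, ]),
    ba = ba[keep]
  )
}

# Normalise a user-supplied candidate list to a lexicographically sorted
# index matrix with strictly increasing rows.
candidate_matrix <- function(gd, candidates, k) {
  m <- do.call(rbind, lapply(candidates, function(cb) sort(resolve_loci(gd, cb))))
  if (ncol(m) != k) abort("all candidate combinations must have size k")
  lex_sort_rows(m)
}

#' Rank locus combinations of size k by balanced accuracy
#'
#' Evaluates the MDR high/low-risk parameterization for each candidate
#' combination of `x_top` loci combinations of size `k` (all \eqn{C(K,k)}
#' combinations unless `candidates` is given) and returns the top `x_top` by
#' fitting balanced accuracy, in descending order. Ties are broken in favour
#' of the lexicographically smallest locus tuple, so the ranking is
#' deterministic.
#'
#' @inheritParams mdr_fit
#' @param k Combination size (number of interacting loci considered).
#' @param x_top Number of top-ranked models to keep (default: all).
#' @param candidates Optional list of locus-name (or index) vectors to
#'   restrict the search.
#' @return A tibble with list-column `loci`, and `ba`, ordered by decreasing
#'   balanced accuracy.
#' @export
mdr_search <- function(data, k, x_top = Inf, candidates = NULL,
                       pheno_col = "Class") {
  if (!is.infinite(x_top) && x_top < 1) abort("`x_top` must be at least 1")
  gd <- geno_matrix(data, pheno_col)
  combos <- if (is.null(candidates)) {
    combo_matrix(ncol(gd$G), k)
  } else {
    candidate_matrix(gd, candidates, k)
  }
  res <- rank_combos(gd, combos, x_top)
  res$rank <- seq_len(nrow(res))
  res[c("rank", "loci", "ba")]
}

#' Best MDR model of size k
#'
#' Exhaustively searches all \eqn{C(K,k)} combinations (or the supplied
#' candidates) and returns the fitted MDR model maximizing balanced accuracy
#' on `data`, ties broken lexicographically.
#'
#' @inheritParams mdr_search
#' @return An `mdr_model`; its fitting balanced accuracy is available via
#'   `mdr_accuracy(model, data)`.
#' @export
mdr_best <- function(data, k, candidates = NULL, pheno_col = "Class") {
  top <- mdr_search(data, k, x_top = 1, candidates = candidates,
                    pheno_col = pheno_col)
  mdr_fit(data, top$loci[[1]], pheno_col = pheno_col)
}
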