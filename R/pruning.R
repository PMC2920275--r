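# Post-hoc pruning of a selected locus set via backward-selection logistic
# regression on genotype indicator variables with all interactions.

#' Full genotype-indicator design for a locus set
#'
#' Builds the saturated logistic-regression design used for pruning: each
#' locus contributes two indicator columns (heterozygote and minor-allele
#' homozygote; the common homozygote is the reference), and every non-empty
#' subset of the loci up to `max_order` forms a term whose columns are all
#' products of one indicator per member locus (a size-`s` term has `2^s`
#' columns). No assumption about the mode of inheritance is imposed.
#'
#' @inheritParams mdr_fit
#' @param loci Locus names (or indices) of the model to prune.
#' @param max_order Highest interaction order included (default: all loci).
#' @return A list with `terms` (named list of locus-name vectors), `X` (the
#'   column-bound indicator matrix), `term_cols` (map from term name to
#'   column indices of `X`) and `y` (the phenotype).
#' @export
mdr_design <- function(data, loci, max_order = NULL, pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col)
  idx <- resolve_loci(gd, loci)
  loci <- gd$loci[idx]
  d <- length(loci)
  max_order <- max_order %||% d
  if (max_order < 1) abort("`max_order` must be at least 1")

  # per-locus indicator pairs
  ind <- lapply(idx, function(j) {
    g <- gd$G[, j]
    cbind(het = as.numeric(g == 1L), hom = as.numeric(g == 2L))
  })
  names(ind) <- loci

  terms <- list()
  for (s in seq_len(min(max_order, d))) {
    subs <- combn(d, s)
    for (col in seq_len(ncol(subs))) {
      members <- loci[subs[, col]]
      terms[[paste(members, collapse = ":")]] <- members
    }
  }

  cols <- list()
  term_cols <- list()
  nxt <- 1L
  for (tn in names(terms)) {
    members <- terms[[tn]]
    # all 2^s products of one indicator column per member locus
    grid <- expand.grid(rep(list(c("het", "hom")), length(members)),
                        stringsAsFactors = FALSE)
    block <- vapply(seq_len(nrow(grid)), function(r) {
      prod_col <- rep(1, length(gd$y))
      for (i in seq_along(members)) {
        prod_col <- prod_col * ind[[members[i]]][, grid[r, i]]
      }
      prod_col
    }, numeric(length(gd$y)))
    colnames(block) <- vapply(seq_len(nrow(grid)), function(r) {
      paste(paste0(members, ".", unlist(grid[r, ])), collapse = ":")
    }, "")
    cols[[tn]] <- block
    term_cols[[tn]] <- seq.int(nxt, length.out = ncol(block))
    nxt <- nxt + ncol(block)
  }
  X <- do.call(cbind, cols)
  list(terms = terms, X = X, term_cols = term_cols, y = gd$y)
}

# Logistic fit returning deviance and effective rank; falls back to a
# ridge-stabilized IRLS fit when glm fails outright (e.g. pathological
# designs), so backward selection always terminates.
fit_logistic <- function(X, y) {
  res <- tryCatch({
    fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                                    family = binomial(),
                                    control = list(maxit = 100)))
    list(deviance = fit$deviance, rank = fit$rank, ok = TRUE)
  }, error = function(e) NULL)
  if (!is.null(res) && is.finite(res$deviance)) return(res)
  ridge_logistic(X, y)
}

# Penalized IRLS with a small L2 penalty; returns the penalized deviance and
# full column rank so likelihood-ratio comparisons remain defined.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 50) {
  Xf <- cbind(1, X)
  p <- ncol(Xf)
  beta <- rep(0, p)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(Xf %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xf, Xf * w) + pen
    beta_new <- tryCatch(solve(H, crossprod(Xf, w * z)),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(Xf %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(deviance = dev, rank = p, ok = FALSE)
}

#' Backward selection over genotype-indicator terms
#'
#' Starting from the full design of [mdr_design()], whole terms (groups of
#' indicator product columns) are removed one at a time. Under
#' `criterion = "p"` the term with the largest likelihood-ratio p-value is
#' dropped while that p-value exceeds `p_cut`; under `"AIC"`/`"BIC"` the
#' single removal that most decreases the criterion is taken, stopping when
#' no removal decreases it. Ties are broken towards the larger term, then
#' lexicographically. Degenerate fits fall back to a ridge-stabilized
#' likelihood; a term whose removal test is still undefined is treated as
#' removable (p = 1). With `column_wise = TRUE` each indicator column is its
#' own removal unit instead of the term grouping.
#'
#' @param design A design from [mdr_design()].
#' @param criterion `"BIC"`, `"AIC"` or `"p"`.
#' @param p_cut Significance level retained terms must beat when
#'   `criterion = "p"` (e.g. 0.1, 0.05, 0.01, 0.001, 1e-4 ... 1e-7).
#' @param column_wise Treat single indicator columns as removal units.
#' @return A list with `terms` (surviving term names), `loci` (union of loci
#'   in surviving terms) and `path` (a tibble logging each removal).
#' @export
backward_select <- function(design, criterion = c("BIC", "AIC", "p"),
                            p_cut = 0.001, column_wise = FALSE) {
  criterion <- match.arg(criterion)
  if (criterion == "p" && (p_cut <= 0 || p_cut >= 1)) {
    abort("`p_cut` must lie strictly between 0 and 1")
  }
  y <- design$y
  n <- length(y)
  if (column_wise) {
    term_cols <- as.list(seq_len(ncol(design$X)))
    names(term_cols) <- colnames(design$X)
    term_loci <- lapply(names(term_cols), function(nm) {
      unique(vapply(strsplit(strsplit(nm, ":")[[1]], ".", fixed = TRUE),
                    `[[`, "", 1))
    })
    names(term_loci) <- names(term_cols)
  } else {
    term_cols <- design$term_cols
    term_loci <- design$terms
  }

  # deterministic candidate order: larger terms first, then lexicographic
  cand_order <- function(nms) {
    sizes <- vapply(term_loci[nms], length, 0L)
    nms[order(-sizes, nms)]
  }
  ic_pen <- function(rank) {
    switch(criterion, AIC = 2 * rank, BIC = log(n) * rank, 0)
  }

  alive <- names(term_cols)
  path <- list()
  repeat {
    if (length(alive) == 0) break
    cols_alive <- unlist(term_cols[alive], use.names = FALSE)
    full <- fit_logistic(design$X[, cols_alive, drop = FALSE], y)
    cand <- cand_order(alive)
    stat <- vapply(cand, function(tn) {
      rest <- setdiff(alive, tn)
      cols <- unlist(term_cols[rest], use.names = FALSE)
      red <- fit_logistic(design$X[, cols, drop = FALSE], y)
      if (criterion == "p") {
        dd <- red$deviance - full$deviance
        df <- full$rank - red$rank
        if (!is.finite(dd) || df < 1) return(1)  # undefined test: removable
        pchisq(max(dd, 0), df = df, lower.tail = FALSE)
      } else {
        red$deviance + ic_pen(red$rank)
      }
    }, 0)
    if (criterion == "p") {
      worst <- cand[which.max(stat)]
      if (stat[worst] <= p_cut) break
      path[[length(path) + 1]] <- tibble::tibble(
        dropped = worst, p_value = unname(stat[worst]), criterion = NA_real_)
    } else {
      full_crit <- full$deviance + ic_pen(full$rank)
      best <- cand[which.min(stat)]
      if (stat[best] >= full_crit) break
      path[[length(path) + 1]] <- tibble::tibble(
        dropped = best, p_value = NA_real_, criterion = unname(stat[best]))
    }
    alive <- setdiff(alive, if (criterion == "p") worst else best)
  }

  loci <- sort(unique(unlist(term_loci[alive])))
  list(terms = alive, loci = if (is.null(loci)) character(0) else loci,
       path = if (length(path)) dplyr::bind_rows(path)
              else tibble::tibble(dropped = character(0),
                                  p_value = numeric(0), criterion = numeric(0)))
}

#' Prune a selected MDR model with backward-selection logistic regression
#'
#' Fits the saturated genotype-indicator logistic regression for the given
#' loci on the entire dataset and prunes it by backward selection (see
#' [backward_select()]). The pruned model is the union of loci involved in
#' the surviving terms; it may be empty, meaning no model survives pruning.
#'
#' @inheritParams mdr_design
#' @inheritParams backward_select
#' @return An object of class `mdr_prune` with `loci` (surviving locus
#'   names, possibly empty), `input_loci`, `empty` flag and the removal
#'   `path`.
#' @examples
#' pm <- penetrance_xor()
#' d <- simulate_mdr_data(pm, n_cases = 200, n_controls = 200, n_loci = 4, seed = 1)
#' mdr_prune(d, c("L1", "L2", "L4"), criterion = "BIC")
#' @export
mdr_prune <- function(data, loci, criterion = c("BIC", "AIC", "p"),
                      p_cut = 0.001, max_order = NULL, column_wise = FALSE,
                      pheno_col = "Class") {
  criterion <- match.arg(criterion)
  design <- mdr_design(data, loci, max_order = max_order,
                       pheno_col = pheno_col)
  sel <- backward_select(design, criterion = criterion, p_cut = p_cut,
                         column_wise = column_wise)
  structure(
    list(loci = sel$loci, input_loci = names(design$terms)[
           vapply(design$terms, length, 0L) == 1],
         terms = sel$terms, empty = length(sel$loci) == 0,
         criterion = criterion,
         p_cut = if (criterion == "p") p_cut else NA_real_,
         path = sel$path),
    class = "mdr_prune"
  )
}

#' @export
print.mdr_prune <- function(x, ...) {
  crit <- if (x$criterion == "p") sprintf("p < %g", x$p_cut) else x$criterion
  cat(sprintf("Post-hoc pruning (%s): %s -> %s\n", crit,
              paste(x$input_loci, collapse = ", "),
              if (x$empty) "<no model survives>"
              else paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' Removal path of a pruning run
#'
#' @param x An `mdr_prune` object.
#' @param ... Unused.
#' @return A tibble with one row per removed term.
#' @export
tidy.mdr_prune <- function(x, ...) x$path

#' One-row summary of a pruning run
#'
#' @inheritParams tidy.mdr_prune
#' @return A tibble with the surviving loci, their count, and the criterion.
#' @export
glance.mdr_prune <- function(x, ...) {
  tibble::tibble(
    model = paste(x$loci, collapse = ", "),
    k = length(x$loci), empty = x$empty,
    criterion = x$criterion, p_cut = x$p_cut,
    n_removed = nrow(x$path)
  )
}
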