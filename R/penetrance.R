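# Penetrance-model algebra: canonical epistatic tables (XOR, ZZ), prevalence
# and heritability under Hardy-Weinberg equilibrium, and numeric solving of
# single-locus penetrance functions for a target heritability and odds ratio.

#' Construct a penetrance model
#'
#' A penetrance model maps each multi-locus genotype combination at `d`
#' disease loci to a disease probability. Genotypes are coded as
#' minor-allele counts; the table is ordered by the base-3 cell index of
#' [mdr_cell_index()] (first locus most significant, common homozygote
#' first).
#'
#' @param table Numeric vector of `3^d` penetrances in `[0, 1]` (or a 3x3
#'   matrix for `d = 2`, rows = first locus genotype 0/1/2).
#' @param maf Minor allele frequency per disease locus (recycled), each in
#'   `(0, 0.5]`.
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(table, maf) {
  if (is.matrix(table)) table <- as.vector(t(table))
  d <- round(log(length(table), 3))
  if (3^d != length(table) || d < 1) {
    abort("`table` must have length 3^d for d >= 1 disease loci")
  }
  if (any(table < 0 | table > 1)) abort("penetrances must lie in [0, 1]")
  maf <- rep_len(maf, d)
  if (any(maf <= 0 | maf > 0.5)) abort("minor allele frequencies must lie in (0, 0.5]")
  structure(list(d = d, maf = maf, table = as.numeric(table)),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("Penetrance model: %d disease locus/loci, MAF %s\n",
              x$d, paste(format(x$maf), collapse = ", ")))
  cat(sprintf("prevalence %.4g, heritability %.4g\n",
              prevalence(x), heritability(x)))
  invisible(x)
}

#' The XOR two-locus epistatic penetrance function
#'
#' A canonical purely epistatic model with no marginal effects at either
#' locus: disease risk is 0.1 whenever the total minor-allele parity is odd
#' (genotypes AABb, AaBB, Aabb, aaBb) and 0 otherwise.
#'
#' @param maf Minor allele frequency at both loci (default 0.5).
#' @return A `penetrance_model` with `d = 2`.
#' @export
penetrance_xor <- function(maf = 0.5) {
  g <- expand.grid(g2 = 0:2, g1 = 0:2)  # g1 slowest = first locus
  p <- ifelse((g$g1 + g$g2) %% 2 == 1, 0.1, 0)
  penetrance_model(p, maf)
}

#' The ZZ two-locus epistatic penetrance function
#'
#' A canonical purely epistatic model: risk 0.1 for the opposite-homozygote
#' genotypes AAbb and aaBB, 0.05 for the double heterozygote AaBb, and 0
#' elsewhere.
#'
#' @inheritParams penetrance_xor
#' @return A `penetrance_model` with `d = 2`.
#' @export
penetrance_zz <- function(maf = 0.5) {
  p <- numeric(9)
  p[mdr_cell_index(c(0, 2)) + 1] <- 0.1
  p[mdr_cell_index(c(2, 0)) + 1] <- 0.1
  p[mdr_cell_index(c(1, 1)) + 1] <- 0.05
  penetrance_model(p, maf)
}

# Hardy-Weinberg genotype frequencies for one locus (codes 0/1/2 = count of
# the minor allele with frequency q).
hwe_freqs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Multi-locus HWE cell frequencies in cell-index order (first locus most
# significant, so each newly added locus varies fastest).
cell_freqs <- function(model) {
  f <- 1
  for (j in seq_len(model$d)) f <- as.vector(outer(hwe_freqs(model$maf[j]), f))
  f
}

#' Population prevalence of a penetrance model
#'
#' \eqn{K = \sum_g f_g p_g} with \eqn{f_g} the HWE multi-locus genotype
#' frequencies.
#'
#' @param model A `penetrance_model`.
#' @return The prevalence, in `[0, 1]`.
#' @export
prevalence <- function(model) {
  sum(cell_freqs(model) * model$table)
}

#' Broad-sense heritability of a penetrance model
#'
#' For a binary trait, heritability is the genotypic variance of penetrance
#' relative to the phenotypic variance:
#' \eqn{h^2 = \sum_g f_g (p_g - K)^2 / (K (1 - K))}, with \eqn{K} the
#' prevalence.
#'
#' @inheritParams prevalence
#' @return Heritability in `[0, 1)`.
#' @export
heritability <- function(model) {
  K <- prevalence(model)
  if (K <= 0 || K >= 1) {
    abort("heritability is undefined for degenerate prevalence (K = 0 or 1)")
  }
  f <- cell_freqs(model)
  sum(f * (model$table - K)^2) / (K * (1 - K))
}

# Effect size of a single-locus table under a genetic mode: the genotype
# relative risk (penetrance ratio) of the exposed group versus baseline
# (per-allele ratio for the additive mode). Exposed for the round-trip
# verification in solve_penetrance and in tests.
single_locus_effect <- function(table, mode) {
  switch(mode,
    dominant = table[2] / table[1],   # carriers share one penetrance
    recessive = table[3] / table[1],
    additive = exp(mean(diff(log(table))))
  )
}

#' Solve a single-locus penetrance function for target effect sizes
#'
#' Numerically determines the penetrance table of a one-locus disease model
#' that attains a requested heritability and effect size simultaneously at a
#' given minor allele frequency:
#'
#' * `dominant`: carriers (Aa, aa) share one penetrance, `or` times the
#'   non-carrier penetrance;
#' * `recessive`: only the minor homozygote aa is elevated, `or` times the
#'   others;
#' * `additive`: penetrance multiplicative per minor allele, `or` per
#'   allele copy.
#'
#' `or` is the genotype relative risk (penetrance ratio), the effect-size
#' scale on which published (heritability, OR) pairs for such models are
#' mutually attainable; on a strict odds scale the same pairs can be
#' infeasible. The baseline penetrance is found by root-finding on the
#' lower (rising, epidemiologically realistic) branch of the heritability
#' curve, and the solution is verified by recomputing both the heritability
#' (within `1e-6`) and the effect ratio.
#'
#' @param mode `"dominant"`, `"recessive"` or `"additive"`.
#' @param maf Minor allele frequency, in `(0, 0.5]`.
#' @param h2 Target heritability, in `(0, 1)`.
#' @param or Target effect ratio, greater than 1.
#' @return A `penetrance_model` with `d = 1`.
#' @examples
#' pm <- solve_penetrance("dominant", maf = 0.5, h2 = 0.05, or = 2.5)
#' heritability(pm)
#' @export
solve_penetrance <- function(mode = c("dominant", "recessive", "additive"),
                             maf, h2, or) {
  mode <- match.arg(mode)
  if (h2 <= 0 || h2 >= 1) abort("target `h2` must lie strictly between 0 and 1")
  if (or <= 1) {
    abort("target effect ratio must exceed 1 (or = 1 implies no effect, h2 = 0)")
  }

  top <- switch(mode, additive = or^2, or)  # largest multiple of the baseline
  table_for <- function(base) {
    # `base` is the reference-genotype penetrance on (0, 1/top)
    switch(mode,
      dominant = c(base, or * base, or * base),
      recessive = c(base, base, or * base),
      additive = base * or^(0:2)
    )
  }
  h2_of <- function(base) heritability(penetrance_model(table_for(base), maf))

  # heritability rises from 0 with the baseline, peaks, and can fall again
  # as the table saturates; solve on the rising branch
  eps <- 1e-12
  peak <- stats::optimize(h2_of, interval = c(eps, 1 / top - eps),
                          maximum = TRUE)
  if (h2 > peak$objective) {
    abort(sprintf(
      "no %s penetrance function attains h2 = %g at MAF %g with effect ratio %g (max attainable h2 = %.4g)",
      mode, h2, maf, or, peak$objective))
  }
  root <- stats::uniroot(function(b) h2_of(b) - h2,
                         lower = eps, upper = peak$maximum, tol = 1e-14)
  model <- penetrance_model(table_for(root$root), maf)

  if (abs(heritability(model) - h2) > 1e-6) {
    abort("penetrance solver failed the heritability round-trip check")
  }
  if (abs(single_locus_effect(model$table, mode) - or) > 1e-6 * or) {
    abort("penetrance solver failed the effect-ratio round-trip check")
  }
  model
}
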