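# Case-control genotype simulation under Hardy-Weinberg equilibrium with a
# penetrance model: prospective Bernoulli draws with rejection sampling to
# the case/control quotas.

#' Simulate a balanced (or unbalanced) case-control genotype dataset
#'
#' Draws individuals prospectively: genotypes at all loci are independent
#' HWE draws (disease loci at the model's minor allele frequencies, nuisance
#' loci at `maf_nuisance`), disease status is Bernoulli with the penetrance
#' of the individual's disease-locus genotype, and sampling continues until
#' both the case and control quotas are filled. Disease loci occupy
#' `disease_cols` (default: the first `d` columns).
#'
#' @param model A `penetrance_model` (e.g. [penetrance_xor()],
#'   [solve_penetrance()]).
#' @param n_cases,n_controls Case and control quotas (defaults 500/500).
#' @param n_loci Total number of loci, disease plus nuisance (default 25).
#' @param maf_nuisance Minor allele frequency of nuisance loci; defaults to
#'   the disease-locus MAF.
#' @param disease_cols Column positions of the disease loci.
#' @param seed Integer seed; identical inputs and seed reproduce the dataset
#'   exactly.
#' @param locus_prefix Prefix for generated locus names (`L1`, `L2`, ...).
#' @param pheno_col Name of the phenotype column to create.
#' @return A tibble of `n_cases + n_controls` rows: integer genotype columns
#'   and the phenotype column (1 = case). The true disease locus names are
#'   attached as attribute `"disease_loci"`.
#' @examples
#' d <- simulate_mdr_data(penetrance_xor(), n_cases = 50, n_controls = 50,
#'                        n_loci = 10, seed = 1)
#' attr(d, "disease_loci")
#' @export
simulate_mdr_data <- function(model, n_cases = 500, n_controls = 500,
                              n_loci = 25, maf_nuisance = NULL,
                              disease_cols = seq_len(model$d), seed = NULL,
                              locus_prefix = "L", pheno_col = "Class") {
  if (!inherits(model, "penetrance_model")) {
    abort("`model` must be a penetrance_model")
  }
  d <- model$d
  if (n_loci < d) abort("`n_loci` must be at least the number of disease loci")
  if (length(disease_cols) != d || anyDuplicated(disease_cols) ||
      any(disease_cols < 1 | disease_cols > n_loci)) {
    abort("`disease_cols` must be d distinct column positions in [1, n_loci]")
  }
  K_prev <- prevalence(model)
  if (K_prev <= 0 || K_prev >= 1) {
    abort(sprintf("prevalence %.3g makes one class unreachable; cannot fill quotas",
                  K_prev))
  }
  maf_nuisance <- maf_nuisance %||% model$maf[1]
  mafs <- rep(maf_nuisance, n_loci)
  mafs[disease_cols] <- model$maf

  with_seed_(seed, {
    cases <- matrix(0L, 0, n_loci)
    controls <- matrix(0L, 0, n_loci)
    while (nrow(cases) < n_cases || nrow(controls) < n_controls) {
      need_cases <- n_cases - nrow(cases)
      need_controls <- n_controls - nrow(controls)
      # batch sized so one or two rounds usually suffice
      B <- max(1000L,
               ceiling(1.3 * max(need_cases / K_prev,
                                 need_controls / (1 - K_prev))))
      G <- vapply(mafs, function(q) rbinom(B, 2L, q), integer(B))
      p <- model$table[mdr_cell_index(G[, disease_cols, drop = FALSE]) + 1L]
      y <- rbinom(B, 1L, p)
      if (need_cases > 0) {
        take <- which(y == 1L)[seq_len(min(need_cases, sum(y == 1L)))]
        cases <- rbind(cases, G[take, , drop = FALSE])
      }
      if (need_controls > 0) {
        take <- which(y == 0L)[seq_len(min(need_controls, sum(y == 0L)))]
        controls <- rbind(controls, G[take, , drop = FALSE])
      }
    }
    G <- rbind(cases, controls)
    colnames(G) <- paste0(locus_prefix, seq_len(n_loci))
    out <- tibble::as_tibble(G)
    out[[pheno_col]] <- rep(c(1L, 0L), c(n_cases, n_controls))
    attr(out, "disease_loci") <- colnames(G)[disease_cols]
    out
  })
}
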