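# Deterministic fixture builders used across test files.

# Genotypes at `n_loci` random loci with a phenotype perfectly determined by
# the minor-allele parity of the first two loci (an XOR-style noiseless map).
perfect_pair_data <- function(n = 200, n_loci = 6, seed = 1) {
  withr::with_seed(seed, {
    G <- matrix(sample(0:2, n * n_loci, replace = TRUE), n, n_loci)
    colnames(G) <- paste0("L", seq_len(n_loci))
    d <- tibble::as_tibble(G)
    d$Class <- as.integer((d$L1 + d$L2) %% 2 == 1)
    # guarantee both classes well represented
    stopifnot(sum(d$Class) > 10, sum(1 - d$Class) > 10)
    d
  })
}

# A perfect single-locus predictor at the given column, noise elsewhere.
perfect_locus_data <- function(n = 120, n_loci = 6, locus = 5, seed = 2) {
  withr::with_seed(seed, {
    G <- matrix(sample(0:2, n * n_loci, replace = TRUE), n, n_loci)
    colnames(G) <- paste0("L", seq_len(n_loci))
    d <- tibble::as_tibble(G)
    d$Class <- as.integer(d[[locus]] >= 1)
    stopifnot(sum(d$Class) > 5, sum(1 - d$Class) > 5)
    d
  })
}

# Pure-noise balanced case-control data.
noise_data <- function(n_cases = 50, n_controls = 50, n_loci = 6, seed = 3,
                       maf = 0.5) {
  withr::with_seed(seed, {
    n <- n_cases + n_controls
    G <- matrix(rbinom(n * n_loci, 2, maf), n, n_loci)
    colnames(G) <- paste0("L", seq_len(n_loci))
    d <- tibble::as_tibble(G)
    d$Class <- rep(c(1L, 0L), c(n_cases, n_controls))
    d
  })
}
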