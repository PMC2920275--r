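# Independent brute-force oracles, deliberately written with hash-map style
# tabulation (paste keys + table) rather than the package's vectorised path.

# Balanced accuracy of the MDR labelling for one locus combination, cellwise.
oracle_combo_ba <- function(data, combo, pheno_col = "Class") {
  y <- data[[pheno_col]]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  key <- do.call(paste, c(data[combo], sep = "|"))
  cells <- unique(key)
  n11 <- 0
  n00 <- 0
  for (cell in cells) {
    ca <- sum(y == 1 & key == cell)
    co <- sum(y == 0 & key == cell)
    high <- if (ca == 0 && co == 0) FALSE
            else if (co == 0) TRUE
            else (ca / co) > (n1 / n0)
    if (high) n11 <- n11 + ca else n00 <- n00 + co
  }
  (n11 / n1 + n00 / n0) / 2
}

# Best combination of size k by exhaustive enumeration; ties keep the first
# (lexicographically smallest) combination.
oracle_best_model <- function(data, k, pheno_col = "Class") {
  loci <- setdiff(names(data), pheno_col)
  best <- NULL
  for (combo in combn(loci, k, simplify = FALSE)) {
    ba <- oracle_combo_ba(data, combo, pheno_col)
    if (is.null(best) || ba > best$ba) best <- list(loci = combo, ba = ba)
  }
  best
}

# Prevalence and heritability by explicit nested enumeration of all 3^d
# genotype combinations under HWE.
oracle_prevalence_h2 <- function(table, mafs) {
  d <- length(mafs)
  geno_freq <- function(g, q) c((1 - q)^2, 2 * q * (1 - q), q^2)[g + 1]
  cells <- expand.grid(rep(list(0:2), d))[, d:1, drop = FALSE]  # first locus slowest
  K <- 0
  for (r in seq_len(nrow(cells))) {
    f <- 1
    for (j in seq_len(d)) f <- f * geno_freq(cells[r, j], mafs[j])
    K <- K + f * table[r]
  }
  v <- 0
  for (r in seq_len(nrow(cells))) {
    f <- 1
    for (j in seq_len(d)) f <- f * geno_freq(cells[r, j], mafs[j])
    v <- v + f * (table[r] - K)^2
  }
  list(prevalence = K, h2 = v / (K * (1 - K)))
}
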