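# Validation and conversion of the tabular genotype format used throughout:
# a data frame with one integer column per locus (minor-allele counts 0/1/2)
# plus a binary phenotype column (default "Class", 1 = case, 0 = control).

# Convert a genotype data frame to the internal matrix representation and
# validate the core invariants. Returns list(G, y, loci, n1, n0).
geno_matrix <- function(data, pheno_col = "Class", require_both_classes = TRUE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of genotypes plus a phenotype column")
  }
  if (!pheno_col %in% names(data)) {
    abort(sprintf("phenotype column '%s' not found in `data`", pheno_col))
  }
  y <- data[[pheno_col]]
  if (!all(y %in% c(0L, 1L))) {
    abort(sprintf("phenotype column '%s' must contain only 0 (control) and 1 (case)",
                  pheno_col))
  }
  y <- as.integer(y)
  locus_names <- setdiff(names(data), pheno_col)
  if (length(locus_names) == 0) abort("`data` contains no locus columns")
  if (anyDuplicated(locus_names)) abort("locus names must be unique")
  G <- as.matrix(data[locus_names])
  if (!is.numeric(G) || anyNA(G) || !all(G %in% c(0L, 1L, 2L))) {
    abort("genotype codes must all be 0, 1 or 2 (minor-allele counts); missing values are not accepted")
  }
  storage.mode(G) <- "integer"
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (require_both_classes && (n1 < 1L || n0 < 1L)) {
    abort("`data` must contain at least one case and one control")
  }
  list(G = G, y = y, loci = locus_names, n1 = n1, n0 = n0)
}

# Resolve loci given by name or integer index to column indices of gd$G.
resolve_loci <- function(gd, loci) {
  if (is.character(loci)) {
    idx <- match(loci, gd$loci)
    if (anyNA(idx)) {
      abort(sprintf("unknown locus name(s): %s",
                    paste(loci[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(loci)
    if (any(idx < 1L | idx > ncol(gd$G))) {
      abort("locus index out of range")
    }
  }
  if (anyDuplicated(idx)) abort("loci in a combination must be distinct")
  idx
}
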