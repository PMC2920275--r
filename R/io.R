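# Tab-delimited dataset format (the de-facto MDR text layout): a header of
# locus names followed by the literal column "Class", then one row per
# individual with genotype codes 0/1/2 and Class 0/1 (1 = case). Parsing is
# strict: any malformed token fails with the offending line number.

#' Read a tab-delimited case-control genotype file
#'
#' @param path Path to a tab-delimited file whose header names the locus
#'   columns and ends with the literal column `Class`.
#' @return A tibble of integer genotype columns plus `Class`.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2) abort("dataset file must have a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncols <- length(header)
  if (header[ncols] != "Class") {
    abort("the last column of the header must be named 'Class'")
  }
  loci <- header[-ncols]
  if (length(loci) == 0) abort("no locus columns found")
  if (anyDuplicated(loci)) {
    abort(sprintf("duplicated locus name(s): %s",
                  paste(unique(loci[duplicated(loci)]), collapse = ", ")))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  out <- matrix(NA_integer_, nrow = length(fields), ncol = ncols)
  for (i in seq_along(fields)) {
    row <- fields[[i]]
    line_no <- i + 1L
    if (length(row) != ncols) {
      abort(sprintf("line %d: expected %d fields, found %d",
                    line_no, ncols, length(row)))
    }
    bad <- which(!row[-ncols] %in% c("0", "1", "2"))
    if (length(bad) > 0) {
      abort(sprintf("line %d: invalid genotype token '%s' in column '%s' (must be 0, 1 or 2)",
                    line_no, row[bad[1]], loci[bad[1]]))
    }
    if (!row[ncols] %in% c("0", "1")) {
      abort(sprintf("line %d: invalid Class token '%s' (must be 0 or 1)",
                    line_no, row[ncols]))
    }
    out[i, ] <- as.integer(row)
  }
  colnames(out) <- header
  tibble::as_tibble(out)
}

#' Write a case-control genotype dataset to the tab-delimited format
#'
#' The inverse of [read_genotypes()]; `write_genotypes(read_genotypes(f), g)`
#' reproduces `f` byte for byte for canonical files.
#'
#' @inheritParams mdr_fit
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(data, path, pheno_col = "Class") {
  gd <- geno_matrix(data, pheno_col, require_both_classes = FALSE)
  header <- paste(c(gd$loci, "Class"), collapse = "\t")
  body <- apply(cbind(gd$G, gd$y), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
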