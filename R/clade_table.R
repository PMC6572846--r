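#' Clade-frequency tables and frequency vectors
#'
#' A clade table is a numeric matrix with seven clade rows (`clade1` ..
#' `clade7`) and one column per population; each entry is the population
#' frequency of that clade.  Published tables are used exactly as printed, so
#' columns may carry rounding error: each column must sum to 1 within a
#' tolerance (0.01 by default), and columns further off trigger a warning
#' rather than an error because some public-panel columns round to slightly
#' less than 1.
#'
#' @param x numeric matrix, clades in rows, populations in columns.
#' @param tol tolerance on the column sums.
#' @return `x`, invisibly, after validation.
#' @seealso [east_asian_freqs()] for the packaged seven-clade table.
#' @export
validate_clade_table <- function(x, tol = 0.01) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(x < 0)) stop("clade frequencies must be non-negative")
  s <- colSums(x)
  off <- abs(s - 1) > tol
  if (any(off)) {
    warning(sprintf(
      "column(s) %s sum to %s (tolerance %.3g); values kept as printed",
      paste(colnames(x)[off], collapse = ", "),
      paste(sprintf("%.3f", s[off]), collapse = ", "), tol))
  }
  invisible(x)
}

#' Seven-clade Y-chromosome frequencies for East Asian populations
#'
#' Returns the packaged table of seven Y-chromosome clade frequencies in
#' seven East Asian population samples (mainland Japanese, Korean, and the
#' five 1000 Genomes East Asian panels JPT, CHB, CHS, CDX, KHV).  Values are
#' kept exactly as printed in the source table; columns are not renormalized.
#'
#' @return numeric matrix, 7 clades x 7 populations.
#' @examples
#' east_asian_freqs()[, "Mainland Japanese"]
#' @export
east_asian_freqs <- function() {
  path <- system.file("extdata", "east_asian_clade_freqs.tsv",
                      package = "ydemos", mustWork = TRUE)
  tab <- read_clade_table(path)
  tab
}

#' Read / write a clade table as TSV
#'
#' The on-disk format is tab-separated with a `clade` identifier column and
#' one column per population, clades in rows.
#'
#' @param path file path.
#' @param x clade table matrix as from [east_asian_freqs()].
#' @return `read_clade_table()` returns the validated matrix;
#'   `write_clade_table()` returns `path` invisibly.
#' @export
read_clade_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"clade" %in% names(df)) stop("clade table must have a 'clade' column")
  m <- as.matrix(df[, setdiff(names(df), "clade"), drop = FALSE])
  rownames(m) <- df$clade
  storage.mode(m) <- "double"
  suppressWarnings(validate_clade_table(m))
  m
}

#' @rdname read_clade_table
#' @export
write_clade_table <- function(x, path) {
  df <- data.frame(clade = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a clade-frequency vector
#'
#' @param x numeric vector of per-clade frequencies.
#' @param n_clades expected length.
#' @param tol tolerance on `sum(x) - 1`.  Simulated vectors sum to 1 to
#'   machine precision; printed vectors carry rounding error, so callers pass
#'   a looser tolerance for those.
#' @return `x` invisibly.
#' @export
validate_freqs <- function(x, n_clades = 7L, tol = 0.01) {
  stopifnot(is.numeric(x))
  if (length(x) != n_clades)
    stop(sprintf("expected %d clade frequencies, got %d", n_clades, length(x)))
  if (any(x < 0)) stop("frequencies must be non-negative")
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("frequencies sum to %.4f, not 1 (tol %.3g)", sum(x), tol))
  invisible(x)
}
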