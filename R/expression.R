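# Expression-matrix input, validation and qPCR-derived expression.

#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' First column gene identifiers, remaining columns samples.  Values must be
#' non-negative and finite (counts, TPM, or relative expression).
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; `"\t"` or `","`.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  df <- read_tsv_checked(path, what = "expression matrix", sep = sep)
  if (ncol(df) < 2L) stop_input("expression matrix needs a gene column plus samples: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- ids
  validate_expression_matrix(m)
  m
}

validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_input("expression values must be a numeric matrix")
  if (anyNA(m) || any(!is.finite(m))) stop_input("expression matrix contains NA/non-finite values")
  if (any(m < 0)) stop_input("expression matrix contains negative values")
  if (anyDuplicated(rownames(m))) stop_input("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(m))) stop_input("duplicate sample ids in expression matrix")
  invisible(m)
}

#' Read a per-sample annotation table
#'
#' Annotation TSVs are keyed by `sample_id` and may carry `group`,
#' `cancer_type` and `<GENE>_mutation` columns (values `WT`/`Mut`).
#'
#' @param path path to the annotation TSV.
#' @return A data frame with a `sample_id` column.
#' @export
read_sample_annotations <- function(path) {
  df <- read_tsv_checked(path, what = "annotation table")
  if (!"sample_id" %in% names(df)) stop_input("annotation table needs a sample_id column: ", path)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop_input("duplicate sample_id in annotation table")
  df
}

#' Per-gene z-standardisation of an expression matrix
#'
#' Centres and scales each gene row to mean 0 and sample standard deviation
#' (n-1 denominator) 1 across samples.  Constant rows, which carry no
#' between-sample information, map to all zeros.
#'
#' @param x numeric gene-by-sample matrix with at least two columns.
#' @return A matrix of the same shape holding per-gene z values.
#' @examples
#' standardize_genes(rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5)))
#' @export
standardize_genes <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) < 2L) stop_input("standardisation needs at least 2 samples")
  if (anyNA(x)) stop_input("standardisation input contains NA")
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Relative expression from qPCR Ct values
#'
#' Converts a gene-by-sample Ct table into relative expression against a
#' single housekeeping gene: `expression(g, s) = 2^-(Ct[g, s] - Ct[hk, s])`.
#' The housekeeping row is 1 everywhere by construction.  Cross-group
#' comparison (the delta-delta-Ct step) is deliberately left to downstream
#' z-standardisation in [cma_score()].
#'
#' @param ct numeric gene-by-sample matrix of Ct values (finite).
#' @param housekeeping symbol of the housekeeping gene; must be a row of
#'   `ct` with a finite value in every sample.
#' @return A gene-by-sample matrix of relative expression (linear scale).
#' @examples
#' ct <- rbind(ACTB = c(20, 20), GOI = c(24, 22))
#' relative_expression_from_ct(ct, "ACTB")
#' @export
relative_expression_from_ct <- function(ct, housekeeping) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop_input("'ct' must be a numeric matrix")
  hk <- toupper(housekeeping)
  ridx <- match(hk, toupper(rownames(ct)))
  if (is.na(ridx)) stop_input("housekeeping gene ", hk, " not found in Ct table")
  hk_ct <- ct[ridx, ]
  bad <- colnames(ct)[!is.finite(hk_ct)]
  if (length(bad)) {
    stop_input("missing housekeeping Ct for sample(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(ct))) stop_input("Ct table contains non-finite values")
  2^(-sweep(ct, 2L, hk_ct, `-`))
}

#' Per-sample NCoR1/RARA expression ratio
#'
#' The expression ratio of the nuclear corepressor NCoR1 to its receptor
#' RARA — the cohort covariate whose increase tracks CMA activation across
#' cancer types.
#'
#' @param expr gene-by-sample expression matrix (genes matched
#'   case-insensitively).
#' @param numerator,denominator gene symbols; defaults `NCOR1` / `RARA`.
#' @return A named numeric vector, one ratio per sample.
#' @export
ncor1_rara_ratio <- function(expr, numerator = "NCOR1", denominator = "RARA") {
  rows <- toupper(rownames(expr))
  ni <- match(toupper(numerator), rows)
  di <- match(toupper(denominator), rows)
  if (is.na(ni)) stop_input("numerator gene ", numerator, " not in matrix")
  if (is.na(di)) stop_input("denominator gene ", denominator, " not in matrix")
  den <- expr[di, ]
  zero <- colnames(expr)[den <= 0]
  if (length(zero)) {
    stop_input("zero/negative ", denominator, " expression in sample(s): ",
               paste(zero, collapse = ", "))
  }
  expr[ni, ] / den
}
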