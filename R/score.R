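#' Per-sample transcriptional CMA score
#'
#' Computes, for each sample \eqn{s}, the weighted and directed average of
#' expression of the CMA-network genes:
#' \deqn{S_s = \frac{\sum_i w_i d_i v_{i,s}}{\sum_i w_i}}
#' where \eqn{w_i > 0} is the component weight (2 for LAMP2A by convention,
#' 1 otherwise), \eqn{d_i \in \{+1,-1\}} its direction, and \eqn{v_{i,s}}
#' the transformed expression value.  By default expression is
#' `log2(x + 1)`-transformed and z-standardised per gene across the samples
#' of the supplied matrix, so raw averaging is not dominated by highly
#' expressed genes and the score is a *comparison within the cohort passed
#' in*; cross-cohort comparisons must therefore score the pooled matrix.
#'
#' @param expr non-negative gene-by-sample numeric matrix (counts, TPM, or
#'   relative expression); gene symbols matched case-insensitively.
#' @param net a [cma_network()].
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param standardize `"per_gene_z"` (default) or `"none"`.
#' @param missing_genes what to do when network genes are absent from the
#'   matrix: `"renormalize"` (default; weights renormalised over the genes
#'   present, with a warning) or `"error"`.
#' @return An object of class `cma_score_result`: a data frame with columns
#'   `sample_id` and `score`, plus attributes `network_name`, `genes_used`
#'   and `params`.
#' @examples
#' net <- cma_network(c("A", "B", "LAMP2A"), weight = c(1, 1, 2),
#'                    direction = c(1, -1, 1))
#' expr <- rbind(A = c(4, 1), B = c(1, 4), LAMP2A = c(8, 1))
#' colnames(expr) <- c("s1", "s2")
#' cma_score(expr, net)
#' @export
cma_score <- function(expr, net,
                      transform = c("log2p1", "none"),
                      standardize = c("per_gene_z", "none"),
                      missing_genes = c("renormalize", "error")) {
  transform <- match.arg(transform)
  standardize <- match.arg(standardize)
  missing_genes <- match.arg(missing_genes)
  net <- as_cma_network(net)
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (anyNA(expr) || any(!is.finite(expr))) stop_input("expression matrix contains NA/non-finite values")

  cov <- network_coverage(net, expr)
  if (length(cov$present) == 0L) {
    stop_input("none of the ", nrow(net), " network genes are present in the matrix")
  }
  if (length(cov$missing)) {
    if (missing_genes == "error") {
      stop_input("network gene(s) missing from matrix: ",
                 paste(cov$missing, collapse = ", "))
    }
    warning("renormalizing weights over ", length(cov$present), "/", nrow(net),
            " network genes present (missing: ",
            paste(cov$missing, collapse = ", "), ")", call. = FALSE)
  }

  v <- expr
  if (transform == "log2p1") v <- log2(v + 1)
  if (standardize == "per_gene_z") v <- standardize_genes(v)

  keep <- net[net$gene %in% cov$present, , drop = FALSE]
  ridx <- match(keep$gene, toupper(rownames(expr)))
  vi <- v[ridx, , drop = FALSE]
  scores <- as.numeric(crossprod(keep$weight * keep$direction, vi)) / sum(keep$weight)

  out <- data.frame(
    sample_id = colnames(expr) %||% paste0("sample_", seq_along(scores)),
    score = scores,
    stringsAsFactors = FALSE
  )
  attr(out, "network_name") <- attr(net, "name")
  attr(out, "genes_used") <- keep$gene
  attr(out, "params") <- list(transform = transform, standardize = standardize,
                              missing_genes = missing_genes)
  class(out) <- c("cma_score_result", "data.frame")
  out
}

#' @export
print.cma_score_result <- function(x, ...) {
  p <- attr(x, "params")
  cat("CMA score (network '", attr(x, "network_name"), "', ",
      length(attr(x, "genes_used")), " genes used; transform=", p$transform,
      ", standardize=", p$standardize, ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
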