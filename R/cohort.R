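# Cohort-level statistics: screen z-score hit calling, ratio-vs-score
# regression, mutation stratification and fold-change filtering.

#' Z-score hit calling for a high-content screen plate
#'
#' Reduces each compound's replicate puncta-per-cell values to a mean, then
#' standardises across the compounds of the batch:
#' `z = (x - mean) / SD` (sample SD, n-1).  Compounds with `z` strictly
#' below `z_threshold` (default -1, the conventional inhibitor cutoff) are
#' flagged as hits.  Because z-scores are affine-invariant, rescaling the
#' raw puncta values leaves calls unchanged.
#'
#' @param plate compound-by-replicate numeric matrix of puncta-per-cell
#'   values (non-negative, finite), rownames = compound ids; a single
#'   column (already-averaged values) is accepted.
#' @param z_threshold hit cutoff on the z scale (strict `<`).
#' @return A data frame `compound`, `mean_puncta`, `z`, `hit`.
#' @examples
#' plate <- matrix(c(10, 10, 10, 10, 2), ncol = 1,
#'                 dimnames = list(paste0("C", 1:5), NULL))
#' zscore_hits(plate)
#' @export
zscore_hits <- function(plate, z_threshold = -1) {
  if (!is.matrix(plate)) plate <- as.matrix(plate)
  if (!is.numeric(plate) || anyNA(plate) || any(!is.finite(plate))) {
    stop_input("plate values must be finite numbers")
  }
  if (nrow(plate) < 3L) stop_input("z-scoring needs >=3 compounds")
  x <- rowMeans(plate)
  s <- sd(x)
  if (s == 0) {
    warning("zero spread across compounds; no hits can be called", call. = FALSE)
    z <- rep(NA_real_, length(x))
    hit <- rep(FALSE, length(x))
  } else {
    z <- (x - mean(x)) / s
    hit <- z < z_threshold
  }
  data.frame(compound = rownames(plate) %||% paste0("compound_", seq_along(x)),
             mean_puncta = x, z = z, hit = hit,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a screen plate TSV
#'
#' First column compound id, remaining columns replicate puncta-per-cell
#' values.
#'
#' @param path plate TSV path.
#' @return A compound-by-replicate numeric matrix.
#' @export
read_screen_plate <- function(path) {
  m <- read_matrix_tsv(path, what = "screen plate")
  if (anyNA(m)) stop_input("screen plate contains non-numeric/missing values: ", path)
  m
}

#' Regression of CMA score on an expression ratio across cohort units
#'
#' Ordinary least squares of `score` on `ratio` (one point per unit, e.g.
#' per cancer type), with the Pearson correlation and the two-tailed
#' p-value for a nonzero slope — the simple-linear-regression summary used
#' to relate the NCoR1/RARA ratio to the CMA score across cancers.
#'
#' @param ratio,score numeric vectors of equal length (>= 3 points; the
#'   ratio must have positive variance).
#' @return A list `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
correlate_ratio_score <- function(ratio, score) {
  if (length(ratio) != length(score)) stop_input("ratio and score lengths differ")
  ok <- is.finite(ratio) & is.finite(score)
  if (!all(ok)) stop_input("non-finite values in ratio/score")
  if (length(ratio) < 3L) stop_input("need >=3 points for regression")
  if (var(ratio) == 0) stop_input("ratio has zero variance")
  fit <- lm(score ~ ratio)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r = unname(cor(ratio, score)),
       p_value = unname(sm$coefficients[2L, 4L]),
       n = length(ratio))
}

#' Stratify per-sample values by mutation status
#'
#' Splits per-sample scores (or ratios) into wild-type and mutant strata of
#' a given gene and compares them with the shared two-tailed Welch test
#' ([welch_test()]), reporting per-stratum mean and SEM and the direction
#' of the difference.
#'
#' @param values named numeric vector, one value per sample.
#' @param annotations data frame with `sample_id` and a
#'   `<gene>_mutation` column with values `WT`/`Mut`.
#' @param gene gene symbol whose mutation status stratifies the cohort
#'   (default `"TP53"`).
#' @return A list with `summary` (data frame: stratum, n, mean, sem),
#'   `difference` (Mut mean minus WT mean) and `p_value`.
#' @export
stratify_by_mutation <- function(values, annotations, gene = "TP53") {
  col <- paste0(gene, "_mutation")
  idx <- match(tolower(col), tolower(names(annotations)))
  if (is.na(idx)) stop_input("annotation table lacks column ", col)
  status <- as.character(annotations[[idx]])
  v <- values[match(annotations$sample_id, names(values))]
  keep <- !is.na(v) & status %in% c("WT", "Mut")
  wt <- v[keep & status == "WT"]
  mut <- v[keep & status == "Mut"]
  if (length(wt) < 2L || length(mut) < 2L) {
    stop_input("each stratum needs >=2 samples (WT: ", length(wt),
               ", Mut: ", length(mut), ")")
  }
  w <- welch_test(matrix(mut, nrow = 1L), matrix(wt, nrow = 1L))
  list(
    summary = data.frame(
      stratum = c("WT", "Mut"),
      n = c(length(wt), length(mut)),
      mean = c(mean(wt), mean(mut)),
      sem = c(sd(wt) / sqrt(length(wt)), sd(mut) / sqrt(length(mut))),
      stringsAsFactors = FALSE
    ),
    difference = w$estimate,
    p_value = w$p_value
  )
}

#' Differential-expression style fold-change filtering
#'
#' Splits genes into up- and down-regulated sets by linear fold change and
#' p-value, with the RNA-seq defaults (up above 1.5-fold, down below
#' 0.5-fold, p < 0.05).  The proteome flavour with 1.5/0.8 defaults is
#' [level_change_filter()].
#'
#' @param fold_change named numeric vector of linear fold changes.
#' @param p_value numeric vector of p-values, same length/order.
#' @param fc_up,fc_down thresholds, `0 < fc_down < 1 < fc_up`.
#' @param alpha significance cutoff.
#' @return A list of character vectors `up` and `down`.
#' @export
de_filter <- function(fold_change, p_value, fc_up = 1.5, fc_down = 0.5,
                      alpha = 0.05) {
  if (length(fold_change) != length(p_value)) stop_input("fold_change and p_value lengths differ")
  if (!(fc_down > 0 && fc_down < 1 && fc_up > 1)) stop_input("need 0 < fc_down < 1 < fc_up")
  ids <- names(fold_change) %||% as.character(seq_along(fold_change))
  list(up = ids[fold_change >= fc_up & p_value < alpha],
       down = ids[fold_change <= fc_down & p_value < alpha])
}
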