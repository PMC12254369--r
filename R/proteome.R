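# Lysosomal-flux proteomics: dataset container, preprocessing, imputation,
# differential abundance and the substrate classifier.

#' Construct a proteome dataset
#'
#' Bundles a protein-by-sample intensity matrix with its condition design.
#' The design encodes the lysosomal-flux experiment: each sample is a
#' combination of `genotype` (`WT` or `L2AKD`, i.e. LAMP2A knockdown),
#' `treatment` (`vehicle` or `drug`) and `inhibition` (`none` or `NL`,
#' ammonium chloride + leupeptin blocking lysosomal proteolysis).
#'
#' @param intensities protein-by-sample numeric matrix; raw positive
#'   intensities (`log2 = FALSE`) or already log2-transformed values.
#'   `NA` marks missing quantifications.
#' @param design data frame with one row per sample (matched to
#'   `colnames(intensities)` via a `sample` column or rownames) and columns
#'   `genotype`, `treatment`, `inhibition`, `replicate`.
#' @param log2 whether `intensities` are already on the log2 scale.
#' @param normalized whether per-sample centring has been applied.
#' @return An object of class `proteome_dataset`.
#' @export
proteome_dataset <- function(intensities, design, log2 = FALSE, normalized = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop_input("'intensities' must be a numeric matrix")
  }
  if (is.null(rownames(intensities))) stop_input("intensities need protein rownames")
  if (is.null(colnames(intensities))) stop_input("intensities need sample colnames")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if ("sample" %in% names(design)) rownames(design) <- design$sample
  need <- c("genotype", "treatment", "inhibition")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop_input("design lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(intensities), rownames(design))
  if (length(absent)) {
    stop_input("sample(s) without a design assignment: ", paste(absent, collapse = ", "))
  }
  design <- design[colnames(intensities), , drop = FALSE]
  bad_g <- !design$genotype %in% c("WT", "L2AKD")
  bad_t <- !design$treatment %in% c("vehicle", "drug")
  bad_i <- !design$inhibition %in% c("none", "NL")
  if (any(bad_g | bad_t | bad_i)) {
    stop_input("invalid design values for sample(s): ",
               paste(rownames(design)[bad_g | bad_t | bad_i], collapse = ", "))
  }
  structure(
    list(intensities = intensities, design = design,
         log2 = isTRUE(log2), normalized = isTRUE(normalized)),
    class = "proteome_dataset"
  )
}

#' @export
print.proteome_dataset <- function(x, ...) {
  cat("proteome_dataset: ", nrow(x$intensities), " proteins x ",
      ncol(x$intensities), " samples (",
      round(100 * mean(is.na(x$intensities)), 1), "% missing; ",
      if (x$log2) "log2" else "raw",
      if (x$normalized) ", sample-centred" else "", ")\n", sep = "")
  print(table(genotype = x$design$genotype, treatment = x$design$treatment,
              inhibition = x$design$inhibition))
  invisible(x)
}

#' Read a proteome dataset from TSV files
#'
#' @param intensities_path wide TSV: first column protein accession,
#'   remaining columns samples; blank/NA cells are missing values.
#' @param design_path design TSV keyed by `sample` with columns `genotype`,
#'   `treatment`, `inhibition`, `replicate`.
#' @return A [proteome_dataset()] of raw intensities.
#' @export
read_proteome <- function(intensities_path, design_path) {
  m <- read_matrix_tsv(intensities_path, what = "intensity matrix")
  design <- read_tsv_checked(design_path, what = "design table")
  if (!"sample" %in% names(design)) stop_input("design table needs a 'sample' column: ", design_path)
  proteome_dataset(m, design)
}

#' Analysis parameters for the lysosomal-flux classifier
#'
#' Houses the pipeline's thresholds: lysosomal degradation is a `fc_flux`
#' (default 1.2)-fold accumulation under protease inhibition; protein-level
#' changes are called above `fc_up` (1.5) or below `fc_down` (0.8);
#' significance is a Welch-test p below `alpha` (0.05, raw by default, the
#' pipeline's historical convention; `multiple_testing = "BH"` enables
#' Benjamini-Hochberg adjustment).  Missing values are imputed from a normal
#' distribution `impute_downshift` (2) sample SDs below the sample mean with
#' spread `impute_width` (0.3) sample SDs.
#'
#' @param fc_flux linear fold-change threshold for lysosomal degradation (> 1).
#' @param fc_up,fc_down level-change thresholds, `0 < fc_down < 1 < fc_up`.
#' @param alpha p-value cutoff in (0, 1).
#' @param impute_downshift non-negative SD multiples below the sample mean.
#' @param impute_width positive fraction of the sample SD used as imputation SD.
#' @param multiple_testing `"none"` (default) or `"BH"`.
#' @return A list of class `flux_params`.
#' @export
flux_params <- function(fc_flux = 1.2, fc_up = 1.5, fc_down = 0.8, alpha = 0.05,
                        impute_downshift = 2.0, impute_width = 0.3,
                        multiple_testing = c("none", "BH")) {
  multiple_testing <- match.arg(multiple_testing)
  if (!is.finite(fc_flux) || fc_flux <= 1) stop_input("fc_flux must be > 1")
  if (!is.finite(fc_up) || !is.finite(fc_down) || !(fc_down > 0 && fc_down < 1 && fc_up > 1)) {
    stop_input("need 0 < fc_down < 1 < fc_up")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (!is.finite(impute_downshift) || impute_downshift < 0) stop_input("impute_downshift must be >= 0")
  if (!is.finite(impute_width) || impute_width <= 0) stop_input("impute_width must be > 0")
  structure(list(fc_flux = fc_flux, fc_up = fc_up, fc_down = fc_down,
                 alpha = alpha, impute_downshift = impute_downshift,
                 impute_width = impute_width, multiple_testing = multiple_testing),
            class = "flux_params")
}

#' Log2-transform and sample-centre a proteome dataset
#'
#' Raw intensities are log2-transformed and each sample column is normalised
#' by its average: the mean of that sample's observed log2 values is
#' subtracted, so every sample's observed mean is 0 afterwards (equivalent
#' to dividing raw intensities by their geometric mean).  The missingness
#' pattern is untouched.
#'
#' @param ds a [proteome_dataset()] of raw positive intensities.
#' @return The dataset with `log2 = TRUE`, `normalized = TRUE`.
#' @export
preprocess_proteome <- function(ds) {
  stopifnot(inherits(ds, "proteome_dataset"))
  m <- ds$intensities
  if (!ds$log2) {
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop_input("non-positive intensity for protein ", rownames(m)[bad[1L, 1L]],
                 ", sample ", colnames(m)[bad[1L, 2L]])
    }
    m <- log2(m)
  }
  if (!ds$normalized) {
    m <- sweep(m, 2L, colMeans(m, na.rm = TRUE), `-`)
  }
  ds$intensities <- m
  ds$log2 <- TRUE
  ds$normalized <- TRUE
  ds
}

#' Impute missing values from a downshifted normal distribution
#'
#' Each missing cell in sample \eqn{s} is drawn from
#' \eqn{N(\mu_s - k\,\sigma_s,\ (w\,\sigma_s)^2)} where \eqn{\mu_s} and
#' \eqn{\sigma_s} are the observed mean and SD of that sample, \eqn{k} is
#' `impute_downshift` (default 2) and \eqn{w} is `impute_width` (default
#' 0.3).  This mimics the MNAR character of proteomics missingness: values
#' are absent mostly because they sit below the detection limit, so they are
#' replaced by draws from the low tail.  Only missing cells change; the same
#' seed always reproduces the same output.
#'
#' @param ds a preprocessed (log2, centred) [proteome_dataset()].
#' @param params a [flux_params()].
#' @param seed integer seed controlling the imputation draws.
#' @return The dataset with no missing values.
#' @export
impute_missing <- function(ds, params = flux_params(), seed = 1L) {
  stopifnot(inherits(ds, "proteome_dataset"))
  if (!ds$log2) stop_input("impute_missing expects a preprocessed (log2) dataset")
  m <- ds$intensities
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2L)) {
    stop_input("sample(s) with <2 observed values: ",
               paste(colnames(m)[n_obs < 2L], collapse = ", "))
  }
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      mu <- mean(m[!miss, j])
      sig <- sd(m[!miss, j])
      m[miss, j] <- rnorm(sum(miss),
                          mean = mu - params$impute_downshift * sig,
                          sd = params$impute_width * sig)
    }
  })
  ds$intensities <- m
  ds
}

# Select sample ids matching a design cell; NULL fields match anything.
select_samples <- function(ds, genotype = NULL, treatment = NULL, inhibition = NULL) {
  d <- ds$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(genotype)) keep <- keep & d$genotype == genotype
  if (!is.null(treatment)) keep <- keep & d$treatment == treatment
  if (!is.null(inhibition)) keep <- keep & d$inhibition == inhibition
  rownames(d)[keep]
}

#' Per-protein differential abundance between two design cells
#'
#' Computes, for every protein, the linear fold change
#' `2^(mean_A - mean_B)` of log2 intensities and a two-tailed Welch
#' (heteroscedastic) t-test p-value via [welch_test()].
#'
#' @param ds a preprocessed, complete (imputed) [proteome_dataset()].
#' @param cell_a,cell_b named lists selecting samples, e.g.
#'   `list(genotype = "WT", treatment = "vehicle", inhibition = "NL")`.
#' @return A data frame with columns `protein`, `log2_fc`, `fold_change`,
#'   `p_value`.
#' @export
proteome_differential <- function(ds, cell_a, cell_b) {
  stopifnot(inherits(ds, "proteome_dataset"))
  sa <- do.call(select_samples, c(list(ds), cell_a))
  sb <- do.call(select_samples, c(list(ds), cell_b))
  if (length(sa) < 2L) stop_input("design cell A has <2 replicates (",
                                  paste(unlist(cell_a), collapse = "/"), ")")
  if (length(sb) < 2L) stop_input("design cell B has <2 replicates (",
                                  paste(unlist(cell_b), collapse = "/"), ")")
  a <- ds$intensities[, sa, drop = FALSE]
  b <- ds$intensities[, sb, drop = FALSE]
  if (anyNA(a) || anyNA(b)) stop_input("dataset has missing values; run impute_missing() first")
  w <- welch_test(a, b)
  data.frame(protein = rownames(ds$intensities),
             log2_fc = w$estimate,
             fold_change = 2^w$estimate,
             p_value = w$p_value,
             stringsAsFactors = FALSE)
}

#' Call lysosomally degraded proteins in one background
#'
#' A protein is degraded in lysosomes if blocking lysosomal proteolysis
#' (ammonium chloride + leupeptin, inhibition `NL`) makes it accumulate: the
#' NL-vs-none fold change in the given (genotype, treatment) background is
#' at least `fc_flux` (inclusive) with Welch p below `alpha`.
#'
#' @param ds imputed [proteome_dataset()].
#' @param genotype,treatment the background, e.g. `"WT"`, `"vehicle"`.
#' @param params a [flux_params()].
#' @return A data frame `protein`, `fold_change`, `p_value`, `degraded`;
#'   the called set is `protein[degraded]`.
#' @export
call_lysosomal_degradation <- function(ds, genotype = "WT", treatment = "vehicle",
                                       params = flux_params()) {
  nl <- select_samples(ds, genotype, treatment, "NL")
  if (length(nl) == 0L) {
    stop_input("no lysosomal-inhibition (NL) samples for ", genotype, "/", treatment)
  }
  diff <- proteome_differential(
    ds,
    list(genotype = genotype, treatment = treatment, inhibition = "NL"),
    list(genotype = genotype, treatment = treatment, inhibition = "none")
  )
  p <- diff$p_value
  if (params$multiple_testing == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- data.frame(protein = diff$protein, fold_change = diff$fold_change,
                    p_value = p,
                    degraded = diff$fold_change >= params$fc_flux & p < params$alpha,
                    stringsAsFactors = FALSE)
  out
}

degraded_set <- function(calls) calls$protein[calls$degraded]

#' Call CMA substrates by loss of degradation on LAMP2A knockdown
#'
#' A lysosomally degraded protein is a CMA substrate if it is no longer
#' degraded in lysosomes in LAMP2A-knockdown (L2AKD) cells: the set
#' difference `degraded_wt` minus `degraded_l2akd`.
#'
#' @param degraded_wt,degraded_l2akd character vectors of proteins called
#'   degraded in the WT and L2AKD backgrounds (same [flux_params()]).
#' @return Character vector, always a subset of `degraded_wt`.
#' @export
call_cma_substrates <- function(degraded_wt, degraded_l2akd) {
  setdiff(degraded_wt, degraded_l2akd)
}

#' Call drug-sensitive substrates by loss of degradation under treatment
#'
#' A lysosomally degraded protein is drug-sensitive if the compound blocks
#' its degradation: degraded under vehicle but not under drug.
#'
#' @param degraded_vehicle,degraded_drug character vectors of proteins
#'   called degraded under vehicle and drug treatment.
#' @return Character vector, always a subset of `degraded_vehicle`.
#' @export
call_drug_sensitive <- function(degraded_vehicle, degraded_drug) {
  setdiff(degraded_vehicle, degraded_drug)
}

#' Fraction of a protein set, as a percentage
#'
#' Reports `100 * |subset| / |total|` together with the truncated whole
#' percent (the convention used when summarising, e.g., the share of the
#' lysosomally degraded proteome whose degradation a compound blocks).
#' Accepts either character sets or bare counts.
#'
#' @param subset,total character vectors (subset must be contained in
#'   total) or single non-negative counts with `subset <= total`.
#' @return A list with `percent` (exact, 0-100), `whole_percent`
#'   (integer-truncated), `n_subset`, `n_total`.
#' @examples
#' summarize_fraction(316, 833)
#' @export
summarize_fraction <- function(subset, total) {
  if (is.character(subset) || is.character(total)) {
    extra <- setdiff(subset, total)
    if (length(extra)) stop_input("subset contains proteins not in total: ",
                                  paste(head(extra, 5L), collapse = ", "))
    ns <- length(unique(subset)); nt <- length(unique(total))
  } else {
    ns <- as.numeric(subset); nt <- as.numeric(total)
    if (length(ns) != 1L || length(nt) != 1L || ns < 0 || ns > nt) {
      stop_input("counts must satisfy 0 <= subset <= total")
    }
  }
  if (nt == 0) stop_input("total set is empty")
  list(percent = 100 * ns / nt,
       whole_percent = (100 * ns) %/% nt,
       n_subset = ns, n_total = nt)
}

#' Split a differential result into up- and down-regulated sets
#'
#' Level-change thresholding: `up` holds proteins with fold change at least
#' `fc_up` and p below `alpha`; `down` those at or below `fc_down`.  The
#' thresholds come from `params` (proteome default 1.5/0.8); see
#' [de_filter()] for the RNA-seq flavour (1.5/0.5).
#'
#' @param diff a data frame from [proteome_differential()] (columns
#'   `protein`/`fold_change`/`p_value`, or named vectors via [de_filter()]).
#' @param params a [flux_params()].
#' @return A list of character vectors `up` and `down` (always disjoint).
#' @export
level_change_filter <- function(diff, params = flux_params()) {
  p <- diff$p_value
  if (params$multiple_testing == "BH") p <- stats::p.adjust(p, method = "BH")
  list(up = diff$protein[diff$fold_change >= params$fc_up & p < params$alpha],
       down = diff$protein[diff$fold_change <= params$fc_down & p < params$alpha])
}

#' Run the full lysosomal-flux classifier
#'
#' End-to-end pipeline on a raw proteome dataset: preprocessing
#' ([preprocess_proteome()]), downshifted-normal imputation
#' ([impute_missing()]), lysosomal-degradation calls in the WT/vehicle,
#' L2AKD/vehicle and WT/drug backgrounds, and the set-logic classification
#' into CMA substrates and drug-sensitive substrates.
#'
#' @param ds a [proteome_dataset()] (raw or preprocessed).
#' @param params a [flux_params()].
#' @param seed seed for the imputation draws.
#' @return An object of class `flux_call_table`: a data frame with one row
#'   per protein carrying per-contrast fold changes and p-values
#'   (`fc_*`/`p_*` for `wt_vehicle`, `l2akd_vehicle`, `wt_drug` NL-vs-none
#'   contrasts), the three `degraded_*` booleans, and `is_cma_substrate` /
#'   `is_drug_sensitive`.
#' @export
call_flux <- function(ds, params = flux_params(), seed = 1L) {
  stopifnot(inherits(ds, "proteome_dataset"))
  if (!ds$log2) ds <- preprocess_proteome(ds)
  if (anyNA(ds$intensities)) ds <- impute_missing(ds, params, seed)

  wt <- call_lysosomal_degradation(ds, "WT", "vehicle", params)
  kd <- call_lysosomal_degradation(ds, "L2AKD", "vehicle", params)
  dr <- call_lysosomal_degradation(ds, "WT", "drug", params)

  cma <- call_cma_substrates(degraded_set(wt), degraded_set(kd))
  sens <- call_drug_sensitive(degraded_set(wt), degraded_set(dr))

  out <- data.frame(
    protein = wt$protein,
    fc_wt_vehicle = wt$fold_change, p_wt_vehicle = wt$p_value,
    fc_l2akd_vehicle = kd$fold_change, p_l2akd_vehicle = kd$p_value,
    fc_wt_drug = dr$fold_change, p_wt_drug = dr$p_value,
    degraded_wt_vehicle = wt$degraded,
    degraded_l2akd_vehicle = kd$degraded,
    degraded_wt_drug = dr$degraded,
    is_cma_substrate = wt$protein %in% cma,
    is_drug_sensitive = wt$protein %in% sens,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("flux_call_table", "data.frame")
  out
}

#' @export
print.flux_call_table <- function(x, ...) {
  n_deg <- sum(x$degraded_wt_vehicle)
  n_cma <- sum(x$is_cma_substrate)
  n_sens <- sum(x$is_drug_sensitive)
  cat("flux_call_table: ", nrow(x), " proteins\n",
      "  degraded in lysosomes (WT/vehicle): ", n_deg, "\n",
      "  CMA substrates (lost in L2AKD):     ", n_cma, "\n",
      "  drug-sensitive substrates:          ", n_sens, sep = "")
  if (n_deg > 0) {
    fr <- summarize_fraction(n_sens, n_deg)
    cat(" (", round(fr$percent, 1), "% of degraded, ~", fr$whole_percent,
        "%)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Write a flux call table to TSV
#'
#' @param calls a `flux_call_table` from [call_flux()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_flux_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls), path)
}
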