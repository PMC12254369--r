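# Seeded generators producing inputs with the statistical structure the
# analysis modules assume, plus planted ground truth for recovery tests.
# All randomness flows from the single `seed` argument; generators are pure
# functions of their arguments.

new_truth <- function(kind, seed, ...) {
  structure(c(list(kind = kind, seed = seed), list(...)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth (", x$kind, ", seed ", x$seed, ")\n", sep = "")
  str(x[setdiff(names(x), c("kind", "seed"))], max.level = 1,
      give.attr = FALSE)
  invisible(x)
}

#' Serialize / read a synthetic truth object as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path JSON file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the object.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "synthetic_truth")
}

#' Simulate an expression cohort with a planted CMA-score shift
#'
#' Generates a gene-by-sample matrix on the count-like scale in which the
#' CMA-network genes of designated groups are shifted *coherently*: each
#' network gene's log2 mean moves by `direction * score_shift`, so
#' activating genes go up and repressing genes go down, exactly the pattern
#' the transcriptional CMA score is designed to detect.  All other genes
#' are i.i.d. noise around gene-specific baselines.
#'
#' @param n_genes total genes (network genes are included among them).
#' @param n_per_group samples per group.
#' @param groups character vector of group names.
#' @param shifted_groups groups receiving the network shift (default: all
#'   but the first group).
#' @param net a [cma_network()].
#' @param score_shift per-gene log2 shift magnitude (default 1).
#' @param noise_sd log2-scale residual SD (default 0.5).
#' @param baseline_log2_mean,baseline_log2_sd distribution of gene baseline
#'   log2 expression.
#' @param seed integer seed.
#' @return A list with `expr` (matrix, linear scale), `annotations`
#'   (data frame `sample_id`, `group`) and `truth` (a `synthetic_truth`
#'   recording the planted shift).
#' @export
simulate_expression_cohort <- function(n_genes = 2000, n_per_group = 20,
                                       groups = c("control", "shifted"),
                                       shifted_groups = groups[-1L],
                                       net = NULL,
                                       score_shift = 1, noise_sd = 0.5,
                                       baseline_log2_mean = 5,
                                       baseline_log2_sd = 2,
                                       seed = 1L) {
  if (n_genes < 1L || n_per_group < 1L) stop_input("n_genes and n_per_group must be positive")
  if (!is.finite(score_shift)) stop_input("score_shift must be finite")
  if (is.null(net)) {
    net <- read_cma_network(system.file("extdata", "cma_network_example.tsv",
                                        package = "cmaflux"))
  }
  net <- as_cma_network(net)
  if (nrow(net) > n_genes) stop_input("n_genes smaller than the network")
  bad <- setdiff(shifted_groups, groups)
  if (length(bad)) stop_input("shifted_groups not in groups: ", paste(bad, collapse = ", "))

  genes <- c(net$gene, sprintf("GENE%05d", seq_len(n_genes - nrow(net))))
  n_samples <- n_per_group * length(groups)
  group_of <- rep(groups, each = n_per_group)
  samples <- paste0(rep(groups, each = n_per_group), "_",
                    rep(seq_len(n_per_group), times = length(groups)))

  with_seed(seed, {
    base <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    shift <- matrix(0, n_genes, n_samples)
    net_idx <- seq_len(nrow(net))
    in_shifted <- group_of %in% shifted_groups
    shift[net_idx, in_shifted] <- net$direction * score_shift
    log2_vals <- base + shift + matrix(rnorm(n_genes * n_samples, 0, noise_sd),
                                       n_genes, n_samples)
  })
  expr <- 2^log2_vals
  dimnames(expr) <- list(genes, samples)

  list(
    expr = expr,
    annotations = data.frame(sample_id = samples, group = group_of,
                             stringsAsFactors = FALSE),
    truth = new_truth("expression_cohort", seed,
                      network_genes = net$gene,
                      directions = setNames(net$direction, net$gene),
                      shifted_groups = as.character(shifted_groups),
                      score_shift = score_shift, noise_sd = noise_sd,
                      groups = groups, n_per_group = n_per_group)
  )
}

#' Simulate a qPCR Ct table
#'
#' Ct values are generated as housekeeping Ct plus a planted per-gene
#' delta-Ct plus measurement noise, so
#' [relative_expression_from_ct()] should recover `2^-delta_ct` up to
#' noise.
#'
#' @param n_genes number of target genes (housekeeping gene added on top).
#' @param n_samples number of samples.
#' @param housekeeping housekeeping gene symbol.
#' @param hk_ct mean housekeeping Ct (default 20 cycles).
#' @param delta_ct planted per-gene delta-Ct values (recycled); default
#'   draws from Uniform(-2, 4).
#' @param noise_sd Ct measurement noise SD in cycles (default 0.1).
#' @param seed integer seed.
#' @return A list with `ct` (matrix including the housekeeping row) and
#'   `truth` (records the planted `delta_ct`).
#' @export
simulate_ct_table <- function(n_genes = 8, n_samples = 6,
                              housekeeping = "ACTB", hk_ct = 20,
                              delta_ct = NULL, noise_sd = 0.1, seed = 1L) {
  if (n_genes < 1L || n_samples < 1L) stop_input("n_genes and n_samples must be positive")
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  with_seed(seed, {
    if (is.null(delta_ct)) delta_ct <- runif(n_genes, -2, 4)
    delta_ct <- rep_len(delta_ct, n_genes)
    hk_row <- hk_ct + rnorm(n_samples, 0, noise_sd)
    target <- outer(delta_ct, hk_row, `+`) +
      matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
  })
  ct <- rbind(matrix(hk_row, 1L, n_samples), target)
  dimnames(ct) <- list(c(toupper(housekeeping), genes), samples)
  list(ct = ct,
       truth = new_truth("ct_table", seed,
                         housekeeping = toupper(housekeeping),
                         delta_ct = setNames(delta_ct, genes),
                         hk_ct = hk_ct, noise_sd = noise_sd))
}

#' Simulate a lysosomal-flux proteome with planted substrate structure
#'
#' Emulates the flux experiment: a full genotype (WT/L2AKD) x treatment
#' (vehicle/drug) x lysosomal inhibition (none/NL) design with `n_reps`
#' replicates per cell.  A planted fraction of proteins are lysosomal
#' substrates that accumulate `flux_fc`-fold (default 1.5, within the
#' 1.2-1.5-fold range protease inhibition typically produces) under NL; a
#' subset of those are CMA substrates whose NL effect disappears in L2AKD
#' cells; a subset are drug-sensitive, losing the effect under drug
#' treatment (drug-sensitive proteins are drawn from the CMA substrates,
#' as a CMA-selective inhibitor only blocks CMA-dependent degradation).
#' Missingness is missing-not-at-random: the probability of a cell being
#' missing increases logistically as its log2 intensity decreases, with the
#' intercept calibrated so the overall rate equals `missing_rate`.
#'
#' @param n_proteins number of proteins.
#' @param n_reps replicates per design cell (default 3).
#' @param frac_lysosomal fraction of proteins that are lysosomal substrates
#'   (default 0.15).
#' @param frac_cma_of_lysosomal fraction of lysosomal substrates that are
#'   CMA substrates (default 0.40).
#' @param frac_drug_sensitive_of_lysosomal fraction of lysosomal substrates
#'   that are drug-sensitive (default 0.37, echoing the roughly one-third
#'   share a CMA-selective compound blocks; must not exceed
#'   `frac_cma_of_lysosomal`).
#' @param flux_fc linear NL accumulation fold change (> 1).
#' @param noise_sd log2-scale replicate noise SD (default 0.1).
#' @param missing_rate overall fraction of missing cells (default 0.05).
#' @param mnar_strength slope (per SD of log2 intensity) of the logistic
#'   intensity-dependence of missingness; 0 = missing completely at random.
#'   The default 10 gives a 10-90% dropout transition of roughly one log2
#'   unit, mimicking detection-limit censoring in label-free proteomics.
#' @param base_log2_mean,base_log2_sd distribution of protein baseline log2
#'   intensities.
#' @param seed integer seed.
#' @return A list with `dataset` (a raw-intensity [proteome_dataset()]) and
#'   `truth` (planted `lysosomal`, `cma_substrates`, `drug_sensitive` id
#'   sets plus all generator parameters).
#' @export
simulate_proteome <- function(n_proteins = 1000, n_reps = 3,
                              frac_lysosomal = 0.15,
                              frac_cma_of_lysosomal = 0.40,
                              frac_drug_sensitive_of_lysosomal = 0.37,
                              flux_fc = 1.5, noise_sd = 0.1,
                              missing_rate = 0.05, mnar_strength = 10,
                              base_log2_mean = 25, base_log2_sd = 2,
                              seed = 1L) {
  if (n_proteins < 1L || n_reps < 2L) stop_input("need n_proteins >= 1 and n_reps >= 2")
  fr <- c(frac_lysosomal, frac_cma_of_lysosomal, frac_drug_sensitive_of_lysosomal)
  if (any(!is.finite(fr) | fr < 0 | fr > 1)) stop_input("fractions must be in [0, 1]")
  if (frac_drug_sensitive_of_lysosomal > frac_cma_of_lysosomal) {
    stop_input("drug-sensitive fraction cannot exceed the CMA-substrate fraction")
  }
  if (!is.finite(flux_fc) || flux_fc <= 1) stop_input("flux_fc must be > 1")

  proteins <- sprintf("PROT%05d", seq_len(n_proteins))
  design <- expand.grid(replicate = seq_len(n_reps),
                        inhibition = c("none", "NL"),
                        treatment = c("vehicle", "drug"),
                        genotype = c("WT", "L2AKD"),
                        stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "inhibition", "replicate")]
  design$sample <- with(design, paste(genotype, treatment, inhibition, replicate,
                                      sep = "_"))
  rownames(design) <- design$sample
  n_samples <- nrow(design)

  with_seed(seed, {
    n_lys <- round(frac_lysosomal * n_proteins)
    lys <- sort(sample(n_proteins, n_lys))
    n_cma <- round(frac_cma_of_lysosomal * n_lys)
    cma <- sort(sample(lys, n_cma))
    n_sens <- round(frac_drug_sensitive_of_lysosomal * n_lys)
    sens <- sort(sample(cma, min(n_sens, n_cma)))

    base <- rnorm(n_proteins, base_log2_mean, base_log2_sd)
    effect <- matrix(0, n_proteins, n_samples)
    for (j in seq_len(n_samples)) {
      if (design$inhibition[j] != "NL") next
      on <- rep(FALSE, n_proteins)
      on[lys] <- TRUE
      if (design$genotype[j] == "L2AKD") on[cma] <- FALSE
      if (design$treatment[j] == "drug") on[sens] <- FALSE
      effect[on, j] <- log2(flux_fc)
    }
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_proteins * n_samples, 0, noise_sd), n_proteins, n_samples)
    } else 0
    log2_int <- base + effect + noise

    m <- 2^log2_int
    dimnames(m) <- list(proteins, design$sample)
    if (missing_rate > 0) {
      z <- as.vector(scale(as.vector(log2_int)))
      # calibrate the logistic intercept so the mean missing probability
      # equals missing_rate
      f <- function(a) mean(stats::plogis(a - mnar_strength * z)) - missing_rate
      a <- uniroot(f, c(-50, 50))$root
      p_miss <- stats::plogis(a - mnar_strength * z)
      m[runif(length(m)) < p_miss] <- NA_real_
    }
  })

  list(
    dataset = proteome_dataset(m, design),
    truth = new_truth("proteome", seed,
                      lysosomal = proteins[lys],
                      cma_substrates = proteins[cma],
                      drug_sensitive = proteins[sens],
                      flux_fc = flux_fc, noise_sd = noise_sd,
                      missing_rate = missing_rate,
                      mnar_strength = mnar_strength,
                      n_reps = n_reps, n_proteins = n_proteins)
  )
}

#' Simulate a high-content screen plate with planted inhibitors
#'
#' Non-hit compounds share a common mean puncta-per-cell value; planted
#' inhibitors have their mean reduced by the fraction `inhibition_depth`.
#' Replicate noise is Gaussian, so at depth 0 the compound z-scores are a
#' standard normal sample and the expected hit rate at the z < -1 cutoff is
#' the Gaussian tail (about 16%).
#'
#' @param n_compounds number of compounds on the plate (default 94).
#' @param n_inhibitors number of planted inhibitors (default 16).
#' @param inhibition_depth fractional puncta reduction in inhibitors
#'   (default 0.8, i.e. an 80% drop).
#' @param baseline_puncta mean puncta per cell for inactive compounds.
#' @param noise_sd replicate noise SD in puncta units (default 0.5).
#' @param n_reps replicates per compound (default 3).
#' @param seed integer seed.
#' @return A list with `plate` (compound-by-replicate matrix) and `truth`
#'   (planted inhibitor ids).
#' @export
simulate_screen <- function(n_compounds = 94, n_inhibitors = 16,
                            inhibition_depth = 0.8, baseline_puncta = 10,
                            noise_sd = 0.5, n_reps = 3, seed = 1L) {
  if (n_inhibitors >= n_compounds) stop_input("n_inhibitors must be < n_compounds")
  if (inhibition_depth < 0 || inhibition_depth > 1) stop_input("inhibition_depth must be in [0, 1]")
  compounds <- sprintf("CPD%03d", seq_len(n_compounds))
  with_seed(seed, {
    inhib <- sort(sample(n_compounds, n_inhibitors))
    mu <- rep(baseline_puncta, n_compounds)
    mu[inhib] <- baseline_puncta * (1 - inhibition_depth)
    plate <- matrix(rnorm(n_compounds * n_reps, mu, noise_sd),
                    n_compounds, n_reps)
  })
  plate <- pmax(plate, 0)
  dimnames(plate) <- list(compounds, paste0("rep", seq_len(n_reps)))
  list(plate = plate,
       truth = new_truth("screen", seed,
                         inhibitors = compounds[inhib],
                         inhibition_depth = inhibition_depth,
                         baseline_puncta = baseline_puncta,
                         noise_sd = noise_sd, n_reps = n_reps))
}
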