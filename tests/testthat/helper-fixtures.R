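# Shared fixtures and small utilities for the suite.

toy_network <- function() {
  cma_network(c("A", "B", "LAMP2A"), weight = c(1, 1, 2),
              direction = c(1, -1, 1), name = "toy")
}

# Caller controls the RNG state.
random_network <- function(n) {
  cma_network(sprintf("G%03d", seq_len(n)),
              weight = runif(n, 0.5, 3),
              direction = sample(c(-1, 1), n, replace = TRUE))
}

# Rebuild the scoring network recorded in an expression-cohort truth object.
toy_network_from_truth <- function(truth) {
  genes <- truth$network_genes
  cma_network(genes,
              weight = ifelse(genes == "LAMP2A", 2, 1),
              direction = unname(truth$directions[genes]))
}

# Sensitivity/specificity of a called set against a planted truth set.
sens_spec <- function(called, truth_set, universe) {
  pos <- universe %in% truth_set
  c(sens = mean(universe[pos] %in% called),
    spec = mean(!(universe[!pos] %in% called)))
}

# Tiny complete proteome dataset built directly on the log2 scale.
log2_proteome <- function(values, design) {
  proteome_dataset(values, design, log2 = TRUE, normalized = TRUE)
}

# Minimal WT/vehicle design with NL and none arms, n reps each.
mini_design <- function(n_reps = 3, genotype = "WT", treatment = "vehicle") {
  d <- expand.grid(replicate = seq_len(n_reps), inhibition = c("none", "NL"),
                   stringsAsFactors = FALSE)
  d$genotype <- genotype
  d$treatment <- treatment
  d$sample <- paste(genotype, treatment, d$inhibition, d$replicate, sep = "_")
  rownames(d) <- d$sample
  d[, c("genotype", "treatment", "inhibition", "replicate", "sample")]
}
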