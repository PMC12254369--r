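test_that("preprocessing log2-transforms and centres each sample", {
  d <- mini_design(1)[1, , drop = FALSE] # a single sample is fine here
  m <- matrix(c(2, 4, 8), 3, 1, dimnames = list(paste0("P", 1:3), d$sample))
  ds <- preprocess_proteome(proteome_dataset(m, d))
  expect_equal(unname(ds$intensities[, 1]), c(-1, 0, 1))
  expect_true(ds$log2 && ds$normalized)

  # already-centred data pass through unchanged
  again <- preprocess_proteome(ds)
  expect_identical(again$intensities, ds$intensities)

  # missingness pattern is preserved
  m2 <- m; m2[2, 1] <- NA
  ds2 <- preprocess_proteome(proteome_dataset(m2, d))
  expect_identical(is.na(ds2$intensities), is.na(m2))

  m3 <- m; m3[1, 1] <- 0
  expect_error(preprocess_proteome(proteome_dataset(m3, d)),
               "non-positive intensity for protein P1")
})

test_that("dataset construction validates the design", {
  d <- mini_design(2)
  m <- matrix(1, 2, nrow(d), dimnames = list(c("P1", "P2"), d$sample))
  expect_s3_class(proteome_dataset(m, d), "proteome_dataset")

  expect_error(proteome_dataset(m, d[-1, ]), "without a design assignment")
  bad <- d; bad$genotype[1] <- "KO"
  expect_error(proteome_dataset(m, bad), "invalid design values")
})

test_that("imputation only fills missing cells, deterministically per seed", {
  d <- mini_design(3)
  set.seed(5)
  m <- matrix(rnorm(60 * 6, 20, 2), 60, 6,
              dimnames = list(sprintf("P%02d", 1:60), d$sample))
  m[sample(length(m), 40)] <- NA
  ds <- preprocess_proteome(proteome_dataset(m, d))

  i1 <- impute_missing(ds, seed = 7)
  i2 <- impute_missing(ds, seed = 7)
  i3 <- impute_missing(ds, seed = 8)
  expect_identical(i1$intensities, i2$intensities)
  expect_false(identical(i1$intensities, i3$intensities))
  expect_false(anyNA(i1$intensities))
  obs <- !is.na(ds$intensities)
  expect_identical(i1$intensities[obs], ds$intensities[obs])

  # complete data are a no-op
  m_full <- matrix(rexp(60 * 6) + 1, 60, 6,
                   dimnames = dimnames(m))
  full <- preprocess_proteome(proteome_dataset(m_full, d))
  expect_identical(impute_missing(full, seed = 1)$intensities, full$intensities)

  sparse <- ds
  sparse$intensities[-1, 1] <- NA
  expect_error(impute_missing(sparse, seed = 1), "<2 observed")
})

test_that("imputed values follow the downshifted-normal model", {
  d <- mini_design(2) # 4 samples
  set.seed(11)
  m <- matrix(rnorm(3000 * 4, 0, 1), 3000, 4,
              dimnames = list(sprintf("P%04d", 1:3000), paste0("WT_vehicle_",
                rep(c("none", "NL"), each = 2), "_", c(1, 2))))
  colnames(m) <- rownames(d)
  miss <- matrix(runif(length(m)) < 0.3, nrow(m))
  m[miss] <- NA
  ds <- log2_proteome(m, d)
  params <- flux_params(impute_downshift = 2, impute_width = 0.3)
  imp <- impute_missing(ds, params, seed = 3)

  # pooled standardized deviation of imputed cells from mu_s - 2 sigma_s
  devs <- unlist(lapply(seq_len(ncol(m)), function(j) {
    ok <- !is.na(m[, j])
    mu <- mean(m[ok, j]); sig <- sd(m[ok, j])
    (imp$intensities[!ok, j] - (mu - 2 * sig)) / (0.3 * sig)
  }))
  expect_gt(length(devs), 3000)
  expect_lt(abs(mean(devs)), 3 / sqrt(length(devs)))
  expect_equal(sd(devs), 1, tolerance = 0.05)
})

test_that("Welch test matches the closed form and stats::t.test", {
  w <- welch_test(c(10.4, 10.5, 10.3), c(10.0, 10.1, 9.9))
  expect_equal(w$estimate, 0.4, tolerance = 1e-12)
  expect_equal(w$t, 0.4 / (0.1 * sqrt(2 / 3)), tolerance = 1e-9)
  expect_equal(w$p_value, 0.008049893, tolerance = 1e-6)

  # identical groups: no change, p = 1
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)

  # cross-check against the reference implementation on fixed cases
  cases <- list(
    list(a = c(1.2, 1.9, 2.3), b = c(0.1, 0.4, -0.2)),
    list(a = c(5, 6, 7, 8), b = c(5.5, 6.5)),
    list(a = rnorm(10), b = rnorm(12, 1, 3)),
    list(a = c(-1, 0, 1, 2, 3), b = c(10, 11, 12)),
    list(a = c(0.01, 0.02, 0.015), b = c(0.5, 0.1, 0.9, 1.2)),
    list(a = c(100, 101), b = c(99, 102, 100.5))
  )
  set.seed(123)
  for (cs in cases) {
    mine <- welch_test(cs$a, cs$b)
    ref <- t.test(cs$a, cs$b)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  }
})

test_that("differential abundance reports linear fold changes with Welch p", {
  d <- mini_design(3)
  m <- rbind(
    UP = c(10.0, 10.1, 9.9, 10.4, 10.5, 10.3),   # none ..., NL ...
    FLAT = c(10, 10.05, 9.95, 10.02, 9.98, 10.0)
  )
  colnames(m) <- d$sample # none first, NL second
  ds <- log2_proteome(m, d)
  diff <- proteome_differential(ds,
    list(genotype = "WT", treatment = "vehicle", inhibition = "NL"),
    list(genotype = "WT", treatment = "vehicle", inhibition = "none"))
  expect_equal(diff$fold_change[diff$protein == "UP"], 2^0.4, tolerance = 1e-9)
  expect_lt(diff$p_value[diff$protein == "UP"], 0.05)

  expect_error(proteome_differential(ds,
    list(genotype = "L2AKD", treatment = "vehicle", inhibition = "NL"),
    list(genotype = "WT", treatment = "vehicle", inhibition = "none")),
    "<2 replicates")

  withNA <- ds; withNA$intensities[1, 1] <- NA
  expect_error(proteome_differential(withNA,
    list(inhibition = "NL"), list(inhibition = "none")), "impute")
})

test_that("degradation calls require both the 1.2-fold and the p threshold", {
  d <- mini_design(3)
  # exact values, zero noise: FC below threshold is never called however small p is
  m <- rbind(
    JUST_UNDER = c(0, 0, 0, rep(log2(1.19), 3)),
    AT_THRESHOLD = c(0, 0, 0, rep(0.3, 3)),
    STRONG = c(0, 0, 0, rep(log2(1.5), 3))
  )
  colnames(m) <- d$sample
  ds <- log2_proteome(m, d)
  # fc_flux chosen to sit exactly on AT_THRESHOLD's fold change (2^0.3 < 1.5)
  calls <- call_lysosomal_degradation(ds, "WT", "vehicle",
                                      flux_params(fc_flux = 2^0.3))
  got <- setNames(calls$degraded, calls$protein)
  expect_false(got[["JUST_UNDER"]])   # p = 0 but FC 1.19 below threshold
  expect_true(got[["AT_THRESHOLD"]])  # threshold is inclusive
  expect_true(got[["STRONG"]])

  expect_error(call_lysosomal_degradation(ds, "L2AKD", "vehicle"), "NL")
})

test_that("a planted 1.5-fold accumulation at noise 0.1 is called degraded", {
  d <- mini_design(3)
  set.seed(21)
  m <- rbind(SUB = c(rnorm(3, 10, 0.1), rnorm(3, 10 + log2(1.5), 0.1)),
             NULL1 = rnorm(6, 12, 0.1),
             NULL2 = rnorm(6, 8, 0.1))
  colnames(m) <- d$sample
  calls <- call_lysosomal_degradation(log2_proteome(m, d), "WT", "vehicle")
  expect_true(calls$degraded[calls$protein == "SUB"])
})

test_that("substrate set logic is plain set difference with containment", {
  expect_setequal(call_cma_substrates(c("P1", "P2", "P3"), "P2"), c("P1", "P3"))
  expect_length(call_cma_substrates(c("P1", "P2"), c("P1", "P2")), 0)
  expect_length(call_drug_sensitive(c("A"), c("A")), 0)
  set.seed(3)
  wt <- sample(LETTERS, 10)
  kd <- sample(LETTERS, 12)
  expect_true(all(call_cma_substrates(wt, kd) %in% wt))
  expect_true(all(call_drug_sensitive(wt, kd) %in% wt))
})

test_that("fractions are exact with truncated whole percents", {
  fr <- summarize_fraction(316, 833)
  expect_equal(fr$percent, 100 * 316 / 833)
  expect_equal(fr$whole_percent, 37)
  expect_equal(summarize_fraction(c("a", "b"), c("a", "b"))$percent, 100)
  expect_equal(summarize_fraction(character(0), c("a"))$percent, 0)
  expect_error(summarize_fraction(character(0), character(0)), "empty")
  expect_error(summarize_fraction("x", c("a", "b")), "not in total")
  expect_error(summarize_fraction(5, 3), "subset <= total")
})

test_that("level-change filtering splits by the 1.5/0.8 thresholds", {
  diff <- data.frame(protein = c("A", "B", "C"),
                     fold_change = c(1.6, 1.4, 0.4),
                     p_value = c(0.01, 0.001, 0.01))
  f <- level_change_filter(diff, flux_params())
  expect_equal(f$up, "A")
  expect_equal(f$down, "C")

  ns <- diff; ns$p_value <- 0.5
  f2 <- level_change_filter(ns, flux_params())
  expect_length(f2$up, 0); expect_length(f2$down, 0)

  # up and down can never intersect since fc_down < 1 < fc_up
  set.seed(9)
  r <- data.frame(protein = paste0("P", 1:200),
                  fold_change = exp(rnorm(200)), p_value = runif(200))
  fr <- level_change_filter(r, flux_params())
  expect_length(intersect(fr$up, fr$down), 0)
})

test_that("raising the flux threshold never enlarges the degraded set", {
  sim <- simulate_proteome(n_proteins = 200, seed = 31)
  ds <- impute_missing(preprocess_proteome(sim$dataset), seed = 32)
  prev <- NULL
  for (fc in c(1.1, 1.2, 1.35, 1.5)) {
    cur <- call_lysosomal_degradation(ds, "WT", "vehicle",
                                      flux_params(fc_flux = fc))
    cur_set <- cur$protein[cur$degraded]
    if (!is.null(prev)) expect_true(all(cur_set %in% prev))
    prev <- cur_set
  }
})

test_that("the full classifier is deterministic and respects containments", {
  sim <- simulate_proteome(n_proteins = 150, seed = 41)
  t1 <- call_flux(sim$dataset, seed = 5)
  t2 <- call_flux(sim$dataset, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  expect_true(all(t1$protein[t1$is_cma_substrate] %in%
                  t1$protein[t1$degraded_wt_vehicle]))
  expect_true(all(t1$protein[t1$is_drug_sensitive] %in%
                  t1$protein[t1$degraded_wt_vehicle]))
})
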