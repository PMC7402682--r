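mediation_graph <- function(full = TRUE) {
  sem_dag(c("intensity -> zB", "study_type -> zB", "taxon_group -> zB",
            if (full) "zB -> zLD", "intensity -> zLD", "study_type -> zLD"),
          exogenous = c("intensity", "study_type", "taxon_group"))
}

test_that("the d-separation basis set enumerates missing edges with both parent sets", {
  bs <- basis_set(mediation_graph(TRUE))
  expect_equal(nrow(bs), 1)
  expect_equal(bs$x, "taxon_group")
  expect_equal(bs$y, "zLD")
  expect_setequal(bs$conditioning[[1]], c("intensity", "study_type", "zB"))

  bs2 <- basis_set(mediation_graph(FALSE))
  expect_equal(nrow(bs2), 2)
  zb <- bs2[bs2$x == "zB", ]
  expect_equal(zb$y, "zLD")
  expect_setequal(zb$conditioning[[1]],
                  c("intensity", "study_type", "taxon_group"))

  # saturated two-node graph: nothing to test
  expect_equal(nrow(basis_set(sem_dag("a -> b", exogenous = "a"))), 0)
  expect_error(sem_dag(c("a -> b", "b -> a")), class = "befmeta_cyclic")
})

test_that("Fisher's C combines claim p-values with 2k degrees of freedom", {
  expect_equal(fishers_c(1), list(C = 0, df = 2, p = 1))
  fc <- fishers_c(c(0.05, 0.05))
  expect_equal(fc$C, -4 * log(0.05), tolerance = 1e-8)
  expect_equal(fc$C, 11.983, tolerance = 1e-3)
  expect_equal(fc$df, 4)
  expect_equal(fc$p, pchisq(fc$C, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(fc$p, 0.0175, tolerance = 1e-2)
  # monotone: smaller p, larger C
  expect_gt(fishers_c(c(0.01, 0.05))$C, fc$C)
  expect_error(fishers_c(c(0, 0.5)), class = "befmeta_degenerate")
})

test_that("Fisher's C over uniform p-values follows its chi-square reference", {
  set.seed(21)
  k <- 3
  C <- -2 * colSums(log(matrix(runif(k * 5000), k)))
  ks <- stats::ks.test(C, stats::pchisq, df = 2 * k)
  expect_gt(ks$p.value, 0.01)
})

test_that("stratified resampling keeps one uniform draw per measurement", {
  paired <- tibble::tibble(link_key = c("a", "a", "a", "b"),
                           obs_id_B = c("x1", "x2", "x3", "y1"))
  one <- stratified_resample(paired, seed = 5)
  expect_equal(nrow(one), 2)
  expect_equal(sort(unique(one$link_key)), c("a", "b"))
  expect_identical(one, stratified_resample(paired, seed = 5))

  # no duplicates: identity for any seed
  nodup <- tibble::tibble(link_key = c("a", "b", "c"), obs_id_B = 1:3)
  expect_identical(stratified_resample(nodup, seed = 1)$obs_id_B, nodup$obs_id_B)

  set.seed(77)
  picks <- replicate(1e4, stratified_resample(paired)$obs_id_B[1])
  freq <- table(picks) / 1e4
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  expect_error(stratified_resample(paired[0, ]))
})

test_that("sub-models recover a null biodiversity path and flag degenerate designs", {
  hits <- logical(40)
  for (r in seq_len(40)) {
    cfg <- sem_config(n_studies = 40, path_b = 0, seed = 300 + r,
                      dup_range = c(1L, 1L))
    d <- split_datasets(simulate_effect_table(cfg)$observations)$stressor_diversity
    f <- fit_submodels(d, kind = "diversity")
    est <- f$zLD$coefficients[["zB"]]
    hits[r] <- abs(est) < 2 * f$zLD$se[["zB"]]
  }
  expect_gte(mean(hits), 0.9)

  d <- split_datasets(simulate_effect_table(sem_config(seed = 1))$observations)$stressor_diversity
  d$intensity <- 1
  expect_error(fit_submodels(d, kind = "diversity"), "intensity",
               class = "befmeta_rank")
})

test_that("the biodiversity path is recovered when sampling noise is negligible", {
  covered <- logical(30)
  for (r in seq_len(30)) {
    cfg <- sem_config(n_studies = 60, path_b = 0.5, seed = 500 + r,
                      dup_range = c(1L, 1L), sigma_obs = 0.3,
                      n_obs_range = c(1000L, 2000L))
    d <- split_datasets(simulate_effect_table(cfg)$observations)$stressor_diversity
    f <- fit_submodels(d, kind = "diversity")$zLD
    covered[r] <- abs(f$coefficients[["zB"]] - 0.5) < 2 * f$se[["zB"]]
  }
  expect_gte(mean(covered), 0.85)
})

test_that("without duplicates the resampled SEM equals the single deterministic fit", {
  cfg <- sem_config(n_studies = 30, seed = 4, dup_range = c(1L, 1L))
  d <- split_datasets(simulate_effect_table(cfg)$observations)$stressor_diversity
  s1 <- run_resampled_sem(d, "diversity", iterations = 3, seed = 1)
  s2 <- run_resampled_sem(d, "diversity", iterations = 7, seed = 99)
  expect_equal(s1$paths$estimate, s2$paths$estimate, tolerance = 1e-4)
  expect_equal(s1$fisher_C, s2$fisher_C, tolerance = 1e-3)

  fits <- fit_submodels(d, kind = "diversity")
  i <- which(s1$paths$from == "zB" & s1$paths$to == "zLD")
  expect_equal(unname(s1$paths$estimate[i]), fits$zLD$coefficients[["zB"]],
               tolerance = 1e-3)
  expect_equal(s1$AIC, fits$zB$AIC_ML + fits$zLD$AIC_ML, tolerance = 1e-4)
})

test_that("resampling averages stabilise across seeds", {
  cfg <- sem_config(n_studies = 50, seed = 6, dup_range = c(2L, 4L))
  d <- split_datasets(simulate_effect_table(cfg)$observations)$stressor_diversity
  sa <- run_resampled_sem(d, "diversity", iterations = 300, seed = 1)
  sb <- run_resampled_sem(d, "diversity", iterations = 300, seed = 2)
  i <- which(sa$paths$from == "zB")
  expect_lt(abs(sa$paths$estimate[i] - sb$paths$estimate[i]),
            0.5 * sa$paths$se[i])
})

test_that("the mediation rule combines poor reduced fit with the AIC guard", {
  fake <- function(C_p, AIC, full = TRUE) {
    structure(list(C_p = C_p, AIC = AIC,
                   dag = mediation_dag("diversity", full),
                   data_hash = "h"), class = "sem_result")
  }
  expect_true(mediation_test(fake(0.2, 100), fake(0.01, 105, FALSE))$supported)
  r1 <- mediation_test(fake(0.2, 100), fake(0.5, 105, FALSE))
  expect_false(r1$supported)
  expect_false(r1$poor_reduced_fit)
  r2 <- mediation_test(fake(0.2, 100), fake(0.01, 97, FALSE))
  expect_false(r2$supported)
  expect_true(r2$criterion_conflict)

  bad <- fake(0.01, 105, FALSE); bad$data_hash <- "other"
  expect_error(mediation_test(fake(0.2, 100), bad), "different data")
  expect_error(mediation_test(fake(0.2, 100), fake(0.01, 105, TRUE)),
               "zB -> zLD")
})

test_that("path standardization and indirect effects follow their definitions", {
  expect_equal(standardize_path(0.42, 1, 1), 0.42)
  expect_equal(standardize_path(0.42, 0.8, 1), 0.336, tolerance = 1e-12)
  expect_equal(sign(standardize_path(-2, 0.3, 0.7)), -1)
  expect_error(standardize_path(1, 0, 1))
  expect_equal(indirect_effect(-0.3, 0.4), -0.12, tolerance = 1e-12)
  expect_equal(indirect_effect(0, 0.9), 0)
})

test_that("the full-graph C p-value is calibrated on correctly specified data", {
  rej <- logical(200)
  for (r in seq_len(200)) {
    cfg <- sem_config(n_studies = 40, path_b = 0.3, seed = 4000 + r,
                      dup_range = c(1L, 1L))
    d <- split_datasets(simulate_effect_table(cfg)$observations)$stressor_diversity
    s <- run_resampled_sem(d, "diversity", iterations = 1, seed = r)
    rej[r] <- s$C_p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("sem results expose tidy, glance and autoplot interfaces", {
  cfg <- sem_config(n_studies = 25, seed = 2)
  d <- split_datasets(simulate_effect_table(cfg)$observations)$stressor_diversity
  s <- run_resampled_sem(d, "diversity", iterations = 5, seed = 3)
  td <- tidy(s)
  expect_true(all(c("from", "to", "estimate", "std_error", "std_estimate")
                  %in% names(td)))
  gl <- glance(s)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("fisher_C", "C_p", "AIC", "indirect_effect")
                  %in% names(gl)))
  expect_equal(gl$n_failed, 0)
  expect_s3_class(autoplot(s), "ggplot")
  # indirect effect is the product of the two averaged standardized paths
  a <- td$std_estimate[td$from == "intensity" & td$to == "zB"]
  b <- td$std_estimate[td$from == "zB" & td$to == "zLD"]
  expect_equal(gl$indirect_effect, a * b, tolerance = 1e-12)
})
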