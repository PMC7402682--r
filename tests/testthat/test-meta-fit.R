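test_that("with variance components fixed at zero the fit is the inverse-variance weighted mean", {
  d <- data.frame(z = c(0.2, 0.6), var_z = c(0.04, 0.01),
                  case_study_id = c("a", "b"))
  f <- fit_meta(d, z ~ 1, sigma2_fixed = 0)
  expect_equal(unname(f$coefficients), 0.52, tolerance = 1e-8)
  expect_equal(unname(f$se), sqrt(1 / 125), tolerance = 1e-8)

  set.seed(4)
  for (i in 1:20) {
    k <- sample(5:30, 1)
    v <- runif(k, 0.01, 0.5)
    y <- rnorm(k)
    x <- runif(k)
    dd <- data.frame(z = y, var_z = v, case_study_id = seq_len(k), x = x)
    f <- fit_meta(dd, z ~ x, sigma2_fixed = 0)
    X <- cbind(1, x)
    W <- diag(1 / v)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("identical effects give zero heterogeneity and that common value", {
  d <- data.frame(z = rep(0.31, 8), var_z = runif(8, 0.02, 0.2),
                  case_study_id = letters[1:8])
  f <- fit_meta(d, z ~ 1)
  expect_lt(f$sigma2[["study"]], 1e-6)
  expect_equal(unname(f$coefficients), 0.31, tolerance = 1e-8)
})

test_that("REML heterogeneity matches a dense-matrix grid search oracle", {
  set.seed(11)
  for (i in 1:3) {
    ns <- sample(6:10, 1)
    study <- rep(seq_len(ns), each = 2)
    v <- runif(2 * ns, 0.02, 0.2)
    y <- 0.2 + rnorm(ns, 0, 0.4)[study] + rnorm(2 * ns, 0, sqrt(v))
    d <- data.frame(z = y, var_z = v, case_study_id = study)
    f <- fit_meta(d, z ~ 1)
    grid <- seq(0, 2, by = 1e-3)
    Xmat <- matrix(1, length(y))
    ll <- vapply(grid, function(t2) dense_reml_ll(t2, y, Xmat, v, study), 0)
    expect_lt(abs(f$sigma2[["study"]] - grid[which.max(ll)]), 2e-3)
  }
})

test_that("estimates agree with metafor on nested multilevel fits", {
  skip_if_not_installed("metafor")
  set.seed(42)
  k <- 60
  study <- rep(1:15, each = 4)
  v <- runif(k, 0.02, 0.2)
  y <- 0.3 - 0.2 * (study %% 2) + rnorm(15, 0, 0.3)[study] +
    rnorm(k, 0, sqrt(v))
  x <- runif(k)
  d <- data.frame(z = y, var_z = v, case_study_id = study, x = x, obs_id = 1:k)

  f1 <- fit_meta(d, z ~ x)
  m1 <- metafor::rma.mv(z, var_z, mods = ~ x, random = ~ 1 | case_study_id,
                        data = d, method = "REML")
  expect_equal(unname(f1$coefficients), as.numeric(coef(m1)), tolerance = 1e-5)
  expect_equal(f1$sigma2[["study"]], m1$sigma2, tolerance = 1e-4)

  f2 <- fit_meta(d, z ~ x, obs = "obs_id")
  m2 <- metafor::rma.mv(z, var_z, mods = ~ x,
                        random = ~ 1 | case_study_id / obs_id,
                        data = d, method = "REML")
  expect_equal(unname(f2$coefficients), as.numeric(coef(m2)), tolerance = 1e-5)
  expect_equal(unname(f2$sigma2), m2$sigma2, tolerance = 1e-4)
  expect_equal(unname(f2$se), as.numeric(m2$se), tolerance = 1e-5)
  expect_equal(f2$QM, m2$QM, tolerance = 1e-4)

  m3 <- metafor::rma.mv(z, var_z, mods = ~ x,
                        random = ~ 1 | case_study_id / obs_id,
                        data = d, method = "ML")
  expect_equal(f2$AIC_ML, as.numeric(stats::AIC(m3)), tolerance = 1e-4)
})

test_that("the pooled mean covers the truth at close to the nominal rate", {
  covered <- logical(60)
  for (r in seq_len(60)) {
    cfg <- truth_config(n_studies = 120, driver_mix = 1,
                        mu_diversity = c(stressor = -0.3, nutrient = 0),
                        mu_abundance = c(stressor = -0.3, nutrient = 0),
                        beta_intensity = c(stressor = 0, nutrient = 0),
                        tau_study = 0.2, obs_per_study_range = c(2L, 4L),
                        seed = 1000 + r)
    obs <- simulate_effect_table(cfg)$observations
    obs <- obs[obs$response != "decomposition", ]
    f <- fit_meta(obs, z ~ 1)
    est <- unname(f$coefficients)
    covered[r] <- abs(est + 0.3) < 2 * unname(f$se)
  }
  expect_gte(mean(covered), 0.9)
})

test_that("adding a constant to all effects shifts only the intercept", {
  set.seed(7)
  k <- 40
  d <- data.frame(z = rnorm(k), var_z = runif(k, 0.05, 0.3),
                  case_study_id = rep(1:10, 4), x = runif(k))
  f0 <- fit_meta(d, z ~ x)
  d$z <- d$z + 0.7
  f1 <- fit_meta(d, z ~ x)
  expect_equal(f1$coefficients[["(Intercept)"]],
               f0$coefficients[["(Intercept)"]] + 0.7, tolerance = 1e-6)
  expect_equal(f1$coefficients[["x"]], f0$coefficients[["x"]],
               tolerance = 1e-6)
})

test_that("rank-deficient designs fail naming the aliased term", {
  d <- data.frame(z = rnorm(10), var_z = 0.1, case_study_id = 1:10,
                  x = 1:10, y = 2 * (1:10))
  expect_error(fit_meta(d, z ~ x + y), "aliased.*y", class = "befmeta_rank")
})

test_that("the moderator Wald test matches its closed form and keeps its size", {
  d <- data.frame(z = c(0.2, 0.6), var_z = c(0.04, 0.01),
                  case_study_id = c("a", "b"))
  f <- fit_meta(d, z ~ 1, sigma2_fixed = 0)
  qm <- wald_qm(f)
  expect_equal(qm$QM, (0.52 / sqrt(1 / 125))^2, tolerance = 1e-6)
  expect_equal(qm$QM, 33.8, tolerance = 1e-2)
  expect_equal(qm$df, 1)

  # type-I error of the moderator test under a null moderator
  set.seed(99)
  rej <- logical(600)
  for (r in seq_len(600)) {
    study <- rep(1:40, each = 1)
    v <- runif(40, 0.02, 0.2)
    d <- data.frame(z = rnorm(40, 0, sqrt(0.04 + v)), var_z = v,
                    case_study_id = study, x = rnorm(40))
    rej[r] <- fit_meta(d, z ~ x)$QM_p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("grand means are coefficient combinations with dual CI/p behaviour", {
  set.seed(13)
  k <- 60
  drv <- rep(c("nutrient", "stressor"), each = k / 2)
  d <- data.frame(z = rnorm(k, ifelse(drv == "stressor", -0.4, 0), 0.2),
                  var_z = runif(k, 0.03, 0.2),
                  case_study_id = rep(1:20, 3), driver = drv)
  f <- fit_meta(d, z ~ driver)
  gm <- grand_means(f)
  expect_equal(gm$group, c("nutrient", "stressor"))
  expect_equal(gm$estimate[1], f$coefficients[["(Intercept)"]])
  expect_equal(gm$estimate[2],
               sum(f$coefficients), tolerance = 1e-10)
  expect_equal(gm$ci_high - gm$estimate, 1.96 * gm$se, tolerance = 1e-3)
  expect_equal((gm$p < 0.05), gm$ci_low > 0 | gm$ci_high < 0)
})

test_that("Egger regression is null on a symmetric funnel and guards inputs", {
  se_i <- seq(0.1, 0.5, length.out = 20)
  eff <- data.frame(z = 0.3, var_z = se_i^2)  # z/SE exactly linear in 1/SE
  eg <- suppressWarnings(egger_test(eff))
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(eg$df, 18)
  expect_error(egger_test(eff[1:2, ]))
  expect_error(egger_test(data.frame(z = rnorm(5), var_z = 0.04)))
})

test_that("funnel data extracts rows and driver groups unchanged", {
  eff <- data.frame(z = rnorm(7), var_z = runif(7, 0.01, 0.2),
                    driver = rep(c("stressor", "nutrient"), c(4, 3)))
  fd <- funnel_data(eff)
  expect_equal(nrow(fd), 7)
  expect_equal(fd$se, sqrt(eff$var_z))
  expect_setequal(unique(fd$group), c("stressor", "nutrient"))
  expect_error(funnel_data(eff[0, ]))
})

test_that("tidy and glance return the documented one-row-per-term layouts", {
  d <- data.frame(z = rnorm(20), var_z = runif(20, 0.05, 0.2),
                  case_study_id = rep(1:5, 4), x = runif(20))
  f <- fit_meta(d, z ~ x)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_true(all(c("estimate", "std_error", "conf_low", "conf_high",
                    "p_value") %in% names(td)))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("tau2_study", "QM", "AIC_ML", "nobs") %in% names(gl)))
  expect_s3_class(autoplot(f), "ggplot")
})
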