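test_that("Hedges' d chain reproduces the hand-computed worked example", {
  hd <- hedges_d(2, 1, 10, 1, 1, 10)
  expect_equal(hd$d, (1 - 3 / 71) * 1, tolerance = 1e-12)
  expect_equal(hd$d, 0.9577, tolerance = 1e-4)
  expect_equal(hd$var_d, 20 / 100 + hd$d^2 / 40, tolerance = 1e-12)

  r <- d_to_r(hd$d, 10, 10)
  expect_equal(r, hd$d / sqrt(hd$d^2 + 4), tolerance = 1e-12)
  expect_equal(r, 0.4319, tolerance = 1e-4)

  z <- fisher_z(r)
  expect_equal(z, 0.46224, tolerance = 1e-4)
  expect_equal(var_z(20), 1 / 17)
})

test_that("Hedges' d is null at equal means, antisymmetric, and guards degenerate SDs", {
  expect_equal(hedges_d(3, 1, 8, 3, 1, 8)$d, 0)
  a <- hedges_d(2.3, 1.1, 7, 1.2, 0.8, 9)
  b <- hedges_d(1.2, 0.8, 9, 2.3, 1.1, 7)
  expect_equal(a$d, -b$d, tolerance = 1e-12)
  expect_error(hedges_d(2, 0, 5, 1, 0, 5), class = "befmeta_degenerate")
})

test_that("d-to-r conversion is null-preserving, bounded, and monotone", {
  expect_equal(d_to_r(0, 10, 10), 0)
  ds <- seq(-5, 5, by = 0.25)
  rs <- vapply(ds, d_to_r, 0, n_t = 7, n_c = 12)
  expect_true(all(abs(rs) < 1))
  expect_true(all(diff(rs) > 0))
})

test_that("gradient correlations match hand Pearson computations", {
  expect_equal(gradient_r(1:4, c(4, 3, 2, 1)), -1)
  expect_equal(gradient_r(0:3, c(1, 2, 2, 3)), 3 / sqrt(10), tolerance = 1e-12)
  expect_error(gradient_r(1:4, rep(2, 4)), class = "befmeta_degenerate")
  expect_error(gradient_r(1:3, c(1, 2, 3)), class = "befmeta_degenerate")
})

test_that("Fisher z transform is odd, invertible, and clips |r| >= 0.999", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
  expect_equal(z1, atanh(0.999))
})

test_that("var_z is 1/(n-3), decreasing, and rejects n below 4", {
  expect_equal(var_z(4), 1)
  expect_equal(var_z(20), 1 / 17, tolerance = 1e-12)
  expect_true(all(diff(var_z(4:50)) < 0))
  expect_error(var_z(3))
})

test_that("mass loss converts to exponential decay rates", {
  expect_equal(mass_loss_to_k(1, 5), 0)
  expect_equal(mass_loss_to_k(exp(-1), 1), 1, tolerance = 1e-12)
  expect_equal(mass_loss_to_k(0.5, 2), log(2) / 2, tolerance = 1e-12)
  expect_error(mass_loss_to_k(0, 1))
  expect_error(mass_loss_to_k(1.2, 1))
})

test_that("SD approximation fits the mean-SD line and guards its preconditions", {
  expect_equal(approximate_sd(4, c(1, 2, 3), c(0.1, 0.2, 0.3)), 0.4,
               tolerance = 1e-10)
  expect_equal(approximate_sd(c(10, 20), c(1, 5, 9), c(2, 2, 2)), c(2, 2),
               tolerance = 1e-10)
  expect_error(approximate_sd(4, c(1, 2), c(0.1, 0.2)),
               class = "befmeta_degenerate")
  expect_error(approximate_sd(4, c(2, 2, 2), c(0.1, 0.2, 0.3)),
               class = "befmeta_degenerate")
})

test_that("log response ratios are ln ratios with delta-method variances", {
  lr <- log_response_ratio(2, 0.5, 10, 1, 0.4, 12)
  expect_equal(lr$lnRR, log(2), tolerance = 1e-12)
  expect_equal(lr$var_lnRR, 0.25 / (10 * 4) + 0.16 / 12, tolerance = 1e-12)
  expect_equal(log_response_ratio(3, 1, 5, 3, 1, 5)$lnRR, 0)
  expect_equal(log_response_ratio(1, 0.4, 12, 2, 0.5, 10)$lnRR, -lr$lnRR)
  expect_error(log_response_ratio(-1, 1, 5, 2, 1, 5),
               class = "befmeta_degenerate")
})

test_that("build_effect_table chains the worked example end to end", {
  rec <- ct_record(1, 1, 10, 2, 1, 10)
  tab <- build_effect_table(rec)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$z, 0.46224, tolerance = 1e-4)
  expect_equal(tab$var_z, 1 / 17, tolerance = 1e-12)
  expect_equal(tab$n_eff, 20)
  expect_equal(tab$method, "hedges_chain")
  expect_false(tab$direction_flipped)
})

test_that("mass_remaining responses are sign-flipped to the common direction", {
  rec <- ct_record(1, 1, 10, 2, 1, 10, response = "decomposition",
                   decomposition_metric = "mass_remaining")
  tab <- build_effect_table(rec)
  expect_true(tab$direction_flipped)
  expect_equal(tab$z, -0.46224, tolerance = 1e-4)
})

test_that("empty input, multi-time-point, and failing records are handled", {
  expect_equal(nrow(build_effect_table(ct_record(1, 1, 10, 2, 1, 10)[0, ])), 0)

  # only the last time point is retained
  rec <- dplyr::bind_rows(
    dplyr::mutate(ct_record(1, 1, 10, 5, 1, 10), time_point = 1),
    dplyr::mutate(ct_record(1, 1, 10, 2, 1, 10), time_point = 2))
  tab <- build_effect_table(rec)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$z, 0.46224, tolerance = 1e-4)

  # degenerate record excluded with a reason, batch not aborted
  bad <- dplyr::mutate(ct_record(1, 0, 10, 2, 0, 10, obs_id = "bad"),
                       link_key = "l2")
  tab2 <- build_effect_table(dplyr::bind_rows(ct_record(1, 1, 10, 2, 1, 10), bad))
  expect_equal(nrow(tab2), 1)
  excl <- attr(tab2, "exclusions")
  expect_equal(excl$obs_id, "bad")
  expect_match(excl$reason, "Pooled")
})

test_that("missing SDs are imputed from the mean-SD regression and flagged", {
  known <- dplyr::bind_rows(lapply(1:4, function(i)
    ct_record(i, 0.1 * i, 10, i + 1, 0.1 * (i + 1), 10,
              obs_id = paste0("k", i))))
  miss <- ct_record(2, NA, 10, 3, NA, 10, obs_id = "m1")
  tab <- build_effect_table(dplyr::bind_rows(known, miss))
  expect_equal(nrow(tab), 5)
  expect_true(tab$sd_approximated[tab$obs_id == "m1"])
  expect_false(any(tab$sd_approximated[tab$obs_id != "m1"]))
})

test_that("the lnRR metric uses control-treatment records only", {
  ct <- ct_record(1, 0.5, 10, 2, 0.5, 10)
  grad <- tibble::tibble(
    obs_id = "g1", case_study_id = "s1", publication_id = "p1",
    driver = "stressor", design = "gradient", response = "diversity",
    taxon_group = "animal", diversity_metric = "richness",
    study_type = "experimental", decomposition_metric = "not_applicable",
    link_key = "l9", group = NA_character_, concentration = c(1, 2, 3, 4),
    mean = c(1, 2, 2, 3), sd = 1, n = 5)
  tab <- build_effect_table(dplyr::bind_rows(ct, grad), effect_metric = "lnRR")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$method, "lnRR")
  expect_equal(tab$z, log(2), tolerance = 1e-12)
  expect_equal(attr(tab, "exclusions")$obs_id, "g1")
})
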