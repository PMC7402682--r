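# Shared fixture builders: small synthetic configurations used across tests.

# A quiet, all-null generator: no true effects, no heterogeneity.
null_config <- function(n_studies = 50, seed = 1, ...) {
  truth_config(n_studies = n_studies,
               mu_diversity = c(stressor = 0, nutrient = 0),
               mu_abundance = c(stressor = 0, nutrient = 0),
               beta_intensity = c(stressor = 0, nutrient = 0),
               path_b = 0, path_direct = 0,
               tau_study = 0, sigma_obs = 0, seed = seed, ...)
}

# A single-dataset (stressor, diversity-only) configuration for SEM tests.
sem_config <- function(n_studies = 80, path_b = 0.5, seed = 1, ...) {
  truth_config(n_studies = n_studies, driver_mix = 1, path_b = path_b,
               moderator_probs = list(
                 study_type = c(experimental = 0.5, observational = 0.5),
                 taxon_group = c(animal = 0.77, microbe = 0.23),
                 diversity_metric = c(richness = 0.6, diversity_index = 0.4),
                 response = c(diversity = 1, abundance = 0)),
               seed = seed, ...)
}

# One control-treatment observation in the long raw-record format.
ct_record <- function(mean_c, sd_c, n_c, mean_t, sd_t, n_t,
                      obs_id = "o1", response = "diversity",
                      decomposition_metric = "not_applicable") {
  tibble::tibble(
    obs_id = obs_id, case_study_id = "s1", publication_id = "p1",
    driver = "stressor", design = "control_treatment", response = response,
    taxon_group = "animal", diversity_metric = "richness",
    study_type = "experimental", decomposition_metric = decomposition_metric,
    link_key = "l1", group = c("control", "treatment"),
    concentration = NA_real_, mean = c(mean_c, mean_t),
    sd = c(sd_c, sd_t), n = c(n_c, n_t))
}

# Dense-matrix REML log-likelihood: an implementation-independent oracle that
# builds the full marginal covariance V = tau2 * ZZ' + diag(v) explicitly.
dense_reml_ll <- function(tau2, y, X, v, study) {
  Z <- stats::model.matrix(~ 0 + factor(study))
  V <- tau2 * tcrossprod(Z) + diag(v)
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
                       determinant(XtViX)$modulus + t(r) %*% Vi %*% r))
}
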