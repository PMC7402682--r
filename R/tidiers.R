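#' Tidy a multilevel meta-analysis fit
#'
#' @param x A [fit_meta()] object.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @method tidy meta_fit
#' @export
tidy.meta_fit <- function(x, conf_level = 0.95, ...) {
  zc <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  tibble::tibble(term = names(est), estimate = unname(est),
                 std_error = unname(x$se),
                 statistic = unname(est / x$se),
                 p_value = 2 * pnorm(-abs(unname(est / x$se))),
                 conf_low = unname(est - zc * x$se),
                 conf_high = unname(est + zc * x$se))
}

#' Glance at a multilevel meta-analysis fit
#'
#' @param x A [fit_meta()] object.
#' @param ... Unused.
#' @return A one-row tibble: variance components, QM test, log-likelihood,
#'   ML AIC, sample sizes.
#' @method glance meta_fit
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(tau2_study = x$sigma2[["study"]],
                 sigma2_obs = if ("observation" %in% names(x$sigma2))
                   x$sigma2[["observation"]] else NA_real_,
                 QM = x$QM %||% NA_real_, QM_df = x$QM_df %||% NA_integer_,
                 QM_p = x$QM_p %||% NA_real_,
                 logLik = x$loglik, AIC_ML = x$AIC_ML,
                 nobs = x$n, n_studies = x$n_studies, method = x$method)
}

#' Tidy a resampled piecewise SEM
#'
#' @param x A [run_resampled_sem()] result.
#' @param ... Unused.
#' @return A tibble of averaged paths: `from`, `to`, `estimate`, `std_error`,
#'   `std_estimate`.
#' @method tidy sem_result
#' @export
tidy.sem_result <- function(x, ...) {
  dplyr::rename(x$paths, std_error = "se")
}

#' Glance at a resampled piecewise SEM
#'
#' @param x A [run_resampled_sem()] result.
#' @param ... Unused.
#' @return A one-row tibble: Fisher's C, its df and p-value, the averaged
#'   AIC, indirect and direct effects, and iteration counts.
#' @method glance sem_result
#' @export
glance.sem_result <- function(x, ...) {
  tibble::tibble(fisher_C = x$fisher_C, C_df = x$C_df, C_p = x$C_p,
                 AIC = x$AIC, indirect_effect = x$indirect_effect,
                 direct_effect = x$direct_effect,
                 n_measurements = x$n_measurements, n_studies = x$n_studies,
                 n_iterations = x$n_iterations, n_failed = x$n_failed)
}
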