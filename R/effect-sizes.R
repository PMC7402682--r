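#' Hedges' d standardized mean difference
#'
#' Small-sample-corrected standardized mean difference between a treatment and
#' a control group, with its large-sample sampling variance.  The correction
#' factor is J = 1 - 3 / (4(n_t + n_c - 2) - 1).
#'
#' @param mean_t,mean_c Group means.
#' @param sd_t,sd_c Group standard deviations (>= 0).
#' @param n_t,n_c Group sample sizes (>= 2).
#'
#' @return A named list with `d` and `var_d`.
#' @examples
#' hedges_d(2, 1, 10, 1, 1, 10)
#' @export
hedges_d <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  stopifnot(n_t >= 2, n_c >= 2, sd_t >= 0, sd_c >= 0)
  df <- n_t + n_c - 2
  s_pooled <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / df)
  if (!is.finite(s_pooled) || s_pooled <= 0) {
    abort("Pooled standard deviation is zero: standardized difference undefined.",
          class = "befmeta_degenerate")
  }
  j <- 1 - 3 / (4 * df - 1)
  d <- j * (mean_t - mean_c) / s_pooled
  var_d <- (n_t + n_c) / (n_t * n_c) + d^2 / (2 * (n_t + n_c))
  list(d = d, var_d = var_d)
}

#' Convert a standardized mean difference to a correlation coefficient
#'
#' Uses r = d / sqrt(d^2 + a) with a = (n_t + n_c)^2 / (n_t n_c), the
#' group-size correction for unequal groups (a = 4 when n_t = n_c).
#'
#' @param d Standardized mean difference.
#' @param n_t,n_c Group sample sizes.
#' @return Correlation coefficient, strictly inside (-1, 1).
#' @examples
#' d_to_r(0.9577, 10, 10)
#' @export
d_to_r <- function(d, n_t, n_c) {
  stopifnot(is.finite(d), n_t >= 2, n_c >= 2)
  a <- (n_t + n_c)^2 / (n_t * n_c)
  d / sqrt(d^2 + a)
}

#' Pearson correlation along a concentration gradient
#'
#' For gradient studies reporting mean outcomes at four or more driver
#' concentrations, the effect size is the Pearson correlation between the
#' level-wise outcome means and the concentrations.
#'
#' @param levels Numeric vector of concentrations (>= 4 values).
#' @param means Numeric vector of outcome means, same length.
#' @return Pearson correlation in \[-1, 1\].
#' @export
gradient_r <- function(levels, means) {
  stopifnot(length(levels) == length(means))
  if (length(levels) < 4) {
    abort("Gradient studies need at least 4 treatment levels.",
          class = "befmeta_degenerate")
  }
  if (sd(levels) == 0 || sd(means) == 0) {
    abort("Correlation undefined: constant concentrations or constant means.",
          class = "befmeta_degenerate")
  }
  stats::cor(levels, means)
}

#' Fisher z transformation
#'
#' z = atanh(r) = log((1 + r) / (1 - r)) / 2.  Correlations at or beyond
#' +/-0.999 in magnitude are clipped to +/-0.999 with a warning, so that
#' perfectly collinear gradients yield a large finite effect rather than an
#' infinite one.
#'
#' @param r Correlation coefficient(s).
#' @return z-transformed value(s).
#' @export
fisher_z <- function(r) {
  clip <- 0.999
  out_of_range <- abs(r) >= clip
  if (any(out_of_range)) {
    warn(sprintf("%d correlation(s) with |r| >= %.3f clipped before atanh.",
                 sum(out_of_range), clip))
    r <- pmin(pmax(r, -clip), clip)
  }
  atanh(r)
}

#' Sampling variance of a Fisher-z effect size
#'
#' @param n_eff Effective sample size (>= 4): total n for control-treatment
#'   chains, number of levels for gradient correlations.
#' @return 1 / (n_eff - 3).
#' @export
var_z <- function(n_eff) {
  if (any(n_eff < 4)) {
    abort("Effective sample size must be at least 4 for var(z) = 1/(n-3).")
  }
  1 / (n_eff - 3)
}

#' Convert litter mass loss to an exponential decay rate
#'
#' k = -log(fraction_remaining) / time, the decay constant of the
#' single-exponential litter mass loss model.
#'
#' @param fraction_remaining Proportion of initial litter mass remaining,
#'   in (0, 1].
#' @param time Elapsed time (any consistent unit; k is per that unit).
#' @return Decay rate k >= 0.
#' @export
mass_loss_to_k <- function(fraction_remaining, time) {
  if (any(fraction_remaining <= 0) || any(fraction_remaining > 1)) {
    abort("fraction_remaining must lie in (0, 1].")
  }
  stopifnot(all(time > 0))
  -log(fraction_remaining) / time
}

#' Approximate missing standard deviations from the mean-SD relationship
#'
#' Fits an ordinary least-squares line sd = a + b * mean on records where both
#' are known and predicts the SD for records where it is missing.  Predictions
#' are floored at a small positive constant so downstream pooled SDs stay
#' positive.
#'
#' @param target_means Means of the records lacking an SD.
#' @param known_means,known_sds Means and SDs of the records where both are
#'   reported (at least 3 pairs, with variation in the means).
#' @param floor Lower bound for predictions (default 1e-6).
#' @return Predicted SDs, one per `target_means`.
#' @export
approximate_sd <- function(target_means, known_means, known_sds, floor = 1e-6) {
  stopifnot(length(known_means) == length(known_sds))
  if (length(known_means) < 3) {
    abort(paste("Fewer than 3 known (mean, sd) pairs: cannot approximate SDs;",
                "exclude the record instead."),
          class = "befmeta_degenerate")
  }
  if (sd(known_means) == 0) {
    abort("Known means are constant: mean-SD regression undefined.",
          class = "befmeta_degenerate")
  }
  fit <- lm(known_sds ~ known_means)
  pred <- unname(coef(fit)[1] + coef(fit)[2] * target_means)
  pmax(pred, floor)
}

#' Log response ratio effect size
#'
#' lnRR = log(mean_t / mean_c), with delta-method variance
#' sd_t^2 / (n_t mean_t^2) + sd_c^2 / (n_c mean_c^2).  Used as the alternative
#' effect-size metric in sensitivity analyses; requires strictly positive
#' means.
#'
#' @inheritParams hedges_d
#' @return A named list with `lnRR` and `var_lnRR`.
#' @export
log_response_ratio <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  if (mean_t <= 0 || mean_c <= 0) {
    abort("Log response ratio requires strictly positive group means.",
          class = "befmeta_degenerate")
  }
  list(lnRR = log(mean_t / mean_c),
       var_lnRR = sd_t^2 / (n_t * mean_t^2) + sd_c^2 / (n_c * mean_c^2))
}

# Columns carried from an observation table onto the effect-size table.
effect_meta_cols <- c("case_study_id", "publication_id", "driver", "design",
                      "response", "taxon_group", "diversity_metric",
                      "study_type", "decomposition_metric", "link_key")

#' Build an effect-size table from raw observation records
#'
#' Routes every observation through the appropriate effect-size chain:
#' control-treatment records via Hedges' d, then d-to-r conversion, then the
#' Fisher z transform; gradient records via the Pearson correlation of
#' level-wise means with concentrations, then Fisher z.  Sampling variances
#' are 1/(n_eff - 3), where n_eff is the total sample size (control-treatment)
#' or the number of gradient levels.  `mass_remaining` decomposition responses
#' are sign-flipped so that a positive z always means the response increases
#' with the driver level.  Records that fail (zero pooled SD, constant
#' gradients, nonpositive means under lnRR, missing SDs that cannot be
#' approximated) are excluded, not fatal; exclusions are returned as an
#' attribute.
#'
#' @param records A data frame of observations, one row per group or gradient
#'   level (long format): columns `case_study_id`, `publication_id`, `driver`,
#'   `design` ("control_treatment" or "gradient"), `response`, `taxon_group`,
#'   `diversity_metric`, `study_type`, `decomposition_metric`, `link_key`,
#'   `obs_id`, plus per-row `group` ("control"/"treatment") or `concentration`,
#'   and `mean`, `sd`, `n`.  An optional `time_point` column triggers
#'   last-time-point filtering.
#' @param effect_metric `"fisher_z"` (default) or `"lnRR"` (control-treatment
#'   records only; gradient records are excluded under lnRR).
#' @param approx_missing_sd Approximate missing SDs from the within-dataset
#'   mean-SD regression (default TRUE).
#'
#' @return A tibble with one row per observation: `obs_id`, the grouping and
#'   moderator columns, `z` (or `lnRR` in column `z`), `var_z`, `n_eff`,
#'   `method`, `sd_approximated`, `direction_flipped`.  Attribute
#'   `"exclusions"` is a tibble of dropped `obs_id`s with reasons.
#' @export
build_effect_table <- function(records, effect_metric = c("fisher_z", "lnRR"),
                               approx_missing_sd = TRUE) {
  effect_metric <- match.arg(effect_metric)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(empty_effect_table())
  }
  stopifnot("obs_id" %in% names(records))

  # keep only the last time point per observation
  if ("time_point" %in% names(records) && !all(is.na(records$time_point))) {
    records <- records |>
      dplyr::group_by(.data$obs_id) |>
      dplyr::filter(is.na(.data$time_point) |
                      .data$time_point == max(.data$time_point)) |>
      dplyr::ungroup()
  }

  if (approx_missing_sd && effect_metric == "fisher_z") {
    records <- impute_missing_sds(records)
  } else if (!"sd_approximated" %in% names(records)) {
    records$sd_approximated <- FALSE
  }

  rows <- split(records, records$obs_id)
  out <- vector("list", length(rows))
  excl <- list()
  for (i in seq_along(rows)) {
    rec <- rows[[i]]
    res <- tryCatch(effect_from_record(rec, effect_metric),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        obs_id = rec$obs_id[1], reason = conditionMessage(res))
    } else {
      out[[i]] <- res
    }
  }
  tab <- dplyr::bind_rows(out)
  if (nrow(tab) == 0) tab <- empty_effect_table()
  attr(tab, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(obs_id = character(), reason = character())
  tab
}

empty_effect_table <- function() {
  tibble::tibble(obs_id = character(),
                 !!!setNames(rep(list(character()), length(effect_meta_cols)),
                             effect_meta_cols),
                 z = numeric(), var_z = numeric(), n_eff = numeric(),
                 method = character(), sd_approximated = logical(),
                 direction_flipped = logical())
}

# One observation -> one effect-size row.
effect_from_record <- function(rec, effect_metric) {
  design <- rec$design[1]
  meta <- rec[1, intersect(effect_meta_cols, names(rec))]
  sd_flag <- isTRUE(any(rec$sd_approximated))
  if (design == "control_treatment") {
    stopifnot(nrow(rec) == 2, all(c("control", "treatment") %in% rec$group))
    ct <- rec[match(c("treatment", "control"), rec$group), ]
    if (any(is.na(ct$sd))) {
      abort("Missing standard deviation and no approximation available.")
    }
    if (effect_metric == "lnRR") {
      lr <- log_response_ratio(ct$mean[1], ct$sd[1], ct$n[1],
                               ct$mean[2], ct$sd[2], ct$n[2])
      z <- lr$lnRR; v <- lr$var_lnRR; n_eff <- sum(ct$n); method <- "lnRR"
    } else {
      hd <- hedges_d(ct$mean[1], ct$sd[1], ct$n[1],
                     ct$mean[2], ct$sd[2], ct$n[2])
      r <- d_to_r(hd$d, ct$n[1], ct$n[2])
      n_eff <- sum(ct$n)
      z <- fisher_z(r); v <- var_z(n_eff); method <- "hedges_chain"
    }
  } else if (design == "gradient") {
    if (effect_metric == "lnRR") {
      abort("Gradient records have no control/treatment pair for lnRR.")
    }
    r <- gradient_r(rec$concentration, rec$mean)
    n_eff <- nrow(rec)
    z <- fisher_z(r); v <- var_z(n_eff); method <- "gradient_pearson"
  } else {
    abort(sprintf("Unknown design '%s'.", design))
  }
  flipped <- identical(meta$decomposition_metric, "mass_remaining")
  if (isTRUE(flipped)) z <- -z
  dplyr::bind_cols(tibble::tibble(obs_id = rec$obs_id[1]), meta,
                   tibble::tibble(z = z, var_z = v, n_eff = n_eff,
                                  method = method,
                                  sd_approximated = sd_flag,
                                  direction_flipped = isTRUE(flipped)))
}

# Fit sd ~ mean within each driver x response-family dataset and fill gaps.
impute_missing_sds <- function(records) {
  if (!"sd" %in% names(records)) abort("Records need an `sd` column.")
  records$sd_approximated <- FALSE
  fam <- ifelse(records$response == "decomposition", "decomposition",
                "biodiversity")
  grp <- paste(records$driver, fam)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    miss <- idx[is.na(records$sd[idx])]
    if (!length(miss)) next
    known <- idx[!is.na(records$sd[idx]) & !is.na(records$mean[idx])]
    pred <- tryCatch(
      approximate_sd(records$mean[miss], records$mean[known],
                     records$sd[known]),
      error = function(e) NULL)
    if (is.null(pred)) next  # leave NA; the record is excluded downstream
    records$sd[miss] <- pred
    records$sd_approximated[miss] <- TRUE
  }
  records
}
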