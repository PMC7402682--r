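#' Pair decomposition effects with their matched biodiversity effects
#'
#' Joins each litter-decomposition effect size to the biodiversity or
#' abundance effect sizes sharing its `link_key` (the same measurement, e.g.
#' one litterbag reported for several taxonomic groups).
#'
#' @param effects Effect-size tibble with columns `obs_id`, `link_key`,
#'   `response`, `z`, `var_z`, `case_study_id`, `driver`, moderators and
#'   (optionally) `intensity`.
#' @return A paired tibble, one row per (decomposition measurement, candidate
#'   biodiversity effect): `link_key`, `case_study_id`, `driver`, moderators,
#'   `intensity`, `zB`, `var_zB`, `obs_id_B`, `zLD`, `var_zLD`, `obs_id_LD`.
#'   Attribute `"unmatched"` lists decomposition effects without a partner.
#' @export
pair_effects <- function(effects) {
  effects <- tibble::as_tibble(effects)
  dec <- effects |>
    dplyr::filter(.data$response == "decomposition") |>
    dplyr::select("link_key", zLD = "z", var_zLD = "var_z",
                  obs_id_LD = "obs_id",
                  dplyr::any_of("intensity"))
  bio <- effects |>
    dplyr::filter(.data$response != "decomposition") |>
    dplyr::select("link_key", "case_study_id", "driver", "response",
                  "study_type", "taxon_group", "diversity_metric",
                  zB = "z", var_zB = "var_z", obs_id_B = "obs_id")
  paired <- dplyr::inner_join(bio, dec, by = "link_key")
  attr(paired, "unmatched") <- setdiff(dec$link_key, bio$link_key)
  paired
}

#' Split an effect-size table into the four analysis datasets
#'
#' Partitions the biodiversity/abundance effects by driver type and response
#' family, pairing each subset with its matched decomposition effects:
#' stressor-diversity, stressor-abundance, nutrient-diversity,
#' nutrient-abundance.
#'
#' @inheritParams pair_effects
#' @return A named list of four paired tibbles (see [pair_effects()]).
#'   Attribute `"unmatched"` lists decomposition measurements with no
#'   biodiversity partner (retained for grand-mean analyses only).
#' @export
split_datasets <- function(effects) {
  paired <- pair_effects(effects)
  out <- list()
  for (drv in c("stressor", "nutrient")) {
    for (resp in c("diversity", "abundance")) {
      out[[paste(drv, resp, sep = "_")]] <- paired |>
        dplyr::filter(.data$driver == drv, .data$response == resp)
    }
  }
  attr(out, "unmatched") <- attr(paired, "unmatched")
  out
}

#' Flag extreme effect sizes by the boxplot-whisker rule
#'
#' Flags values below Q1 - 1.5 IQR or above Q3 + 1.5 IQR, with quartiles by
#' linear interpolation (`stats::quantile` type 7).
#'
#' @param x Numeric vector (at least 4 values; otherwise nothing is flagged,
#'   with a warning).
#' @return Logical vector, `TRUE` for extremes.
#' @export
flag_extremes <- function(x) {
  if (length(x) < 4) {
    warn("Fewer than 4 values: no extremes flagged.")
    return(rep(FALSE, length(x)))
  }
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete inference chain on an effect-size table:
#' first-level meta-analyses of the three response variables (driver as
#' moderator, case-study random intercept) with grand means and Wald tests;
#' publication-bias diagnostics (Egger regressions, funnel data) per dataset;
#' the four resampled piecewise SEMs with mediation tests;
#' biodiversity-decomposition meta-regressions on measurement-averaged
#' effects; second-level intensity and moderator meta-regressions; and the
#' requested sensitivity reruns (excluding approximated SDs, excluding
#' extreme effect sizes).
#'
#' @param data Either a `sim_dataset` (from [simulate_effect_table()]), an
#'   effect-size data frame (columns `z`, `var_z`, `case_study_id`, `driver`,
#'   `response`, moderators, `link_key`, `intensity`), or a list with
#'   `records` and `compound_levels` (raw summaries, routed through
#'   [build_effect_table()] and [add_intensity()] first).
#' @param iterations SEM resampling iterations (default 1000).
#' @param seed Integer seed for the resampling streams.
#' @param sensitivity Character subset of `c("drop_approx_sd",
#'   "drop_extremes", "lnRR_rerun")`; the log-response-ratio rerun applies
#'   only when raw records are supplied (the alternative metric needs group
#'   means, not ready-made z values).
#' @param log_base Log base for intensity standardization of raw input.
#' @return A list of class `analysis_report`: `grand_means`,
#'   `driver_tests`, `bias`, `sem` (per-dataset full/reduced/mediation),
#'   `bef_regressions`, `intensity_regressions`, `moderators`, `sensitivity`,
#'   `exclusions`, and `meta` (seed, iterations, counts).
#' @export
run_pipeline <- function(data, iterations = 1000, seed = 1L,
                         sensitivity = c("drop_approx_sd", "drop_extremes"),
                         log_base = 10) {
  exclusions <- tibble::tibble(obs_id = character(), reason = character())
  raw_records <- NULL
  if (inherits(data, "sim_dataset")) {
    effects <- data$observations
  } else if (is.data.frame(data)) {
    effects <- tibble::as_tibble(data)
  } else if (is.list(data) && !is.null(data$records)) {
    raw_records <- data
    effects <- build_effect_table(data$records)
    exclusions <- attr(effects, "exclusions")
    if (!is.null(data$compound_levels)) {
      effects <- add_intensity(effects, data$compound_levels,
                               log_base = log_base)
    }
  } else {
    abort("Unrecognized input: need a sim_dataset, an effect table, or raw records.")
  }
  required <- c("obs_id", "z", "var_z", "case_study_id", "driver", "response",
                "link_key")
  if (length(miss <- setdiff(required, names(effects)))) {
    abort(sprintf("Input is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }

  report <- analyze_effects(effects, iterations = iterations, seed = seed)
  report$exclusions <- exclusions

  # sensitivity reruns never touch the primary tables
  sens <- list()
  if ("drop_approx_sd" %in% sensitivity && "sd_approximated" %in% names(effects) &&
      any(effects$sd_approximated)) {
    sens$drop_approx_sd <-
      analyze_effects(dplyr::filter(effects, !.data$sd_approximated),
                      iterations = iterations, seed = seed, core_only = TRUE)
  }
  if ("drop_extremes" %in% sensitivity) {
    ext <- effects |>
      dplyr::group_by(.data$driver, .data$response) |>
      dplyr::mutate(extreme = flag_extremes(.data$z)) |>
      dplyr::ungroup()
    if (any(ext$extreme)) {
      sens$drop_extremes <-
        analyze_effects(dplyr::filter(ext, !.data$extreme),
                        iterations = iterations, seed = seed, core_only = TRUE)
    } else {
      sens$drop_extremes <- "no extreme values; primary results apply"
    }
  }
  if ("lnRR_rerun" %in% sensitivity) {
    if (is.null(raw_records)) {
      sens$lnRR_rerun <- "raw records not supplied; lnRR rerun skipped"
    } else {
      lnrr <- build_effect_table(raw_records$records, effect_metric = "lnRR")
      if (!is.null(raw_records$compound_levels)) {
        lnrr <- add_intensity(lnrr, raw_records$compound_levels,
                              log_base = log_base)
      }
      sens$lnRR_rerun <- analyze_effects(lnrr, iterations = iterations,
                                         seed = seed, core_only = TRUE)
    }
  }
  report$sensitivity <- sens
  report$meta <- list(seed = seed, iterations = iterations,
                      n_observations = nrow(effects),
                      n_studies = length(unique(effects$case_study_id)))
  structure(report, class = "analysis_report")
}

# The primary analysis chain on a ready effect-size table.  core_only skips
# the SEMs (used by the sensitivity reruns, which the mediation conclusions
# are checked against at the grand-mean/regression level).
analyze_effects <- function(effects, iterations, seed, core_only = FALSE) {
  has_intensity <- "intensity" %in% names(effects) &&
    !all(is.na(effects$intensity))

  # first-level meta-analysis per response variable
  gm <- list(); drv_tests <- list(); bias <- list()
  for (resp in intersect(c("diversity", "abundance", "decomposition"),
                         unique(effects$response))) {
    dat <- dplyr::filter(effects, .data$response == resp)
    fit <- tryCatch(fit_meta(dat, z ~ driver), error = function(e) NULL)
    if (is.null(fit)) next
    gm[[resp]] <- dplyr::mutate(grand_means(fit), response = resp,
                                .before = 1)
    drv_tests[[resp]] <- tibble::tibble(response = resp, QM = fit$QM,
                                        df = fit$QM_df, p = fit$QM_p,
                                        tau2 = fit$sigma2[["study"]],
                                        k_studies = fit$n_studies,
                                        k_obs = fit$n)
  }
  for (drv in unique(effects$driver)) {
    for (resp in unique(effects$response)) {
      dat <- dplyr::filter(effects, .data$driver == drv,
                           .data$response == resp)
      eg <- tryCatch(egger_test(dat), error = function(e) NULL)
      if (!is.null(eg)) {
        bias[[paste(drv, resp, sep = "_")]] <-
          dplyr::mutate(eg, driver = drv, response = resp, .before = 1)
      }
    }
  }
  out <- list(grand_means = dplyr::bind_rows(gm),
              driver_tests = dplyr::bind_rows(drv_tests),
              bias = dplyr::bind_rows(bias),
              funnel = funnel_data(effects))

  datasets <- split_datasets(effects)
  out$unmatched <- attr(datasets, "unmatched")

  # biodiversity-decomposition meta-regressions on measurement-averaged
  # biodiversity effects (simple mean across duplicates)
  bef <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    if (nrow(d) < 5) next
    avg <- d |>
      dplyr::group_by(.data$link_key, .data$case_study_id, .data$zLD,
                      .data$var_zLD) |>
      dplyr::summarise(zB = mean(.data$zB), .groups = "drop")
    fit <- tryCatch(fit_meta(avg, zLD ~ zB, variance = "var_zLD"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    bef[[nm]] <- tibble::tibble(dataset = nm,
                                slope = fit$coefficients[["zB"]],
                                se = fit$se[["zB"]], QM = fit$QM,
                                p = fit$QM_p, k_obs = fit$n)
  }
  out$bef_regressions <- dplyr::bind_rows(bef)

  # second-level meta-regressions: intensity slopes and categorical moderators
  if (has_intensity) {
    ir <- list()
    for (drv in unique(effects$driver)) {
      for (resp in unique(effects$response)) {
        dat <- dplyr::filter(effects, .data$driver == drv,
                             .data$response == resp,
                             !is.na(.data$intensity))
        if (nrow(dat) < 5 || sd(dat$intensity) == 0) next
        fit <- tryCatch(fit_meta(dat, z ~ intensity),
                        error = function(e) NULL)
        if (is.null(fit)) next
        ir[[paste(drv, resp)]] <- tibble::tibble(
          driver = drv, response = resp,
          slope = fit$coefficients[["intensity"]],
          se = fit$se[["intensity"]], QM = fit$QM, p = fit$QM_p,
          k_studies = fit$n_studies, k_obs = fit$n)
      }
    }
    out$intensity_regressions <- dplyr::bind_rows(ir)
  }
  mods <- list()
  for (drv in unique(effects$driver)) {
    for (resp in intersect(c("diversity", "abundance"),
                           unique(effects$response))) {
      dat <- dplyr::filter(effects, .data$driver == drv,
                           .data$response == resp)
      terms <- c("taxon_group", "study_type",
                 if (resp == "diversity") "diversity_metric")
      for (tm in terms) {
        if (length(unique(dat[[tm]])) < 2) next
        fit <- tryCatch(fit_meta(dat, as.formula(paste("z ~", tm))),
                        error = function(e) NULL)
        if (is.null(fit)) next
        mods[[paste(drv, resp, tm)]] <-
          grand_means(fit) |>
          dplyr::mutate(driver = drv, response = resp, moderator = tm,
                        QM = fit$QM, QM_p = fit$QM_p, .before = 1)
      }
    }
  }
  out$moderators <- dplyr::bind_rows(mods)

  if (!core_only && has_intensity) {
    sems <- list()
    for (nm in names(datasets)) {
      d <- datasets[[nm]]
      if (nrow(d) < 10 || length(unique(d$case_study_id)) < 4) next
      kind <- if (grepl("diversity", nm)) "diversity" else "abundance"
      sems[[nm]] <- tryCatch(
        run_sem(d, kind = kind, iterations = iterations, seed = seed),
        error = function(e) e)
    }
    out$sem <- sems
  }
  out
}

#' Write an analysis report to disk
#'
#' Writes every tabular component of a [run_pipeline()] report as CSV and the
#' run metadata (seed, iterations, SEM fit statistics, mediation verdicts) as
#' JSON, mirroring the tidy coefficient-table layout of meta-analytic
#' appendix tables.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tabs <- Filter(is.data.frame, report)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- report$meta
  if (!is.null(report$sem)) {
    meta$sem <- lapply(report$sem, function(s) {
      if (inherits(s, "error")) return(list(error = conditionMessage(s)))
      list(fisher_C = s$full$fisher_C, C_df = s$full$C_df, C_p = s$full$C_p,
           AIC_full = s$full$AIC, AIC_reduced = s$reduced$AIC,
           mediation_supported = s$mediation$supported,
           indirect_effect = s$full$indirect_effect,
           direct_effect = s$full$direct_effect)
    })
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "run_metadata.json")
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", x$meta$n_observations, "observations,",
      x$meta$n_studies, "studies\n\nGrand means (z scale):\n")
  print(x$grand_means)
  if (!is.null(x$sem) && length(x$sem)) {
    cat("\nMediation verdicts:\n")
    for (nm in names(x$sem)) {
      s <- x$sem[[nm]]
      if (inherits(s, "error")) {
        cat(sprintf("  %s: failed (%s)\n", nm, conditionMessage(s)))
      } else {
        cat(sprintf("  %s: supported = %s (reduced C_p = %.3g, dAIC = %.2f)\n",
                    nm, s$mediation$supported, s$mediation$reduced_C_p,
                    s$mediation$delta_AIC))
      }
    }
  }
  invisible(x)
}
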