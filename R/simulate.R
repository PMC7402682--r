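#' Ground-truth configuration for the synthetic-data generator
#'
#' Collects the generative parameters of the synthetic meta-analytic dataset:
#' grand mean effects (Fisher-z scale) per driver, intensity slopes, the SEM
#' path coefficients, the variance components of the nested study/observation
#' structure, the duplication structure tying several biodiversity effects to
#' one decomposition measurement, moderator category probabilities, and a
#' publication-bias strength.  Defaults emulate a synthesis of ~69 case
#' studies with ~660 observations of stressor and nutrient effects on
#' decomposer diversity, abundance, and litter decomposition.
#'
#' @param n_studies Number of case studies.
#' @param obs_per_study_range Integer (min, max) observations per study.
#' @param driver_mix Proportion of studies assigned the `stressor` driver
#'   (the rest are `nutrient`).
#' @param mu_diversity,mu_abundance Named numeric `c(stressor=, nutrient=)`:
#'   true grand mean biodiversity effects on the z scale per driver.
#' @param beta_intensity Named numeric per driver: true slope of the
#'   biodiversity effect against standardized driver intensity.
#' @param path_b True coefficient from the biodiversity effect to the
#'   decomposition effect (the mediated path).
#' @param path_direct True direct coefficient from intensity to the
#'   decomposition effect.
#' @param tau_study SD of the study-level random intercepts of the
#'   biodiversity and decomposition equations (drawn independently per
#'   equation; with a nonzero mediated path the decomposition effects still
#'   carry study-level dependence on the biodiversity effects, which the SEM
#'   random effects must absorb).
#' @param sigma_obs SD of the measurement-level deviations of the latent
#'   effects (shared by duplicated biodiversity observations).
#' @param n_obs_range Integer (min, max) within-observation sample sizes
#'   (total n behind each effect size; must be >= 4).
#' @param dup_range Integer (min, max) biodiversity observations matched to
#'   each decomposition measurement (min >= 1).
#' @param intensity_range Range of the standardized driver intensity,
#'   drawn uniformly; the default (-2, 3) spans levels well below to well
#'   above environmental quality criteria.
#' @param moderator_probs Named list of probability vectors for `study_type`
#'   (experimental/observational), `taxon_group` (animal/microbe),
#'   `diversity_metric` (richness/diversity_index), and `response`
#'   (diversity/abundance share of biodiversity observations).
#' @param missing_sd_prob Fraction of raw control-treatment records whose SDs
#'   are withheld (exercises SD approximation).
#' @param pub_bias_strength Nonnegative publication-bias suppression strength
#'   (0 = none).
#' @param seed Integer seed.
#'
#' @return A validated list of class `truth_config`.
#' @export
truth_config <- function(n_studies = 69,
                         obs_per_study_range = c(4L, 15L),
                         driver_mix = 0.5,
                         mu_diversity = c(stressor = -0.3, nutrient = 0.05),
                         mu_abundance = c(stressor = -0.25, nutrient = 0.1),
                         beta_intensity = c(stressor = -0.1, nutrient = -0.15),
                         path_b = 0.42,
                         path_direct = -0.05,
                         tau_study = 0.2,
                         sigma_obs = 0.15,
                         n_obs_range = c(4L, 30L),
                         dup_range = c(1L, 4L),
                         intensity_range = c(-2, 3),
                         moderator_probs = list(
                           study_type = c(experimental = 0.5,
                                          observational = 0.5),
                           taxon_group = c(animal = 0.77, microbe = 0.23),
                           diversity_metric = c(richness = 0.6,
                                                diversity_index = 0.4),
                           response = c(diversity = 0.3, abundance = 0.7)),
                         missing_sd_prob = 0.1,
                         pub_bias_strength = 0,
                         seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              obs_per_study_range = as.integer(obs_per_study_range),
              driver_mix = driver_mix, mu_diversity = mu_diversity,
              mu_abundance = mu_abundance, beta_intensity = beta_intensity,
              path_b = path_b, path_direct = path_direct,
              tau_study = tau_study, sigma_obs = sigma_obs,
              n_obs_range = as.integer(n_obs_range),
              dup_range = as.integer(dup_range),
              intensity_range = intensity_range,
              moderator_probs = moderator_probs,
              missing_sd_prob = missing_sd_prob,
              pub_bias_strength = pub_bias_strength,
              seed = as.integer(seed))
  validate_truth_config(cfg)
  structure(cfg, class = "truth_config")
}

validate_truth_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_studies >= 1, tau_study >= 0, sigma_obs >= 0,
              pub_bias_strength >= 0, missing_sd_prob >= 0,
              missing_sd_prob <= 1,
              driver_mix >= 0, driver_mix <= 1)
    for (rg in list(obs_per_study_range, n_obs_range, dup_range,
                    intensity_range)) {
      if (length(rg) != 2 || rg[1] > rg[2]) {
        abort("Ranges must be (min, max) with min <= max.")
      }
    }
    if (dup_range[1] < 1) abort("dup_range minimum must be at least 1.")
    if (n_obs_range[1] < 4) abort("n_obs_range minimum must be at least 4.")
    for (nm in names(moderator_probs)) {
      pr <- moderator_probs[[nm]]
      if (any(pr < 0) || any(pr > 1) || abs(sum(pr) - 1) > 1e-8) {
        abort(sprintf("moderator_probs$%s must be probabilities summing to 1.",
                      nm))
      }
    }
    for (v in list(mu_diversity, mu_abundance, beta_intensity)) {
      stopifnot(all(c("stressor", "nutrient") %in% names(v)))
    }
  })
  invisible(cfg)
}

# sample() with a length-1 x draws from 1:x; this never does
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Simulate an effect-size table with known ground truth
#'
#' Generates the nested study -> measurement -> observation structure the
#' analysis assumes.  For each study, independent random intercepts
#' \eqn{u_B, u_{LD} \sim N(0, \tau^2_{study})} are drawn; each decomposition
#' measurement gets a driver intensity \eqn{I \sim} Uniform(`intensity_range`)
#' and `dup` matched biodiversity observations.  True biodiversity effects are
#' \eqn{\zeta_B = \mu_{driver,response} + \beta_{driver} I + u_B + \delta}
#' with one measurement-level deviation \eqn{\delta \sim N(0, \sigma^2_{obs})}
#' shared by the measurement's duplicated biodiversity observations (they
#' are alternative metrics of the same community response); true
#' decomposition effects are
#' \eqn{\zeta_{LD} = path_{direct} I + path_b \bar\zeta_B + u_{LD} + N(0,
#' \sigma^2_{obs})}, with \eqn{\bar\zeta_B} the mean latent biodiversity
#' effect of the measurement's matched observations.  Observed effects are
#' \eqn{z \sim N(\zeta, 1/(n-3))} with \eqn{n} drawn from `n_obs_range`.
#'
#' @param config A [truth_config()].
#' @return A list of class `sim_dataset`: `observations` (tibble with one row
#'   per effect-size observation, including the latent `true_z`) and `truth`
#'   (the config).  Deterministic given `config$seed`.
#' @export
simulate_effect_table <- function(config = truth_config()) {
  validate_truth_config(config)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  mp <- config$moderator_probs
  rows <- vector("list", config$n_studies)
  for (i in seq_len(config$n_studies)) {
    sid <- sprintf("study_%03d", i)
    driver <- if (runif(1) < config$driver_mix) "stressor" else "nutrient"
    # independent study intercepts per equation: under a nonzero mediated
    # path the decomposition effect still inherits study-level dependence on
    # the biodiversity effect through path_b * zeta_B, while under a null
    # path the two channels are conditionally independent, which is what the
    # d-separation claims assert
    u_b <- rnorm(1, 0, config$tau_study)
    u_ld <- rnorm(1, 0, config$tau_study)
    study_type <- sample_cat(1, mp$study_type)
    target <- resample(config$obs_per_study_range[1]:config$obs_per_study_range[2], 1)

    made <- 0L
    link <- 0L
    srows <- list()
    while (made < target) {
      link <- link + 1L
      lkey <- sprintf("%s_m%02d", sid, link)
      dup <- resample(config$dup_range[1]:config$dup_range[2], 1)
      # truncate the last measurement so the study hits its observation target
      dup <- max(min(dup, target - made - 1L), 1L)
      intensity <- runif(1, config$intensity_range[1], config$intensity_range[2])
      response <- sample_cat(dup, mp$response)
      taxon <- sample_cat(dup, mp$taxon_group)
      metric <- ifelse(response == "diversity",
                       sample_cat(dup, mp$diversity_metric), "not_applicable")
      mu <- ifelse(response == "diversity",
                   config$mu_diversity[driver], config$mu_abundance[driver])
      # the measurement-level deviation is shared by the duplicated
      # biodiversity observations: they are alternative metrics of the same
      # underlying community response in the same measurement
      zeta_b <- mu + config$beta_intensity[driver] * intensity + u_b +
        rnorm(1, 0, config$sigma_obs)
      zeta_ld <- config$path_direct * intensity +
        config$path_b * mean(zeta_b) + u_ld + rnorm(1, 0, config$sigma_obs)
      n_bio <- resample(config$n_obs_range[1]:config$n_obs_range[2], dup,
                        replace = TRUE)
      n_ld <- resample(config$n_obs_range[1]:config$n_obs_range[2], 1)
      srows[[link]] <- tibble::tibble(
        case_study_id = sid, publication_id = sid, driver = driver,
        study_type = study_type, link_key = lkey,
        response = c(response, "decomposition"),
        taxon_group = c(taxon, "not_applicable"),
        diversity_metric = c(metric, "not_applicable"),
        decomposition_metric = c(rep("not_applicable", dup), "k_rate"),
        intensity = intensity,
        true_z = unname(c(zeta_b, zeta_ld)),
        n_eff = c(n_bio, n_ld))
      made <- made + dup + 1L
    }
    rows[[i]] <- dplyr::bind_rows(srows)
  }
  obs <- dplyr::bind_rows(rows)
  obs$var_z <- 1 / (obs$n_eff - 3)
  obs$z <- rnorm(nrow(obs), obs$true_z, sqrt(obs$var_z))
  obs$obs_id <- sprintf("obs_%04d", seq_len(nrow(obs)))
  obs <- obs[c("obs_id", setdiff(names(obs), "obs_id"))]
  out <- structure(list(observations = obs, truth = config),
                   class = "sim_dataset")
  if (config$pub_bias_strength > 0) {
    out <- apply_publication_bias(out, config$pub_bias_strength,
                                  seed = config$seed + 1L)
  }
  out
}

#' Simulate raw study summaries
#'
#' Emits the raw observation records the effect-size module consumes, rather
#' than ready-made effect sizes: control-treatment records (two groups with
#' sampled means, SDs and sizes implying a target Hedges' d) and gradient
#' records (4-8 concentration levels with outcome means constructed to give
#' exactly the target Pearson correlation).  A fraction `missing_sd_prob` of
#' control-treatment records has its SDs withheld, to exercise the mean-SD
#' approximation.  Target correlations come from the same latent model as
#' [simulate_effect_table()].
#'
#' @param config A [truth_config()].
#' @return A list of class `sim_raw`: `records` (long-format observation
#'   table for [build_effect_table()]), `compound_levels` (per-observation
#'   compound concentrations and criteria for [add_intensity()]), `truth`,
#'   and `targets` (per-observation target correlations).
#' @export
simulate_raw_studies <- function(config = truth_config()) {
  sim <- simulate_effect_table(config)
  obs <- sim$observations
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 1000L)

  r_target <- tanh(pmin(pmax(obs$true_z, -2.64), 2.64))  # |r| <= 0.99
  design <- ifelse(runif(nrow(obs)) < 0.5, "control_treatment", "gradient")
  recs <- vector("list", nrow(obs))
  for (k in seq_len(nrow(obs))) {
    meta <- obs[k, c("obs_id", "case_study_id", "publication_id", "driver",
                     "response", "taxon_group", "diversity_metric",
                     "study_type", "decomposition_metric", "link_key")]
    r <- r_target[k]
    if (design[k] == "control_treatment") {
      n_g <- max(ceiling(obs$n_eff[k] / 2), 3)
      d <- 2 * r / sqrt(1 - r^2)           # a = 4 for equal groups
      j <- 1 - 3 / (4 * (2 * n_g - 2) - 1)
      s <- 1
      mu_c <- 10
      mu_t <- mu_c + d * s / j
      sds <- s * sqrt(stats::rchisq(2, n_g - 1) / (n_g - 1))
      means <- rnorm(2, c(mu_c, mu_t), s / sqrt(n_g))
      miss <- runif(1) < config$missing_sd_prob
      recs[[k]] <- dplyr::bind_cols(
        meta[rep(1, 2), ],
        tibble::tibble(design = "control_treatment",
                       group = c("control", "treatment"),
                       concentration = NA_real_,
                       mean = means,
                       sd = if (miss) NA_real_ else sds,
                       n = n_g))
    } else {
      L <- sample(4:8, 1)
      conc <- 10^seq(-1, 1, length.out = L)
      e <- rnorm(L)
      e <- stats::residuals(lm(e ~ conc))    # orthogonal to the gradient
      xs <- (conc - mean(conc)) / sd(conc)
      y <- 10 + r * xs + sqrt(max(1 - r^2, 0)) * e / sd(e)
      recs[[k]] <- dplyr::bind_cols(
        meta[rep(1, L), ],
        tibble::tibble(design = "gradient", group = NA_character_,
                       concentration = conc, mean = y, sd = 1,
                       n = max(ceiling(obs$n_eff[k] / L), 3)))
    }
  }
  records <- dplyr::bind_rows(recs)

  # dominant compound at the observation's intensity plus a weaker bystander
  compound_levels <- dplyr::bind_rows(
    tibble::tibble(obs_id = obs$obs_id, compound = "primary",
                   conc_treatment = 10^obs$intensity, conc_criteria = 1),
    tibble::tibble(obs_id = obs$obs_id, compound = "secondary",
                   conc_treatment = 10^(obs$intensity - runif(nrow(obs), 0.5, 2)),
                   conc_criteria = 1))
  structure(list(records = records, compound_levels = compound_levels,
                 truth = config,
                 targets = tibble::tibble(obs_id = obs$obs_id, r = r_target,
                                          true_z = obs$true_z)),
            class = "sim_raw")
}

#' Apply publication bias to a synthetic dataset
#'
#' Retains each observation with a probability that increases with its
#' one-sided significance \eqn{s = z/SE}:
#' \eqn{p_{keep} = logistic(s - 1.645)^{strength}}.  Strength 0 retains
#' everything; larger strengths suppress nonsignificant and negative effects
#' increasingly harshly, producing the funnel asymmetry Egger's regression
#' is meant to detect.
#'
#' @param dataset A `sim_dataset` (from [simulate_effect_table()]) or a plain
#'   effect-size data frame with `z` and `var_z`.
#' @param strength Suppression strength (>= 0).
#' @param seed Integer seed for the retention draws.
#' @return Same type as the input, with suppressed rows removed.
#' @export
apply_publication_bias <- function(dataset, strength, seed = 1L) {
  if (strength < 0) abort("Bias strength must be nonnegative.")
  is_sim <- inherits(dataset, "sim_dataset")
  obs <- if (is_sim) dataset$observations else tibble::as_tibble(dataset)
  if (strength == 0) return(dataset)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- obs$z / sqrt(obs$var_z)
  p_keep <- stats::plogis(s - 1.645)^strength
  keep <- runif(nrow(obs)) < p_keep
  obs <- obs[keep, ]
  if (is_sim) {
    dataset$observations <- obs
    dataset
  } else {
    obs
  }
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic effect-size dataset: %d observations, %d studies (seed %d)\n",
              nrow(x$observations),
              length(unique(x$observations$case_study_id)), x$truth$seed))
  print(x$observations, ...)
  invisible(x)
}
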